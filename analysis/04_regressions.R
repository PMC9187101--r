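#!/usr/bin/env Rscript
# Stage 4: bivariate regression screens of multifunctionality against every
# diversity and soil predictor, in linear and quadratic (single-peak) form.

library(desertMF)

divpd <- utils::read.delim("results/diversity_pd.tsv")
fm <- utils::read.delim("results/functions_mf.tsv")
soil <- add_cn_ratio(read_soil("results/data/soil.tsv"))

plot_table <- data.frame(divpd,
                         soil[match(divpd$plot, soil$plot),
                              c("pH", "SSC", "CN")],
                         MF = fm$MF[match(divpd$plot, fm$plot)])
write_tsv_table(plot_table, "results/plot_table.tsv")

predictors <- c("richness", "shannon", "simpson", "PD", "NRI", "NTI",
                "pH", "SSC", "CN")
screens <- screen_table(plot_table, "MF", predictors)
write_tsv_table(screens, "results/regression_screens.tsv")

lin <- screens[screens$form == "linear", ]
lin <- lin[order(-lin$r2), ]
cat("linear screens of MF, strongest first:\n")
for (i in seq_len(nrow(lin)))
  cat(sprintf("  MF ~ %-9s R2 = %.3f  p = %.2g\n",
              lin$predictor[i], lin$r2[i], lin$p[i]))
quad <- screens[screens$form == "quadratic" & screens$predictor %in%
                  c("NRI", "NTI"), ]
cat("quadratic (single-peak) forms for NRI/NTI: R2 =",
    paste(round(quad$r2, 3), collapse = ", "), "\n")
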