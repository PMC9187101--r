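#!/usr/bin/env Rscript
# Stage 6: random-forest ranking of the four single ecosystem functions by
# their out-of-bag permutation importance for multifunctionality.

library(desertMF)

fm <- utils::read.delim("results/functions_mf.tsv")
imp <- rank_function_importance(fm, n_trees = 500, n_perm = 10, seed = 606)
write_tsv_table(as.data.frame(imp), "results/importance.tsv")
print(imp)
cat("note: MF is the mean of the four functions, so the ranking reflects\n",
    "each function's variance/covariance contribution, not causal weight\n")
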