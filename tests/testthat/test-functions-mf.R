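make_soil <- function(n = 10, seed = 2) {
  set.seed(seed)
  data.frame(plot = sprintf("p%02d", 1:n),
             TP = runif(n, 0.3, 0.8), TN = runif(n, 0.3, 0.9),
             AP = runif(n, 4, 12), AN = runif(n, 10, 40),
             SOC = runif(n, 3, 12), SWC = runif(n, 5, 25),
             pH = runif(n, 7, 9), SSC = runif(n, 1, 8),
             stringsAsFactors = FALSE)
}

test_that("z-score standardization uses the sample SD and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(rep(4, 5), "SOC"), "SOC")
  z <- zscore(rnorm(20))
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("single functions are built from the prescribed indicators", {
  soil <- make_soil()
  h <- stats::setNames(runif(10, 0.5, 3), soil$plot)
  fm <- single_functions(soil, h)
  expect_equal(fm$carbon_stocks, zscore(soil$SOC))
  expect_equal(fm$water_regulation, zscore(soil$SWC))
  expect_equal(fm$wood_production, zscore(unname(h[soil$plot])))
  # every column standardized
  for (col in mf_function_names()) {
    expect_equal(mean(fm[[col]]), 0, tolerance = 1e-9)
    expect_equal(sd(fm[[col]]), 1, tolerance = 1e-9)
  }
  # perfectly collinear nutrient constituents collapse to the common z pattern
  soil2 <- soil
  soil2$TN <- 2 * soil2$TP + 1
  soil2$AP <- 10 * soil2$TP
  soil2$AN <- 5 * soil2$TP - 0.5
  fm2 <- single_functions(soil2, h)
  expect_equal(fm2$nutrient_cycling, zscore(soil2$TP), tolerance = 1e-9)
})

test_that("plot order equivariance: permuting plots permutes outputs", {
  soil <- make_soil()
  h <- stats::setNames(runif(10, 0.5, 3), soil$plot)
  fm <- multifunctionality(single_functions(soil, h))
  set.seed(8)
  perm <- sample(10)
  fmp <- multifunctionality(single_functions(soil[perm, ], h))
  expect_equal(fmp$MF, fm$MF[perm], tolerance = 1e-12)
})

test_that("multifunctionality is the mean of the four standardized functions", {
  fm <- data.frame(plot = c("a", "b", "c"),
                   nutrient_cycling = c(0, 1, 1),
                   carbon_stocks = c(0, -1, 1),
                   water_regulation = c(0, 1, 0),
                   wood_production = c(0, -1, 0))
  out <- multifunctionality(fm)
  expect_equal(out$MF, c(0, 0, 0.5))
  expect_error(multifunctionality(fm[, 1:3]), "lacks columns")
})

test_that("MF is invariant to affine rescaling of raw indicators", {
  soil <- make_soil(12, seed = 5)
  h <- stats::setNames(runif(12, 0.5, 3), soil$plot)
  base <- multifunctionality(single_functions(soil, h))
  for (v in c("TP", "AN", "SOC", "SWC")) {
    soil2 <- soil
    soil2[[v]] <- 3.7 * soil2[[v]] + 11
    alt <- multifunctionality(single_functions(soil2, h))
    expect_lt(max(abs(as.matrix(alt[, -1]) - as.matrix(base[, -1]))), 1e-9)
  }
  # scaling heights too
  alt_h <- multifunctionality(single_functions(soil, 2.2 * h))
  expect_lt(max(abs(alt_h$MF - base$MF)), 1e-9)
})

test_that("MF has mean zero and SD at most one, and responds to dominance", {
  soil <- make_soil(15, seed = 6)
  h <- stats::setNames(runif(15, 0.5, 3), soil$plot)
  fm <- multifunctionality(single_functions(soil, h))
  expect_equal(mean(fm$MF), 0, tolerance = 1e-9)
  expect_lte(sd(fm$MF), 1 + 1e-9)
  # raising every raw constituent of one plot above all others makes it the max
  soil2 <- soil
  for (v in c("TP", "TN", "AP", "AN", "SOC", "SWC"))
    soil2[[v]][3] <- max(soil2[[v]]) * 2
  h2 <- h; h2[3] <- max(h) * 2
  fm2 <- multifunctionality(single_functions(soil2, h2))
  expect_equal(which.max(fm2$MF), 3L)
})

test_that("layer aggregation averages depths and C:N derives from SOC/TN", {
  soil <- data.frame(plot = rep(c("a", "b"), each = 3),
                     layer = rep(c("0-10", "10-20", "20-30"), 2),
                     SOC = c(6, 4, 2, 9, 6, 3), TN = c(0.6, 0.4, 0.2, 0.9, 0.6, 0.3))
  agg <- aggregate_layers(soil)
  expect_equal(agg$SOC, c(4, 6))
  top <- aggregate_layers(soil, "first")
  expect_equal(top$SOC, c(6, 9))
  withcn <- add_cn_ratio(agg)
  expect_equal(withcn$CN, agg$SOC / agg$TN)
  # supplied C:N is left untouched
  agg$CN <- c(1, 2)
  expect_equal(add_cn_ratio(agg)$CN, c(1, 2))
})
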