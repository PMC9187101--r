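sim_chain <- function(n, a = 0.6, b = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + sqrt(1 - a^2) * rnorm(n)
  y <- b * m + sqrt(1 - b^2) * rnorm(n)
  data.frame(x = x, m = m, y = y)
}

test_that("path model specification validates the DAG", {
  m <- path_model(c("x -> m", "m -> y"))
  expect_equal(m$exogenous, "x")
  expect_setequal(m$endogenous, c("m", "y"))
  expect_error(path_model(c("a -> b", "b -> a")), "cycle")
  expect_error(path_model("a b"), "malformed")
  expect_error(path_model("a -> a"), "self-loop")
})

test_that("saturated models fit perfectly: df = 0, chi-square = 0, CFI = 1", {
  set.seed(21)
  d <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
  names(d) <- c("a", "b", "c", "e")
  sat <- path_model(c("a -> b", "a -> c", "a -> e", "b -> c", "b -> e", "c -> e"))
  fit <- fit_path_model(sat, d)
  expect_equal(fit$df, 0)
  expect_equal(fit$chisq, 0)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$implied, fit$sample, tolerance = 1e-9)
})

test_that("a generating chain is recovered with small bias", {
  d <- sim_chain(5000, a = 0.6, b = 0.5, seed = 31)
  fit <- fit_path_model(path_model(c("x -> m", "m -> y")), d)
  co <- fit$coefficients
  expect_equal(co$estimate[co$from == "x" & co$to == "m"], 0.6, tolerance = 0.05)
  expect_equal(co$estimate[co$from == "m" & co$to == "y"], 0.5, tolerance = 0.05)
  expect_equal(indirect_effect(fit, "x", "y"), 0.30, tolerance = 0.05)
  expect_equal(fit$df, 1)
  # a single spurious edge between independent normals is near zero
  set.seed(32)
  d2 <- data.frame(u = rnorm(2000), v = rnorm(2000))
  f2 <- fit_path_model(path_model("u -> v"), d2)
  expect_lt(abs(f2$coefficients$estimate[1]), 3 / sqrt(2000))
})

test_that("indirect effects sum coefficient products over directed paths", {
  # two parallel 2-edge routes built from known structural coefficients
  set.seed(41)
  n <- 20000
  x <- rnorm(n)
  m1 <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  m2 <- -0.4 * x + sqrt(1 - 0.16) * rnorm(n)
  y <- 0.2 * m1 + 0.1 * m2 + 0.3 * x + 0.8 * rnorm(n)
  d <- data.frame(x = x, m1 = m1, m2 = m2, y = y)
  fit <- fit_path_model(path_model(c("x -> m1", "x -> m2", "m1 -> y",
                                     "m2 -> y", "x -> y")), d)
  co <- fit$coefficients
  grab <- function(f, t) co$estimate[co$from == f & co$to == t]
  # oracle: explicit enumeration of the two length-2 paths
  oracle <- grab("x", "m1") * grab("m1", "y") + grab("x", "m2") * grab("m2", "y")
  expect_equal(indirect_effect(fit, "x", "y"), oracle, tolerance = 1e-12)
  expect_equal(total_effect(fit, "x", "y"), oracle + grab("x", "y"),
               tolerance = 1e-12)
  expect_equal(indirect_effect(fit, "y", "x"), 0)  # no path
})

test_that("total effects obey Wright's path-tracing consistency", {
  set.seed(51)
  d <- as.data.frame(matrix(rnorm(300 * 4), 300, 4))
  names(d) <- c("a", "b", "c", "e")
  d$b <- 0.5 * d$a + d$b
  d$c <- 0.4 * d$a - 0.3 * d$b + d$c
  d$e <- 0.2 * d$a + 0.6 * d$c + d$e
  sat <- path_model(c("a -> b", "a -> c", "a -> e", "b -> c", "b -> e", "c -> e"))
  fit <- fit_path_model(sat, d)
  # in a fully recursive model the total effect of the source equals the
  # marginal standardized slope (the correlation)
  for (v in c("b", "c", "e"))
    expect_equal(total_effect(fit, "a", v), std_slope(d$a, d[[v]]),
                 tolerance = 1e-6)
})

test_that("chi-square of a correctly specified model is calibrated to its df", {
  chis <- vapply(1:400, function(r) {
    d <- sim_chain(400, a = 0.6, b = 0.5, seed = 5000 + r)
    fit_path_model(path_model(c("x -> m", "m -> y")), d)$chisq
  }, numeric(1))
  expect_equal(mean(chis), 1, tolerance = 0.15)  # df = 1
})

test_that("degenerate inputs are rejected with informative errors", {
  m <- path_model(c("x -> m", "m -> y"))
  d <- sim_chain(50)
  expect_error(fit_path_model(m, d[, c("x", "m")]), "lacks model variables")
  d2 <- d; d2$m <- d2$x  # singular correlation matrix
  expect_error(fit_path_model(m, d2), "singular")
})
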