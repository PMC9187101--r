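test_that("phylogeny simulation is reproducible and properly labeled", {
  t1 <- simulate_phylogeny(12, 1, seed = 2)
  t2 <- simulate_phylogeny(12, 1, seed = 2)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(t1$tip.label, sprintf("sp%03d", 1:12))
  t3 <- simulate_phylogeny(2, 1, seed = 2)
  depths <- diag(ape::vcv(t3))
  expect_lt(max(depths) - min(depths), 1e-9)   # cherry with equal depths
})

test_that("trait simulation is Brownian on the log scale", {
  tr <- simulate_phylogeny(15, 1, seed = 3)
  flat <- simulate_traits(tr, sigma2 = 0, root = log(2), seed = 4)
  expect_equal(flat$height, rep(2, 15), tolerance = 1e-12)
  # variance of log-heights scales with sigma2 (Monte Carlo over replicates)
  v_small <- mean(vapply(1:40, function(s)
    var(log(simulate_traits(tr, 0.1, 0, seed = s)$height)), numeric(1)))
  v_large <- mean(vapply(1:40, function(s)
    var(log(simulate_traits(tr, 1, 0, seed = s)$height)), numeric(1)))
  expect_gt(v_large, 5 * v_small)
  # siblings are more similar than random pairs on average
  d <- patristic_distances(tr)
  sib_gap <- function(s) {
    h <- log(simulate_traits(tr, 0.5, 0, seed = 100 + s)$height)
    names(h) <- tr$tip.label
    pairs <- t(utils::combn(tr$tip.label, 2))
    gaps <- abs(h[pairs[, 1]] - h[pairs[, 2]])
    close <- d[pairs] < stats::median(d[pairs])
    mean(gaps[close]) - mean(gaps[!close])
  }
  expect_lt(mean(vapply(1:40, sib_gap, numeric(1))), 0)
})

test_that("the simulated landscape satisfies all table invariants", {
  land <- simulate_landscape(sim_config(n_plots = 30, pool_size = 15, seed = 6))
  expect_equal(dim(land$community), c(30, 15))
  expect_true(all(land$community >= 0))
  expect_true(all(rowSums(land$community) > 0))
  expect_true(all(land$soil$SWC >= 0 & land$soil$SWC <= 100))
  expect_true(all(land$soil$pH > 0 & land$soil$pH < 14))
  expect_true(all(land$soil$CN > 0))
  expect_true(all(land$traits$height > 0))
  expect_setequal(colnames(land$community), land$tree$tip.label)
  # deterministic from the master seed
  land2 <- simulate_landscape(sim_config(n_plots = 30, pool_size = 15, seed = 6))
  expect_identical(land$community, land2$community)
  expect_identical(land$soil, land2$soil)
})

test_that("soil variables follow the configured gradient couplings", {
  land <- simulate_landscape(sim_config(n_plots = 60, seed = 8))
  g <- land$gradient
  expect_lt(cor(g, land$soil$SWC), -0.8)   # drier away from the river
  expect_gt(cor(g, land$soil$SSC), 0.6)    # saltier
  expect_lt(cor(g, land$soil$pH), -0.5)    # alkaline riparian soils
  expect_lt(cor(g, land$soil$SOC), -0.8)
})

test_that("emitted files round-trip through the pipeline readers cleanly", {
  land <- simulate_landscape(sim_config(n_plots = 12, pool_size = 10, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_landscape(land, dir)
  expect_true(all(file.exists(paths)))
  tree <- parse_newick(paste(readLines(paths["tree"]), collapse = ""))
  comm <- read_community(paths["community"])
  traits <- read_traits(paths["traits"])
  soil <- read_soil(paths["soil"])
  expect_equal(unname(comm), unname(land$community))
  issues <- validate_inputs(tree, comm, traits, soil)
  expect_equal(nrow(issues), 0L)
})

test_that("strong phylogenetic clustering yields positive NRI landscapes", {
  tr <- two_clade_tree(10, stem = 40, seed = 12)
  cfg <- sim_config(n_plots = 40, pool_size = 20, clustering = 1,
                    niche_width = 0.12, seed = 13)
  land <- simulate_landscape(cfg, tree = tr)
  d <- patristic_distances(tr)
  keep <- rowSums(land$community > 0) >= 2
  nri <- nri_table(land$community[keep, ], d, n_rand = 99, seed = 14)
  expect_gt(mean(nri$nri, na.rm = TRUE), 0)
})

test_that("when SOC dominates MF variance the ranking places carbon first", {
  # each function's contribution to var(MF) is cov(function, MF)/4; among
  # replicate landscapes where carbon stocks is the clearly dominant
  # contributor (>= 5% covariance margin over the runner-up), the forest
  # must rank it first
  res <- vapply(1:25, function(r) {
    land <- simulate_landscape(sim_config(soil_coefs = soc_dominant_coefs(),
                                          height_niche_slope = 0.3,
                                          seed = 400 + r))
    heights <- stats::setNames(land$traits$height, land$traits$species)
    cwm_h <- cwm_table(land$community, heights)
    fm <- multifunctionality(single_functions(land$soil, cwm_h))
    covs <- vapply(mf_function_names(), function(v) cov(fm[[v]], fm$MF),
                   numeric(1))
    s <- sort(covs, decreasing = TRUE)
    imp <- rank_function_importance(fm, n_trees = 300, n_perm = 6,
                                    seed = 500 + r)
    c(premise = names(which.max(covs)) == "carbon_stocks" &&
        (s[1] - s[2]) / s[1] > 0.05,
      recovered = imp$feature[1] == "carbon_stocks")
  }, c(premise = FALSE, recovered = FALSE))
  premise <- as.logical(res["premise", ])
  expect_gte(sum(premise), 8)
  expect_gte(mean(res["recovered", premise]), 0.9)
})
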