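three_sp_dist <- function() {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d
}

test_that("MPD and MNTD match hand-computed values on small communities", {
  d <- three_sp_dist()
  expect_equal(mpd(c("A", "B"), d), 2)
  expect_equal(mpd(c("A", "B", "C"), d), 10 / 3)
  expect_equal(mntd(c("A", "B"), d), 2)
  expect_equal(mntd(c("A", "B", "C"), d), 8 / 3)
  expect_true(is.na(mpd("A", d)))       # undefined marker, not an error
  expect_true(is.na(mntd("A", d)))
})

test_that("MPD/MNTD equal exhaustive enumeration on all small communities", {
  tr <- random_tree(8, seed = 21)
  d <- patristic_distances(tr)
  pool <- rownames(d)
  for (k in 2:5) {
    combos <- utils::combn(pool, k)
    for (i in seq_len(ncol(combos))) {
      sp <- combos[, i]
      expect_equal(mpd(sp, d), oracle_mpd(sp, d))
      expect_equal(mntd(sp, d), oracle_mntd(sp, d))
    }
  }
  # cross-check one community against picante
  comm <- matrix(0, 1, 8, dimnames = list("p1", pool))
  comm[1, 1:5] <- 1
  expect_equal(mpd(pool[1:5], d), unname(picante::mpd(comm, d)))
  expect_equal(mntd(pool[1:5], d), unname(picante::mntd(comm, d)))
})

test_that("abundance-weighted MPD/MNTD match the weighted oracles", {
  tr <- random_tree(7, seed = 31)
  d <- patristic_distances(tr)
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    sp <- sample(rownames(d), k)
    ab <- stats::setNames(rpois(k, 3) + 1, sp)
    expect_equal(mpd(ab, d, abundance_weighted = TRUE),
                 unname(oracle_mpd_weighted(ab, d)))
    expect_equal(mntd(ab, d, abundance_weighted = TRUE),
                 unname(oracle_mntd_weighted(ab, d)))
  }
})

test_that("taxa-shuffle null converges to the exhaustive permutation mean", {
  d <- three_sp_dist()
  # community of 2 from a 3-species pool: exact null mean over all label
  # permutations is the mean pair distance (2+4+4)/3
  null <- null_distribution("mpd", c("A", "B"), d, n_rand = 4000, seed = 9)
  expect_equal(null$mean, 10 / 3, tolerance = 0.05)
  # determinism
  n2 <- null_distribution("mpd", c("A", "B"), d, n_rand = 50, seed = 123)
  n3 <- null_distribution("mpd", c("A", "B"), d, n_rand = 50, seed = 123)
  expect_identical(n2$samples, n3$samples)
  # community spanning the full pool: the shuffle cannot change the metric
  n4 <- null_distribution("mpd", c("A", "B", "C"), d, n_rand = 30, seed = 1)
  expect_equal(n4$sd, 0)
  expect_match(n4$flag, "zero-variance")
})

test_that("NRI follows the negated-SES sign convention", {
  d <- three_sp_dist()
  res <- ses_metric(c("A", "B"), d, "mpd", n_rand = 199, seed = 11)
  null <- null_distribution("mpd", c("A", "B"), d, 199, seed = 11)
  expect_equal(res$ses, -1 * (res$obs - null$mean) / null$sd)
  expect_gt(res$ses, 0)  # A,B are the close pair: clustered, so positive NRI
  expect_true(res$p > 0 && res$p <= 1)

  # clade-confined community on a deep two-clade tree is clustered
  tr <- two_clade_tree(8, stem = 50, seed = 3)
  dd <- patristic_distances(tr)
  res2 <- ses_metric(tr$tip.label[1:5], dd, "mpd", n_rand = 199, seed = 4)
  expect_gt(res2$ses, 1)
  # NTI is also positive, though weaker: random draws often still find a
  # same-clade nearest neighbour, so only NRI is pushed far above 1
  res3 <- ses_metric(tr$tip.label[1:5], dd, "mntd", n_rand = 199, seed = 4)
  expect_gt(res3$ses, 0)
})

test_that("branch-length scaling scales MPD/MNTD but leaves NRI/NTI unchanged", {
  tr <- random_tree(10, seed = 41)
  d <- patristic_distances(tr)
  sp <- rownames(d)[1:4]
  r1 <- ses_metric(sp, d, "mpd", n_rand = 99, seed = 17)
  r2 <- ses_metric(sp, 3.5 * d, "mpd", n_rand = 99, seed = 17)
  expect_equal(r2$obs, 3.5 * r1$obs)
  expect_equal(r2$ses, r1$ses, tolerance = 1e-12)
  m1 <- ses_metric(sp, d, "mntd", n_rand = 99, seed = 17)
  m2 <- ses_metric(sp, 3.5 * d, "mntd", n_rand = 99, seed = 17)
  expect_equal(m2$obs, 3.5 * m1$obs)
  expect_equal(m2$ses, m1$ses, tolerance = 1e-12)
})

test_that("per-plot SES tables are reproducible and flag degenerate cases", {
  tr <- random_tree(9, seed = 51)
  d <- patristic_distances(tr)
  comm <- matrix(0, 4, 9, dimnames = list(paste0("p", 1:4), rownames(d)))
  comm[1, 1:3] <- 1
  comm[2, c(2, 5, 7, 8)] <- c(2, 1, 1, 3)
  comm[3, 4] <- 1          # singleton: undefined metric
  comm[4, ] <- 1           # full pool: zero-variance null
  t1 <- nri_table(comm, d, n_rand = 99, seed = 5)
  t2 <- nri_table(comm, d, n_rand = 99, seed = 5)
  expect_identical(t1, t2)
  expect_match(t1$flag[t1$plot == "p3"], "fewer than 2")
  expect_match(t1$flag[t1$plot == "p4"], "zero-variance")
  expect_false(any(is.na(t1$nri[t1$plot %in% c("p1", "p2")])))
  # abundance weighting changes the observed metric where abundances differ
  tw <- nri_table(comm[2, , drop = FALSE], d, n_rand = 99, seed = 5,
                  abundance_weighted = TRUE)
  expect_false(isTRUE(all.equal(tw$obs, t1$obs[t1$plot == "p2"])))
})
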