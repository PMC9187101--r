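#' Mean pairwise phylogenetic distance of a community
#'
#' Unweighted: mean patristic distance over all unordered pairs of member
#' species. Abundance-weighted: \eqn{\sum_{i \ne j} p_i p_j d_{ij} /
#' \sum_{i \ne j} p_i p_j}.
#'
#' @param members Character vector of member species, or a named non-negative
#'   abundance vector (names = species) when `abundance_weighted = TRUE`.
#' @param dist Patristic distance matrix (see [patristic_distances()]).
#' @param abundance_weighted Weight pairs by relative abundances.
#' @return MPD in branch-length units; `NA` (undefined) for communities with
#'   fewer than two species.
#' @export
mpd <- function(members, dist, abundance_weighted = FALSE) {
  m <- resolve_members(members, dist, abundance_weighted)
  if (length(m$idx) < 2L) return(NA_real_)
  d <- dist[m$idx, m$idx, drop = FALSE]
  if (!abundance_weighted) {
    mean(d[lower.tri(d)])
  } else {
    w <- outer(m$ab, m$ab)
    diag(w) <- 0
    sum(w * d) / sum(w)
  }
}

#' Mean nearest-taxon distance of a community
#'
#' Unweighted: mean, over member species, of the distance to the nearest other
#' member. Abundance-weighted: \eqn{\sum_i p_i \min_{j \ne i} d_{ij}}.
#'
#' @inheritParams mpd
#' @return MNTD in branch-length units; `NA` for communities with fewer than
#'   two species.
#' @export
mntd <- function(members, dist, abundance_weighted = FALSE) {
  m <- resolve_members(members, dist, abundance_weighted)
  if (length(m$idx) < 2L) return(NA_real_)
  d <- dist[m$idx, m$idx, drop = FALSE]
  diag(d) <- Inf
  nearest <- apply(d, 1, min)
  if (!abundance_weighted) mean(nearest) else sum(m$ab * nearest)
}

resolve_members <- function(members, dist, abundance_weighted) {
  pool <- rownames(dist)
  if (is.null(pool)) stop("distance matrix must have species names")
  if (is.character(members)) {
    sp <- unique(members)
    ab <- rep(1, length(sp))
  } else {
    if (is.null(names(members))) stop("abundance vector must be named by species")
    members <- members[members > 0]
    sp <- names(members)
    ab <- as.numeric(members)
  }
  idx <- match(sp, pool)
  if (anyNA(idx)) stop("species not in distance matrix: ",
                       paste(sp[is.na(idx)], collapse = ", "))
  list(idx = idx, ab = ab / sum(ab))
}

#' Null distribution of MPD/MNTD under the taxa-shuffle model
#'
#' Each randomization permutes tip labels uniformly across the full species
#' pool of the distance matrix (Phylocom-style "phylogeny shuffle"), which for
#' a community of k species amounts to re-assigning its k abundances to k
#' species drawn without replacement from the pool; community size is
#' preserved by construction. The metric is recomputed for every
#' randomization.
#'
#' @param metric `"mpd"` or `"mntd"`.
#' @param members As in [mpd()].
#' @param dist Patristic distance matrix for the full species pool.
#' @param n_rand Number of randomizations (>= 2).
#' @param seed Integer seed; the draw is fully reproducible.
#' @param abundance_weighted Passed to the metric.
#' @return List with `mean`, `sd` (sample SD, n-1 denominator), and the
#'   vector `samples` of length `n_rand`.
#' @export
null_distribution <- function(metric = c("mpd", "mntd"), members, dist,
                              n_rand = 999, seed = 1L,
                              abundance_weighted = FALSE) {
  metric <- match.arg(metric)
  stopifnot(n_rand >= 2)
  fn <- if (metric == "mpd") mpd else mntd
  m <- resolve_members(members, dist, abundance_weighted)
  k <- length(m$idx)
  if (k < 2L) stop("metric undefined for fewer than 2 species")
  # canonical (sorted) pool order so draws do not depend on how the
  # distance matrix happens to be ordered
  pool <- sort(rownames(dist))
  samples <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      sp <- pool[sample.int(length(pool), k)]
      mem <- if (abundance_weighted) stats::setNames(m$ab, sp) else sp
      fn(mem, dist, abundance_weighted)
    }, numeric(1))
  })
  out <- list(mean = mean(samples), sd = stats::sd(samples), samples = samples)
  if (out$sd == 0) out$flag <- "zero-variance null (community spans the whole pool?)"
  out
}

#' Standardized effect size of a phylogenetic structure metric (NRI / NTI)
#'
#' NRI is the negated standardized effect size of MPD against the taxa-shuffle
#' null; NTI is the analogue for MNTD:
#' \deqn{NRI = -1 \times (MPD_{obs} - \overline{MPD_{null}}) / SD(MPD_{null})}
#' Positive values indicate phylogenetic clustering (observed distances
#' smaller than the null expectation), negative values overdispersion.
#'
#' @param members Community membership as in [mpd()].
#' @param dist Patristic distance matrix for the full pool.
#' @param metric `"mpd"` (gives NRI) or `"mntd"` (gives NTI).
#' @param n_rand Number of randomizations (999 by default).
#' @param seed Integer seed.
#' @param abundance_weighted Weight by abundances.
#' @return One-row `data.frame`: `metric`, `obs`, `null_mean`, `null_sd`,
#'   `ses` (NRI or NTI), `p` (two-sided rank-based), `p_low` (one-sided,
#'   low tail), `n_rand`, `seed`, `flag`.
#' @export
ses_metric <- function(members, dist, metric = c("mpd", "mntd"),
                       n_rand = 999, seed = 1L, abundance_weighted = FALSE) {
  metric <- match.arg(metric)
  fn <- if (metric == "mpd") mpd else mntd
  obs <- fn(members, dist, abundance_weighted)
  if (is.na(obs)) {
    return(data.frame(metric = metric, obs = NA_real_, null_mean = NA_real_,
                      null_sd = NA_real_, ses = NA_real_, p = NA_real_,
                      p_low = NA_real_, n_rand = n_rand, seed = seed,
                      flag = "undefined: fewer than 2 species",
                      stringsAsFactors = FALSE))
  }
  null <- null_distribution(metric, members, dist, n_rand, seed,
                            abundance_weighted)
  flag <- ""
  if (null$sd > 0) {
    ses <- -1 * (obs - null$mean) / null$sd
  } else {
    ses <- NA_real_
    flag <- "undefined: zero-variance null"
  }
  r_le <- sum(null$samples <= obs)
  r_ge <- sum(null$samples >= obs)
  p_low <- (r_le + 1) / (n_rand + 1)
  p_high <- (r_ge + 1) / (n_rand + 1)
  p <- min(1, 2 * min(p_low, p_high))
  data.frame(metric = metric, obs = obs, null_mean = null$mean,
             null_sd = null$sd, ses = ses, p = p, p_low = p_low,
             n_rand = n_rand, seed = seed, flag = flag,
             stringsAsFactors = FALSE)
}

#' Net relatedness index / nearest taxon index for every plot
#'
#' Runs [ses_metric()] per plot of a community matrix, with an independent,
#' deterministically derived RNG stream per plot so that serial and
#' plot-parallel runs agree.
#'
#' @param comm Plot-by-species abundance matrix.
#' @param dist Patristic distance matrix for the full species pool (all
#'   community species must be present).
#' @param metric `"mpd"` (NRI) or `"mntd"` (NTI).
#' @param n_rand Randomizations per plot.
#' @param seed Master seed; per-plot seeds are drawn from it.
#' @param abundance_weighted Weight by abundances.
#' @return `data.frame` with one row per plot: `plot` plus the [ses_metric()]
#'   columns.
#' @export
ses_table <- function(comm, dist, metric = c("mpd", "mntd"), n_rand = 999,
                      seed = 1L, abundance_weighted = FALSE) {
  metric <- match.arg(metric)
  comm <- as_community_matrix(comm)
  comm <- drop_empty_plots(comm)
  missing <- setdiff(colnames(comm), rownames(dist))
  if (length(missing))
    stop("community species absent from distance matrix: ",
         paste(missing, collapse = ", "))
  plot_seeds <- derive_seeds(seed, nrow(comm))
  rows <- lapply(seq_len(nrow(comm)), function(i) {
    x <- comm[i, ]
    members <- if (abundance_weighted) {
      stats::setNames(x, colnames(comm))[x > 0]
    } else {
      colnames(comm)[x > 0]
    }
    cbind(data.frame(plot = rownames(comm)[i], stringsAsFactors = FALSE),
          ses_metric(members, dist, metric, n_rand, plot_seeds[i],
                     abundance_weighted))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname ses_table
#' @export
nri_table <- function(comm, dist, n_rand = 999, seed = 1L,
                      abundance_weighted = FALSE) {
  out <- ses_table(comm, dist, "mpd", n_rand, seed, abundance_weighted)
  names(out)[names(out) == "ses"] <- "nri"
  out
}

#' @rdname ses_table
#' @export
nti_table <- function(comm, dist, n_rand = 999, seed = 1L,
                      abundance_weighted = FALSE) {
  out <- ses_table(comm, dist, "mntd", n_rand, seed, abundance_weighted)
  names(out)[names(out) == "ses"] <- "nti"
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-unit seed streams below 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}
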