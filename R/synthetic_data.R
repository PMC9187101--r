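#' Configuration for the synthetic desert-landscape generator
#'
#' Defaults emulate the study design the pipeline targets: 80 plots of
#' 30 m x 30 m along a water/salt gradient running away from a river in an
#' arid desert basin, a regional pool of 30 woody/herbaceous desert species
#' with a Yule phylogeny and log-Brownian plant heights, and soil variables
#' responding linearly to the latent gradient with Gaussian noise. Soil
#' coefficients are set so that soil organic carbon tracks the gradient most
#' tightly (carbon stocks dominate MF variance, the situation reported for
#' arid desert systems), followed by water content, then the nutrient pool,
#' with wood production linked only indirectly through community turnover.
#'
#' @param n_plots Number of plots (default 80).
#' @param pool_size Species-pool size (default 30).
#' @param birth_rate Yule speciation rate (default 1; tree depth is in
#'   arbitrary evolutionary-distance units).
#' @param bm_sigma2 Brownian variance of log plant height per unit branch
#'   length (default 0.25).
#' @param bm_root Root value of log height (default `log(1.5)`, i.e. a 1.5 m
#'   tall ancestral shrub).
#' @param niche_width SD of the Gaussian niche response on the latent
#'   gradient (default 0.15, gradient scaled to [0, 1]): communities turn over along the gradient and single plots hold a modest subset of the pool, as in real desert vegetation.
#' @param height_niche_slope Coupling of log plant height to niche position
#'   (default 0.6): species whose optima lie toward the dry, saline end of
#'   the gradient are shorter (riparian phreatophyte trees near the river,
#'   dwarf shrubs far from it), so community-weighted height declines along
#'   the gradient like the soil-borne functions do.
#' @param clustering Phylogenetic autocorrelation of niche optima in [0, 1]:
#'   0 = optima independent of the tree, 1 = optima fully Brownian (default
#'   0.5).
#' @param lambda_max Expected abundance of a species at its niche optimum
#'   (Poisson mean, default 12 individuals).
#' @param soil_coefs `data.frame(var, intercept, slope, sd)` giving each soil
#'   variable as `intercept + slope * g + N(0, sd)` of the latent gradient g.
#' @param seed Master seed; all randomized quantities derive per-purpose
#'   streams from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_plots = 80, pool_size = 30, birth_rate = 1,
                       bm_sigma2 = 0.25, bm_root = log(1.5),
                       niche_width = 0.15, clustering = 0.5, lambda_max = 12,
                       height_niche_slope = 0.6,
                       soil_coefs = default_soil_coefs(), seed = 1L) {
  stopifnot(n_plots >= 4, pool_size >= 4, niche_width > 0, lambda_max > 0,
            clustering >= 0, clustering <= 1, all(soil_coefs$sd > 0))
  structure(list(n_plots = n_plots, pool_size = pool_size,
                 birth_rate = birth_rate, bm_sigma2 = bm_sigma2,
                 bm_root = bm_root, niche_width = niche_width,
                 clustering = clustering, lambda_max = lambda_max,
                 height_niche_slope = height_niche_slope,
                 soil_coefs = soil_coefs, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_soil_coefs <- function() {
  # g in [0,1] runs from river edge (wet, fresh) to distal desert (dry, saline)
  data.frame(
    var       = c("SWC", "SSC", "pH", "SOC", "TN",  "TP",  "AP", "AN"),
    intercept = c(22,    2.5,   8.4,  9,     0.65,  0.60,  9,    26),
    slope     = c(-14,   5,     -0.8, -6,    -0.28, -0.18, -4,   -11),
    sd        = c(2.5,   0.8,   0.25, 0.35,  0.12,  0.07,  2.5,  7),
    stringsAsFactors = FALSE
  )
}

#' Soil coefficients for a carbon-dominated landscape scenario
#'
#' A variant of [default_soil_coefs()] in which soil organic carbon tracks
#' the water/salt gradient tightly while the nutrient pool and soil water
#' content are only moderately coupled to it (larger measurement noise).
#' Because the multifunctionality index is the mean of four standardized
#' functions, a function's contribution to its variance is
#' `cov(function, MF)/4 = (1 + sum of its correlations with the others)/4`;
#' under this scenario carbon stocks is usually the clearly dominant
#' contributor, which is the premise of the importance-recovery checks.
#' Pair with a weak `height_niche_slope` (0.3) so wood production stays
#' subordinate.
#'
#' @return `data.frame(var, intercept, slope, sd)` as for
#'   [default_soil_coefs()].
#' @export
soc_dominant_coefs <- function() {
  sc <- default_soil_coefs()
  sc$sd[sc$var == "SWC"] <- 7
  sc$sd[sc$var == "TN"] <- 0.24
  sc$sd[sc$var == "TP"] <- 0.16
  sc$sd[sc$var == "AP"] <- 3.5
  sc$sd[sc$var == "AN"] <- 9.5
  sc
}

#' Simulate an ultrametric Yule phylogeny for the species pool
#'
#' @param pool_size Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @return `"phylo"` tree with tips `sp001..spN` and equal root-to-tip depths.
#' @export
simulate_phylogeny <- function(pool_size, birth_rate = 1, seed = 1L) {
  stopifnot(pool_size >= 2)
  tr <- with_seed(seed, ape::rphylo(pool_size, birth = birth_rate, death = 0))
  tr$tip.label <- sprintf("sp%03d", seq_len(pool_size))
  tr
}

#' Simulate plant heights with phylogenetic signal
#'
#' Brownian motion of log height along the tree (so sibling species have
#' similar heights), exponentiated to guarantee positive heights.
#'
#' @param tree A `"phylo"` tree.
#' @param sigma2 Brownian variance per unit branch length.
#' @param root Root value on the log scale.
#' @param seed Integer seed.
#' @return `data.frame(species, height)` (height in metres).
#' @export
simulate_traits <- function(tree, sigma2 = 0.25, root = log(1.5), seed = 1L) {
  validate_phylogeny(tree)
  stopifnot(sigma2 >= 0)
  logh <- with_seed(seed, ape::rTraitCont(tree, model = "BM",
                                          sigma = sqrt(sigma2),
                                          root.value = root))
  data.frame(species = tree$tip.label,
             height = exp(as.numeric(logh[tree$tip.label])),
             stringsAsFactors = FALSE)
}

#' Simulate the 80-plot desert landscape
#'
#' Each plot receives a latent water/salt gradient value g (evenly spaced on
#' [0, 1], mimicking transects running away from the river). Soil variables
#' are linear in g plus Gaussian noise (`soil_coefs`). Species have Gaussian
#' niche responses on g; niche optima are a mixture of a Brownian (tree-
#' correlated) component and an independent uniform component, weighted by
#' `clustering`. Abundances are Poisson draws around
#' `lambda_max * exp(-(g - optimum)^2 / (2 niche_width^2))`. Plots that come
#' up empty are redrawn up to 50 times, then flagged.
#'
#' @param config A [sim_config()].
#' @param tree Optional phylogeny (simulated from the config when omitted).
#' @return List: `community` (plot x species matrix), `soil` (`data.frame`
#'   incl. computed `CN`), `traits`, `tree`, `gradient`, and `params` (the
#'   generating values, for recovery tests).
#' @export
simulate_landscape <- function(config = sim_config(), tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 5L)
  if (is.null(tree))
    tree <- simulate_phylogeny(config$pool_size, config$birth_rate, seeds[1])
  validate_phylogeny(tree)
  n_sp <- ape::Ntip(tree)
  g <- seq(0, 1, length.out = config$n_plots)
  plots <- sprintf("Q%03d", seq_len(config$n_plots))

  # niche optima: Brownian component blended with an independent draw
  optima <- with_seed(seeds[3], {
    bm <- as.numeric(ape::rTraitCont(tree, model = "BM", sigma = 1,
                                     root.value = 0))
    bm <- (rank(bm) - 0.5) / n_sp            # tree-correlated, uniform margins
    indep <- stats::runif(n_sp)
    config$clustering * bm + (1 - config$clustering) * indep
  })
  names(optima) <- tree$tip.label

  # Brownian log-heights, tilted by niche position: species of the dry,
  # saline end are shorter (centred at the gradient midpoint so the overall
  # height scale is untouched)
  traits <- simulate_traits(tree, config$bm_sigma2, config$bm_root, seeds[2])
  traits$height <- traits$height *
    exp(-config$height_niche_slope * (optima[traits$species] - 0.5))

  comm <- with_seed(seeds[4], {
    m <- matrix(0L, config$n_plots, n_sp, dimnames = list(plots, tree$tip.label))
    flagged <- character(0)
    for (i in seq_len(config$n_plots)) {
      lam <- config$lambda_max *
        exp(-(g[i] - optima)^2 / (2 * config$niche_width^2))
      row <- stats::rpois(n_sp, lam)
      tries <- 0L
      while (sum(row) == 0L && tries < 50L) {
        row <- stats::rpois(n_sp, lam)
        tries <- tries + 1L
      }
      if (sum(row) == 0L) flagged <- c(flagged, plots[i])
      m[i, ] <- row
    }
    list(m = m, flagged = flagged)
  })
  empty_plots <- comm$flagged
  comm <- comm$m
  if (length(empty_plots))
    warning("plots still empty after retries: ",
            paste(empty_plots, collapse = ", "))

  soil <- with_seed(seeds[5], {
    sc <- config$soil_coefs
    out <- data.frame(plot = plots, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(sc))) {
      x <- sc$intercept[r] + sc$slope[r] * g + stats::rnorm(length(g), 0, sc$sd[r])
      if (sc$var[r] %in% c("SWC", "SSC", "SOC", "TN", "TP", "AP", "AN"))
        x <- pmax(x, 0.01)
      if (sc$var[r] == "SWC") x <- pmin(x, 100)
      if (sc$var[r] == "pH") x <- pmin(pmax(x, 0.1), 13.9)
      out[[sc$var[r]]] <- x
    }
    out
  })
  soil <- add_cn_ratio(soil)

  list(community = comm, soil = soil, traits = traits, tree = tree,
       gradient = stats::setNames(g, plots), empty_plots = empty_plots,
       params = list(config = config, optima = optima, seeds = seeds))
}

#' Write a simulated landscape to the pipeline's file formats
#'
#' Emits the Newick tree and the community/trait/soil tables as
#' tab-separated text, plus a provenance file recording the generating
#' parameters and seeds, into `dir`.
#'
#' @param land A [simulate_landscape()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_landscape <- function(land, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             community = file.path(dir, "community.tsv"),
             traits = file.path(dir, "traits.tsv"),
             soil = file.path(dir, "soil.tsv"),
             provenance = file.path(dir, "provenance.txt"))
  write_newick(land$tree, paths["tree"])
  write_community(land$community, paths["community"])
  write_tsv_table(land$traits, paths["traits"])
  write_tsv_table(land$soil, paths["soil"])
  cfg <- land$params$config
  prov <- c(
    sprintf("generator: desertMF synthetic landscape"),
    sprintf("master_seed: %d", cfg$seed),
    sprintf("derived_seeds: %s", paste(land$params$seeds, collapse = ",")),
    sprintf("n_plots: %d", cfg$n_plots),
    sprintf("pool_size: %d", cfg$pool_size),
    sprintf("birth_rate: %g", cfg$birth_rate),
    sprintf("bm_sigma2: %g", cfg$bm_sigma2),
    sprintf("bm_root: %g", cfg$bm_root),
    sprintf("niche_width: %g", cfg$niche_width),
    sprintf("clustering: %g", cfg$clustering),
    sprintf("lambda_max: %g", cfg$lambda_max),
    "soil_coefs (var intercept slope sd):",
    sprintf("  %s %g %g %g", cfg$soil_coefs$var, cfg$soil_coefs$intercept,
            cfg$soil_coefs$slope, cfg$soil_coefs$sd))
  writeLines(prov, paths["provenance"])
  invisible(paths)
}
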