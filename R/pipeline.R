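#' Configure an end-to-end pipeline run
#'
#' A single configuration object governs the whole analysis: data sources
#' (paths to a Newick tree and community/trait/soil tables, or the synthetic
#' generator), randomization settings, and the path models to fit.
#'
#' @param tree,community,traits,soil Input paths (all four required unless
#'   `synthetic` is given).
#' @param synthetic Optional [sim_config()]; when supplied the landscape is
#'   generated instead of read.
#' @param n_rand Randomizations for NRI/NTI (default 999).
#' @param seed Master seed for every randomized stage.
#' @param abundance_weighted Abundance-weight MPD/MNTD.
#' @param layer_mode Soil depth-layer aggregation, see [aggregate_layers()].
#' @param path_models Named list of edge-string vectors (see [path_model()]);
#'   defaults to the five driver models relating diversity and soil factors
#'   to each single function and to MF.
#' @param n_trees,n_perm Random-forest settings for the importance ranking.
#' @param out_dir Output directory for result tables and the run log.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(tree = NULL, community = NULL, traits = NULL,
                       soil = NULL, synthetic = NULL, n_rand = 999,
                       seed = 1L, abundance_weighted = FALSE,
                       layer_mode = "mean", path_models = default_path_models(),
                       n_trees = 500, n_perm = 10, out_dir = NULL) {
  if (is.null(synthetic)) {
    paths <- c(tree = tree, community = community, traits = traits, soil = soil)
    if (length(paths) < 4)
      stop("supply tree, community, traits and soil paths, or a synthetic config")
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("input files not found: ",
                              paste(missing, collapse = ", "))
  }
  stopifnot(n_rand >= 2)
  structure(list(tree = tree, community = community, traits = traits,
                 soil = soil, synthetic = synthetic, n_rand = n_rand,
                 seed = as.integer(seed),
                 abundance_weighted = abundance_weighted,
                 layer_mode = layer_mode, path_models = path_models,
                 n_trees = n_trees, n_perm = n_perm, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_path_models <- function() {
  list(
    nutrient_cycling = c("CN -> richness", "CN -> nutrient_cycling",
                         "pH -> nutrient_cycling", "PD -> nutrient_cycling",
                         "richness -> nutrient_cycling"),
    carbon_stocks = c("CN -> carbon_stocks", "pH -> carbon_stocks",
                      "PD -> NTI", "NTI -> NRI", "PD -> carbon_stocks",
                      "NTI -> carbon_stocks", "NRI -> carbon_stocks"),
    water_regulation = c("pH -> NRI", "NTI -> NRI", "PD -> NTI",
                         "pH -> water_regulation", "NTI -> water_regulation",
                         "NRI -> water_regulation", "PD -> water_regulation"),
    wood_production = c("CN -> richness", "PD -> wood_production",
                        "richness -> wood_production", "pH -> wood_production",
                        "CN -> wood_production"),
    multifunctionality = c("pH -> PD", "CN -> PD", "pH -> MF", "CN -> MF",
                           "PD -> MF")
  )
}

#' Validate pipeline inputs against each other
#'
#' Cross-checks species sets (community species must be tree tips and have
#' trait values), plot sets (community vs soil), and the range constraints of
#' the soil table (soil water content in [0, 100] %, pH in (0, 14), no
#' negative concentrations).
#'
#' @param tree A `"phylo"` tree.
#' @param comm Plot x species matrix.
#' @param traits `data.frame(species, height)`.
#' @param soil Soil `data.frame`.
#' @return `data.frame(level, message)` of issues (`error` rows make
#'   [run_pipeline()] abort); zero rows when everything is consistent.
#' @export
validate_inputs <- function(tree, comm, traits, soil) {
  issues <- list()
  note <- function(level, msg)
    issues[[length(issues) + 1L]] <<- data.frame(level = level, message = msg,
                                                 stringsAsFactors = FALSE)
  sp <- colnames(comm)
  bad <- setdiff(sp, tree$tip.label)
  if (length(bad)) note("error", paste("community species not in tree:",
                                       paste(bad, collapse = ", ")))
  bad <- setdiff(sp[colSums(comm) > 0], traits$species)
  if (length(bad)) note("error", paste("species without trait values:",
                                       paste(bad, collapse = ", ")))
  soil_plots <- unique(as.character(soil$plot))
  bad <- setdiff(rownames(comm), soil_plots)
  if (length(bad)) note("error", paste("plots missing from soil table:",
                                       paste(bad, collapse = ", ")))
  bad <- setdiff(soil_plots, rownames(comm))
  if (length(bad)) note("warning", paste("soil plots absent from community:",
                                         paste(bad, collapse = ", ")))
  if ("SWC" %in% names(soil) && any(soil$SWC < 0 | soil$SWC > 100))
    note("error", "SWC outside [0, 100] %")
  if ("pH" %in% names(soil) && any(soil$pH <= 0 | soil$pH >= 14))
    note("error", "pH outside (0, 14)")
  for (v in intersect(c("SSC", "SOC", "TP", "AP", "TN", "AN"), names(soil)))
    if (any(soil[[v]] < 0)) note("error", paste(v, "has negative values"))
  if (any(rowSums(comm) == 0))
    note("warning", paste("plots with zero total abundance:",
                          paste(rownames(comm)[rowSums(comm) == 0],
                                collapse = ", ")))
  if (length(issues)) do.call(rbind, issues)
  else data.frame(level = character(0), message = character(0))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate inputs; validate; species diversity and
#' CWM height; Faith's PD and NRI/NTI (taxa-shuffle null); single functions
#' and the multifunctionality index; bivariate regression screens of MF
#' against every predictor; recursive path models; random-forest importance
#' ranking of the four functions. Deterministic given the config.
#'
#' @param config A [run_config()].
#' @return List with `diversity`, `ses_mpd`, `ses_mntd`, `functions`
#'   (function matrix incl. `MF`), `plot_table` (merged per-plot analysis
#'   table), `screens`, `path_fits`, `importance`, `validation`, and `log`
#'   (character vector also written to `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("desertMF %s | R %s.%s", as.character(utils::packageVersion("desertMF")),
                   R.version$major, R.version$minor),
           sprintf("master seed %d, n_rand %d, abundance_weighted %s",
                   config$seed, config$n_rand, config$abundance_weighted))

  if (!is.null(config$synthetic)) {
    land <- simulate_landscape(config$synthetic)
    tree <- land$tree; comm <- land$community
    traits <- land$traits; soil <- land$soil
    log <- c(log, sprintf("synthetic landscape: %d plots, %d species pool, seed %d",
                          config$synthetic$n_plots, config$synthetic$pool_size,
                          config$synthetic$seed))
  } else {
    tree <- parse_newick(paste(readLines(config$tree), collapse = ""))
    comm <- read_community(config$community)
    traits <- read_traits(config$traits)
    soil <- read_soil(config$soil)
    log <- c(log, sprintf("inputs: %s | %s | %s | %s", config$tree,
                          config$community, config$traits, config$soil))
  }
  soil <- aggregate_layers(soil, config$layer_mode)
  soil <- add_cn_ratio(soil)

  val <- validate_inputs(tree, comm, traits, soil)
  for (i in seq_len(nrow(val)))
    log <- c(log, sprintf("validation %s: %s", val$level[i], val$message[i]))
  if (any(val$level == "error"))
    stop("input validation failed:\n  ",
         paste(val$message[val$level == "error"], collapse = "\n  "))

  empty <- rownames(comm)[rowSums(comm) == 0]
  if (length(empty)) {
    log <- c(log, sprintf("excluded empty plots: %s", paste(empty, collapse = ", ")))
    comm <- comm[rowSums(comm) > 0, , drop = FALSE]
  }

  div <- diversity_table(comm)
  heights <- stats::setNames(traits$height, traits$species)
  cwm_h <- cwm_table(comm, heights)

  dist <- patristic_distances(tree)
  pd <- vapply(rownames(comm), function(pl)
    faith_pd(tree, colnames(comm)[comm[pl, ] > 0]), numeric(1))
  seeds <- derive_seeds(config$seed, 2L)
  ses_mpd <- nri_table(comm, dist, config$n_rand, seeds[1],
                       config$abundance_weighted)
  ses_mntd <- nti_table(comm, dist, config$n_rand, seeds[2],
                        config$abundance_weighted)
  und <- c(ses_mpd$plot[ses_mpd$flag != ""], ses_mntd$plot[ses_mntd$flag != ""])
  if (length(und))
    log <- c(log, sprintf("undefined NRI/NTI flags for plots: %s",
                          paste(unique(und), collapse = ", ")))

  soil <- soil[match(rownames(comm), soil$plot), , drop = FALSE]
  fm <- single_functions(soil, cwm_h)
  fm <- multifunctionality(fm)

  plot_table <- data.frame(
    plot = rownames(comm), richness = div$richness, shannon = div$shannon,
    simpson = div$simpson, PD = unname(pd),
    NRI = ses_mpd$nri[match(rownames(comm), ses_mpd$plot)],
    NTI = ses_mntd$nti[match(rownames(comm), ses_mntd$plot)],
    pH = soil$pH, SSC = soil$SSC, CN = soil$CN,
    fm[match(rownames(comm), fm$plot),
       c(mf_function_names(), "MF")],
    stringsAsFactors = FALSE)
  rownames(plot_table) <- NULL

  predictors <- c("richness", "shannon", "simpson", "PD", "NRI", "NTI",
                  "pH", "SSC", "CN")
  screens <- screen_table(plot_table, "MF", predictors)

  path_fits <- lapply(config$path_models, function(edges) {
    fit_path_model(path_model(edges), plot_table)
  })
  for (nm in names(path_fits))
    log <- c(log, sprintf("path model %s: chi2 = %.3f, df = %d, NC = %.3f, CFI = %.3f",
                          nm, path_fits[[nm]]$chisq, path_fits[[nm]]$df,
                          path_fits[[nm]]$nc, path_fits[[nm]]$cfi))

  seeds_rf <- derive_seeds(config$seed + 1L, 1L)
  imp <- rank_function_importance(fm, n_trees = config$n_trees,
                                  n_perm = config$n_perm, seed = seeds_rf[1])
  log <- c(log, paste("importance ranking:", paste(imp$feature, collapse = " > ")),
           "note: MF is the mean of the four functions; importance reflects variance/covariance contribution, not causal weight")

  out <- list(diversity = div, cwm = cwm_h, pd = pd, ses_mpd = ses_mpd,
              ses_mntd = ses_mntd, functions = fm, plot_table = plot_table,
              screens = screens, path_fits = path_fits, importance = imp,
              validation = val, log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(div, file.path(config$out_dir, "diversity.tsv"))
    write_tsv_table(ses_mpd, file.path(config$out_dir, "ses_mpd.tsv"))
    write_tsv_table(ses_mntd, file.path(config$out_dir, "ses_mntd.tsv"))
    write_tsv_table(fm, file.path(config$out_dir, "functions_mf.tsv"))
    write_tsv_table(plot_table, file.path(config$out_dir, "plot_table.tsv"))
    write_tsv_table(screens, file.path(config$out_dir, "regression_screens.tsv"))
    write_tsv_table(as.data.frame(imp), file.path(config$out_dir, "importance.tsv"))
    for (nm in names(path_fits))
      write_tsv_table(path_fits[[nm]]$coefficients,
                      file.path(config$out_dir, sprintf("path_%s.tsv", nm)))
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  out
}
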