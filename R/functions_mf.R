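#' Z-score standardization of a plot-level indicator
#'
#' \eqn{(x - \bar x)/s} with the sample SD (n-1 denominator). All single
#' ecosystem functions are standardized this way before averaging into the
#' multifunctionality index.
#'
#' @param x Numeric vector over plots (length >= 2).
#' @param name Indicator name used in error messages.
#' @return Standardized vector with mean 0 and sample SD 1.
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 plots to standardize ", name)
  if (anyNA(x)) stop("missing values in ", name)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance in ", name, ": cannot z-score")
  (x - mean(x)) / s
}

#' Four single ecosystem functions from soil and trait data
#'
#' Builds the plot-level single-function matrix used throughout the analysis:
#' * nutrient cycling — composite of soil total phosphorus (TP), total
#'   nitrogen (TN), available phosphorus (AP) and ammonium nitrogen (AN);
#'   constituents are z-scored before averaging (their units differ:
#'   g/kg vs mg/kg), switchable to a raw mean via `nutrient_mode`;
#' * carbon stocks — soil organic carbon (SOC);
#' * water regulation — soil water content (SWC);
#' * wood production — community-weighted mean plant height.
#' Every column is (re-)standardized so the returned matrix has mean 0 and
#' sample SD 1 per column.
#'
#' @param soil `data.frame` with a `plot` column and columns `TP`, `TN`,
#'   `AP`, `AN`, `SOC`, `SWC` (one row per plot; see [aggregate_layers()] for
#'   per-depth-layer records).
#' @param cwm_height `data.frame` with columns `plot`, `cwm` (from
#'   [cwm_table()]), or a named vector keyed by plot.
#' @param nutrient_mode `"zscore"` (default: z-score constituents before
#'   averaging) or `"raw"` (average raw values; sensitivity analysis only).
#' @return `data.frame`: `plot`, `nutrient_cycling`, `carbon_stocks`,
#'   `water_regulation`, `wood_production` (all standardized).
#' @export
single_functions <- function(soil, cwm_height, nutrient_mode = c("zscore", "raw")) {
  nutrient_mode <- match.arg(nutrient_mode)
  needed <- c("plot", "TP", "TN", "AP", "AN", "SOC", "SWC")
  missing <- setdiff(needed, names(soil))
  if (length(missing)) stop("soil table lacks columns: ", paste(missing, collapse = ", "))
  if (is.data.frame(cwm_height)) {
    cwm_height <- stats::setNames(cwm_height$cwm, cwm_height$plot)
  }
  plots <- as.character(soil$plot)
  miss <- setdiff(plots, names(cwm_height))
  if (length(miss)) stop("no CWM height for plots: ", paste(miss, collapse = ", "))
  h <- as.numeric(cwm_height[plots])
  for (v in c("TP", "TN", "AP", "AN", "SOC", "SWC")) {
    if (anyNA(soil[[v]])) stop("missing ", v, " for plots: ",
                               paste(plots[is.na(soil[[v]])], collapse = ", "))
  }
  nutrient <- if (nutrient_mode == "zscore") {
    rowMeans(cbind(zscore(soil$TP, "TP"), zscore(soil$TN, "TN"),
                   zscore(soil$AP, "AP"), zscore(soil$AN, "AN")))
  } else {
    rowMeans(soil[, c("TP", "TN", "AP", "AN")])
  }
  data.frame(
    plot = plots,
    nutrient_cycling = zscore(nutrient, "nutrient cycling composite"),
    carbon_stocks = zscore(soil$SOC, "SOC"),
    water_regulation = zscore(soil$SWC, "SWC"),
    wood_production = zscore(h, "CWM height"),
    stringsAsFactors = FALSE
  )
}

#' Averaged ecosystem multifunctionality index
#'
#' The per-plot mean of the standardized single ecosystem functions
#' (the z-score averaging multifunctionality index): with 4 functions,
#' \eqn{MF_a = \frac{1}{4} \sum_i z(f_i)}. The MF column has mean 0 across
#' plots by construction.
#'
#' @param fm Output of [single_functions()] (all four function columns
#'   required).
#' @return `fm` with an added `MF` column.
#' @export
multifunctionality <- function(fm) {
  cols <- mf_function_names()
  missing <- setdiff(cols, names(fm))
  if (length(missing)) stop("function matrix lacks columns: ",
                            paste(missing, collapse = ", "))
  fm$MF <- rowMeans(fm[, cols])
  fm
}

#' @rdname multifunctionality
#' @export
mf_function_names <- function() {
  c("nutrient_cycling", "carbon_stocks", "water_regulation", "wood_production")
}

#' Aggregate per-depth-layer soil records to one row per plot
#'
#' Field soils are often sampled in several depth layers (e.g. 0-10, 10-20,
#' 20-30 cm). Analyses run on one value per plot; the default takes the
#' unweighted mean across layers, `mode = "first"` keeps only the first
#' (topmost) layer.
#'
#' @param soil `data.frame` with `plot`, optionally `layer`, and numeric soil
#'   columns.
#' @param mode `"mean"` or `"first"`.
#' @return One row per plot, layer column removed.
#' @export
aggregate_layers <- function(soil, mode = c("mean", "first")) {
  mode <- match.arg(mode)
  if (!"layer" %in% names(soil)) return(soil)
  vars <- setdiff(names(soil), c("plot", "layer"))
  if (mode == "first") {
    first_layer <- sort(unique(soil$layer))[1]
    out <- soil[soil$layer == first_layer, c("plot", vars)]
  } else {
    out <- stats::aggregate(soil[vars], by = list(plot = soil$plot), FUN = mean)
  }
  out[order(out$plot), , drop = FALSE]
}

#' Carbon-to-nitrogen ratio, computed when not supplied
#'
#' @param soil Soil table with `SOC` and `TN` columns (both g/kg).
#' @return `soil` with a `CN` column (existing `CN` kept untouched).
#' @export
add_cn_ratio <- function(soil) {
  if (!"CN" %in% names(soil)) {
    if (!all(c("SOC", "TN") %in% names(soil)))
      stop("need SOC and TN to compute the C:N ratio")
    if (any(soil$TN <= 0)) stop("TN must be positive to form C:N")
    soil$CN <- soil$SOC / soil$TN
  }
  soil
}
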