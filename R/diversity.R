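#' Relative abundances within a plot
#'
#' Converts raw abundance counts to the proportions \eqn{P_i} used by the
#' Shannon-Wiener, Simpson and community-weighted-mean computations.
#'
#' @param counts Non-negative abundance vector (individuals per species).
#' @return Vector of proportions summing to 1; zero-count species keep 0.
#' @export
relative_abundances <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative abundances")
  tot <- sum(counts)
  if (tot <= 0) stop("degenerate plot: all abundances are zero")
  counts / tot
}

#' Shannon-Wiener diversity index (natural log)
#'
#' \eqn{H' = -\sum_i P_i \ln P_i}, summing over species with \eqn{P_i > 0}.
#'
#' @param p Probability vector (relative abundances).
#' @return H' in nats; 0 for a monoculture, at most \eqn{\ln S}.
#' @export
shannon <- function(p) {
  p <- check_probs(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Simpson dominance index
#'
#' \eqn{F = 1 - \sum_i P_i^2}.
#'
#' @param p Probability vector (relative abundances).
#' @return F in [0, 1 - 1/S].
#' @export
simpson <- function(p) {
  p <- check_probs(p)
  1 - sum(p^2)
}

#' Species richness of a plot
#'
#' @param counts Abundance vector.
#' @return Number of species with abundance > 0.
#' @export
richness <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative abundances")
  if (sum(counts) <= 0) stop("degenerate plot: all abundances are zero")
  sum(counts > 0)
}

#' Community-weighted mean of a trait
#'
#' \eqn{CWM = \sum_i P_i \times trait_i} over the species present in a plot.
#'
#' @param p Named probability vector (relative abundances), or unnamed and
#'   aligned with `traits`.
#' @param traits Trait values; if named, matched to `names(p)`.
#' @return The abundance-weighted mean trait (trait units).
#' @export
cwm <- function(p, traits) {
  p <- check_probs(p)
  if (!is.null(names(p)) && !is.null(names(traits))) {
    need <- names(p)[p > 0]
    missing <- setdiff(need, names(traits))
    if (length(missing))
      stop("missing trait values for species: ", paste(missing, collapse = ", "))
    traits <- traits[names(p)]
  } else if (length(traits) != length(p)) {
    stop("traits and abundances have different lengths and no names to match on")
  }
  traits <- as.numeric(traits)
  if (anyNA(traits[p > 0])) stop("missing trait value for a present species")
  sum(p[p > 0] * traits[p > 0])
}

check_probs <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || anyNA(p)) stop("invalid probability vector")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  p
}

#' Per-plot species diversity table
#'
#' Computes richness, Shannon-Wiener H' (nats) and the Simpson dominance
#' index for every plot of a community matrix. Plots with zero total
#' abundance are dropped with a warning rather than aborting the pipeline.
#'
#' @param comm Plot-by-species abundance matrix (rownames = plots,
#'   colnames = species).
#' @return `data.frame` with columns `plot`, `richness`, `shannon`,
#'   `simpson`.
#' @export
diversity_table <- function(comm) {
  comm <- as_community_matrix(comm)
  comm <- drop_empty_plots(comm)
  res <- lapply(rownames(comm), function(pl) {
    p <- relative_abundances(comm[pl, ])
    data.frame(plot = pl, richness = sum(comm[pl, ] > 0),
               shannon = shannon(p), simpson = simpson(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Community-weighted mean trait per plot
#'
#' @param comm Plot-by-species abundance matrix.
#' @param traits Named vector (or 2-column data.frame species/value) of trait
#'   values, e.g. plant height in metres.
#' @return `data.frame` with columns `plot`, `cwm`.
#' @export
cwm_table <- function(comm, traits) {
  comm <- as_community_matrix(comm)
  comm <- drop_empty_plots(comm)
  traits <- as_trait_vector(traits)
  out <- data.frame(
    plot = rownames(comm),
    cwm = vapply(rownames(comm), function(pl) {
      p <- relative_abundances(comm[pl, ])
      names(p) <- colnames(comm)
      cwm(p, traits)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

as_community_matrix <- function(comm) {
  if (is.data.frame(comm)) comm <- as.matrix(comm)
  if (!is.matrix(comm) || !is.numeric(comm)) stop("community must be a numeric matrix")
  if (is.null(rownames(comm))) rownames(comm) <- paste0("plot", seq_len(nrow(comm)))
  if (is.null(colnames(comm))) stop("community matrix must have species column names")
  if (any(comm < 0)) stop("negative abundances in community matrix")
  comm
}

drop_empty_plots <- function(comm) {
  empty <- rowSums(comm) <= 0
  if (any(empty)) {
    warning("excluding plots with zero total abundance: ",
            paste(rownames(comm)[empty], collapse = ", "))
    comm <- comm[!empty, , drop = FALSE]
  }
  if (nrow(comm) == 0) stop("no non-empty plots")
  comm
}

as_trait_vector <- function(traits) {
  if (is.data.frame(traits)) {
    stopifnot(ncol(traits) >= 2)
    out <- as.numeric(traits[[2]])
    names(out) <- as.character(traits[[1]])
    traits <- out
  }
  if (is.null(names(traits))) stop("traits must be named by species")
  traits <- traits[is.finite(traits) | TRUE]
  if (any(!is.finite(traits))) stop("non-finite trait values")
  if (any(traits <= 0)) stop("trait (height) values must be positive")
  traits
}
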