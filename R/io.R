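#' Read and write pipeline tables
#'
#' All tabular I/O is tab-separated text with a header; the first column of
#' the community matrix is the plot identifier, of the trait table the
#' species name. Plots and species are matched downstream by exact string
#' identity — no fuzzy joins.
#'
#' @param path File path.
#' @return `read_community`: plot x species numeric matrix;
#'   `read_traits`: `data.frame(species, height)`;
#'   `read_soil`: `data.frame` with `plot` plus soil columns.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_community <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("community table needs a plot column plus species columns: ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundances in ", path)
  rownames(m) <- as.character(d[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicate plot identifiers in ", path)
  as_community_matrix(m)
}

#' @rdname pipeline_io
#' @param comm Plot x species matrix.
#' @export
write_community <- function(comm, path) {
  d <- data.frame(plot = rownames(comm), comm, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write_tsv_table(d, path)
}

#' @rdname pipeline_io
#' @export
read_traits <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("trait table needs species + value columns: ", path)
  names(d)[1:2] <- c("species", "height")
  if (anyDuplicated(d$species)) stop("duplicate species in trait table ", path)
  d
}

#' @rdname pipeline_io
#' @export
read_soil <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"plot" %in% names(d)) names(d)[1] <- "plot"
  d$plot <- as.character(d$plot)
  d
}

#' @rdname pipeline_io
#' @param x A `data.frame`.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
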