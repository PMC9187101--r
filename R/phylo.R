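#' Parse a Newick string into a validated phylogeny
#'
#' Reads a rooted phylogeny with branch lengths from Newick text and validates
#' it for downstream distance and phylogenetic-diversity computations: unique,
#' non-empty tip labels; non-negative branch lengths with at least one positive
#' length; branch lengths present on every edge (or defaulted, see
#' `missing_length`). Internal node labels are permitted and ignored.
#'
#' @param text A Newick string (terminating `;` optional for `ape`).
#' @param missing_length How to treat edges without a branch length:
#'   `"error"` (default) aborts, `"one"` substitutes 1.0. Silent defaults can
#'   corrupt phylogenetic-diversity sums, so substitution is opt-in.
#' @return An object of class `"phylo"` (from \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text, missing_length = c("error", "one")) {
  missing_length <- match.arg(missing_length)
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_parens(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr)) stop("failed to parse Newick string")
  if (is.null(tr$edge.length)) {
    if (missing_length == "error")
      stop("tree has no branch lengths (use missing_length = \"one\" to default them to 1)")
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (missing_length == "error")
      stop("tree has edges without branch lengths (use missing_length = \"one\" to default them to 1)")
    tr$edge.length[is.na(tr$edge.length)] <- 1
  }
  validate_phylogeny(tr)
  tr
}

# cheap structural pre-check so malformed input fails with a character position
check_newick_parens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' (string ends at character %d)",
                 depth, length(chars)))
  invisible(TRUE)
}

#' Validate a phylogeny for diversity computations
#'
#' Checks the invariants assumed throughout the pipeline: a rooted tree,
#' unique non-empty tip labels, all branch lengths non-negative and at least
#' one positive.
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly; aborts with a descriptive error otherwise.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("tree has empty tip labels")
  if (anyDuplicated(labs)) {
    dups <- unique(labs[duplicated(labs)])
    stop("duplicate tip labels: ", paste(dups, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (!any(tree$edge.length > 0)) stop("all branch lengths are zero")
  invisible(tree)
}

#' Write a phylogeny to Newick text
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if omitted the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Patristic (tree-path) distance matrix between tips
#'
#' Pairwise evolutionary distances: the sum of branch lengths along the unique
#' tree path between every pair of tips. These distances feed MPD/MNTD and
#' their standardized effect sizes.
#'
#' @param tree A validated `"phylo"` object.
#' @return A symmetric numeric matrix with zero diagonal, rows/columns named
#'   and ordered as `tree$tip.label`.
#' @examples
#' d <- patristic_distances(parse_newick("((A:1,B:1):1,C:2);"))
#' d["A", "C"]  # 4
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Faith's phylogenetic diversity of a set of species
#'
#' Sum of branch lengths of the minimal subtree connecting the given species.
#' The convention is root-inclusive (Phylocom-style): the path from the
#' community's most recent common ancestor up to the root of the supplied tree
#' is counted, so a single-species community has PD equal to its root-to-tip
#' path length.
#'
#' @param tree A validated `"phylo"` object.
#' @param species Character vector of tip labels (at least one).
#' @return PD in branch-length units.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B"))  # 3: the two cherries plus the stem to the root
#' @export
faith_pd <- function(tree, species) {
  validate_phylogeny(tree)
  species <- unique(as.character(species))
  if (length(species) < 1L) stop("species set is empty")
  idx <- match(species, tree$tip.label)
  if (anyNA(idx))
    stop("species not in tree: ", paste(species[is.na(idx)], collapse = ", "))
  parent_edge <- integer(max(tree$edge))     # node -> row of tree$edge entering it
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  keep <- logical(nrow(tree$edge))
  for (tip in idx) {
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      if (keep[e]) break                     # path above already marked
      keep[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[keep])
}
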