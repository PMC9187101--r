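# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: distances come from root-to-tip edge sets,
# MPD/MNTD from explicit loops, indirect effects from explicit path listing.

# edge rows on the path from the root to each tip
root_to_tip_edges <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
}

# patristic distance = branch lengths on the symmetric difference of the two
# root-to-tip edge sets
oracle_patristic <- function(tree) {
  paths <- root_to_tip_edges(tree)
  n <- ape::Ntip(tree)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sym <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
    d[i, j] <- sum(tree$edge.length[sym])
  }
  d
}

oracle_faith_pd <- function(tree, species) {
  paths <- root_to_tip_edges(tree)
  idx <- match(species, tree$tip.label)
  sum(tree$edge.length[unique(unlist(paths[idx]))])
}

oracle_mpd <- function(sp, d) {
  tot <- 0; np <- 0
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i < j) { tot <- tot + d[sp[i], sp[j]]; np <- np + 1 }
  }
  tot / np
}

oracle_mntd <- function(sp, d) {
  mean(vapply(sp, function(i) min(d[i, setdiff(sp, i)]), numeric(1)))
}

oracle_mpd_weighted <- function(ab, d) {
  sp <- names(ab); p <- ab / sum(ab)
  num <- 0; den <- 0
  for (i in sp) for (j in sp) {
    if (i != j) { num <- num + p[i] * p[j] * d[i, j]; den <- den + p[i] * p[j] }
  }
  num / den
}

oracle_mntd_weighted <- function(ab, d) {
  sp <- names(ab); p <- ab / sum(ab)
  sum(vapply(sp, function(i) p[i] * min(d[i, setdiff(sp, i)]), numeric(1)))
}

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr
}

# deep two-clade pool: two Yule clades joined by long stems, so communities
# confined to one clade are strongly phylogenetically clustered
two_clade_tree <- function(n_per_clade = 10, stem = 50, seed = 1) {
  a <- simulate_phylogeny(n_per_clade, 1, seed)
  b <- simulate_phylogeny(n_per_clade, 1, seed + 1)
  b$tip.label <- sprintf("sp%03d", n_per_clade + seq_len(n_per_clade))
  na <- sub(";$", "", ape::write.tree(a))
  nb <- sub(";$", "", ape::write.tree(b))
  parse_newick(sprintf("(%s:%g,%s:%g);", na, stem, nb, stem))
}

# standardized correlation-scale slope of y on a single x
std_slope <- function(x, y) stats::cor(x, y)
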