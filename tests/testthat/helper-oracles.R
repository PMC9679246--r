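# Independent oracles, kept deliberately naive and separate from the
# package's own algorithms.

# brute-force shared-path covariance: for each pair of leaves, sum the
# branch lengths of the edges common to both root-to-leaf paths
brute_force_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- sum(tree$edge.length[shared])
    }
  }
  V
}

# all-pairs leaf path lengths by naive path enumeration
brute_force_distances <- function(tree) {
  n <- ape::Ntip(tree)
  V <- brute_force_vcv(tree)
  D <- matrix(0, n, n, dimnames = dimnames(V))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- V[i, i] + V[j, j] - 2 * V[i, j]
    }
  }
  D
}

# random non-ultrametric tree with distinct labels and positive lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# a small deterministic analysis bundle for pipeline tests
small_bundle <- function(seed = 101, n_taxa = 30, ...) {
  simulate_dataset(sim_config(seed = seed, n_taxa = n_taxa, ...))
}
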