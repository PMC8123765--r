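# Shared fixtures, built in code at test time.

# Tiny deterministic graphs
toy_graph <- function() {
  # d1-t1, d2-t1: a 3-node path through the protein
  build_graph(data.frame(drug = c("d1", "d2"), protein = c("t1", "t1")))
}

single_edge_graph <- function() {
  build_graph(data.frame(drug = "d1", protein = "t1"))
}

# Random bipartite graph over n drugs x m proteins, each pair an edge with
# probability p; retries until at least one edge exists.
random_graph <- function(n, m, p = 0.4, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  repeat {
    hit <- which(matrix(runif(n * m) < p, n, m), arr.ind = TRUE)
    if (nrow(hit) > 0L) break
  }
  build_graph(data.frame(drug = sprintf("d%02d", hit[, 1L]),
                         protein = sprintf("t%02d", hit[, 2L])))
}

# Planted 60x40 fixture with attributes; memoised per seed because the
# fingerprint backend is an external process.
.fixture_cache <- new.env(parent = emptyenv())
planted_fixture <- function(seed = 1L) {
  key <- as.character(seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sg <- synth_graph(60L, 40L, 2L, 0.3, 0.02, seed = seed)
  g <- sg$graph
  am <- build_attribute_matrix(
    g,
    synth_molecules(60L, seed = seed + 100L, ids = g$drug_ids),
    synth_proteins(40L, seed = seed + 200L, ids = g$protein_ids))
  out <- list(g = am$graph, x = am$x, drug_blocks = sg$drug_blocks,
              protein_blocks = sg$protein_blocks)
  .fixture_cache[[key]] <- out
  out
}

# Brute-force AUROC: pairwise-comparison estimator with half credit for ties.
auroc_bruteforce <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Dense normalization oracle: D^{-1/2} A D^{-1/2} via explicit diagonal
# matrices, kept independent of normalize_adjacency's elementwise path.
normalize_oracle <- function(a) {
  dinv <- diag(1 / sqrt(rowSums(a)))
  dinv %*% a %*% dinv
}

# Connected components by breadth-first search over the adjacency list.
components_bruteforce <- function(g) {
  N <- n_nodes(g)
  A <- build_adjacency(g, add_self_loops = FALSE)
  comp <- rep(NA_integer_, N)
  cid <- 0L
  for (s in seq_len(N)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(A[v, ] > 0 & is.na(comp)))
    }
  }
  comp
}
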