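#' DeepWalk configuration
#'
#' Hyperparameters of the random-walk corpus and skip-gram training. Defaults:
#' walk length `t = 30`, window `w = 5`, `epochs = 10` walk epochs (each node
#' starts one walk per epoch), embedding dimension `d = 64` (matching the
#' 64-dimensional attribute blocks), initial learning rate `alpha = 0.025`
#' decaying linearly to `alpha/100`, hierarchical-softmax objective over a
#' Huffman tree (`"hs"`; `"ns"` = negative sampling with 5 noise draws from
#' the unigram^0.75 distribution).
#'
#' @param walk_length Steps per walk (`t`).
#' @param window Context window half-width (`w`), must be `< walk_length`.
#' @param epochs Walk epochs (`gamma`).
#' @param dim Embedding dimension (`d`).
#' @param alpha Initial SGD learning rate.
#' @param objective `"hs"` or `"ns"`.
#' @param negative Noise samples per pair when `objective = "ns"`.
#' @param seed Integer seed controlling walks, init and training order.
#' @return A `walk_config` list.
#' @export
walk_config <- function(walk_length = 30L, window = 5L, epochs = 10L,
                        dim = 64L, alpha = 0.025, objective = c("hs", "ns"),
                        negative = 5L, seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(walk_length >= 1L, window >= 1L, epochs >= 1L, dim >= 1L,
            alpha > 0, negative >= 1L)
  if (window >= walk_length)
    stop("window (", window, ") must be smaller than walk_length (",
         walk_length, ")")
  structure(list(walk_length = as.integer(walk_length),
                 window = as.integer(window), epochs = as.integer(epochs),
                 dim = as.integer(dim), alpha = alpha, objective = objective,
                 negative = as.integer(negative), seed = as.integer(seed)),
            class = "walk_config")
}

#' Truncated random walk
#'
#' Uniform-neighbor random walk of length `t` starting at `start` (global
#' node index, drugs `1..n` then proteins `n+1..n+m`). Self-loops are never
#' walked: the walkable graph is the plain bipartite edge set. A node with no
#' neighbors halts the walk immediately (length-1 walks are dropped from
#' corpora).
#'
#' @param g A `bipartite_graph`.
#' @param start Global node index.
#' @param t Walk length.
#' @param adj Optional precomputed adjacency list (internal fast path).
#' @return Integer vector of visited global node indices, length `<= t`.
#' @export
random_walk <- function(g, start, t, adj = NULL) {
  if (is.null(adj)) adj <- adjacency_list(g)
  start <- as.integer(start)
  if (start < 1L || start > length(adj)) stop("invalid start index: ", start)
  stopifnot(t >= 1L)
  walk <- integer(t)
  walk[1L] <- start
  cur <- start
  for (i in seq_len(t - 1L)) {
    nb <- adj[[cur]]
    if (length(nb) == 0L) return(walk[seq_len(i)])
    cur <- nb[sample.int(length(nb), 1L)]
    walk[i + 1L] <- cur
  }
  walk
}

#' Build the random-walk corpus
#'
#' Runs `epochs` passes; in each pass the node set is shuffled and one
#' truncated walk is launched from every node. Walks that stop before
#' visiting a second node (isolated nodes) are discarded with a warning.
#'
#' @param g A `bipartite_graph`.
#' @param cfg A [walk_config()].
#' @return A list of integer walk vectors (class `walk_corpus`), attribute
#'   `n_nodes` carrying the graph size.
#' @export
build_corpus <- function(g, cfg) {
  stopifnot(inherits(g, "bipartite_graph"), inherits(cfg, "walk_config"))
  if (nrow(g$edges) == 0L) stop("no walkable edges")
  adj <- adjacency_list(g)
  N <- n_nodes(g)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  walks <- vector("list", cfg$epochs * N)
  w_i <- 0L
  n_dropped <- 0L
  for (ep in seq_len(cfg$epochs)) {
    for (v in sample.int(N)) {
      wk <- random_walk(g, v, cfg$walk_length, adj = adj)
      if (length(wk) >= 2L) {
        w_i <- w_i + 1L
        walks[[w_i]] <- wk
      } else {
        n_dropped <- n_dropped + 1L
      }
    }
  }
  if (n_dropped > 0L)
    warning("dropped ", n_dropped, " length-1 walk(s) from isolated nodes")
  structure(walks[seq_len(w_i)], class = "walk_corpus", n_nodes = N)
}

#' Center-context pairs of a walk
#'
#' For each position `j`, emits `(walk[j], walk[k])` for every `k` within
#' `w` positions of `j` (excluding `j`), window clipped at the walk
#' boundaries. This is the pair stream the skip-gram objective sums over.
#'
#' @param walk Integer (or character) sequence of nodes.
#' @param w Window half-width.
#' @return Two-column matrix `(center, context)`; zero rows for length-1 walks.
#' @export
context_pairs <- function(walk, w) {
  stopifnot(w >= 1L)
  t <- length(walk)
  if (t < 2L) return(cbind(center = walk[0L], context = walk[0L]))
  out <- vector("list", t)
  for (j in seq_len(t)) {
    ks <- max(1L, j - w):min(t, j + w)
    ks <- ks[ks != j]
    out[[j]] <- cbind(center = rep(walk[j], length(ks)), context = walk[ks])
  }
  do.call(rbind, out)
}

#' Train skip-gram embeddings on a walk corpus
#'
#' One SGD pass over all center-context pairs of the corpus (the corpus
#' already encodes `epochs` walk epochs), minimizing `-log Pr(context |
#' psi(center))` with hierarchical softmax over a Huffman tree built from
#' corpus node frequencies, or with negative sampling. The learning rate
#' decays linearly from `alpha` to `alpha/100`. Single-threaded and fully
#' deterministic given the config seed. Nodes absent from the corpus receive
#' zero embeddings with a warning.
#'
#' @param corpus A `walk_corpus` from [build_corpus()].
#' @param cfg A [walk_config()].
#' @param passes Number of SGD passes (default 1; more are useful only for
#'   descent diagnostics on frozen mini-corpora).
#' @param eval_objective If `TRUE`, also evaluate the total objective J before
#'   each pass and after the last, returned as attribute `objective`.
#' @return `|V| x d` embedding matrix `psi`.
#' @export
train_skipgram <- function(corpus, cfg, passes = 1L, eval_objective = FALSE) {
  stopifnot(inherits(cfg, "walk_config"))
  if (length(corpus) == 0L) stop("nothing to train on: empty corpus")
  if (isTRUE(eval_objective) && cfg$objective != "hs")
    stop("objective evaluation is only defined for the hs objective")
  N <- attr(corpus, "n_nodes")
  if (is.null(N)) N <- max(vapply(corpus, max, 1L))
  walks0 <- lapply(corpus, function(w) as.integer(w) - 1L)
  res <- cpp_train_skipgram(walks0, as.integer(N), cfg$dim, cfg$window,
                            cfg$alpha, cfg$seed,
                            cfg$objective == "hs", cfg$negative,
                            as.integer(passes), isTRUE(eval_objective))
  psi <- res$psi
  absent <- res$count == 0L
  if (any(absent)) {
    warning(sum(absent), " node(s) absent from corpus; zero embeddings")
    psi[absent, ] <- 0
  }
  if (isTRUE(eval_objective)) attr(psi, "objective") <- res$objective
  psi
}

#' End-to-end DeepWalk node embedding
#'
#' Composition of [build_corpus()] and [train_skipgram()]: samples truncated
#' random walks from the bipartite graph (self-loops excluded) and trains the
#' skip-gram model on them, mapping every node to a `d`-dimensional vector.
#'
#' @param g A `bipartite_graph`.
#' @param cfg A [walk_config()].
#' @return `(n+m) x d` matrix `psi`, rownames = node ids.
#' @export
embed_nodes <- function(g, cfg = walk_config()) {
  psi <- train_skipgram(build_corpus(g, cfg), cfg)
  rownames(psi) <- c(g$drug_ids, g$protein_ids)
  psi
}
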