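#' Glorot-uniform GCN weight initialization
#'
#' The graph convolution here is an untrained random-projection aggregator:
#' weights are drawn once from `U(-sqrt(6/(d_in+d_out)), +sqrt(6/(d_in+d_out)))`
#' and never updated — all supervised learning happens in the downstream
#' pair classifier. Fully determined by `seed`.
#'
#' @param d_in,d_out Input and output dimensions (default 64 x 64).
#' @param seed Integer seed.
#' @return A `d_in x d_out` numeric matrix with attribute `seed`.
#' @export
init_weights <- function(d_in = 64L, d_out = 64L, seed = 1L) {
  stopifnot(d_in >= 1L, d_out >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  lim <- sqrt(6 / (d_in + d_out))
  w <- matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
  attr(w, "seed") <- seed
  w
}

#' One graph-convolution layer
#'
#' Computes `ReLU(S X W)` where `S = D^{-1/2} (A + I) D^{-1/2}` is the
#' symmetrically normalized self-looped adjacency: each node's new
#' representation is the degree-weighted average of its own and its
#' neighbors' attributes, linearly mixed by `W`.
#'
#' @param x Node feature matrix, `(n+m) x d_in`.
#' @param a_norm Normalized adjacency from [normalize_adjacency()].
#' @param w Weight matrix, `d_in x d_out`.
#' @return Non-negative `(n+m) x d_out` matrix.
#' @export
gcn_layer <- function(x, a_norm, w) {
  if (nrow(x) != ncol(a_norm) || ncol(x) != nrow(w))
    stop("dimension error: a_norm ", nrow(a_norm), "x", ncol(a_norm),
         ", x ", nrow(x), "x", ncol(x), ", w ", nrow(w), "x", ncol(w))
  h <- a_norm %*% x %*% w
  h[h < 0] <- 0
  h
}

#' Local-structure (GF) features with raw-attribute re-injection
#'
#' Applies `n_layers` graph convolutions; after each layer the raw attribute
#' matrix X is re-injected to counter over-smoothing: `"concat"` (default)
#' appends X column-wise so the output carries the aggregated block alongside
#' the verbatim attributes (width `d_hidden + d_attr`, 128 with defaults);
#' `"sum"` adds X elementwise (requires `d_hidden == d_attr`).
#'
#' @param x Node attribute matrix, `(n+m) x d_attr`.
#' @param a_norm Normalized self-looped adjacency.
#' @param w Weight matrix from [init_weights()].
#' @param n_layers Number of convolutions, default 1.
#' @param mode `"concat"` or `"sum"`.
#' @return The GF matrix; with concat its right `d_attr` columns equal `x`.
#' @export
gf_features <- function(x, a_norm, w, n_layers = 1L,
                        mode = c("concat", "sum")) {
  mode <- match.arg(mode)
  stopifnot(n_layers >= 1L)
  if (mode == "sum" && nrow(w) != ncol(w))
    stop("incompatible sum mode: d_hidden (", ncol(w),
         ") must equal d_attr (", nrow(w), ")")
  h <- x
  for (l in seq_len(n_layers)) {
    act <- gcn_layer(h, a_norm, w)
    h <- if (mode == "concat") cbind(act, x) else act + x
    # subsequent layers (rarely used; the default is l = 1) propagate the
    # combined representation, so w must be square for n_layers > 1
    if (l < n_layers && ncol(h) != nrow(w))
      stop("dimension error: layer ", l + 1L, " expects width ", nrow(w),
           ", got ", ncol(h))
  }
  rownames(h) <- rownames(x)
  h
}
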