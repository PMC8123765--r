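#' Build a bipartite drug-protein interaction graph
#'
#' Constructs a `bipartite_graph` from an edge list of (drug_id, protein_id)
#' records. Node ordering is fixed and reproducible: drugs sorted
#' lexicographically occupy rows `1..n`, proteins sorted lexicographically
#' occupy rows `n+1..n+m`. Duplicate records collapse to a single undirected
#' edge (a message reports how many were dropped).
#'
#' @param edge_records A two-column data.frame (or matrix) of drug and protein
#'   identifiers, or a list of length-2 character vectors.
#' @return An object of class `bipartite_graph` with elements `drug_ids`,
#'   `protein_ids` and `edges` (integer matrix, columns `drug` and `protein`,
#'   1-based indices into the respective id vectors).
#' @examples
#' g <- build_graph(data.frame(drug = c("d1", "d1", "d2"),
#'                             protein = c("t1", "t1", "t1")))
#' g$n; g$m; nrow(g$edges)
#' @export
build_graph <- function(edge_records) {
  if (is.list(edge_records) && !is.data.frame(edge_records)) {
    bad <- which(vapply(edge_records, length, 1L) != 2L)
    if (length(bad) > 0L)
      stop("malformed record at line ", bad[1L], ": expected 2 fields")
    edge_records <- data.frame(
      drug = vapply(edge_records, function(r) as.character(r[[1L]]), ""),
      protein = vapply(edge_records, function(r) as.character(r[[2L]]), ""),
      stringsAsFactors = FALSE)
  }
  edge_records <- as.data.frame(edge_records, stringsAsFactors = FALSE)
  if (nrow(edge_records) == 0L) stop("empty edge list")
  if (ncol(edge_records) < 2L) stop("malformed record: expected 2 columns")
  d <- as.character(edge_records[[1L]])
  p <- as.character(edge_records[[2L]])
  bad <- which(is.na(d) | is.na(p) | d == "" | p == "")
  if (length(bad) > 0L)
    stop("malformed record at line ", bad[1L], ": missing field")
  drug_ids <- sort(unique(d))
  protein_ids <- sort(unique(p))
  di <- match(d, drug_ids)
  pi <- match(p, protein_ids)
  key <- paste(di, pi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message("collapsed ", sum(dup), " duplicate edge record(s)")
  edges <- cbind(drug = di[!dup], protein = pi[!dup])
  o <- order(edges[, 1L], edges[, 2L])
  edges <- edges[o, , drop = FALSE]
  structure(list(drug_ids = drug_ids, protein_ids = protein_ids,
                 edges = edges, n = length(drug_ids), m = length(protein_ids)),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("bipartite DTI graph: ", x$n, " drugs, ", x$m, " proteins, ",
      nrow(x$edges), " interactions\n", sep = "")
  invisible(x)
}

#' Number of nodes in a bipartite graph
#' @param g A `bipartite_graph`.
#' @return Integer, `n + m`.
#' @export
n_nodes <- function(g) g$n + g$m

# Global node index of each edge endpoint: drugs are rows 1..n, proteins n+1..n+m.
edge_node_index <- function(g) {
  cbind(g$edges[, 1L], g$n + g$edges[, 2L])
}

#' Read a drug-protein edge list from delimited text
#'
#' Tab- or comma-delimited, two columns (drug_id, protein_id). Lines starting
#' with `#` are skipped. Header presence is declared by the caller, never
#' guessed.
#'
#' @param path Path to the file.
#' @param header Logical; does the first (non-comment) line carry column names?
#' @return A two-column character data.frame.
#' @export
read_edge_list <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (header) lines <- lines[-1L]
  if (length(lines) == 0L) stop("empty edge list")
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 2L))
    stop("malformed record at line ", which(nf < 2L)[1L], " of ", path)
  data.frame(drug = trimws(vapply(parts, `[[`, "", 1L)),
             protein = trimws(vapply(parts, `[[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Adjacency matrix of the bipartite graph
#'
#' Builds the `(n+m) x (n+m)` symmetric 0/1 adjacency with drugs first, then
#' proteins. With `add_self_loops`, returns the self-looped form
#' `A + I` (every diagonal entry 1), the matrix the normalized GCN propagation
#' operator is built from.
#'
#' @param g A `bipartite_graph`.
#' @param add_self_loops Logical; add the identity to the adjacency.
#' @return A numeric matrix with attribute `self_loops`.
#' @export
build_adjacency <- function(g, add_self_loops = FALSE) {
  stopifnot(inherits(g, "bipartite_graph"))
  N <- n_nodes(g)
  A <- matrix(0, N, N)
  if (nrow(g$edges) > 0L) {
    idx <- edge_node_index(g)
    A[idx] <- 1
    A[idx[, c(2L, 1L), drop = FALSE]] <- 1
  }
  if (add_self_loops) diag(A) <- 1
  rn <- c(g$drug_ids, g$protein_ids)
  dimnames(A) <- list(rn, rn)
  attr(A, "self_loops") <- add_self_loops
  A
}

#' Symmetrically normalized adjacency
#'
#' Returns `D^{-1/2} A D^{-1/2}` for a self-looped adjacency `A`, the
#' propagation operator of the graph convolution. Requires self-loops so every
#' degree is positive.
#'
#' @param a Adjacency matrix as returned by [build_adjacency()].
#' @return A symmetric matrix with entries `A[i,j] / sqrt(d_i d_j)`.
#' @export
normalize_adjacency <- function(a) {
  deg <- rowSums(a)
  if (any(deg == 0))
    stop("isolated node; enable self-loops")
  dinv <- 1 / sqrt(deg)
  out <- a * tcrossprod(dinv)
  attr(out, "self_loops") <- attr(a, "self_loops")
  out
}

#' Node-edge incidence matrix
#'
#' One column per edge in canonical edge order; each column has exactly two
#' ones, at the edge's drug row and protein row. `B %*% t(B)` has off-diagonal
#' equal to the self-loop-free adjacency and diagonal equal to node degrees.
#'
#' @param g A `bipartite_graph`.
#' @return An `(n+m) x |E|` 0/1 matrix.
#' @export
build_incidence <- function(g) {
  stopifnot(inherits(g, "bipartite_graph"))
  N <- n_nodes(g)
  ne <- nrow(g$edges)
  B <- matrix(0, N, ne)
  if (ne > 0L) {
    idx <- edge_node_index(g)
    B[cbind(idx[, 1L], seq_len(ne))] <- 1
    B[cbind(idx[, 2L], seq_len(ne))] <- 1
  }
  B
}

# Neighbor lists over global node indices (self-loops excluded): the walkable
# graph DeepWalk samples from.
adjacency_list <- function(g) {
  N <- n_nodes(g)
  nb <- vector("list", N)
  if (nrow(g$edges) > 0L) {
    idx <- edge_node_index(g)
    nb <- split(c(idx[, 2L], idx[, 1L]),
                factor(c(idx[, 1L], idx[, 2L]), levels = seq_len(N)))
    nb <- lapply(nb, function(v) sort(unique(as.integer(v))))
  } else {
    nb <- rep(list(integer(0)), N)
  }
  nb
}

#' Remove a set of edges from a graph
#'
#' Used by the leakage-safe cross-validation protocol: held-out positive test
#' edges are removed before structural features are computed.
#'
#' @param g A `bipartite_graph`.
#' @param edges Integer matrix with columns (drug index, protein index).
#' @return A `bipartite_graph` with the same node sets and the edges removed.
#' @export
remove_edges <- function(g, edges) {
  stopifnot(inherits(g, "bipartite_graph"))
  if (length(edges) == 0L) return(g)
  edges <- matrix(as.integer(edges), ncol = 2L)
  drop_key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  have_key <- paste(g$edges[, 1L], g$edges[, 2L], sep = "\r")
  g$edges <- g$edges[!(have_key %in% drop_key), , drop = FALSE]
  g
}
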