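# Reduced amino-acid alphabet: 20 standard residues partitioned into 4
# physicochemical groups. Group 0 hydrophobic, 1 polar, 2 basic, 3 acidic.
.aa_groups <- c(
  A = 0L, V = 0L, L = 0L, I = 0L, M = 0L, F = 0L, W = 0L, P = 0L,
  G = 1L, S = 1L, T = 1L, C = 1L, N = 1L, Q = 1L, Y = 1L,
  R = 2L, K = 2L, H = 2L,
  D = 3L, E = 3L)

#' Map amino acids to their reduced-alphabet group
#'
#' The 20 standard residues partition into four groups:
#' 0 = \{A,V,L,I,M,F,W,P\}, 1 = \{G,S,T,C,N,Q,Y\}, 2 = \{R,K,H\},
#' 3 = \{D,E\}. Case-insensitive. Non-standard codes (B, J, O, U, X, Z)
#' return `NA` — callers strip them before k-mer counting.
#'
#' @param residue Character vector of one-letter codes.
#' @return Integer vector of group indices in `{0,1,2,3}`, `NA` for
#'   non-standard codes.
#' @export
reduce_residue <- function(residue) {
  unname(.aa_groups[toupper(residue)])
}

#' Protein k-mer composition over the reduced alphabet
#'
#' Translates a protein sequence into its reduced 4-letter alphabet and counts
#' the `4^k` possible k-mers over all `L - k + 1` overlapping windows,
#' normalized to frequencies. With the default `k = 3` this is the
#' 64-dimensional protein attribute vector. Slot index of a reduced k-mer
#' `(g1, ..., gk)` is `sum(g_i * 4^(k-i))` (big-endian base 4), zero-based.
#'
#' Non-standard residues are removed before windowing (with a warning giving
#' the count); the cleaned sequence must still be at least `k` long.
#'
#' @param sequence Amino-acid string.
#' @param k k-mer length, default 3.
#' @param id Optional identifier used in error messages.
#' @return Numeric vector of length `4^k` summing to 1.
#' @examples
#' kmer_features("AVLD")  # 2 windows: AVL -> slot 1, VLD -> slot 4
#' @export
kmer_features <- function(sequence, k = 3L, id = NULL) {
  stopifnot(length(sequence) == 1L, k >= 1L)
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  grp <- unname(.aa_groups[res])
  n_bad <- sum(is.na(grp))
  if (n_bad > 0L) {
    warning("removed ", n_bad, " non-standard residue(s)",
            if (!is.null(id)) paste0(" from ", id))
    grp <- grp[!is.na(grp)]
  }
  L <- length(grp)
  if (L < k)
    stop("sequence too short",
         if (!is.null(id)) paste0(" for protein ", id),
         ": ", L, " usable residues, need >= ", k)
  nw <- L - k + 1L
  idx <- integer(nw)
  for (j in seq_len(k)) idx <- idx * 4L + grp[j:(j + nw - 1L)]
  tabulate(idx + 1L, nbins = 4L^k) / nw
}

# One python process per batch: reads "id\tsmiles" lines on a temp file,
# writes one line per molecule with the 0/1 bit string, or "!" if RDKit
# cannot parse the SMILES.
.rdkit_morgan_batch <- function(smiles, radius, n_bits) {
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(smiles, inp)
  script <- paste(
    "import sys",
    "from rdkit import Chem, RDLogger",
    "from rdkit.Chem import rdFingerprintGenerator",
    "RDLogger.DisableLog('rdApp.*')",
    sprintf("gen = rdFingerprintGenerator.GetMorganGenerator(radius=%d, fpSize=%d)",
            radius, n_bits),
    "for line in open(sys.argv[1]):",
    "    smi = line.strip()",
    "    m = Chem.MolFromSmiles(smi) if smi else None",
    "    if m is None:",
    "        print('!')",
    "    else:",
    "        print(gen.GetFingerprint(m).ToBitString())",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(inp)),
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("RDKit fingerprint backend failed (python exit ", status, ")")
  if (length(out) != length(smiles))
    stop("RDKit fingerprint backend returned ", length(out),
         " records for ", length(smiles), " molecules")
  bits <- matrix(NA_real_, length(smiles), n_bits)
  ok <- out != "!"
  if (any(ok)) {
    parsed <- strsplit(out[ok], "", fixed = TRUE)
    bits[ok, ] <- t(vapply(parsed, function(b) as.numeric(b == "1"),
                           numeric(n_bits)))
  }
  bits
}

#' Morgan fingerprint bit vectors for drugs
#'
#' Folded circular (Morgan/ECFP-style) fingerprints computed with the RDKit
#' backend, hashed to `n_bits` bits. Radius 2 with 64 bits by default, so drug
#' attribute rows match the 64-dimensional protein k-mer rows in one shared
#' node attribute matrix. Deterministic for a fixed backend version.
#'
#' @param smiles Character vector of SMILES strings (names, if any, are used
#'   as drug ids in error messages).
#' @param radius Morgan radius, default 2 (ECFP4-like).
#' @param n_bits Folded length, default 64.
#' @param on_invalid `"fail"` (default) stops naming the offending drug;
#'   `"drop"` returns `NA` rows for unparseable SMILES so callers can prune.
#' @return Numeric 0/1 matrix, one row per input molecule, `n_bits` columns.
#' @export
drug_fingerprint <- function(smiles, radius = 2L, n_bits = 64L,
                             on_invalid = c("fail", "drop")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(length(smiles) >= 1L, radius >= 0L, n_bits >= 1L)
  bits <- .rdkit_morgan_batch(as.character(smiles), radius, n_bits)
  bad <- which(is.na(bits[, 1L]))
  if (length(bad) > 0L && on_invalid == "fail") {
    who <- if (!is.null(names(smiles))) names(smiles)[bad] else
      paste0("#", bad)
    stop("invalid SMILES for drug(s): ", paste(who, collapse = ", "))
  }
  rownames(bits) <- names(smiles)
  bits
}

#' Read a SMILES table
#'
#' Delimited text with columns (drug_id, smiles); tab, comma or whitespace
#' separated; `#` comment lines skipped.
#'
#' @param path File path.
#' @param header Logical; first line is a header.
#' @return Named character vector of SMILES keyed by drug id.
#' @export
read_smiles_table <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("SMILES table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (header) lines <- lines[-1L]
  parts <- strsplit(trimws(lines), "[\t, ]+")
  nf <- vapply(parts, length, 1L)
  if (any(nf < 2L))
    stop("malformed SMILES record at line ", which(nf < 2L)[1L], " of ", path)
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

#' Read protein sequences from FASTA
#'
#' The record id is the header up to the first whitespace.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop("malformed FASTA (no '>' header): ", path)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Assemble the node attribute matrix X
#'
#' Stacks drug fingerprint rows over protein k-mer rows in graph node order,
#' giving the `(n+m) x d_attr` intrinsic attribute matrix the graph
#' convolution consumes. Drugs and proteins share one width (`d_attr`, default
#' 64) because the matrix is a single block-stacked X.
#'
#' @param g A `bipartite_graph`.
#' @param smiles Named character vector of SMILES keyed by drug id.
#' @param sequences Named character vector of protein sequences keyed by
#'   protein id.
#' @param d_attr Shared attribute width (fingerprint bits, `4^k` k-mer slots).
#' @param radius Morgan radius for the drug fingerprints.
#' @param on_invalid `"fail"` stops on an unparseable SMILES; `"drop"` removes
#'   the drug node and its edges from the returned graph.
#' @return A list with `x` (the attribute matrix, rownames = node ids) and
#'   `graph` (the input graph, pruned if `on_invalid = "drop"` fired).
#' @export
build_attribute_matrix <- function(g, smiles, sequences, d_attr = 64L,
                                   radius = 2L,
                                   on_invalid = c("fail", "drop")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(inherits(g, "bipartite_graph"))
  k <- as.integer(round(log(d_attr, 4)))
  if (4L^k != d_attr)
    stop("d_attr must be a power of 4 so protein k-mer rows fit (got ",
         d_attr, ")")
  miss_d <- setdiff(g$drug_ids, names(smiles))
  miss_p <- setdiff(g$protein_ids, names(sequences))
  if (length(miss_d) + length(miss_p) > 0L)
    stop("attribute missing for node(s): ",
         paste(c(miss_d, miss_p), collapse = ", "))
  fp <- drug_fingerprint(smiles[g$drug_ids], radius = radius, n_bits = d_attr,
                         on_invalid = on_invalid)
  if (anyNA(fp)) {
    bad_ids <- g$drug_ids[is.na(fp[, 1L])]
    message("dropping ", length(bad_ids), " drug(s) with invalid SMILES: ",
            paste(bad_ids, collapse = ", "))
    keep <- !(g$drug_ids %in% bad_ids)
    g <- build_graph(data.frame(
      drug = g$drug_ids[g$edges[, 1L]],
      protein = g$protein_ids[g$edges[, 2L]],
      stringsAsFactors = FALSE)[g$drug_ids[g$edges[, 1L]] %in%
                                  g$drug_ids[keep], , drop = FALSE])
    fp <- fp[g$drug_ids, , drop = FALSE]
  }
  pk <- t(vapply(g$protein_ids,
                 function(id) kmer_features(sequences[[id]], k = k, id = id),
                 numeric(d_attr)))
  x <- rbind(fp, pk)
  rownames(x) <- c(g$drug_ids, g$protein_ids)
  list(x = x, graph = g)
}
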