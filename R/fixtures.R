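#' Planted-partition bipartite DTI graph
#'
#' Synthetic stand-in for a curated DTI benchmark: drugs and proteins are
#' assigned to `n_blocks` communities round-robin, and a drug-protein edge is
#' drawn with probability `p_in` within a block and `p_out` across blocks.
#' All three feature families react differently to this structure (raw
#' attributes are block-independent, GF and DeepWalk capture it), which makes
#' the feature-ablation ordering testable. If a draw yields zero edges the
#' generator retries (warning) up to 20 times, then errors.
#'
#' @param n_drugs,n_proteins Node counts (defaults 60 and 40, a desk-scale
#'   miniature of the 984 x 635 benchmark).
#' @param n_blocks Number of planted communities.
#' @param p_in,p_out Within/between-block edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param seed Integer seed.
#' @return A list: `graph` (a `bipartite_graph` retaining all nodes, including
#'   any isolated ones), `drug_blocks`, `protein_blocks` (named integer
#'   vectors).
#' @export
synth_graph <- function(n_drugs = 60L, n_proteins = 40L, n_blocks = 2L,
                        p_in = 0.3, p_out = 0.02, seed = 1L) {
  stopifnot(n_drugs >= 1L, n_proteins >= 1L, n_blocks >= 1L,
            p_out >= 0, p_out < p_in || (p_in == p_out), p_in <= 1)
  if (n_drugs * n_proteins * max(p_in, p_out) < 1)
    stop("parameters yield an empty expected graph")
  wd <- max(3L, nchar(as.character(n_drugs)))
  wp <- max(3L, nchar(as.character(n_proteins)))
  drug_ids <- sprintf(paste0("D%0", wd, "d"), seq_len(n_drugs))
  protein_ids <- sprintf(paste0("P%0", wp, "d"), seq_len(n_proteins))
  bd <- rep_len(seq_len(n_blocks), n_drugs)
  bp <- rep_len(seq_len(n_blocks), n_proteins)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  prob <- matrix(p_out, n_drugs, n_proteins)
  prob[outer(bd, bp, "==")] <- p_in
  edges <- NULL
  for (try in seq_len(20L)) {
    draw <- matrix(stats::runif(n_drugs * n_proteins), n_drugs, n_proteins) < prob
    if (any(draw)) { edges <- which(draw, arr.ind = TRUE); break }
    warning("empty edge draw, retrying (", try, "/20)")
  }
  if (is.null(edges)) stop("could not generate a non-empty graph in 20 tries")
  em <- cbind(drug = as.integer(edges[, 1L]),
              protein = as.integer(edges[, 2L]))
  em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  g <- structure(list(drug_ids = drug_ids, protein_ids = protein_ids,
                      edges = em, n = n_drugs, m = n_proteins),
                 class = "bipartite_graph")
  list(graph = g,
       drug_blocks = stats::setNames(bd, drug_ids),
       protein_blocks = stats::setNames(bp, protein_ids))
}

# Fragment vocabulary for synthetic molecules. Every unit is a complete,
# valence-safe SMILES fragment; plain concatenation of any units forms a
# valid linear molecule (ring-closure digits are reused only after closing).
.smiles_units <- c("C", "CC", "CCC", "N", "O", "CO", "CN", "CS",
                   "C(C)C", "C(=O)N", "C(=O)O",
                   "c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCNCC1",
                   "C1CCOCC1")
.smiles_terminals <- c("", "C", "O", "N", "Cl", "F", "Br")

#' Random valid SMILES molecules
#'
#' Assembles 2-6 fragments from a vetted valence-safe vocabulary (alkyl
#' chains, common heteroatoms, aromatic and aliphatic rings) plus an optional
#' terminal atom. Syntactic validity holds by construction; chemistry is
#' deliberately naive — the fixture targets fingerprint diversity, not
#' drug-likeness.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param ids Drug identifiers (names of the result).
#' @return Named character vector of SMILES.
#' @export
synth_molecules <- function(n, seed = 1L,
                            ids = sprintf("D%03d", seq_len(n))) {
  stopifnot(n >= 1L, length(ids) == n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  smi <- vapply(seq_len(n), function(i) {
    n_units <- sample(2:6, 1L)
    paste0(paste(sample(.smiles_units, n_units, replace = TRUE),
                 collapse = ""),
           sample(.smiles_terminals, 1L))
  }, "")
  stats::setNames(smi, ids)
}

#' Random protein sequences
#'
#' Uniform residues over the 20 standard amino acids, lengths uniform in
#' `length_range`.
#'
#' @param n Number of sequences.
#' @param length_range Two-element integer range (default 100-300).
#' @param seed Integer seed.
#' @param ids Protein identifiers (names of the result).
#' @param k k-mer length of the downstream featurizer; `min(length_range)`
#'   must be at least `k`.
#' @return Named character vector of sequences.
#' @export
synth_proteins <- function(n, length_range = c(100L, 300L), seed = 1L,
                           ids = sprintf("P%03d", seq_len(n)), k = 3L) {
  stopifnot(n >= 1L, length(ids) == n, length(length_range) == 2L)
  if (min(length_range) < k)
    stop("length_range minimum (", min(length_range),
         ") is below the featurizer k (", k, ")")
  aa <- names(.aa_groups)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), "")
  stats::setNames(seqs, ids)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the exact file formats the readers consume — `edges.tsv` (drug_id,
#' protein_id), `drugs.smi` (drug_id, SMILES), `proteins.fasta` and
#' `labels.tsv` (node_id, block) — so fixtures double as format round-trip
#' tests.
#'
#' @param dir Output directory (created if absent).
#' @param n_drugs,n_proteins,n_blocks,p_in,p_out,seed Passed to the
#'   generators ([synth_graph()] etc.), each stage with a fixed seed offset.
#' @return Invisibly, the list from [synth_graph()] plus file paths.
#' @export
write_fixture_set <- function(dir, n_drugs = 60L, n_proteins = 40L,
                              n_blocks = 2L, p_in = 0.3, p_out = 0.02,
                              seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sg <- synth_graph(n_drugs, n_proteins, n_blocks, p_in, p_out,
                    seed = stage_seed(seed, "synth"))
  g <- sg$graph
  smi <- synth_molecules(n_drugs, seed = stage_seed(seed, "synth") + 1L,
                         ids = g$drug_ids)
  prot <- synth_proteins(n_proteins, seed = stage_seed(seed, "synth") + 2L,
                         ids = g$protein_ids)
  edges_path <- file.path(dir, "edges.tsv")
  writeLines(paste(g$drug_ids[g$edges[, 1L]], g$protein_ids[g$edges[, 2L]],
                   sep = "\t"), edges_path)
  smi_path <- file.path(dir, "drugs.smi")
  writeLines(paste(names(smi), smi, sep = "\t"), smi_path)
  fa_path <- file.path(dir, "proteins.fasta")
  writeLines(paste0(">", names(prot), "\n", prot), fa_path)
  lab_path <- file.path(dir, "labels.tsv")
  writeLines(c(paste(names(sg$drug_blocks), sg$drug_blocks, sep = "\t"),
               paste(names(sg$protein_blocks), sg$protein_blocks,
                     sep = "\t")), lab_path)
  invisible(c(sg, list(paths = c(edges = edges_path, smiles = smi_path,
                                 fasta = fa_path, labels = lab_path))))
}
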