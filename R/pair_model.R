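#' Sample negative drug-protein pairs
#'
#' Draws `n_neg` distinct pairs uniformly without replacement from the
#' non-edges of the bipartite graph. The benchmark convention is a 1:1
#' negative:positive ratio.
#'
#' @param g A `bipartite_graph`.
#' @param n_neg Number of negatives.
#' @param seed Integer seed.
#' @return Integer matrix with columns `drug`, `protein` (1-based indices).
#' @export
sample_negatives <- function(g, n_neg, seed = 1L) {
  stopifnot(inherits(g, "bipartite_graph"), n_neg >= 1L)
  total <- as.numeric(g$n) * g$m
  pos_lin <- (g$edges[, 1L] - 1) * g$m + g$edges[, 2L]  # 1..n*m
  n_avail <- total - nrow(g$edges)
  if (n_neg > n_avail)
    stop("insufficient non-edges: requested ", n_neg, ", available ", n_avail)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  cand <- setdiff(seq_len(total), pos_lin)
  pick <- sort(cand[sample.int(length(cand), n_neg)])
  cbind(drug = as.integer((pick - 1) %/% g$m + 1),
        protein = as.integer((pick - 1) %% g$m + 1))
}

#' Positive + sampled-negative labeled pair set
#'
#' Positives are exactly the graph's edges (label 1); negatives are sampled
#' uniformly from non-edges (label 0), `ratio` per positive.
#'
#' @param g A `bipartite_graph`.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed for the negative sample.
#' @return A data.frame (`drug`, `protein`, `label`) with attribute
#'   `provenance` recording seed and policy.
#' @export
labeled_pairs <- function(g, ratio = 1, seed = 1L) {
  neg <- sample_negatives(g, round(ratio * nrow(g$edges)), seed = seed)
  out <- data.frame(
    drug = c(g$edges[, 1L], neg[, 1L]),
    protein = c(g$edges[, 2L], neg[, 2L]),
    label = rep(c(1L, 0L), c(nrow(g$edges), nrow(neg))))
  attr(out, "provenance") <- list(seed = seed, ratio = ratio,
                                  policy = "uniform non-edges")
  out
}

# Node representation matrix for a feature mode. attribute -> X;
# gf -> GF; lgdti -> [GF | psi] column-concatenated.
node_representation <- function(mode, x, gf = NULL, psi = NULL) {
  switch(mode,
    attribute = x,
    gf = { if (is.null(gf)) stop("mode 'gf' needs the GF matrix"); gf },
    lgdti = {
      if (is.null(gf) || is.null(psi))
        stop("mode 'lgdti' needs both GF and psi")
      cbind(gf, psi)
    },
    stop("unknown feature mode: ", mode))
}

#' Per-pair feature rows
#'
#' Each pair's feature row is the drug node's representation concatenated
#' with the protein node's, under the chosen mode: `"attribute"` (raw X,
#' 64+64 with defaults), `"gf"` (local structure, 128+128) or `"lgdti"`
#' (local + global, (128+64)+(128+64) = 384).
#'
#' @param pairs Data.frame or matrix with `drug` and `protein` index columns.
#' @param mode `"attribute"`, `"gf"` or `"lgdti"`.
#' @param x Node attribute matrix.
#' @param gf GF matrix (for modes gf/lgdti).
#' @param psi Embedding matrix (for mode lgdti).
#' @param g The `bipartite_graph` (for the drug/protein row offset).
#' @return Numeric matrix, one row per pair.
#' @export
pair_features <- function(pairs, mode = c("lgdti", "gf", "attribute"),
                          x, gf = NULL, psi = NULL, g) {
  mode <- match.arg(mode)
  rep_mat <- node_representation(mode, x, gf, psi)
  di <- as.integer(pairs[, "drug"])
  pj <- as.integer(pairs[, "protein"])
  if (any(di < 1L | di > g$n) || any(pj < 1L | pj > g$m))
    stop("pair index out of range")
  cbind(rep_mat[di, , drop = FALSE], rep_mat[g$n + pj, , drop = FALSE])
}

#' Binary-classification metrics with ROC and PR curves
#'
#' Hard metrics (accuracy, MCC, sensitivity, specificity, precision) at the
#' decision threshold, AUROC by the tie-aware trapezoidal rule over the full
#' ROC (equal to the Mann-Whitney pairwise estimator with half credit for
#' ties), and AUPR by the step-wise (non-interpolated) precision integral.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold for the hard metrics (default 0.5).
#' @return A list: scalar metrics (fractions in `[0, 1]`), `roc` and `pr`
#'   curve point data.frames, and the confusion counts.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("AUROC undefined: labels contain a single class")
  tp <- sum(labels == 1L & scores >= threshold)
  fp <- sum(labels == 0L & scores >= threshold)
  fn <- P - tp
  tn <- N - fp
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den

  # tie-grouped ROC / PR sweep, scores descending
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  cut <- which(diff(s) != 0)            # last index of each tie group
  cut <- c(cut, length(s))
  ctp <- cumsum(l)[cut]
  cfp <- cut - ctp
  tpr <- c(0, ctp / P)
  fpr <- c(0, cfp / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec_curve <- ctp / (ctp + cfp)
  rec_curve <- ctp / P
  aupr <- sum(diff(c(0, rec_curve)) * prec_curve)

  list(acc = (tp + tn) / (P + N), mcc = mcc,
       sen = tp / P, spec = tn / N,
       prec = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       auroc = auroc, aupr = aupr,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = c(0, rec_curve),
                       precision = c(1, prec_curve)))
}

# Stratified fold assignment: shuffle within each label class, deal folds
# round-robin, so per-fold class balance is within one pair of global.
stratified_folds <- function(labels, k, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Structural representations (GF and, unless skipped, psi) for one graph.
structure_features <- function(g, x, w, dwcfg, need_psi) {
  a_norm <- normalize_adjacency(build_adjacency(g, add_self_loops = TRUE))
  gf <- gf_features(x, a_norm, w)
  psi <- if (need_psi) suppressWarnings(embed_nodes(g, dwcfg)) else NULL
  list(gf = gf, psi = psi)
}

#' Stratified k-fold cross-validation of the pair classifier
#'
#' Splits the labeled pair set into `k` stratified folds; per fold, trains on
#' the other folds and scores the held-out pairs. Under
#' `leakage = "strict"` (default) the structural representations (GF and the
#' DeepWalk embedding) are recomputed per fold on the graph with that fold's
#' positive test edges removed, so no test interaction informs the features.
#' `leakage = "paper"` computes them once on the full graph, reproducing the
#' protocol typically used with whole-graph embeddings.
#'
#' @param pairs Labeled pair set from [labeled_pairs()].
#' @param g The `bipartite_graph`.
#' @param x Node attribute matrix (rows in graph node order).
#' @param mode Feature mode: `"lgdti"`, `"gf"` or `"attribute"`.
#' @param classifier Classifier name, see [fit_classifier()].
#' @param k Number of folds (default 5).
#' @param seed Seed fanning out to folds, weights, walks and learners.
#' @param leakage `"strict"` or `"paper"`.
#' @param dwcfg DeepWalk [walk_config()]; its seed field is overridden by the
#'   fan-out seed.
#' @param threshold Decision threshold for hard metrics.
#' @param ... Passed to [fit_classifier()].
#' @return A `metrics_report`: per-fold metric data.frame (`folds`), `mean`
#'   and `sd` rows, per-fold curves, and the resolved configuration.
#' @export
crossvalidate <- function(pairs, g, x, mode = c("lgdti", "gf", "attribute"),
                          classifier = "rf", k = 5L, seed = 1L,
                          leakage = c("strict", "paper"),
                          dwcfg = walk_config(), threshold = 0.5, ...) {
  mode <- match.arg(mode)
  leakage <- match.arg(leakage)
  stopifnot(k >= 2L)
  labels <- pairs$label
  if (length(unique(labels)) < 2L) stop("both classes required")
  fold <- stratified_folds(labels, k, stage_seed(seed, "cv"))
  for (f in seq_len(k))
    if (length(unique(labels[fold == f])) < 2L)
      stop("degenerate fold; reduce k or add data")

  w <- init_weights(ncol(x), ncol(x), seed = stage_seed(seed, "gcn"))
  need_struct <- mode != "attribute"
  need_psi <- mode == "lgdti"
  full_rep <- NULL
  if (need_struct && leakage == "paper") {
    dw <- dwcfg; dw$seed <- stage_seed(seed, "deepwalk")
    full_rep <- structure_features(g, x, w, dw, need_psi)
  }

  fold_metrics <- vector("list", k)
  curves <- vector("list", k)
  scores_all <- numeric(length(labels))
  for (f in seq_len(k)) {
    test <- fold == f
    rep_f <- if (!need_struct) {
      list(gf = NULL, psi = NULL)
    } else if (leakage == "paper") {
      full_rep
    } else {
      test_pos <- pairs[test & labels == 1L, c("drug", "protein")]
      g_f <- remove_edges(g, as.matrix(test_pos))
      dw <- dwcfg; dw$seed <- stage_seed(seed, "deepwalk") + f
      structure_features(g_f, x, w, dw, need_psi)
    }
    feats_tr <- pair_features(pairs[!test, ], mode, x, rep_f$gf, rep_f$psi, g)
    feats_te <- pair_features(pairs[test, ], mode, x, rep_f$gf, rep_f$psi, g)
    model <- fit_classifier(feats_tr, labels[!test], classifier,
                            seed = stage_seed(seed, "classifier") + f, ...)
    sc <- predict_classifier(model, feats_te)
    scores_all[test] <- sc
    m <- compute_metrics(labels[test], sc, threshold)
    curves[[f]] <- list(roc = m$roc, pr = m$pr)
    fold_metrics[[f]] <- data.frame(fold = f, acc = m$acc, mcc = m$mcc,
                                    sen = m$sen, spec = m$spec,
                                    prec = m$prec, auroc = m$auroc,
                                    aupr = m$aupr)
  }
  folds <- do.call(rbind, fold_metrics)
  metric_cols <- setdiff(names(folds), "fold")
  structure(list(
    folds = folds,
    mean = colMeans(folds[metric_cols]),
    sd = vapply(folds[metric_cols], stats::sd, 0.0),
    curves = curves,
    scores = scores_all,
    fold_assignment = fold,
    config = list(mode = mode, classifier = classifier, k = k, seed = seed,
                  leakage = leakage, threshold = threshold,
                  deepwalk = unclass(dwcfg))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cfg <- x$config
  cat("5x cross-validated DTI prediction (mode=", cfg$mode, ", classifier=",
      cfg$classifier, ", k=", cfg$k, ", leakage=", cfg$leakage, ")\n",
      sep = "")
  pct <- function(v) sprintf("%.2f", 100 * v)
  for (nm in c("acc", "mcc", "sen", "spec", "prec"))
    cat(sprintf("  %-5s %s +/- %s %%\n", paste0(toupper(nm), "."),
                pct(x$mean[[nm]]), pct(x$sd[[nm]])))
  cat(sprintf("  AUROC %.4f +/- %.4f\n", x$mean[["auroc"]], x$sd[["auroc"]]))
  cat(sprintf("  AUPR  %.4f +/- %.4f\n", x$mean[["aupr"]], x$sd[["aupr"]]))
  invisible(x)
}

#' Train the pair model on all known interactions
#'
#' Fits the chosen classifier on every positive edge plus a 1:1 uniform
#' negative sample, with features computed on the full graph — the protocol
#' used for candidate-target ranking.
#'
#' @inheritParams crossvalidate
#' @param ratio Negatives per positive.
#' @param ... Passed to [fit_classifier()].
#' @return A `dti_model` holding the classifier and the node representations.
#' @export
train_pair_model <- function(g, x, mode = c("lgdti", "gf", "attribute"),
                             classifier = "rf", seed = 1L,
                             dwcfg = walk_config(), ratio = 1, ...) {
  mode <- match.arg(mode)
  w <- init_weights(ncol(x), ncol(x), seed = stage_seed(seed, "gcn"))
  dw <- dwcfg; dw$seed <- stage_seed(seed, "deepwalk")
  rep_full <- if (mode == "attribute") list(gf = NULL, psi = NULL) else
    structure_features(g, x, w, dw, mode == "lgdti")
  pairs <- labeled_pairs(g, ratio = ratio,
                         seed = stage_seed(seed, "negatives"))
  feats <- pair_features(pairs, mode, x, rep_full$gf, rep_full$psi, g)
  model <- fit_classifier(feats, pairs$label, classifier,
                          seed = stage_seed(seed, "classifier"), ...)
  structure(list(model = model, g = g, x = x, gf = rep_full$gf,
                 psi = rep_full$psi, mode = mode),
            class = "dti_model")
}

#' Rank candidate targets for a query drug
#'
#' Scores every protein not already linked to the drug and returns them in
#' descending score order (ties broken by protein id for reproducibility).
#'
#' @param m A `dti_model` from [train_pair_model()].
#' @param drug_id Drug identifier present in the graph.
#' @param top Optional cap on the number of rows returned.
#' @return Data.frame (`protein_id`, `score`, `rank`), may have zero rows if
#'   the drug is linked to every protein.
#' @export
rank_targets <- function(m, drug_id, top = NULL) {
  stopifnot(inherits(m, "dti_model"))
  g <- m$g
  di <- match(drug_id, g$drug_ids)
  if (is.na(di)) stop("unknown drug id: ", drug_id)
  linked <- g$edges[g$edges[, 1L] == di, 2L]
  cand <- setdiff(seq_len(g$m), linked)
  if (length(cand) == 0L)
    return(data.frame(protein_id = character(0), score = numeric(0),
                      rank = integer(0)))
  pairs <- cbind(drug = rep(di, length(cand)), protein = cand)
  feats <- pair_features(pairs, m$mode, m$x, m$gf, m$psi, g)
  sc <- predict_classifier(m$model, feats)
  ids <- g$protein_ids[cand]
  o <- order(-sc, ids)
  out <- data.frame(protein_id = ids[o], score = sc[o],
                    rank = seq_along(o))
  if (!is.null(top)) out <- utils::head(out, top)
  out
}
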