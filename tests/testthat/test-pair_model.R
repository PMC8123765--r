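test_that("sample_negatives draws exactly the non-edges when exhausted", {
  g <- build_graph(data.frame(drug = c("d1", "d2"), protein = c("t1", "t2")))
  neg <- sample_negatives(g, 2, seed = 1)
  expect_equal(neg[order(neg[, 1]), ],
               cbind(drug = 1:2, protein = 2:1))

  # complete bipartite graph has no non-edges
  gc <- build_graph(expand.grid(drug = c("d1", "d2"),
                                protein = c("t1", "t2")))
  expect_error(sample_negatives(gc, 1), "insufficient non-edges")

  g2 <- random_graph(6, 6, p = 0.3, seed = 2)
  expect_identical(sample_negatives(g2, 5, seed = 9),
                   sample_negatives(g2, 5, seed = 9))
  # sampled pairs are never edges
  neg2 <- sample_negatives(g2, 10, seed = 4)
  key <- paste(neg2[, 1], neg2[, 2])
  expect_length(intersect(key, paste(g2$edges[, 1], g2$edges[, 2])), 0L)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("labeled_pairs holds positives exactly and no duplicates", {
  g <- random_graph(6, 5, p = 0.4, seed = 3)
  pairs <- labeled_pairs(g, seed = 2)
  pos <- pairs[pairs$label == 1, ]
  expect_equal(as.matrix(pos[c("drug", "protein")]),
               g$edges, ignore_attr = TRUE)
  expect_equal(sum(pairs$label == 0), nrow(g$edges))
  expect_equal(anyDuplicated(pairs[c("drug", "protein")]), 0L)
})

test_that("pair_features concatenates the mode's node blocks", {
  fx <- planted_fixture(1)
  g <- fx$g
  S <- normalize_adjacency(build_adjacency(g, TRUE))
  w <- init_weights(64, 64, seed = 2)
  gf <- gf_features(fx$x, S, w)
  psi <- embed_nodes(g, walk_config(dim = 64, seed = 3))
  pairs <- cbind(drug = c(1L, 5L), protein = c(2L, 7L))

  fa <- pair_features(pairs, "attribute", fx$x, g = g)
  expect_equal(ncol(fa), 128L)
  fg <- pair_features(pairs, "gf", fx$x, gf, g = g)
  expect_equal(ncol(fg), 256L)
  fl <- pair_features(pairs, "lgdti", fx$x, gf, psi, g = g)
  expect_equal(ncol(fl), 384L)

  # row = [drug block || protein block], elementwise
  expect_equal(unname(fl[1, ]),
               unname(c(gf[1, ], psi[1, ], gf[g$n + 2, ], psi[g$n + 2, ])))
  expect_error(pair_features(cbind(drug = 999L, protein = 1L), "attribute",
                             fx$x, g = g), "out of range")
})

test_that("compute_metrics matches the hand-computed confusion matrix", {
  # TP=5, TN=5 perfect split
  m <- compute_metrics(rep(c(1, 0), each = 5),
                       rep(c(0.9, 0.1), each = 5))
  for (v in c("acc", "mcc", "sen", "spec", "prec", "auroc", "aupr"))
    expect_equal(m[[v]], 1, info = v)

  # TP=3, FP=1, TN=2, FN=2 at threshold 0.5
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2)
  m2 <- compute_metrics(labels, scores)
  expect_equal(unname(m2$confusion), c(3, 1, 2, 2))
  expect_equal(m2$mcc, 4 / sqrt(240))
  expect_equal(m2$acc, 0.625)
  expect_equal(m2$sen, 0.6)
  expect_equal(m2$spec, 2 / 3)
  expect_equal(m2$prec, 0.75)

  expect_equal(compute_metrics(c(0, 1), c(0, 1))$auroc, 1)
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.4)), "single class")
})

test_that("AUROC equals the brute-force pairwise estimator", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    expect_lt(abs(compute_metrics(labels, scores)$auroc -
                    auroc_bruteforce(labels, scores)), 1e-9)
  }
})

test_that("crossvalidate partitions pairs, stratifies, and is reproducible", {
  fx <- planted_fixture(1)
  pairs <- labeled_pairs(fx$g, seed = 5)
  rep1 <- crossvalidate(pairs, fx$g, fx$x, mode = "gf", classifier = "lr",
                        k = 5, seed = 11)
  fold <- rep1$fold_assignment
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, nrow(pairs))  # every pair scored exactly once
  # stratification: per-fold positive fraction within 2% of global
  for (f in 1:5)
    expect_lt(abs(mean(pairs$label[fold == f]) - mean(pairs$label)), 0.02)

  rep2 <- crossvalidate(pairs, fx$g, fx$x, mode = "gf", classifier = "lr",
                        k = 5, seed = 11)
  expect_identical(rep1$folds, rep2$folds)
  expect_identical(rep1$scores, rep2$scores)
})

test_that("a leaked label column drives metrics to their ceiling", {
  fx <- planted_fixture(1)
  pairs <- labeled_pairs(fx$g, seed = 6)
  # features with the label smuggled in: perfect separability
  feats <- pair_features(pairs, "attribute", fx$x, g = fx$g)
  feats <- cbind(feats, leak = pairs$label)
  fold <- rep(1:3, length.out = nrow(feats))
  for (f in 1:3) {
    # lr finds the separating column deterministically; rf's feature
    # subsampling can leave a handful of trees blind to it
    m <- fit_classifier(feats[fold != f, ], pairs$label[fold != f], "lr",
                        seed = 3)
    met <- compute_metrics(pairs$label[fold == f],
                           predict_classifier(m, feats[fold == f, ]))
    expect_equal(met$acc, 1)
    expect_equal(met$mcc, 1)
    expect_equal(met$auroc, 1)
  }
})

test_that("degenerate folds and single-class inputs are rejected", {
  fx <- planted_fixture(1)
  pairs <- labeled_pairs(fx$g, seed = 5)
  expect_error(crossvalidate(pairs[pairs$label == 1, ], fx$g, fx$x,
                             mode = "attribute"), "both classes")
  expect_error(crossvalidate(pairs, fx$g, fx$x, mode = "attribute", k = 1),
               "k >= 2")
})

test_that("paper leakage policy reuses whole-graph representations", {
  fx <- planted_fixture(1)
  pairs <- labeled_pairs(fx$g, seed = 5)
  rep_paper <- crossvalidate(pairs, fx$g, fx$x, mode = "lgdti",
                             classifier = "rf", k = 3, seed = 4,
                             leakage = "paper")
  rep_strict <- crossvalidate(pairs, fx$g, fx$x, mode = "lgdti",
                              classifier = "rf", k = 3, seed = 4,
                              leakage = "strict")
  # whole-graph embeddings have seen the test edges; they must not do worse
  expect_gte(rep_paper$mean[["auroc"]], rep_strict$mean[["auroc"]])
})

test_that("rank_targets orders unlinked proteins and respects ties", {
  fx <- planted_fixture(1)
  model <- train_pair_model(fx$g, fx$x, mode = "gf", classifier = "rf",
                            seed = 8)
  drug <- fx$g$drug_ids[1]
  linked <- fx$g$protein_ids[fx$g$edges[fx$g$edges[, 1] == 1, 2]]
  ranked <- rank_targets(model, drug)
  expect_equal(nrow(ranked), fx$g$m - length(linked))
  expect_length(intersect(ranked$protein_id, linked), 0L)
  expect_true(all(diff(ranked$score) <= 0))
  top5 <- rank_targets(model, drug, top = 5)
  expect_equal(nrow(top5), 5L)

  expect_error(rank_targets(model, "nosuchdrug"), "unknown drug id")

  # drug linked to every protein -> nothing to rank
  gc <- build_graph(data.frame(drug = c("d1", "d1", "d2"),
                               protein = c("t1", "t2", "t1")))
  xc <- matrix(runif(4 * 64), 4, 64)
  mc <- train_pair_model(gc, xc, mode = "attribute", classifier = "lr",
                         ratio = 1 / 3, seed = 1)
  expect_equal(nrow(rank_targets(mc, "d1")), 0L)
})

test_that("ranked candidates recover the query drug's planted block", {
  hits <- vapply(1:5, function(s) {
    fx <- planted_fixture(s)
    model <- train_pair_model(fx$g, fx$x, mode = "lgdti", classifier = "rf",
                              seed = s)
    drug <- fx$g$drug_ids[1]
    top5 <- rank_targets(model, drug, top = 5)
    sum(fx$protein_blocks[top5$protein_id] == fx$drug_blocks[drug])
  }, 0)
  expect_gte(mean(hits), 3)
})
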