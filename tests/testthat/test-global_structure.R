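test_that("walk_config validates its fields", {
  cfg <- walk_config()
  expect_equal(cfg$walk_length, 30L)
  expect_equal(cfg$window, 5L)
  expect_error(walk_config(walk_length = 4, window = 5), "smaller than")
  expect_error(walk_config(alpha = -1))
})

test_that("random_walk follows the single-edge path deterministically", {
  g <- single_edge_graph()
  wk <- random_walk(g, 1L, 5L)
  expect_equal(wk, c(1L, 2L, 1L, 2L, 1L))  # each node has one neighbor

  # isolated node halts immediately
  g2 <- toy_graph()
  g2$edges <- g2$edges[g2$edges[, 1L] == 1L, , drop = FALSE]  # d2 isolated
  expect_equal(random_walk(g2, 2L, 5L), 2L)

  expect_error(random_walk(g, 99L, 3L), "invalid start")
})

test_that("walks stay on graph edges and have exact length on connected graphs", {
  g <- random_graph(5, 4, p = 0.5, seed = 3)
  A <- build_adjacency(g, add_self_loops = FALSE)
  set.seed(11)
  for (i in 1:50) {
    wk <- random_walk(g, sample.int(n_nodes(g), 1L), 12L)
    if (length(wk) > 1L)
      for (j in seq_len(length(wk) - 1L)) {
        expect_equal(A[wk[j], wk[j + 1L]], 1)   # neighbors only
        expect_false(wk[j] == wk[j + 1L])       # self-loops never walked
      }
  }
})

test_that("build_corpus launches one walk per node per epoch, reproducibly", {
  g <- random_graph(5, 5, p = 0.6, seed = 2)
  cfg <- walk_config(walk_length = 10, window = 3, epochs = 2, dim = 8,
                     seed = 5)
  corp <- build_corpus(g, cfg)
  expect_length(corp, 2L * n_nodes(g))
  expect_true(all(lengths(corp) == 10L))
  expect_identical(corp, build_corpus(g, cfg))

  # every node starts exactly `epochs` walks
  cfg2 <- walk_config(walk_length = 5, window = 2, epochs = 50, dim = 8,
                      seed = 6)
  starts <- table(vapply(build_corpus(g, cfg2), `[[`, 1L, 1L))
  expect_true(all(starts == 50L))

  g0 <- single_edge_graph()
  g0$edges <- g0$edges[0, , drop = FALSE]
  expect_error(build_corpus(g0, cfg), "no walkable edges")
})

test_that("context_pairs enumerates clipped windows", {
  p <- context_pairs(c("a", "b", "c"), 1)
  expect_equal(nrow(p), 4L)
  expect_equal(paste(p[, 1], p[, 2]), c("a b", "b a", "b c", "c b"))

  expect_equal(nrow(context_pairs("a", 3)), 0L)

  # w >= t: every ordered pair of distinct positions appears once
  for (t in c(2, 4, 7)) {
    p2 <- context_pairs(seq_len(t), t)
    expect_equal(nrow(p2), t * (t - 1L))
    expect_equal(nrow(unique(as.data.frame(p2))), t * (t - 1L))
  }
})

test_that("skip-gram embeddings have the right shape and are deterministic", {
  g <- random_graph(5, 4, p = 0.6, seed = 7)
  cfg <- walk_config(walk_length = 10, window = 3, epochs = 5, dim = 16,
                     seed = 9)
  corp <- build_corpus(g, cfg)
  psi <- train_skipgram(corp, cfg)
  expect_equal(dim(psi), c(n_nodes(g), 16L))
  expect_true(all(is.finite(psi)))
  expect_identical(psi, train_skipgram(corp, cfg))
  expect_identical(embed_nodes(g, cfg), embed_nodes(g, cfg))

  expect_error(train_skipgram(structure(list(), class = "walk_corpus",
                                        n_nodes = 4L), cfg),
               "nothing to train on")
})

test_that("negative sampling is a working alternative objective", {
  g <- random_graph(6, 5, p = 0.5, seed = 13)
  cfg <- walk_config(walk_length = 10, window = 3, epochs = 5, dim = 16,
                     objective = "ns", seed = 9)
  psi <- embed_nodes(g, cfg)
  expect_equal(dim(psi), c(n_nodes(g), 16L))
  expect_true(all(is.finite(psi)))
  expect_identical(psi, embed_nodes(g, cfg))
})

test_that("two disjoint bicliques separate in embedding space", {
  # community-separation oracle: walks never cross components, so intra
  # cosine similarity must exceed inter
  edges <- rbind(expand.grid(drug = paste0("a", 1:4), protein = paste0("x", 1:4)),
                 expand.grid(drug = paste0("b", 1:4), protein = paste0("y", 1:4)))
  g <- build_graph(edges)
  cfg <- walk_config(walk_length = 20, window = 4, epochs = 10, dim = 16,
                     seed = 21)
  psi <- embed_nodes(g, cfg)
  cs <- psi / sqrt(rowSums(psi^2))
  sim <- tcrossprod(cs)
  block <- ifelse(grepl("^[ax]", rownames(psi)), 1L, 2L)
  same <- outer(block, block, "==") & upper.tri(sim)
  diffb <- outer(block, block, "!=") & upper.tri(sim)
  expect_gt(mean(sim[same]), mean(sim[diffb]))
})

test_that("the hierarchical-softmax objective decreases over SGD passes", {
  g <- random_graph(4, 4, p = 0.6, seed = 31)
  cfg <- walk_config(walk_length = 8, window = 2, epochs = 2, dim = 8,
                     alpha = 0.01, seed = 3)
  corp <- build_corpus(g, cfg)
  psi <- train_skipgram(corp, cfg, passes = 5, eval_objective = TRUE)
  J <- attr(psi, "objective")
  expect_length(J, 6L)
  expect_true(all(diff(J) < 0))

  cfg_ns <- walk_config(objective = "ns", seed = 3)
  expect_error(train_skipgram(corp, cfg_ns, eval_objective = TRUE),
               "only defined for the hs objective")
})

test_that("community separation does not shrink as walk epochs grow", {
  gap <- function(gamma, seed) {
    sg <- synth_graph(12, 10, 2, 0.6, 0.05, seed = seed)
    cfg <- walk_config(walk_length = 10, window = 3, epochs = gamma,
                       dim = 8, seed = seed)
    psi <- suppressWarnings(embed_nodes(sg$graph, cfg))
    keep <- rowSums(psi != 0) > 0
    cs <- psi[keep, ] / sqrt(rowSums(psi[keep, , drop = FALSE]^2))
    sim <- tcrossprod(cs)
    bl <- c(sg$drug_blocks, sg$protein_blocks)[keep]
    same <- outer(bl, bl, "==") & upper.tri(sim)
    mean(sim[same]) - mean(sim[!same & upper.tri(sim)])
  }
  gaps1 <- vapply(1:5, function(s) gap(1L, s), 0.0)
  gaps20 <- vapply(1:5, function(s) gap(20L, s), 0.0)
  expect_gte(mean(gaps20), mean(gaps1))
})
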