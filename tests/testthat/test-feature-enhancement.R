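test_that("gini impurity matches its closed form", {
  expect_equal(gini_impurity(c(1, 0)), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(c(10, 10, 20)), 1 - (0.25^2 + 0.25^2 + 0.5^2))
  expect_error(gini_impurity(c(-1, 2)), "non-negative")
})

test_that("a label-determining feature is ranked first, matching the tree oracle", {
  withr::with_seed(3, {
    n <- 200
    y <- rep(0:2, length.out = n)
    x <- matrix(runif(n * 6), n, 6)
    x[, 1] <- y + runif(n, 0, 0.3)   # feature 1 separates the classes
  })
  ranking <- rank_features(x, y, n_trees = 25, seed = 1)
  expect_equal(ranking$ranking$feature_index[1], 1L)
  # independent check: exhaustive single Gini tree puts its importance on
  # feature 1 as well
  oracle <- oracle_tree(x, y)
  expect_equal(which.max(oracle$importance), 1L)
  # scores non-negative and sorted non-increasingly
  expect_true(all(ranking$ranking$importance >= 0))
  expect_true(all(diff(ranking$ranking$importance) <= 1e-12))
})

test_that("forest importance is the sum of its per-tree importances", {
  sm <- random_signal_matrix(n = 90, d = 12, seed = 5)
  total <- rank_features(sm, n_trees = 8, seed = 100)
  # tree j of the 8-tree forest is the same fit as the single tree of a
  # 1-tree ranking with base seed 100 + j - 1
  acc <- numeric(12)
  for (j in 1:8) {
    r1 <- rank_features(sm, n_trees = 1, seed = 100 + j - 1)
    idx <- order(r1$ranking$feature_index)
    acc <- acc + r1$ranking$importance[idx]
  }
  idx <- order(total$ranking$feature_index)
  expect_equal(total$ranking$importance[idx], acc, tolerance = 1e-10)
})

test_that("rank_features refuses single-class input and is deterministic", {
  x <- matrix(runif(40), 10, 4)
  expect_error(rank_features(x, rep(1, 10)), "single class")
  sm <- random_signal_matrix(n = 40, d = 6, seed = 2)
  expect_equal(rank_features(sm, n_trees = 5, seed = 9),
               rank_features(sm, n_trees = 5, seed = 9))
})

test_that("top-k selection preserves ranking order and validates k", {
  sm <- random_signal_matrix(n = 60, d = 10, seed = 4)
  ranking <- rank_features(sm, n_trees = 10, seed = 3)
  expect_equal(select_top_k(ranking, 10),
               ranking$ranking$feature_index)
  expect_length(select_top_k(ranking, 4), 4)
  expect_error(select_top_k(ranking, 11), "exceeds")
  # ties break toward the lower feature index
  tied <- structure(list(ranking = data.table::data.table(
    feature_index = c(2L, 1L, 3L), feature = c("b", "a", "c"),
    importance = c(5, 5, 1)), n_trees = 1L, seed = 1L),
    class = "importance_ranking")
  data.table::setorder(tied$ranking, -importance, feature_index)
  expect_equal(select_top_k(tied, 2), c(1L, 2L))
})

test_that("GAN training is deterministic and its discriminator outputs probabilities", {
  x <- withr::with_seed(8, matrix(rexp(200 * 4), 200, 4) *
                          (runif(800) < 0.4))
  cfg <- gan_config(epochs = 10, batch_size = 32, seed = 4)
  g1 <- train_gan(x, cfg)
  g2 <- train_gan(x, cfg)
  expect_equal(g1$generator, g2$generator)
  expect_identical(generate_features(g1, 20, seed = 2),
                   generate_features(g2, 20, seed = 2))
  p <- discriminate(g1, x)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(is.finite(as.matrix(g1$log[, -1]))))
  expect_error(train_gan(x[1:10, ], cfg), "batch_size")
  expect_error(train_gan(cbind(x, Inf), cfg), "finite")
})

test_that("a GAN on 1-D uniform data recovers the sample mean", {
  x <- withr::with_seed(1, matrix(runif(512, 0.4, 0.6), ncol = 1))
  g <- train_gan(x, gan_config(epochs = 2000, batch_size = 64,
                               noise_dim = 8, hidden = c(16, 16),
                               output_activation = "sigmoid", seed = 3))
  gen <- generate_features(g, 500, seed = 5)
  expect_lt(abs(mean(gen) - mean(x)), 0.1)
})

test_that("generated features lie within the training ranges", {
  x <- withr::with_seed(12, matrix(rexp(300 * 6, 0.2), 300, 6) *
                          (runif(1800) < 0.3))
  g <- train_gan(x, gan_config(epochs = 20, batch_size = 32, seed = 1))
  gen <- generate_features(g, 100, seed = 7)
  for (j in seq_len(ncol(x))) {
    expect_gte(min(gen[, j]), min(x[, j]))
    expect_lte(max(gen[, j]), max(x[, j]))
  }
})

test_that("appending a generated block widens the matrix without touching originals", {
  sm <- random_signal_matrix(n = 30, d = 8, seed = 3)
  block <- matrix(1, 30, 3,
                  dimnames = list(NULL, paste0("gen_", 1:3)))
  enh <- append_features(sm, block)
  expect_equal(ncol(enh$values), 11)
  expect_equal(enh$values[, 1:8], sm$values, ignore_attr = TRUE)
  expect_equal(enh$labels, sm$labels)
  expect_equal(enh$provenance, c(rep("real", 8), rep("generated", 3)))
  # zero-width block is the identity
  ident <- append_features(sm, matrix(0, 30, 0))
  expect_equal(ident$values, sm$values)
  expect_equal(ident$labels, sm$labels)
  expect_error(append_features(sm, matrix(1, 29, 2)), "row mismatch")
})

test_that("feature selection references original columns; enhancement keeps them all", {
  sm <- random_signal_matrix(n = 50, d = 9, seed = 6)
  before <- sm$values + 0
  out <- enhance_signal_matrix(sm, top_k = 4,
                               config = gan_config(epochs = 10,
                                                   batch_size = 16,
                                                   seed = 2),
                               n_trees = 10, seed = 5)
  expect_equal(sm$values, before)                       # no mutation
  expect_true(all(out$selected %in% seq_len(9)))
  expect_equal(ncol(out$enhanced$values), 9 + 4)
  expect_equal(out$enhanced$values[, 1:9], sm$values, ignore_attr = TRUE)
  expect_equal(sum(out$enhanced$provenance == "generated"), 4)
})

test_that("enhanced-matrix CSV carries a provenance header row", {
  sm <- random_signal_matrix(n = 20, d = 5, seed = 8)
  enh <- append_features(sm, matrix(0.5, 20, 2,
                                    dimnames = list(NULL, c("gen_a",
                                                            "gen_b"))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_enhanced_matrix(enh, f)
  lines <- readLines(f, n = 2L)
  expect_match(lines[2], "^provenance")
  expect_equal(length(strsplit(lines[1], ",")[[1]]),
               length(strsplit(lines[2], ",")[[1]]))
})
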