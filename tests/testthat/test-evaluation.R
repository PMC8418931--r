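test_that("confusion matrix counts true/predicted pairs and conserves n", {
  perfect <- confusion_matrix(c(0, 1, 2, 1), c(0, 1, 2, 1))
  expect_equal(sum(diag(perfect)), 4)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)

  m <- confusion_matrix(c(0, 0, 1), c(0, 1, 1))
  expect_equal(m["0", "0"], 1L)
  expect_equal(m["0", "1"], 1L)
  expect_equal(m["1", "1"], 1L)
  expect_equal(sum(m), 3)
  expect_error(confusion_matrix(c(0, 1), c(0)), "length mismatch")
})

test_that("per-class metrics follow the one-vs-rest definitions", {
  m <- confusion_matrix(c(0, 0, 0, 1, 1, 2), c(0, 0, 1, 1, 0, 2))
  c0 <- class_metrics(m, 0)
  expect_equal(c0$precision, 2 / 3)
  expect_equal(c0$recall, 2 / 3)
  expect_equal(c0$f1, 2 / 3)
  # degenerate denominators yield 0
  none <- confusion_matrix(c(0, 0), c(1, 1))
  c2 <- class_metrics(none, 2)
  expect_equal(unlist(c2), c(precision = 0, recall = 0, f1 = 0))
  # P = R = 1 gives F1 = 1; P or R = 0 gives F1 = 0
  expect_equal(class_metrics(confusion_matrix(0, 0), 0)$f1, 1)
})

test_that("accuracy is the trace over the total and mean per-sample correctness", {
  expect_equal(accuracy(confusion_matrix(c(0, 1, 2), c(0, 1, 2))), 1)
  expect_equal(accuracy(confusion_matrix(c(0, 1, 2), c(0, 0, 0))), 1 / 3)
  withr::with_seed(5, {
    true <- sample(0:2, 60, replace = TRUE)
    pred <- sample(0:2, 60, replace = TRUE)
    expect_equal(accuracy(confusion_matrix(true, pred)),
                 mean(true == pred))
  })
})

test_that("macro and weighted averages combine per-class metrics correctly", {
  pc <- data.frame(precision = c(0.9, 0.6, 0.3),
                   recall = c(0.8, 0.5, 0.2),
                   f1 = c(0.85, 0.55, 0.24))
  mac <- macro_average(pc)
  expect_equal(mac$macro_precision, 0.6)
  expect_equal(mac$macro_recall, 0.5)
  expect_equal(mac$macro_f1, mean(pc$f1))
  expect_equal(mac$macro_f1_pr, 2 * 0.6 * 0.5 / 1.1)
  # identical classes: macro equals the common value
  same <- data.frame(precision = rep(0.7, 3), recall = rep(0.7, 3),
                     f1 = rep(0.7, 3))
  expect_equal(unlist(macro_average(same))[1:3],
               c(macro_precision = 0.7, macro_recall = 0.7,
                 macro_f1 = 0.7))
  # equal class sizes make weighted equal macro
  w <- weighted_average(pc, c(10, 10, 10))
  expect_equal(w$weighted_precision, mac$macro_precision)
  # degenerate weights pick out one class
  w1 <- weighted_average(pc, c(5, 0, 0))
  expect_equal(unlist(w1), c(weighted_precision = 0.9,
                             weighted_recall = 0.8, weighted_f1 = 0.85))
})

test_that("weighted recall equals accuracy for any prediction", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      true <- sample(0:2, 50, replace = TRUE)
      pred <- sample(0:2, 50, replace = TRUE)
      r <- evaluate_predictions(true, pred)
      expect_equal(r$weighted$weighted_recall, r$accuracy,
                   tolerance = 1e-12)
    }
  })
})

test_that("ROC/AUC agree with Mann-Whitney pair counting on small instances", {
  # 6-sample binary toy
  positive <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  scores <- c(0.9, 0.7, 0.4, 0.6, 0.3, 0.1)
  true <- ifelse(positive, 0, 1)
  sc <- cbind(`0` = scores, `1` = 1 - scores, `2` = 0)
  r <- suppressWarnings(roc_auc(true, sc))
  expect_equal(unname(r$auc["0"]), oracle_auc(positive, scores))
  # random instances, including ties
  withr::with_seed(10, {
    for (rep in 1:10) {
      n <- 20
      pos <- runif(n) < 0.4
      s <- round(runif(n), 1)
      tr <- ifelse(pos, 0, 1)
      m <- cbind(`0` = s, `1` = 1 - s, `2` = 0)
      got <- suppressWarnings(roc_auc(tr, m))$auc[["0"]]
      expect_equal(got, oracle_auc(pos, s), tolerance = 1e-12)
    }
  })
})

test_that("ROC endpoints, perfect separation, chance level and degeneracy", {
  true <- rep(c(0, 1), each = 10)
  perfect <- cbind(`0` = rep(c(0.9, 0.1), each = 10),
                   `1` = rep(c(0.1, 0.9), each = 10), `2` = 0)
  r <- suppressWarnings(roc_auc(true, perfect))
  expect_equal(unname(r$auc[c("0", "1")]), c(1, 1))
  for (pts in r$roc) {
    expect_equal(as.numeric(pts[1]), c(0, 0))
    expect_equal(as.numeric(pts[nrow(pts)]), c(1, 1))
  }
  # large-n random scores sit near chance
  withr::with_seed(11, {
    n <- 4000
    tr <- sample(0:1, n, replace = TRUE)
    s <- runif(n)
    auc <- suppressWarnings(roc_auc(tr, cbind(`0` = s, `1` = 1 - s,
                                              `2` = 0)))$auc[["0"]]
    expect_lt(abs(auc - 0.5), 0.05)
  })
  # reversed scores rank the class backwards: AUC < 0.5, flagged
  wb <- capture_warnings(
    bad <- roc_auc(true[1:20],
                   cbind(`0` = rep(c(0.1, 0.9), each = 10),
                         `1` = rep(c(0.9, 0.1), each = 10),
                         `2` = seq(0, 1, length.out = 20))))
  expect_match(wb, "below chance", all = FALSE)
  expect_lt(bad$auc[["0"]], 0.5)

  # constant scores: one degenerate warning per class, AUC 0.5
  w <- capture_warnings(
    rc <- roc_auc(true, cbind(`0` = 0.5, `1` = 0.3, `2` = 0.2)[rep(1, 20), ]))
  expect_length(w, 3)
  expect_match(w, "degenerate", all = TRUE)
  expect_equal(unname(rc$auc), rep(0.5, 3))
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    n <- 50
    pos <- runif(n) < 0.5
    s <- runif(n)
  })
  ours <- suppressWarnings(
    roc_auc(ifelse(pos, 0, 1), cbind(`0` = s, `1` = 1 - s, `2` = 0)))$auc[["0"]]
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(pos, s,
                                                         direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("evaluation report bundles all metrics and serializes to JSON", {
  withr::with_seed(13, {
    true <- sample(0:2, 40, replace = TRUE)
    pred <- sample(0:2, 40, replace = TRUE)
    scores <- matrix(runif(120), 40)
    scores <- scores / rowSums(scores)
    colnames(scores) <- as.character(0:2)
  })
  r <- evaluate_predictions(true, pred, scores)
  expect_s3_class(r, "evaluation_report")
  expect_equal(sum(r$confusion), 40)
  expect_true(all(unlist(r$per_class[, -1]) >= 0 &
                    unlist(r$per_class[, -1]) <= 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(r, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$accuracy, r$accuracy)
  expect_equal(back$n, 40)
})
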