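## Random-forest risk classifier. The forest contract -- bootstrap samples
## of size N per tree, Gini splits over a random feature subset at every
## node, trees grown to purity without pruning, prediction by vote -- is
## delegated to ranger; vote aggregation and tie-breaking are done here so
## ties resolve deterministically toward the lower label.

#' Random-forest configuration
#'
#' @param n_trees number of trees `K`.
#' @param mtry features tried per split: `"sqrt"` (default, `floor(sqrt(d))`)
#'   or an integer.
#' @param seed integer seed; training is deterministic.
#' @param replace bootstrap with replacement (the standard scheme). Setting
#'   `replace = FALSE` with `sample_fraction = 1` makes each tree see the
#'   identity sample, which is how a single fully-deterministic Gini tree is
#'   obtained.
#' @param sample_fraction fraction of the training set drawn per tree.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, mtry = "sqrt", seed = 1L,
                          replace = TRUE, sample_fraction = 1) {
  structure(list(n_trees = check_count(n_trees, "n_trees"),
                 mtry = mtry, seed = as.integer(seed),
                 replace = isTRUE(replace),
                 sample_fraction = check_fraction(sample_fraction,
                                                  "sample_fraction",
                                                  lo_open = TRUE)),
            class = "forest_config")
}

#' Train the random-forest risk classifier
#'
#' @param x feature matrix, `balanced_dataset`, `signal_matrix` or
#'   `enhanced_matrix`.
#' @param labels integer class labels (taken from `x` when it carries them).
#' @param config a [forest_config()].
#' @return An object of class `risk_forest` wrapping the fitted forest, the
#'   class levels, feature names and config.
#' @export
train_forest <- function(x, labels = NULL, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  if (inherits(x, "balanced_dataset")) {
    labels <- x$labels
    x <- x$features
  } else if (inherits(x, c("signal_matrix", "enhanced_matrix"))) {
    labels <- x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("cannot train on a single class", call. = FALSE)
  }
  d <- ncol(x)
  mtry <- if (identical(config$mtry, "sqrt")) max(1L, floor(sqrt(d))) else
    check_count(config$mtry, "mtry")
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(d))
  levels <- sort(unique(labels))
  fit <- ranger::ranger(x = df, y = factor(labels, levels = levels),
                        num.trees = config$n_trees, mtry = mtry,
                        min.node.size = 1L, replace = config$replace,
                        sample.fraction = config$sample_fraction,
                        seed = config$seed, num.threads = 1L)
  structure(list(fit = fit, levels = levels, n_features = d,
                 config = config),
            class = "risk_forest")
}

#' Per-class vote fractions of the forest
#'
#' Every tree casts one vote per sample; scores are vote counts divided by
#' the number of trees, so each row sums to 1.
#'
#' @param forest a [train_forest()] model.
#' @param x feature matrix with the training feature count.
#' @return `n x n_classes` matrix of vote fractions, columns named by label.
#' @export
predict_scores <- function(forest, x) {
  stopifnot(inherits(forest, "risk_forest"))
  if (inherits(x, "balanced_dataset")) x <- x$features
  if (inherits(x, c("signal_matrix", "enhanced_matrix"))) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) != forest$n_features) {
    stop(sprintf("feature-count mismatch: model expects %d features, got %d",
                 forest$n_features, ncol(x)), call. = FALSE)
  }
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  votes <- predict(forest$fit, data = df, predict.all = TRUE,
                   num.threads = 1L)$predictions
  n_class <- length(forest$levels)
  scores <- t(apply(votes, 1L, tabulate, nbins = n_class)) /
    forest$fit$num.trees
  colnames(scores) <- as.character(forest$levels)
  scores
}

#' Predict risk-class labels by majority vote
#'
#' Argmax of the vote fractions; ties resolve to the lowest label.
#'
#' @inheritParams predict_scores
#' @return Integer vector of predicted labels.
#' @export
predict_labels <- function(forest, x) {
  scores <- predict_scores(forest, x)
  forest$levels[apply(scores, 1L, which_max_first)]
}

#' @export
print.risk_forest <- function(x, ...) {
  cat(sprintf("risk forest: %d trees, %d features, classes %s\n",
              x$fit$num.trees, x$n_features,
              paste(x$levels, collapse = "/")))
  invisible(x)
}
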