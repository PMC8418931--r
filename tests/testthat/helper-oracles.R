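# Independent oracles used to cross-check the implementation.

# Brute-force PRR from raw (drug, adr) record pairs: enumerate the four
# contingency cells by counting records, then apply the same zero-handling
# rules as prr().
oracle_prr_matrix <- function(records, zero_correction = "haldane",
                              cap = 100) {
  drugs <- sort(unique(records$drug_name))
  adrs <- sort(unique(records$adr_symptom))
  out <- matrix(0, length(drugs), length(adrs),
                dimnames = list(drugs, adrs))
  for (i in seq_along(drugs)) {
    for (j in seq_along(adrs)) {
      is_d <- records$drug_name == drugs[i]
      is_a <- records$adr_symptom == adrs[j]
      A <- sum(is_d & is_a)
      if (A == 0) next
      B <- sum(is_d & !is_a)
      C <- sum(!is_d & is_a)
      D <- sum(!is_d & !is_a)
      out[i, j] <- if (C == 0) {
        if (zero_correction == "cap") cap else
          ((A + 0.5) / (A + B + 1)) / ((C + 0.5) / (C + D + 1))
      } else {
        (A / (A + B)) / (C / (C + D))
      }
    }
  }
  out
}

# Exhaustive all-pairs Euclidean distance sort for k nearest neighbors,
# ties broken by index.
oracle_knn <- function(x, i, k) {
  d <- sqrt(colSums((t(x) - x[i, ])^2))
  ord <- order(d, seq_len(nrow(x)))
  ord <- ord[ord != i]
  ord[seq_len(k)]
}

# Mann-Whitney pair-counting AUC: fraction of (positive, negative) pairs
# ordered correctly, ties counted 1/2.
oracle_auc <- function(positive, scores) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Gini decision tree: tries every feature and every midpoint
# threshold, picks the split with minimum weighted child impurity
# (ties: lowest feature, lowest threshold), recurses to purity.
# Returns a nested list usable by oracle_tree_predict; accumulates
# per-feature Gini importance (impurity decrease weighted by node size).
oracle_tree <- function(x, y, importance = NULL) {
  if (is.null(importance)) importance <- numeric(ncol(x))
  gini <- function(lab) {
    p <- table(lab) / length(lab)
    1 - sum(p^2)
  }
  build <- function(idx) {
    lab <- y[idx]
    if (length(unique(lab)) == 1L) {
      return(list(leaf = TRUE, label = lab[1]))
    }
    best <- list(score = Inf)
    for (f in seq_len(ncol(x))) {
      v <- x[idx, f]
      cuts <- sort(unique(v))
      if (length(cuts) < 2L) next
      mids <- (head(cuts, -1) + cuts[-1]) / 2
      for (th in mids) {
        l <- idx[v <= th]
        r <- idx[v > th]
        score <- (length(l) * gini(y[l]) + length(r) * gini(y[r])) /
          length(idx)
        if (score < best$score - 1e-12) {
          best <- list(score = score, f = f, th = th, l = l, r = r)
        }
      }
    }
    if (!is.finite(best$score)) {
      # constant features with mixed labels: majority leaf
      tab <- table(y[idx])
      return(list(leaf = TRUE, label = names(tab)[which.max(tab)]))
    }
    decrease <- (gini(lab) - best$score) * length(idx) / length(y)
    importance[best$f] <<- importance[best$f] + decrease
    list(leaf = FALSE, f = best$f, th = best$th,
         left = build(best$l), right = build(best$r))
  }
  tree <- build(seq_along(y))
  list(tree = tree, importance = importance)
}

oracle_tree_predict <- function(tree, x) {
  predict_one <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$f] <= node$th) node$left else node$right
    }
    node$label
  }
  apply(x, 1L, function(r) predict_one(tree$tree, r))
}

# quick random labeled sparse PRR-like matrix
random_signal_matrix <- function(n = 60, d = 20, seed = 1) {
  withr::with_seed(seed, {
    values <- matrix(stats::rexp(n * d, rate = 0.3), n, d) *
      (stats::runif(n * d) < 0.3)
    colnames(values) <- sprintf("adr_%03d", seq_len(d))
    structure(list(drugs = sprintf("drug_%03d", seq_len(n)),
                   adr_terms = colnames(values),
                   values = values,
                   labels = rep(0:2, length.out = n)),
              class = "signal_matrix")
  })
}

# small synthetic corpus -> labeled signal matrix
small_signal_matrix <- function(seed = 1, n_rx = 30, n_otc_a = 12,
                                n_otc_b = 8, n_adr = 60, mu = 40, ...) {
  cfg <- generator_config(n_rx = n_rx, n_otc_a = n_otc_a, n_otc_b = n_otc_b,
                          n_adr_terms = n_adr, reports_per_drug_mean = mu,
                          seed = seed, ...)
  catalog <- generate_catalog(cfg)
  reports <- generate_reports(cfg, catalog)
  cleaned <- clean_reports(reports)
  tab <- attach_labels(aggregate_counts(cleaned$reports), catalog$drugs)
  build_signal_matrix(tab)
}
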