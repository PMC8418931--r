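## SMOTE minority oversampling, written out from first principles: for each
## minority sample find its k nearest minority neighbors by Euclidean
## distance, pick a neighbor at random, and place a synthetic sample at a
## random point on the segment between the two. Used to grow the OTC-A and
## OTC-B classes to the Rx class size.

#' SMOTE configuration
#'
#' @param k_neighbors number of nearest minority neighbors considered for
#'   each minority sample (Chawla's default of 5).
#' @param seed integer seed; balancing is deterministic given the seed.
#' @param balance_mode `"exact_majority"` grows each minority class to
#'   exactly the majority-class count; `"k_times"` synthesizes exactly
#'   `K * N-` samples per minority class, where `K = floor(N+ / N-)` is the
#'   oversampling rate from the imbalance ratio. With class counts
#'   887/113/47 the two modes give 887/887/887 and 887/904/893
#'   respectively; `exact_majority` is the default because it yields the
#'   fully balanced design.
#' @param direction `"interpolate"` places synthetic samples between a
#'   sample and its neighbor (`x + u (xbar - x)`, the canonical SMOTE rule);
#'   `"extrapolate"` mirrors the step away from the neighbor
#'   (`x + u (x - xbar)`).
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5L, seed = 1L,
                         balance_mode = c("exact_majority", "k_times"),
                         direction = c("interpolate", "extrapolate")) {
  structure(list(k_neighbors = check_count(k_neighbors, "k_neighbors"),
                 seed = as.integer(seed),
                 balance_mode = match.arg(balance_mode),
                 direction = match.arg(direction)),
            class = "smote_config")
}

#' Imbalance ratio and oversampling rate
#'
#' `IR = N+ / N-` (majority over minority count) and `K = floor(IR)`, the
#' integer oversampling rate.
#'
#' @param n_major majority-class count.
#' @param n_minor minority-class count (> 0).
#' @return List with `IR` (real) and `K` (integer).
#' @export
#' @examples
#' imbalance_ratio(887, 47) # IR ~ 18.87, K = 18
imbalance_ratio <- function(n_major, n_minor) {
  if (n_minor <= 0) stop("degenerate class: minority count must be > 0",
                         call. = FALSE)
  ir <- n_major / n_minor
  list(IR = ir, K = as.integer(floor(ir)))
}

#' k nearest minority neighbors of a minority sample
#'
#' Euclidean distance to every other sample in the minority set; returns the
#' `k` nearest, excluding the sample itself, with distance ties broken by
#' ascending sample index.
#'
#' @param minority numeric matrix of minority-class samples (rows).
#' @param i row index of the query sample within `minority`.
#' @param k number of neighbors; requires at least `k + 1` minority samples.
#' @return Integer vector of `k` row indices.
#' @export
nearest_minority_neighbors <- function(minority, i, k) {
  minority <- as.matrix(minority)
  n <- nrow(minority)
  if (n < k + 1L) {
    stop(sprintf(
      "minority class too small for SMOTE: %d samples, need at least k + 1 = %d",
      n, k + 1L), call. = FALSE)
  }
  d2 <- colSums((t(minority) - minority[i, ])^2)
  ord <- order(d2, seq_len(n))
  ord <- ord[ord != i]
  ord[seq_len(k)]
}

#' Synthesize one SMOTE sample
#'
#' @param x minority sample (numeric vector).
#' @param neighbor one of its minority neighbors.
#' @param u random scalar in (0, 1).
#' @param direction see [smote_config()].
#' @return The synthetic sample, collinear with `x` and `neighbor`.
#' @export
synthesize <- function(x, neighbor, u,
                       direction = c("interpolate", "extrapolate")) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(neighbor))
  if (direction == "interpolate") x + u * (neighbor - x) else
    x + u * (x - neighbor)
}

#' Balance classes by SMOTE minority oversampling
#'
#' Identifies the majority class (ties break toward the lower label) and
#' oversamples every other class per the configuration. All original rows
#' are retained unchanged; synthetic rows are appended after them and
#' flagged. In `exact_majority` mode the synthetic count `G` for a class of
#' size `n` is `n_major - n`, spread as evenly as possible over the class's
#' samples (the first `G mod n` samples get one extra).
#'
#' @param x numeric feature matrix, a `signal_matrix` or an
#'   `enhanced_matrix`.
#' @param labels integer class labels (taken from `x` when it carries them).
#' @param config a [smote_config()].
#' @return An object of class `balanced_dataset`: list with `features`,
#'   `labels`, logical `synthetic` flags, row `ids`, and `provenance`
#'   (data.table with, per synthetic row, the base row id, neighbor row id
#'   and interpolation draw `u`).
#' @export
balance_classes <- function(x, labels = NULL, config = smote_config()) {
  stopifnot(inherits(config, "smote_config"))
  ids <- NULL
  if (inherits(x, c("signal_matrix", "enhanced_matrix"))) {
    labels <- x$labels
    ids <- x$drugs
    x <- x$values
  }
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.null(ids)) ids <- if (is.null(rownames(x)))
    sprintf("row_%04d", seq_len(nrow(x))) else rownames(x)

  counts <- table(labels)
  class_levels <- as.integer(names(counts))
  major_label <- class_levels[which_max_first(as.vector(counts))]
  n_major <- max(counts)

  syn_feats <- list()
  syn_labels <- integer()
  prov <- list()
  with_seed(config$seed, {
    for (cl in class_levels) {
      if (cl == major_label) next
      rows <- which(labels == cl)
      n <- length(rows)
      n_syn <- if (config$balance_mode == "exact_majority") {
        n_major - n
      } else {
        imbalance_ratio(n_major, n)$K * n
      }
      if (n_syn == 0L) next
      if (n < config$k_neighbors + 1L) {
        stop(sprintf(
          "class %d has %d samples; SMOTE with k = %d needs at least %d",
          cl, n, config$k_neighbors, config$k_neighbors + 1L), call. = FALSE)
      }
      sub <- x[rows, , drop = FALSE]
      nn <- t(vapply(seq_len(n), function(i)
        nearest_minority_neighbors(sub, i, config$k_neighbors),
        integer(config$k_neighbors)))
      per_sample <- rep(n_syn %/% n, n) +
        (seq_len(n) <= n_syn %% n)
      base_idx <- rep(seq_len(n), per_sample)
      nb_pick <- sample.int(config$k_neighbors, n_syn, replace = TRUE)
      u <- stats::runif(n_syn)
      newx <- matrix(0, n_syn, ncol(x))
      for (s in seq_len(n_syn)) {
        b <- base_idx[s]
        nb <- nn[b, nb_pick[s]]
        newx[s, ] <- synthesize(sub[b, ], sub[nb, ], u[s],
                                direction = config$direction)
      }
      syn_feats[[length(syn_feats) + 1L]] <- newx
      syn_labels <- c(syn_labels, rep(cl, n_syn))
      prov[[length(prov) + 1L]] <- data.table::data.table(
        label = cl,
        base_id = ids[rows[base_idx]],
        neighbor_id = ids[rows[nn[cbind(base_idx, nb_pick)]]],
        u = u)
    }
  })

  syn <- if (length(syn_feats)) do.call(rbind, syn_feats) else
    matrix(0, 0L, ncol(x))
  colnames(syn) <- colnames(x)
  features <- rbind(x, syn)
  all_labels <- c(labels, syn_labels)
  synthetic <- c(rep(FALSE, nrow(x)), rep(TRUE, nrow(syn)))
  all_ids <- c(ids, if (nrow(syn)) sprintf("syn_%d_%04d", syn_labels,
                                           seq_len(nrow(syn))) else character())
  rownames(features) <- all_ids
  structure(list(features = features, labels = all_labels,
                 synthetic = synthetic, ids = all_ids,
                 provenance = if (length(prov)) data.table::rbindlist(prov)
                 else data.table::data.table(),
                 config = config),
            class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("balanced dataset: %d samples (%d synthetic), class counts %s\n",
              nrow(x$features), sum(x$synthetic),
              paste(sprintf("%s=%d", names(tab), as.vector(tab)),
                    collapse = " ")))
  invisible(x)
}

#' @rdname balance_classes
#' @param dataset a `balanced_dataset`.
#' @param path output CSV path; schema matches the enhanced-matrix CSV plus
#'   a `synthetic` flag column.
#' @export
write_balanced_dataset <- function(dataset, path) {
  dt <- data.table::as.data.table(dataset$features)
  dt <- cbind(data.table::data.table(id = dataset$ids), dt,
              data.table::data.table(label = dataset$labels,
                                     synthetic = dataset$synthetic))
  data.table::fwrite(dt, path)
  invisible(path)
}
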