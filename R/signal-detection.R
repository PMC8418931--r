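## PRR disproportionality signal detection.
##
## For each drug--ADR pair the standard 2x2 contingency table is formed over
## report mentions:
##
##                    target ADR   other ADRs
##   target drug          A            B
##   other drugs          C            D
##
## and the proportional reporting ratio PRR = (A/(A+B)) / (C/(C+D))
## quantifies how disproportionately the ADR is reported for the drug.
## PRR > 1 indicates the drug reports the ADR more often than the rest of
## the database does.

#' Build the 2x2 contingency table for one drug--ADR pair
#'
#' Counting units are cleaned report mentions: `A` is the number of mentions
#' pairing the target drug with the target ADR, `B` the drug's other
#' mentions, `C` the ADR's mentions under other drugs, and `D` everything
#' else, so `A + B + C + D` equals the grand total.
#'
#' @param table a `drug_adr_counts` object.
#' @param drug,adr drug/ADR name (character) or index.
#' @return An object of class `contingency_cells`, a list with `A`, `B`,
#'   `C`, `D`.
#' @export
contingency <- function(table, drug, adr) {
  stopifnot(inherits(table, "drug_adr_counts"))
  i <- if (is.character(drug)) match(drug, table$drugs) else as.integer(drug)
  j <- if (is.character(adr)) match(adr, table$adr_terms) else as.integer(adr)
  if (is.na(i) || i < 1L || i > length(table$drugs)) {
    stop("unknown drug: ", drug, call. = FALSE)
  }
  if (is.na(j) || j < 1L || j > length(table$adr_terms)) {
    stop("unknown ADR term: ", adr, call. = FALSE)
  }
  A <- table$counts[i, j]
  B <- table$row_totals[[i]] - A
  C <- table$col_totals[[j]] - A
  D <- table$grand_total - A - B - C
  structure(list(A = A, B = B, C = C, D = D), class = "contingency_cells")
}

#' Proportional reporting ratio of a 2x2 contingency table
#'
#' Computes `PRR = (A/(A+B)) / (C/(C+D))`. The source data never pins down
#' the degenerate cases, so they are handled by explicit rules:
#' * `A = 0`: the pair was never reported; PRR is defined as 0 (no signal).
#' * `A > 0, C = 0`: the raw ratio is infinite. Under
#'   `zero_correction = "haldane"` (default) the Haldane--Anscombe
#'   continuity correction adds 0.5 to all four cells; under `"cap"` the
#'   result is replaced by `cap`.
#' * `A + B = 0` is an error: PRR is undefined for a drug with no mentions.
#'
#' @param cells a `contingency_cells` object (or list with `A`,`B`,`C`,`D`).
#' @param zero_correction how to keep the value finite when `C = 0`.
#' @param cap ceiling used when `zero_correction = "cap"`.
#' @return A single non-negative finite number.
#' @export
#' @examples
#' prr(list(A = 10, B = 90, C = 10, D = 890)) # 9
prr <- function(cells, zero_correction = c("haldane", "cap"), cap = 100) {
  zero_correction <- match.arg(zero_correction)
  A <- cells$A; B <- cells$B; C <- cells$C; D <- cells$D
  if (any(c(A, B, C, D) < 0)) stop("contingency cells must be non-negative",
                                   call. = FALSE)
  if (A + B == 0) {
    stop("PRR undefined: target drug has no mentions (A + B = 0)",
         call. = FALSE)
  }
  if (A == 0) return(0)
  if (C == 0) {
    if (zero_correction == "cap") return(cap)
    A <- A + 0.5; B <- B + 0.5; C <- C + 0.5; D <- D + 0.5
  }
  (A / (A + B)) / (C / (C + D))
}

#' Build the PRR signal matrix from a labeled count table
#'
#' Computes the PRR for every drug--ADR pair with a nonzero count; cells
#' with a zero count stay exactly 0, so the signal matrix preserves the
#' sparsity pattern of the count table. Drugs are samples (rows), ADR terms
#' are features (columns), and the per-drug risk-class label (0/1/2) rides
#' along as the final column when written out.
#'
#' @param table a `drug_adr_counts`, labeled via [attach_labels()] (or pass
#'   `labels`).
#' @param labels optional labels, as in [attach_labels()].
#' @inheritParams prr
#' @return An object of class `signal_matrix`: list with `drugs`,
#'   `adr_terms`, numeric `values` matrix, integer `labels`, and the
#'   zero-handling settings used.
#' @export
build_signal_matrix <- function(table, labels = NULL,
                                zero_correction = c("haldane", "cap"),
                                cap = 100) {
  zero_correction <- match.arg(zero_correction)
  if (!is.null(labels)) table <- attach_labels(table, labels)
  if (is.null(table$labels)) {
    stop("count table has no labels; call attach_labels() first",
         call. = FALSE)
  }
  A <- table$counts
  rt <- table$row_totals
  ct <- table$col_totals
  n <- table$grand_total
  B <- sweep(A, 1L, rt, function(a, r) r - a)
  C <- sweep(A, 2L, ct, function(a, c) c - a)
  D <- n - A - B - C

  values <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  pos <- A > 0
  czero <- pos & (C == 0)
  plain <- pos & !czero
  values[plain] <- (A[plain] / (A[plain] + B[plain])) /
    (C[plain] / (C[plain] + D[plain]))
  if (any(czero)) {
    if (zero_correction == "cap") {
      values[czero] <- cap
    } else {
      Ah <- A[czero] + 0.5; Bh <- B[czero] + 0.5
      Ch <- C[czero] + 0.5; Dh <- D[czero] + 0.5
      values[czero] <- (Ah / (Ah + Bh)) / (Ch / (Ch + Dh))
    }
  }
  structure(list(drugs = table$drugs, adr_terms = table$adr_terms,
                 values = values, labels = table$labels,
                 zero_correction = zero_correction, cap = cap),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("PRR signal matrix: %d drugs x %d ADR terms (%.2f%% nonzero)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$values > 0)))
  cat("class counts:",
      paste(sprintf("%d=%d", 0:2, tabulate(x$labels + 1L, 3L)),
            collapse = " "), "\n")
  invisible(x)
}

#' Fraction of nonzero entries of a matrix
#'
#' The PRR matrix is sparse because a drug causes only a small subset of all
#' ADR terms; this fraction is the package's sparsity measure. A small
#' threshold `eps` makes the measure well-defined for continuous generated
#' values that are never exactly zero.
#'
#' @param x numeric matrix (or `signal_matrix`).
#' @param eps threshold on the PRR scale; entries `> eps` count as nonzero.
#' @return Fraction in `[0, 1]`.
#' @export
nonzero_fraction <- function(x, eps = 0.01) {
  if (inherits(x, "signal_matrix")) x <- x$values
  mean(x > eps)
}

#' @rdname build_signal_matrix
#' @param x a `signal_matrix`.
#' @param path output CSV path: first column `drug_name`, one column per
#'   ADR term, final column `label`.
#' @export
write_signal_matrix <- function(x, path) {
  dt <- data.table::as.data.table(x$values)
  dt <- cbind(data.table::data.table(drug_name = x$drugs), dt,
              data.table::data.table(label = x$labels))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname build_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  dt <- data.table::fread(path)
  values <- as.matrix(dt[, !c("drug_name", "label")])
  rownames(values) <- dt$drug_name
  structure(list(drugs = dt$drug_name,
                 adr_terms = colnames(values),
                 values = values,
                 labels = as.integer(dt$label),
                 zero_correction = NA_character_, cap = NA_real_),
            class = "signal_matrix")
}
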