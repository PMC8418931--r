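## ETL for spontaneous reports: cleaning, name standardization, and
## aggregation into the drug-by-ADR count table that signal detection
## operates on.

#' Clean a spontaneous-report corpus
#'
#' Removes records with a missing drug name or ADR term ("no reference
#' value"), then removes exact duplicates on the key
#' `(report_id, drug_name, adr_symptom)`, keeping the first occurrence.
#' Two records that differ only in `report_id` are distinct reports of the
#' same drug--ADR pair and are both kept.
#'
#' @param reports data.table/data.frame with at least `report_id`,
#'   `drug_name`, `adr_symptom` columns.
#' @return A list with `reports` (the cleaned data.table) and `log`, a list
#'   with the total raw count `raw`, kept count `kept`, and rejected counts
#'   by reason (`incomplete`, `duplicate`).
#' @export
#' @examples
#' r <- data.frame(report_id = c("a", "a", "b"),
#'                 drug_name = c("d1", "d1", NA),
#'                 adr_symptom = c("rash", "rash", "rash"))
#' clean_reports(r)$log
clean_reports <- function(reports) {
  reports <- data.table::as.data.table(reports)
  n_raw <- nrow(reports)
  if (n_raw == 0L) {
    return(list(reports = reports,
                log = list(raw = 0L, kept = 0L,
                           incomplete = 0L, duplicate = 0L)))
  }
  complete <- !is.na(reports$drug_name) & reports$drug_name != "" &
    !is.na(reports$adr_symptom) & reports$adr_symptom != ""
  valid <- reports[complete]
  dup <- duplicated(valid, by = c("report_id", "drug_name", "adr_symptom"))
  kept <- valid[!dup]
  list(reports = kept,
       log = list(raw = n_raw,
                  kept = nrow(kept),
                  incomplete = n_raw - nrow(valid),
                  duplicate = sum(dup)))
}

#' Standardize drug and ADR term names with an explicit synonym map
#'
#' Applies a term-to-canonical-term map to the `drug_name` and `adr_symptom`
#' columns. Terms absent from the map pass through unchanged; the operation
#' is idempotent. The map must itself be canonical: any value that also
#' appears as a key must map to itself.
#'
#' @param reports report data.table/data.frame.
#' @param synonym_map named character vector, `names` are raw terms and
#'   values are canonical terms. An empty map is a no-op.
#' @return The reports with standardized names.
#' @export
standardize_names <- function(reports, synonym_map = character()) {
  reports <- data.table::as.data.table(reports)
  if (length(synonym_map) == 0L) return(reports)
  if (is.null(names(synonym_map)) || any(names(synonym_map) == "")) {
    stop("`synonym_map` must be a fully named character vector",
         call. = FALSE)
  }
  bad <- intersect(unname(synonym_map), names(synonym_map))
  bad <- bad[synonym_map[bad] != bad]
  if (length(bad)) {
    stop("non-idempotent synonym map: value(s) ",
         paste(sQuote(bad), collapse = ", "),
         " are themselves mapped to a different term", call. = FALSE)
  }
  canon <- function(x) {
    hit <- x %in% names(synonym_map)
    x[hit] <- unname(synonym_map[x[hit]])
    x
  }
  out <- data.table::copy(reports)
  out[, drug_name := canon(drug_name)]
  out[, adr_symptom := canon(adr_symptom)]
  out[]
}

#' Aggregate cleaned reports into a drug-by-ADR count table
#'
#' Each cleaned record increments the count of its (drug, ADR) cell by one,
#' so the grand total equals the number of cleaned records. Drugs and ADR
#' terms with no cleaned records do not appear. Row/column order is
#' lexicographic in the (standardized) names, making the result independent
#' of input record order.
#'
#' @param reports cleaned (and standardized) reports.
#' @return An object of class `drug_adr_counts`: list with `drugs`,
#'   `adr_terms`, the integer `counts` matrix, `row_totals`, `col_totals`
#'   and `grand_total`.
#' @export
aggregate_counts <- function(reports) {
  reports <- data.table::as.data.table(reports)
  if (nrow(reports) == 0L) {
    counts <- matrix(0L, 0L, 0L)
    return(structure(list(drugs = character(), adr_terms = character(),
                          counts = counts, row_totals = integer(),
                          col_totals = integer(), grand_total = 0L),
                     class = "drug_adr_counts"))
  }
  tab <- reports[, .N, by = .(drug_name, adr_symptom)]
  drugs <- sort(unique(tab$drug_name))
  adr_terms <- sort(unique(tab$adr_symptom))
  counts <- matrix(0L, length(drugs), length(adr_terms),
                   dimnames = list(drugs, adr_terms))
  counts[cbind(match(tab$drug_name, drugs),
               match(tab$adr_symptom, adr_terms))] <- tab$N
  structure(list(drugs = drugs, adr_terms = adr_terms, counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts)),
            class = "drug_adr_counts")
}

#' Attach risk-class labels to a count table
#'
#' @param table a `drug_adr_counts` object.
#' @param labels either a named vector (names = drug names, values in
#'   0/1/2) or a data.frame with columns `drug_name`, `label`. Every drug in
#'   the table must be present.
#' @return The table with a `labels` integer vector aligned to its drug
#'   order (0 = Rx, 1 = OTC-A, 2 = OTC-B).
#' @export
attach_labels <- function(table, labels) {
  stopifnot(inherits(table, "drug_adr_counts"))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$drug_name)
  }
  missing <- setdiff(table$drugs, names(labels))
  if (length(missing)) {
    stop("no label for drug(s): ",
         paste(sQuote(utils::head(missing, 5L)), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)",
                                           length(missing) - 5L),
         call. = FALSE)
  }
  lab <- as.integer(labels[table$drugs])
  if (any(is.na(lab)) || !all(lab %in% 0:2)) {
    stop("labels must be 0 (Rx), 1 (OTC-A) or 2 (OTC-B)", call. = FALSE)
  }
  table$labels <- lab
  table
}

#' @rdname aggregate_counts
#' @param table a `drug_adr_counts` object.
#' @param path file path; counts are written as CSV with drugs as rows and
#'   ADR terms as columns.
#' @export
write_count_table <- function(table, path) {
  dt <- data.table::as.data.table(table$counts, keep.rownames = "drug_name")
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname clean_reports
#' @param log a rejection log from `clean_reports()`.
#' @param path file path for the JSON rejection log.
#' @export
write_rejection_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
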