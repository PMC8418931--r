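## Synthetic spontaneous-report generator.
##
## Emulates the statistical structure of a large regional spontaneous
## reporting system (SRS) extract: ~1000 drugs in three risk classes with
## strongly imbalanced class sizes, ~750 ADR symptom terms, a sparse
## drug-by-ADR co-occurrence structure, plus duplicated and incomplete
## records to exercise the cleaning stage. Nothing here attempts to
## reproduce real term vocabularies, MedDRA coding or temporal trends.

#' Configuration for the synthetic spontaneous-report generator
#'
#' @param n_rx,n_otc_a,n_otc_b Number of drugs in the prescription (label 0),
#'   OTC-A (label 1) and OTC-B (label 2) classes. Defaults are the class
#'   sizes of the motivating pharmacovigilance extract (887/113/47).
#' @param n_adr_terms Number of distinct ADR symptom terms in the vocabulary.
#' @param reports_per_drug_mean Mean of the Poisson distribution of report
#'   counts per drug. 50 reports/drug is enough for stable PRR values while
#'   keeping corpora small; real extracts are much deeper.
#' @param class_profile_shift In `[0, 1]`: probability that a report's ADR
#'   term is drawn from the drug's class-typical term pool rather than from
#'   the shared background distribution. 0 makes the three classes
#'   statistically indistinguishable; 1 makes every report class-typical.
#' @param target_nonzero_fraction Target fraction of nonzero cells in the
#'   downstream drug-by-ADR count (and hence PRR) matrix. The generator
#'   tunes the per-drug active term set size and the background skew so the
#'   realized fraction approximates this value.
#' @param dup_rate Fraction (of base reports) of injected exact duplicate
#'   records, `[0, 1)`.
#' @param invalid_rate Fraction (of base reports) of injected incomplete
#'   records with a missing drug name and/or ADR term, `[0, 1)`.
#' @param seed Integer seed; the full corpus is a deterministic function of
#'   the configuration including this seed.
#'
#' @return An object of class `generator_config` (a named list).
#' @export
#' @examples
#' cfg <- generator_config(n_rx = 5, n_otc_a = 3, n_otc_b = 2,
#'                         n_adr_terms = 30, seed = 1)
generator_config <- function(n_rx = 887L, n_otc_a = 113L, n_otc_b = 47L,
                             n_adr_terms = 751L,
                             reports_per_drug_mean = 50,
                             class_profile_shift = 0.8,
                             target_nonzero_fraction = 0.017,
                             dup_rate = 0.02,
                             invalid_rate = 0.02,
                             seed = 1L) {
  cfg <- list(
    n_rx = check_count(n_rx, "n_rx"),
    n_otc_a = check_count(n_otc_a, "n_otc_a"),
    n_otc_b = check_count(n_otc_b, "n_otc_b"),
    n_adr_terms = check_count(n_adr_terms, "n_adr_terms"),
    reports_per_drug_mean = reports_per_drug_mean,
    class_profile_shift = check_fraction(class_profile_shift,
                                         "class_profile_shift"),
    target_nonzero_fraction = check_fraction(target_nonzero_fraction,
                                             "target_nonzero_fraction",
                                             lo = 0, hi = 1, lo_open = TRUE),
    dup_rate = check_fraction(dup_rate, "dup_rate", hi = 1, hi_open = TRUE),
    invalid_rate = check_fraction(invalid_rate, "invalid_rate",
                                  hi = 1, hi_open = TRUE),
    seed = as.integer(seed)
  )
  if (!is.numeric(reports_per_drug_mean) || reports_per_drug_mean <= 0) {
    stop("`reports_per_drug_mean` must be a positive number", call. = FALSE)
  }
  if (cfg$dup_rate + cfg$invalid_rate >= 1) {
    stop("dup_rate + invalid_rate must be < 1", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate the drug catalog and ADR term vocabulary
#'
#' Builds the labeled drug list (labels 0 = Rx, 1 = OTC-A, 2 = OTC-B) and the
#' ADR term vocabulary, partitioned into three class-typical pools. Adjacent
#' risk classes share 30% of their pool so the classification problem is not
#' perfectly separable.
#'
#' @param config A [generator_config()].
#' @return An object of class `adr_catalog`: a list with `drugs`
#'   (data.table of `drug_name`, `label`), `adr_terms` (character vector),
#'   `pools` (list of three integer index vectors into `adr_terms`) and the
#'   `config`.
#' @export
generate_catalog <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must be created by generator_config()", call. = FALSE)
  }
  n_class <- c(config$n_rx, config$n_otc_a, config$n_otc_b)
  n_drugs <- sum(n_class)
  drugs <- data.table::data.table(
    drug_name = sprintf("drug_%04d", seq_len(n_drugs)),
    label = rep(0:2, times = n_class)
  )
  adr_terms <- sprintf("adr_%04d", seq_len(config$n_adr_terms))

  ## three pool windows over the term indices, 30% overlap between neighbors
  overlap <- 0.3
  v <- config$n_adr_terms
  w <- max(1L, ceiling(v / (3 - 2 * overlap)))
  pools <- lapply(1:3, function(c) {
    s <- round((c - 1) * (v - w) / 2) + 1L
    e <- min(v, s + w - 1L)
    seq.int(max(1L, s), e)
  })

  structure(list(drugs = drugs, adr_terms = adr_terms, pools = pools,
                 config = config),
            class = "adr_catalog")
}

## Solve for a Zipf exponent `a` such that the expected number of distinct
## terms seen in `n_draws` i.i.d. draws from p_t ∝ t^(-a) over `v` terms is
## approximately `target`. Returns the weight vector.
zipf_weights_for_distinct <- function(v, n_draws, target) {
  expected_distinct <- function(a) {
    p <- seq_len(v)^(-a)
    p <- p / sum(p)
    sum(1 - (1 - p)^n_draws)
  }
  if (n_draws <= 0 || target <= 0) {
    return(rep(1 / v, v))
  }
  ## uniform (a = 0) maximizes distinct count; clamp if target unattainable
  if (expected_distinct(0) <= target) {
    a <- 0
  } else if (expected_distinct(8) >= target) {
    a <- 8
  } else {
    a <- stats::uniroot(function(a) expected_distinct(a) - target,
                        c(0, 8), tol = 1e-4)$root
  }
  p <- seq_len(v)^(-a)
  p / sum(p)
}

#' Generate a synthetic spontaneous-report corpus
#'
#' Each drug receives a Poisson number of reports. A report's ADR term is
#' drawn, with probability `class_profile_shift`, uniformly from a per-drug
#' "active" subset of the drug's class-typical pool, and otherwise from a
#' shared background distribution common to all drugs. The active-set size
#' and the background skew are tuned so that the nonzero fraction of the
#' downstream drug-by-ADR matrix approximates `target_nonzero_fraction`.
#' Report counts are zero-truncated (every drug files at least one report)
#' and every vocabulary term is guaranteed at least one mention, from a drug
#' whose class pool contains it, so the realized drug-by-ADR table has the
#' full configured dimensions. Exact duplicate records and incomplete
#' records are then injected at the configured rates and the row order is
#' shuffled.
#'
#' @param config A [generator_config()].
#' @param catalog The matching [generate_catalog()] output.
#' @return A data.table of reports with columns `report_id`, `region`, `age`,
#'   `gender`, `drug_name`, `adr_symptom` (missing values as `NA`), carrying
#'   attributes `n_base`, `n_duplicate`, `n_invalid`.
#' @export
generate_reports <- function(config, catalog) {
  if (!inherits(catalog, "adr_catalog") || nrow(catalog$drugs) == 0L) {
    stop("`catalog` must be a non-empty adr_catalog", call. = FALSE)
  }
  shift <- config$class_profile_shift
  v <- config$n_adr_terms
  mu <- config$reports_per_drug_mean
  target_distinct <- config$target_nonzero_fraction * v

  with_seed(config$seed, {
    n_drugs <- nrow(catalog$drugs)
    labels <- catalog$drugs$label
    n_reports <- pmax(1L, stats::rpois(n_drugs, mu))

    ## background distribution: Zipf-skewed over a random permutation of the
    ## vocabulary (permuted so background mass is independent of the pools),
    ## tuned to contribute its share of the per-drug distinct-term target
    exp_class_draws <- shift * mu
    s_active <- if (shift > 0) max(1L, round(shift * target_distinct)) else 0L
    exp_class_distinct <- if (s_active > 0) {
      s_active * (1 - (1 - 1 / s_active)^exp_class_draws)
    } else 0
    bg_target <- max(0, target_distinct - exp_class_distinct)
    bg_perm <- sample.int(v)
    bg_weights <- numeric(v)
    bg_weights[bg_perm] <- zipf_weights_for_distinct(v, (1 - shift) * mu,
                                                     bg_target)

    ## per-drug active subset of the class pool
    rows <- vector("list", n_drugs)
    for (i in seq_len(n_drugs)) {
      n_i <- n_reports[i]
      if (n_i == 0L) next
      pool <- catalog$pools[[labels[i] + 1L]]
      from_class <- stats::runif(n_i) < shift
      adr_idx <- integer(n_i)
      if (any(from_class)) {
        active <- if (s_active >= length(pool)) pool else
          sample(pool, s_active)
        adr_idx[from_class] <- sample(active, sum(from_class), replace = TRUE)
      }
      if (any(!from_class)) {
        adr_idx[!from_class] <- sample.int(v, sum(!from_class),
                                           replace = TRUE, prob = bg_weights)
      }
      rows[[i]] <- data.table::data.table(
        drug_name = catalog$drugs$drug_name[i],
        adr_symptom = catalog$adr_terms[adr_idx]
      )
    }
    base <- data.table::rbindlist(rows)

    ## guarantee full vocabulary coverage: one mention of each unseen term
    ## by a random drug whose class pool contains it
    unseen <- setdiff(seq_len(v), match(unique(base$adr_symptom),
                                        catalog$adr_terms))
    if (length(unseen)) {
      in_pool <- vapply(catalog$pools, function(p) unseen %in% p,
                        logical(length(unseen)))
      in_pool <- matrix(in_pool, nrow = length(unseen))
      extra_drug <- vapply(seq_along(unseen), function(q) {
        classes <- which(in_pool[q, ]) - 1L
        sample(which(labels %in% classes), 1L)
      }, integer(1))
      base <- rbind(base, data.table::data.table(
        drug_name = catalog$drugs$drug_name[extra_drug],
        adr_symptom = catalog$adr_terms[unseen]))
    }
    n_base <- nrow(base)

    reports <- data.table::data.table(
      report_id = sprintf("R%07d", seq_len(n_base)),
      region = sprintf("region_%02d", sample.int(13L, n_base, replace = TRUE)),
      age = ifelse(stats::runif(n_base) < 0.04, NA_integer_,
                   sample(0:95, n_base, replace = TRUE)),
      gender = ifelse(stats::runif(n_base) < 0.03, NA_character_,
                      sample(c("M", "F"), n_base, replace = TRUE)),
      drug_name = base$drug_name,
      adr_symptom = base$adr_symptom
    )

    ## exact duplicates (same report_id, removed by the cleaning stage)
    n_dup <- round(config$dup_rate * n_base)
    if (n_dup > 0) {
      dup_rows <- reports[sample.int(n_base, n_dup, replace = TRUE)]
      reports <- rbind(reports, dup_rows)
    }

    ## incomplete records: missing drug name and/or ADR term
    n_inv <- round(config$invalid_rate * n_base)
    if (n_inv > 0) {
      kind <- sample.int(3L, n_inv, replace = TRUE)
      inv <- data.table::data.table(
        report_id = sprintf("R%07d", n_base + seq_len(n_inv)),
        region = sprintf("region_%02d", sample.int(13L, n_inv, replace = TRUE)),
        age = sample(0:95, n_inv, replace = TRUE),
        gender = sample(c("M", "F"), n_inv, replace = TRUE),
        drug_name = ifelse(kind != 2L, NA_character_,
                           sample(catalog$drugs$drug_name, n_inv,
                                  replace = TRUE)),
        adr_symptom = ifelse(kind != 1L, NA_character_,
                             sample(catalog$adr_terms, n_inv, replace = TRUE))
      )
      ## kind 1: missing drug only; kind 2: missing ADR only; kind 3: both
      reports <- rbind(reports, inv)
    }

    reports <- reports[sample.int(nrow(reports))]
    data.table::setattr(reports, "n_base", n_base)
    data.table::setattr(reports, "n_duplicate", n_dup)
    data.table::setattr(reports, "n_invalid", n_inv)
    reports[]
  })
}

#' Read and write report corpora, drug labels and generator configurations
#'
#' Reports are stored as CSV with header
#' `report_id,region,age,gender,drug_name,adr_symptom` (missing fields
#' empty); drug labels as CSV `drug_name,label`; configurations as YAML.
#'
#' @param reports data.table of reports as from [generate_reports()].
#' @param catalog an `adr_catalog` (for [write_drug_labels()]).
#' @param config a [generator_config()].
#' @param path file path.
#' @return The read functions return a data.table (or `generator_config`);
#'   the write functions return `path` invisibly.
#' @export
write_reports <- function(reports, path) {
  data.table::fwrite(reports, path, na = "")
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  data.table::fread(path,
                    colClasses = list(character = c("report_id", "region",
                                                    "gender", "drug_name",
                                                    "adr_symptom"),
                                      integer = "age"),
                    na.strings = "")
}

#' @rdname write_reports
#' @export
write_drug_labels <- function(catalog, path) {
  labels <- if (inherits(catalog, "adr_catalog")) catalog$drugs else catalog
  data.table::fwrite(labels[, c("drug_name", "label")], path)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_drug_labels <- function(path) {
  data.table::fread(path, colClasses = list(character = "drug_name",
                                            integer = "label"))
}

#' @rdname write_reports
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_generator_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}
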