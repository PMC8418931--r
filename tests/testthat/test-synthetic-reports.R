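test_that("catalog has the configured class structure and is deterministic", {
  cfg <- generator_config(n_rx = 887, n_otc_a = 113, n_otc_b = 47, seed = 1)
  catalog <- generate_catalog(cfg)
  expect_equal(nrow(catalog$drugs), 1047)
  expect_equal(as.vector(table(catalog$drugs$label)), c(887, 113, 47))
  expect_length(catalog$adr_terms, 751)
  expect_identical(catalog, generate_catalog(cfg))

  minimal <- generate_catalog(generator_config(n_rx = 1, n_otc_a = 1,
                                               n_otc_b = 1,
                                               n_adr_terms = 10))
  expect_equal(sort(minimal$drugs$label), 0:2)
})

test_that("class-typical pools cover the vocabulary and overlap between neighbors", {
  catalog <- generate_catalog(generator_config(seed = 1))
  expect_setequal(sort(unique(unlist(catalog$pools))),
                  seq_along(catalog$adr_terms))
  ov12 <- length(intersect(catalog$pools[[1]], catalog$pools[[2]]))
  ov23 <- length(intersect(catalog$pools[[2]], catalog$pools[[3]]))
  expect_gt(ov12 / length(catalog$pools[[1]]), 0.2)
  expect_lt(ov12 / length(catalog$pools[[1]]), 0.4)
  expect_gt(ov23 / length(catalog$pools[[2]]), 0.2)
  # non-adjacent classes share nothing
  expect_length(intersect(catalog$pools[[1]], catalog$pools[[3]]), 0)
})

test_that("config invariants are enforced", {
  expect_error(generator_config(n_rx = 0), "positive integer")
  expect_error(generator_config(dup_rate = 0.6, invalid_rate = 0.5),
               "< 1")
  expect_error(generator_config(target_nonzero_fraction = 0), "\\(0, 1")
  expect_error(generate_reports(generator_config(), list()), "catalog")
})

test_that("a clean corpus has only valid, unique records", {
  cfg <- generator_config(n_rx = 10, n_otc_a = 5, n_otc_b = 5,
                          n_adr_terms = 40, reports_per_drug_mean = 20,
                          dup_rate = 0, invalid_rate = 0, seed = 7)
  reports <- generate_reports(cfg, generate_catalog(cfg))
  expect_false(anyNA(reports$drug_name))
  expect_false(anyNA(reports$adr_symptom))
  expect_false(any(duplicated(reports,
                              by = c("report_id", "drug_name",
                                     "adr_symptom"))))
})

test_that("injected duplicate and invalid counts match the configured rates", {
  cfg <- generator_config(n_rx = 20, n_otc_a = 8, n_otc_b = 6,
                          n_adr_terms = 50, reports_per_drug_mean = 30,
                          dup_rate = 0.05, invalid_rate = 0.03, seed = 3)
  reports <- generate_reports(cfg, generate_catalog(cfg))
  n_base <- attr(reports, "n_base")
  expect_equal(attr(reports, "n_duplicate"), round(0.05 * n_base))
  expect_equal(attr(reports, "n_invalid"), round(0.03 * n_base))
  expect_equal(nrow(reports),
               n_base + round(0.05 * n_base) + round(0.03 * n_base))
  # the cleaning stage recovers exactly those counts
  log <- clean_reports(reports)$log
  expect_equal(log$duplicate, attr(reports, "n_duplicate"))
  expect_equal(log$incomplete, attr(reports, "n_invalid"))
})

test_that("identical configuration yields a byte-identical corpus file", {
  cfg <- generator_config(n_rx = 8, n_otc_a = 4, n_otc_b = 3,
                          n_adr_terms = 30, reports_per_drug_mean = 15,
                          seed = 11)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_reports(generate_reports(cfg, generate_catalog(cfg)), f1)
  write_reports(generate_reports(cfg, generate_catalog(cfg)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("report/label/config round-trips preserve content", {
  cfg <- generator_config(n_rx = 6, n_otc_a = 3, n_otc_b = 2,
                          n_adr_terms = 20, reports_per_drug_mean = 10,
                          seed = 5)
  catalog <- generate_catalog(cfg)
  reports <- generate_reports(cfg, catalog)
  f <- withr::local_tempfile(fileext = ".csv")
  write_reports(reports, f)
  back <- read_reports(f)
  expect_equal(as.data.frame(back), as.data.frame(reports),
               ignore_attr = TRUE)
  fl <- withr::local_tempfile(fileext = ".csv")
  write_drug_labels(catalog, fl)
  expect_equal(read_drug_labels(fl)$label, catalog$drugs$label)
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, fy)
  expect_equal(read_generator_config(fy), cfg)
})

test_that("zero class-profile shift collapses classes onto one shared distribution", {
  # with shift = 0 every report draws from the same background, so the
  # per-class ADR term distributions are homogeneous
  cfg <- generator_config(n_rx = 40, n_otc_a = 40, n_otc_b = 40,
                          n_adr_terms = 100, reports_per_drug_mean = 85,
                          class_profile_shift = 0,
                          dup_rate = 0, invalid_rate = 0, seed = 2)
  catalog <- generate_catalog(cfg)
  reports <- generate_reports(cfg, catalog)
  expect_gt(nrow(reports), 1e4)
  lab <- catalog$drugs$label[match(reports$drug_name,
                                   catalog$drugs$drug_name)]
  tab <- table(lab, reports$adr_symptom)
  keep <- colSums(tab) >= 15  # chi-square validity on the realized tail
  p <- suppressWarnings(chisq.test(tab[, keep])$p.value)
  expect_gt(p, 0.01)
})

test_that("corpus density tracks the target nonzero fraction at full scale", {
  run <- reference_scale_run()
  expect_equal(length(run$table$drugs), 1047)
  expect_equal(length(run$table$adr_terms), 751)
  frac <- nonzero_fraction(run$sm)
  expect_lt(abs(frac - 0.017), 0.01)
})
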