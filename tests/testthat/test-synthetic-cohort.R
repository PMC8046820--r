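cfg <- fh_default_config()

test_that("degenerate configurations produce the implied degenerate cohorts", {
  cfg0 <- unclass(cfg)
  cfg0$snv_panel <- lapply(cfg0$snv_panel, function(s) {
    s$eaf <- 1e-12 # frequencies ~0: every dosage 0
    s
  })
  cfg0$generator$plp_carrier_rate <- 0
  cfg0$generator$vus_carrier_rate <- 0
  coh <- generate_population(validate_config(cfg0), n = 200, seed = 1)
  expect_true(all(coh$genotypes == 0))
  expect_true(all(coh$truth$raw_pgs == 0))
  expect_equal(nrow(coh$carriage), 0)
  expect_false(any(coh$truth$etiology_truth == "monogenic"))
})

test_that("seed determinism: identical config and seed give identical cohorts", {
  a <- generate_population(cfg, n = 300, seed = 9)
  b <- generate_population(cfg, n = 300, seed = 9)
  expect_identical(a$participants, b$participants)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$lipids, b$lipids)
  expect_identical(a$carriage, b$carriage)
  c2 <- generate_population(cfg, n = 300, seed = 10)
  expect_false(identical(a$genotypes, c2$genotypes))
})

test_that("invalid generator configuration is rejected with the field named", {
  bad <- unclass(cfg)
  bad$generator$plp_carrier_rate <- 1.5
  expect_error(generate_population(as_unchecked_config(bad)), "plp_carrier_rate")
  bad2 <- unclass(cfg)
  bad2$generator$residual_sd <- NaN
  expect_error(generate_population(as_unchecked_config(bad2)), "residual_sd")
  bad3 <- unclass(cfg)
  bad3$snv_panel[[1]]$weight <- -0.1
  expect_error(generate_population(as_unchecked_config(bad3)), "snv_panel")
})

test_that("genotypes satisfy Hardy-Weinberg at moderate n", {
  coh <- generate_population(cfg, n = 5000, seed = 21)
  panel <- snv_panel_table(cfg)
  pvals <- vapply(seq_len(nrow(panel)), function(j) {
    obs <- tabulate(coh$genotypes[, j] + 1L, nbins = 3)
    p <- panel$eaf[j]
    expected <- 5000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - expected)^2 / expected)
    stats::pchisq(stat, df = 2, lower.tail = FALSE)
  }, numeric(1))
  expect_gte(sum(pvals > 0.001), 11)
})

test_that("carriers' LDL shift and statin treatment flow into observed values", {
  coh <- generate_population(cfg, n = 20000, seed = 13)
  tr <- coh$truth
  carrier <- tr$etiology_truth == "monogenic"
  expect_gt(
    mean(tr$untreated_ldl[carrier]) - mean(tr$untreated_ldl[!carrier]), 25
  )
  p <- coh$participants
  on <- p$statin_active_on_index
  expect_gt(sum(on), 0)
  # observed = untreated * (1 - r): imputing back recovers untreated
  obs <- coh$lipids$ldl[match(p$id[on], coh$lipids$id)]
  rec <- impute_untreated_ldl(obs, p$statin_type[on], p$statin_dose[on], cfg$statins)
  expect_equal(rec, tr$untreated_ldl[on], tolerance = 1e-9)
  expect_true(all(obs <= tr$untreated_ldl[on]))
})

test_that("count fixture reproduces requested cross-tab exactly and validates input", {
  fx <- fixture_from_counts()
  expect_equal(nrow(fx$participants), 1682)
  res <- run_pipeline(fx)
  expect_equal(summary_pct(res$summary, "fh_among_monogenic"), 40.0)
  expect_equal(res$summary$numerator[res$summary$name == "monogenic"], 25)

  # all-zero counts: everyone unexplained and unlikely
  zero <- list(
    total = 10L, monogenic = 0L, polygenic = 0L, phenotypic_fh = 0L,
    monogenic_fh = 0L, polygenic_fh = 0L, ldl_ge190 = 0L, ldl_ge250 = 0L,
    ldl_ge95 = 0L, ldl_ge99 = 0L, monogenic_ldl_ge190 = 0L,
    monogenic_ldl_ge250 = 0L, monogenic_ldl_ge95 = 0L, monogenic_ldl_ge99 = 0L,
    ldlr_carriers = 0L, apob_carriers = 0L, pcsk9_carriers = 0L
  )
  fx0 <- fixture_from_counts(zero)
  res0 <- run_pipeline(fx0)
  expect_true(all(res0$table$etiology == "none"))
  expect_true(all(res0$table$dlcn_category == "unlikely"))

  # joint exceeding its marginal is rejected
  expect_error(
    fixture_from_counts(list(monogenic_fh = 30L)),
    "inconsistent counts"
  )
})

test_that("writing and re-reading a cohort reproduces it", {
  coh <- generate_population(cfg, n = 40, seed = 33)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.vcf")))
  back <- read_cohort(dir, cfg)
  expect_equal(back$participants, coh$participants)
  expect_equal(back$lipids, coh$lipids, tolerance = 1e-6)
  expect_identical(back$genotypes, coh$genotypes)
  o <- function(df) df[order(df$id, df$variant_id), c("id", "variant_id", "allele_count")]
  a <- o(coh$carriage)
  b <- o(back$carriage)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_error(write_cohort(empty_cohort(coh), withr::local_tempdir()), "empty")
})
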