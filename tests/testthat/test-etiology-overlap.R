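test_that("etiology labels give monogenic precedence", {
  expect_equal(classify_etiology(TRUE, TRUE), "monogenic")
  expect_equal(classify_etiology(TRUE, FALSE), "monogenic")
  expect_equal(classify_etiology(FALSE, TRUE), "polygenic")
  expect_equal(classify_etiology(FALSE, FALSE), "none")
})

test_that("the shared rounding routine rounds half up to one decimal", {
  expect_equal(round_half_up(100 * 10 / 142, 1), 7.0)
  expect_equal(round_half_up(100 * 27 / 262, 1), 10.3)
  expect_equal(round_half_up(100 * 37 / 287, 1), 12.9)
  expect_equal(round_half_up(0.25, 1), 0.3) # ties up, unlike round()
  expect_equal(round_half_up(-0.25, 1), -0.3) # away from zero
})

make_calls <- function(etiology, fh, ldl = 160) {
  data.frame(
    etiology = etiology, phenotypic_fh = fh,
    ge190 = ldl >= 190, ge250 = ldl >= 250, ge95 = ldl >= 170, ge99 = ldl >= 235,
    stringsAsFactors = FALSE
  )
}

test_that("cross-tab percentages carry auditable numerators and denominators", {
  calls <- make_calls(
    c("monogenic", "polygenic", "polygenic", "none"),
    c(TRUE, TRUE, FALSE, FALSE),
    ldl = c(260, 200, 180, 150)
  )
  s <- crosstab_overlap(calls)
  # recomputing each percentage from its own counts reproduces it exactly
  ok <- !is.na(s$percent)
  expect_equal(
    s$percent[ok],
    round_half_up(100 * s$numerator[ok] / s$denominator[ok], 1)
  )
  expect_equal(summary_pct(s, "genetic_etiology"), 75.0)
  expect_equal(summary_pct(s, "fh_among_genetic"), round_half_up(100 * 2 / 3, 1))
})

test_that("single-participant and empty subgroups behave as documented", {
  one <- make_calls("monogenic", TRUE, ldl = 260)
  s <- crosstab_overlap(one)
  expect_equal(summary_pct(s, "monogenic"), 100.0)
  expect_equal(summary_pct(s, "fh_among_monogenic"), 100.0)
  # no polygenic subjects: the within-polygenic percentage is undefined, not 0
  expect_true(is.na(summary_pct(s, "fh_among_polygenic")))
  expect_error(
    crosstab_overlap(make_calls(character(), logical(), ldl = numeric())),
    "empty"
  )
})

test_that("group comparisons wrap the standard two-sided tests", {
  # identical groups: chi-square p = 1, t-statistic 0
  tab <- matrix(c(20, 30, 20, 30), 2)
  ch <- group_compare(tab, kind = "chisq")
  expect_equal(ch$p_value, 1)
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  tt <- group_compare(x, g, kind = "t")
  expect_equal(tt$statistic, 0)
  expect_false(tt$significant)
  expect_error(group_compare(c(1, 2), c("a", "b"), kind = "t"), "n < 2")

  # monogenic-vs-rest LDL at the configured +46 mg/dl shift is detected
  cfg <- fh_default_config()
  coh <- generate_population(cfg, n = 5000, seed = 17)
  carrier <- coh$truth$etiology_truth == "monogenic"
  res <- group_compare(coh$truth$untreated_ldl, ifelse(carrier, "mono", "rest"), kind = "t")
  expect_lt(res$p_value, 0.01)

  # three equal-mean groups: ANOVA keeps its nominal type-I error
  set.seed(29)
  reps <- 400
  rejected <- sum(vapply(seq_len(reps), function(i) {
    y <- rnorm(60)
    g3 <- rep(c("a", "b", "c"), each = 20)
    group_compare(y, g3, kind = "anova")$p_value < 0.05
  }, logical(1)))
  expect_gt(stats::binom.test(rejected, reps, 0.05)$p.value, 0.001)
})

test_that("variance decomposition reports per-model R2 and flags collinearity", {
  cfg <- fh_default_config()
  coh <- generate_population(cfg, n = 8000, seed = 23)
  tab <- data.frame(
    coh$truth,
    coh$participants[c("age", "sex", "race", "bmi", "diabetes", "famhx_hypercholesterolemia")],
    monogenic = coh$truth$etiology_truth == "monogenic"
  )
  v <- variance_explained(tab)
  expect_true(v$r2_genetic > 0 && v$r2_genetic < 1)
  expect_gt(v$r2_genetic, v$r2_clinical)

  # null case: shuffle LDL so genetic factors explain ~nothing
  tab0 <- tab
  set.seed(1)
  tab0$untreated_ldl <- sample(tab0$untreated_ldl)
  v0 <- variance_explained(tab0)
  expect_lt(v0$r2_genetic, 0.005)

  # duplicated predictor: monogenic column collinear with the score
  tab2 <- tab
  tab2$monogenic <- tab2$raw_pgs
  expect_error(variance_explained(tab2), "collinear")
  tab3 <- tab
  tab3$bmi <- 29.5
  expect_error(variance_explained(tab3), "constant")
  expect_error(variance_explained(tab[, 1:3]), "missing column")
})
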