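cfg <- fh_default_config()

test_that("functional and rare filters follow the stated rules", {
  expect_true(functional_filter("stop_gain"))
  expect_true(functional_filter("missense"))
  expect_false(functional_filter("synonymous"))
  expect_false(functional_filter("intronic"))

  expect_true(rare_filter(0.0009))
  expect_false(rare_filter(0.001)) # strict <
  expect_true(rare_filter(NA)) # never observed => rare
  expect_error(rare_filter(0.1, threshold = 0), "\\(0, 1\\]")
})

test_that("evidence assignment applies the gene mechanism gate and annotations", {
  s <- cfg$pathogenicity
  expect_setequal(assign_evidence("LDLR", "frameshift", NA, settings = s), c("PVS1", "PM2"))
  # PCSK9 is not a loss-of-function gene here: no PVS1
  expect_setequal(assign_evidence("PCSK9", "stop_gain", NA, settings = s), "PM2")
  expect_setequal(
    assign_evidence("LDLR", "missense", 0.0005, pred_verdict = "damaging", settings = s),
    c("PM2", "PP3")
  )
  expect_setequal(
    assign_evidence("APOB", "missense", 0.0002,
      clnsig = "pathogenic", pred_verdict = "damaging",
      supplied = "PS3", settings = s
    ),
    c("PM2", "PP3", "PP5", "PS3")
  )
  # disabling PP5/BP6 drops database-derived tags
  s2 <- s
  s2$use_pp5_bp6 <- FALSE
  expect_setequal(
    assign_evidence("LDLR", "missense", NA, clnsig = "pathogenic", settings = s2),
    "PM2"
  )
  expect_error(
    assign_evidence("LDLR", "missense", NA,
      pred_verdict = "damaging", supplied = "BP4", settings = s
    ),
    "contradictory"
  )
  expect_error(assign_evidence("LDLR", "missense", NA, supplied = "PX9", settings = s), "unknown ACMG")
})

test_that("combining engine reproduces worked classifications", {
  expect_equal(combine_acmg(character())$class, "uncertain")
  expect_equal(combine_acmg(c("PVS1", "PM2"))$class, "likely_pathogenic")
  expect_equal(combine_acmg(c("PVS1", "PM2", "PP3"))$class, "pathogenic")
  expect_equal(combine_acmg(c("PS3", "PM2"))$class, "likely_pathogenic")
  expect_equal(combine_acmg(c("PS1", "PS3"))$class, "pathogenic")
  expect_equal(combine_acmg(c("BS1", "BP4"))$class, "likely_benign")
  expect_equal(combine_acmg("BA1")$class, "benign")
  expect_equal(combine_acmg(c("PM2", "PP3"))$class, "uncertain")
  # conflicting directions are uncertain, whatever the strength
  expect_equal(combine_acmg(c("BA1", "PVS1", "PS1"))$class, "uncertain")
  expect_true(combine_acmg(c("PVS1", "PM2"))$plp)
  expect_false(combine_acmg(c("PM2"))$plp)
})

test_that("adding pathogenic evidence to a non-conflicted set never moves toward benign", {
  rank <- c(benign = 1, likely_benign = 2, uncertain = 3, likely_pathogenic = 4, pathogenic = 5)
  sets <- list(
    character(), "PM2", c("PM1", "PM2"), c("PS1"), c("PVS1"),
    c("PS1", "PM2"), c("PM1", "PM2", "PP3"), c("PP1", "PP2")
  )
  adds <- c("PVS1", "PS2", "PM3", "PP4")
  for (s in sets) {
    for (a in adds) {
      if (a %in% s) next
      before <- combine_acmg(s)$class
      after <- combine_acmg(c(s, a))$class
      expect_gte(rank[[after]], rank[[before]])
    }
  }
})

test_that("classify_variants partitions candidates by first failing filter", {
  variants <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    gene = c("LDLR", "LDLR", "APOB", "LDLR"),
    consequence = c("stop_gain", "synonymous", "missense", "missense"),
    ref_af = c(NA, NA, 0.004, 0.00005),
    stringsAsFactors = FALSE
  )
  res <- classify_variants(variants, cfg$pathogenicity)
  expect_equal(res$filter_status, c("pass", "fail_functional", "fail_rare", "pass"))
  expect_equal(sum(res$filter_status == "pass") +
    sum(res$filter_status == "fail_functional") +
    sum(res$filter_status == "fail_rare"), nrow(variants))
  # synonymous-and-common fails on the functional rule first
  both <- data.frame(
    variant_id = "x", gene = "LDLR", consequence = "synonymous", ref_af = 0.2,
    stringsAsFactors = FALSE
  )
  expect_equal(classify_variants(both, cfg$pathogenicity)$filter_status, "fail_functional")
  expect_error(
    classify_variants(data.frame(
      variant_id = "c", gene = "LDLR", consequence = "cnv", ref_af = NA
    ), cfg$pathogenicity),
    "not supported"
  )
  # classification independent of input order
  res_rev <- classify_variants(variants[4:1, ], cfg$pathogenicity)
  expect_equal(
    res[order(res$variant_id), "class"],
    res_rev[order(res_rev$variant_id), "class"]
  )
})

test_that("monogenic calls require a P/LP allele and classified variants", {
  classifications <- data.frame(
    variant_id = c("plp1", "vus1"), gene = c("LDLR", "LDLR"),
    plp = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  carriage <- data.frame(
    id = c("a", "b"), variant_id = c("plp1", "vus1"), allele_count = 1L,
    stringsAsFactors = FALSE
  )
  calls <- call_monogenic(carriage, classifications, c("a", "b", "c"))
  expect_equal(calls$monogenic, c(TRUE, FALSE, FALSE))
  expect_equal(calls$carrier_gene, c("LDLR", NA, NA))
  expect_error(
    call_monogenic(
      data.frame(id = "a", variant_id = "ghost", allele_count = 1L),
      classifications, "a"
    ),
    "unclassified"
  )
})
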