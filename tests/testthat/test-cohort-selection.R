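test_that("index date is the earliest qualifying measure, boundary inclusive", {
  expect_equal(
    find_index_date(c("2010-01-01", "2011-06-01"), c(150, 156)),
    as.Date("2011-06-01")
  )
  # threshold is inclusive
  expect_equal(find_index_date("2012-01-01", 155.0), as.Date("2012-01-01"))
  # later low measures do not override the first qualifying date
  expect_equal(
    find_index_date(c("2014-05-01", "2013-02-01", "2015-01-01"), c(160, 170, 150)),
    as.Date("2013-02-01")
  )
  expect_true(is.na(find_index_date(c("2010-01-01"), c(154))))
  expect_true(is.na(find_index_date(character(), numeric())))
})

test_that("secondary causes exclude only within the +/-365 day window", {
  p <- data.frame(id = c("a", "b"), age = 50, stringsAsFactors = FALSE)
  lip <- data.frame(
    id = c("a", "b"), date = as.Date("2015-01-01"), ldl = 180,
    stringsAsFactors = FALSE
  )
  dx <- data.frame(
    id = c("a", "b"),
    date = as.Date("2015-01-01") + c(300, 400),
    code = "hypothyroidism", age_at_event = 50, stringsAsFactors = FALSE
  )
  sel <- apply_selection(mini_cohort(p, lip, dx), default_criteria())
  expect_equal(sel$retained_ids, "b")
  expect_equal(unname(sel$exclusions["secondary_cause_in_window"]), 1L)

  # boundary day: 365 days out is inside the inclusive window
  dx$date <- as.Date("2015-01-01") + c(365, -365)
  sel <- apply_selection(mini_cohort(p, lip, dx), default_criteria())
  expect_length(sel$retained_ids, 0)

  # non-secondary codes never exclude
  dx$code <- "CHD"
  sel <- apply_selection(mini_cohort(p, lip, dx), default_criteria())
  expect_equal(sort(sel$retained_ids), c("a", "b"))
})

test_that("age bounds are inclusive at 18 and 70", {
  p <- data.frame(id = c("a", "b", "c", "d"), age = c(17, 18, 70, 71))
  lip <- data.frame(id = p$id, date = as.Date("2015-01-01"), ldl = 180)
  sel <- apply_selection(mini_cohort(p, lip), default_criteria())
  expect_equal(sort(sel$retained_ids), c("b", "c"))
  expect_equal(unname(sel$exclusions["age_out_of_range"]), 2L)
})

test_that("exclusion reasons attribute to the first failing rule in fixed order", {
  # participant fails both the index rule and age: counted under no_index_date
  p <- data.frame(id = "a", age = 80)
  lip <- data.frame(id = "a", date = as.Date("2015-01-01"), ldl = 120)
  sel <- apply_selection(mini_cohort(p, lip), default_criteria())
  expect_equal(unname(sel$exclusions["no_index_date"]), 1L)
  expect_equal(unname(sel$exclusions["age_out_of_range"]), 0L)
})

test_that("funnel conserves totals, is idempotent, and ignores record order", {
  cohort <- random_selection_cohort(1000, seed = 42)
  sel <- apply_selection(cohort, default_criteria())
  expect_equal(length(sel$retained_ids) + sum(sel$exclusions), 1000)
  expect_equal(
    sel$funnel$n[sel$funnel$stage == "screened"],
    sum(sel$funnel$n[sel$funnel$stage != "screened"])
  )

  # idempotence: re-selecting the retained cohort removes nobody
  keep <- sel$retained_ids
  cohort2 <- mini_cohort(
    cohort$participants[cohort$participants$id %in% keep, ],
    cohort$lipids[cohort$lipids$id %in% keep, ],
    cohort$diagnoses[cohort$diagnoses$id %in% keep, ]
  )
  sel2 <- apply_selection(cohort2, default_criteria())
  expect_setequal(sel2$retained_ids, keep)

  # order-independence
  perm <- sample(nrow(cohort$participants))
  cohort3 <- cohort
  cohort3$participants <- cohort$participants[perm, ]
  sel3 <- apply_selection(cohort3, default_criteria())
  expect_setequal(sel3$retained_ids, sel$retained_ids)
})
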