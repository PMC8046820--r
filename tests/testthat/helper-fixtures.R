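# shared builders for unit tests; everything generated in code, no files

tiny_panel <- function() {
  data.frame(
    id = c("snvA", "snvB", "snvC"),
    gene = c("G1", "G2", "G3"),
    chrom = c("1", "2", "3"), pos = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.2, 0.5, 0.8), weight = c(0.1, 0.25, 0.4),
    stringsAsFactors = FALSE
  )
}

# minimal cohort-shaped list for selection tests
mini_cohort <- function(participants, lipids, diagnoses = NULL) {
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(
      id = character(), date = as.Date(character()), code = character(),
      age_at_event = numeric(), stringsAsFactors = FALSE
    )
  }
  list(participants = participants, lipids = lipids, diagnoses = diagnoses)
}

default_criteria <- function() {
  list(
    age_min = 18, age_max = 70, ldl_threshold_mgdl = 155,
    window_days = 365, window_inclusive = TRUE,
    secondary_causes = c(
      "hypothyroidism", "cholestatic_liver_disease", "severe_kidney_disease",
      "nephrotic_syndrome", "pregnancy"
    )
  )
}

# random cohort-shaped list exercising every exclusion path
random_selection_cohort <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("R%04d", seq_len(n))
  participants <- data.frame(
    id = ids, age = sample(10:80, n, replace = TRUE), stringsAsFactors = FALSE
  )
  n_meas <- sample(0:3, n, replace = TRUE)
  lipids <- data.frame(
    id = rep(ids, n_meas),
    date = as.Date("2012-01-01") + sample(0:2000, sum(n_meas), replace = TRUE),
    ldl = round(runif(sum(n_meas), 100, 260)),
    stringsAsFactors = FALSE
  )
  has_dx <- runif(n) < 0.3
  diagnoses <- data.frame(
    id = ids[has_dx],
    date = as.Date("2012-01-01") + sample(-200:2200, sum(has_dx), replace = TRUE),
    code = sample(c("hypothyroidism", "pregnancy", "diabetes_like_noncause"),
      sum(has_dx), replace = TRUE
    ),
    age_at_event = 50,
    stringsAsFactors = FALSE
  )
  mini_cohort(participants, lipids, diagnoses)
}

dlcn_points <- function() fh_default_config()$dlcn$points

# bypass load-time validation so generate_population's own check fires
as_unchecked_config <- function(x) structure(x, class = c("fh_config", "list"))

empty_cohort <- function(cohort) {
  cohort$participants <- cohort$participants[0, , drop = FALSE]
  cohort
}
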