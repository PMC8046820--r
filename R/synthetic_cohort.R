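#' Generate a synthetic genotype-phenotype population
#'
#' Simulates an unrelated general population with the statistical
#' structure the pipeline assumes: panel genotypes drawn under
#' Hardy-Weinberg equilibrium from the configured effect-allele
#' frequencies; untreated LDL-C composed of an age/sex baseline, a linear
#' contribution of the raw polygenic score, a Gaussian monogenic shift for
#' rare-variant carriers, and Gaussian residual noise; statin exposure
#' multiplying observed LDL-C by `(1 - r)`; and secondary-cause,
#' family-history and physical-sign flags drawn at configured prevalences.
#' Rare-variant carriers are assigned records from the configured
#' catalogue, whose annotations classify through the real ACMG engine.
#'
#' The generator produces a *general* population: left-truncation at the
#' 155 mg/dl inclusion threshold is the job of [apply_selection()].
#'
#' @param config an `fh_config`.
#' @param n number of subjects (default `config$generator$n_population`).
#' @param seed integer RNG seed (default `config$seed`). A fixed seed
#'   gives an identical cohort.
#' @return an `fh_cohort`: list with `participants`, `lipids`,
#'   `diagnoses`, `genotypes` (dosage matrix), `variants`, `carriage`,
#'   `truth` and the generating `config`.
#' @export
generate_population <- function(config = fh_default_config(),
                                n = config$generator$n_population,
                                seed = config$seed) {
  config <- validate_config(unclass(config))
  gen <- config$generator
  if (!is.numeric(n) || n < 1) stop_field("generator.n_population", "must be >= 1")
  set.seed(as.integer(seed))

  panel <- snv_panel_table(config)
  ids <- sprintf("S%05d", seq_len(n))

  age <- sample(seq(gen$age_range[[1]], gen$age_range[[2]]), n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < gen$male_fraction, "male", "female")
  race <- ifelse(stats::runif(n) < gen$white_fraction, "white", "other")
  bmi <- pmax(15, stats::rnorm(n, gen$bmi$mean, gen$bmi$sd))
  prev <- gen$prevalence
  draw <- function(p) stats::runif(n) < p

  # HWE panel genotypes: dosage ~ Binomial(2, eaf)
  genotypes <- vapply(panel$eaf, function(p) stats::rbinom(n, 2L, p), integer(n))
  if (n == 1) genotypes <- matrix(genotypes, nrow = 1)
  dimnames(genotypes) <- list(ids, panel$id)
  raw_pgs <- as.numeric(genotypes %*% panel$weight)

  # rare-variant carriage
  rv <- rare_variant_table(config)
  plp_rv <- rv[rv$plp_intent, , drop = FALSE]
  vus_rv <- rv[!rv$plp_intent, , drop = FALSE]
  carrier <- draw(gen$plp_carrier_rate)
  vus_carrier <- !carrier & draw(gen$vus_carrier_rate)
  carriage <- data.frame(id = character(), variant_id = character(), allele_count = integer())
  if (any(carrier)) {
    pick <- sample(plp_rv$variant_id, sum(carrier), replace = TRUE, prob = plp_rv$mix)
    carriage <- rbind(carriage, data.frame(
      id = ids[carrier], variant_id = pick, allele_count = 1L, stringsAsFactors = FALSE
    ))
  }
  if (any(vus_carrier) && nrow(vus_rv)) {
    pick <- sample(vus_rv$variant_id, sum(vus_carrier), replace = TRUE, prob = vus_rv$mix)
    carriage <- rbind(carriage, data.frame(
      id = ids[vus_carrier], variant_id = pick, allele_count = 1L, stringsAsFactors = FALSE
    ))
  }

  base <- gen$ldl_baseline
  genetic_ldl <- gen$pgs_to_ldl_scale * raw_pgs +
    ifelse(carrier, stats::rnorm(n, gen$monogenic_shift_mean, gen$monogenic_shift_sd), 0)
  untreated_ldl <- base$intercept + base$age_slope * (age - base$age_ref) +
    ifelse(sex == "male", base$male_offset, 0) +
    genetic_ldl + stats::rnorm(n, 0, gen$residual_sd)
  untreated_ldl <- pmax(untreated_ldl, 30) # floor far below any threshold of interest

  # statin exposure: observed LDL is the treated value
  on_statin <- draw(prev$statin_use)
  statin_type <- rep(NA_character_, n)
  statin_dose <- rep(NA_real_, n)
  reduction <- rep(0, n)
  if (any(on_statin)) {
    k <- sum(on_statin)
    types <- sample(names(config$statins), k, replace = TRUE)
    doses <- vapply(types, function(t) {
      as.numeric(sample(names(config$statins[[t]]), 1))
    }, numeric(1))
    statin_type[on_statin] <- types
    statin_dose[on_statin] <- doses
    reduction[on_statin] <- mapply(function(t, d) config$statins[[t]][[as.character(d)]], types, doses)
  }
  observed_ldl <- untreated_ldl * (1 - reduction)

  d0 <- as.Date(gen$date_range[[1]])
  d1 <- as.Date(gen$date_range[[2]])
  measure_date <- d0 + floor(stats::runif(n) * as.numeric(d1 - d0 + 1))
  lipids <- data.frame(
    id = ids, date = measure_date,
    ldl = observed_ldl,
    trig = pmax(30, stats::rnorm(n, 154.9, 67.7)),
    hdl = pmax(20, stats::rnorm(n, 54.8, 14.6)),
    stringsAsFactors = FALSE
  )

  # diagnoses: secondary causes near the measure date; ASCVD events with ages
  dx_list <- list()
  sec_codes <- c(
    "hypothyroidism", "cholestatic_liver_disease", "severe_kidney_disease",
    "nephrotic_syndrome", "pregnancy"
  )
  for (code in sec_codes) {
    has <- draw(prev[[code]])
    if (code == "pregnancy") has <- has & sex == "female"
    if (any(has)) {
      offset <- floor(stats::runif(sum(has), -500, 501))
      dx_list[[code]] <- data.frame(
        id = ids[has], date = measure_date[has] + offset, code = code,
        age_at_event = age[has], stringsAsFactors = FALSE
      )
    }
  }
  asc_codes <- c(
    personal_chd = "CHD", personal_cerebrovascular = "cerebrovascular",
    personal_peripheral_artery = "peripheral_artery"
  )
  for (nm in names(asc_codes)) {
    has <- draw(prev[[nm]])
    if (any(has)) {
      ev_age <- pmin(age[has], floor(stats::runif(sum(has), 30, 71)))
      dx_list[[nm]] <- data.frame(
        id = ids[has], date = measure_date[has] - floor(stats::runif(sum(has), 0, 3000)),
        code = asc_codes[[nm]], age_at_event = ev_age, stringsAsFactors = FALSE
      )
    }
  }
  diagnoses <- if (length(dx_list)) do.call(rbind, dx_list) else {
    data.frame(id = character(), date = as.Date(character()), code = character(),
      age_at_event = numeric(), stringsAsFactors = FALSE)
  }
  rownames(diagnoses) <- NULL

  arcus <- draw(prev$arcus_cornealis)
  participants <- data.frame(
    id = ids, age = age, sex = sex, race = race, bmi = round(bmi, 1),
    diabetes = draw(prev$diabetes), hypertension = draw(prev$hypertension),
    premature_ascvd_relative = draw(prev$premature_ascvd_relative),
    relative_ldl_gt95 = draw(prev$relative_ldl_gt95),
    relative_xanthomata_or_arcus = draw(prev$relative_xanthomata_or_arcus),
    child_ldl_gt95 = draw(prev$child_ldl_gt95),
    famhx_hypercholesterolemia = draw(prev$famhx_hypercholesterolemia),
    tendon_xanthomata = draw(prev$tendon_xanthomata),
    arcus_cornealis = arcus,
    arcus_age = ifelse(arcus, floor(stats::runif(n, 30, 61)), NA_real_),
    statin_type = statin_type, statin_dose = statin_dose,
    statin_active_on_index = on_statin,
    eligible = TRUE,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    id = ids,
    etiology_truth = ifelse(carrier, "monogenic",
      ifelse(raw_pgs >= config$pgs$threshold, "polygenic_tail", "neither")
    ),
    raw_pgs = raw_pgs,
    genetic_ldl = genetic_ldl,
    untreated_ldl = untreated_ldl,
    stringsAsFactors = FALSE
  )

  variants <- rv[, setdiff(names(rv), c("mix", "plp_intent")), drop = FALSE]
  structure(
    list(
      participants = participants, lipids = lipids, diagnoses = diagnoses,
      genotypes = genotypes, variants = variants, carriage = carriage,
      truth = truth, config = config
    ),
    class = "fh_cohort"
  )
}

#' @export
print.fh_cohort <- function(x, ...) {
  cat("<fh_cohort>", nrow(x$participants), "participants,",
    ncol(x$genotypes), "panel SNVs,", nrow(x$variants), "rare variant records\n")
  cat("  carriers:", length(unique(x$carriage$id)), "\n")
  invisible(x)
}

#' Reference marginal and joint counts for the worked-example fixture
#'
#' Marginals and joints characteristic of a primary-hypercholesterolemia
#' screening cohort of 1682 adults, used by [fixture_from_counts()] for
#' exact, deterministic end-to-end checks of the overlap statistics.
#'
#' @return named list of counts.
#' @export
default_fixture_counts <- function() {
  list(
    total = 1682L,
    monogenic = 25L, polygenic = 262L,
    phenotypic_fh = 142L, monogenic_fh = 10L, polygenic_fh = 27L,
    ldl_ge190 = 590L, ldl_ge250 = 69L, ldl_ge95 = 818L, ldl_ge99 = 372L,
    monogenic_ldl_ge190 = 20L, monogenic_ldl_ge250 = 8L,
    monogenic_ldl_ge95 = 21L, monogenic_ldl_ge99 = 18L,
    ldlr_carriers = 18L, apob_carriers = 6L, pcsk9_carriers = 1L
  )
}

#' Build a deterministic cohort from marginal and joint counts
#'
#' Constructs a cohort of exactly `counts$total` subjects whose etiology
#' labels, DLCN categories and LDL strata reproduce the requested counts
#' exactly, with no randomness. Attributes are assigned minimally so the
#' labels are produced by the *real* classifiers, not passed through:
#' monogenic subjects carry catalogued P/LP variants (LDLR null variants,
#' APOB/PCSK9 missense with curated evidence), polygenic subjects carry
#' panel dosages scoring above the threshold, phenotypic-FH subjects get
#' tendon xanthomata (6 DLCN points), and LDL strata are triggered by
#' mg/dl values at stratum midpoints against a one-band percentile
#' reference attached to the cohort (95th cut 170, 99th cut 235 mg/dl).
#'
#' LDL strata are treated as nested:
#' `ldl_ge250 <= ldl_ge99 <= ldl_ge190 <= ldl_ge95 <= total`.
#'
#' @param counts named list of counts as in [default_fixture_counts()].
#' @param config an `fh_config` (supplies the variant catalogue and panel).
#' @return an `fh_cohort` with a `percentile_reference` attribute.
#' @export
fixture_from_counts <- function(counts = default_fixture_counts(),
                                config = fh_default_config()) {
  c0 <- utils::modifyList(default_fixture_counts(), counts)
  n <- c0$total
  check_le <- function(a, b) {
    if (c0[[a]] > c0[[b]]) stop("inconsistent counts: ", a, " (", c0[[a]], ") exceeds ", b, " (", c0[[b]], ")")
  }
  for (nm in c("monogenic", "polygenic", "phenotypic_fh", "ldl_ge95")) check_le(nm, "total")
  check_le("monogenic_fh", "monogenic"); check_le("monogenic_fh", "phenotypic_fh")
  check_le("polygenic_fh", "polygenic"); check_le("polygenic_fh", "phenotypic_fh")
  check_le("ldl_ge250", "ldl_ge99"); check_le("ldl_ge99", "ldl_ge190")
  check_le("ldl_ge190", "ldl_ge95")
  check_le("monogenic_ldl_ge250", "monogenic_ldl_ge99")
  check_le("monogenic_ldl_ge99", "monogenic_ldl_ge190")
  check_le("monogenic_ldl_ge190", "monogenic_ldl_ge95")
  check_le("monogenic_ldl_ge95", "monogenic")
  if (c0$monogenic + c0$polygenic > n) stop("inconsistent counts: etiology groups exceed total")
  if (c0$ldlr_carriers + c0$apob_carriers + c0$pcsk9_carriers != c0$monogenic) {
    stop("inconsistent counts: gene carrier counts must sum to monogenic")
  }

  ids <- sprintf("F%05d", seq_len(n))
  etiology <- rep("none", n)
  if (c0$monogenic > 0) etiology[seq_len(c0$monogenic)] <- "monogenic"
  if (c0$polygenic > 0) etiology[c0$monogenic + seq_len(c0$polygenic)] <- "polygenic"

  # FH flag: first monogenic_fh monogenic subjects, first polygenic_fh
  # polygenic subjects, remainder among the unexplained
  fh <- rep(FALSE, n)
  fh[which(etiology == "monogenic")[seq_len2(c0$monogenic_fh)]] <- TRUE
  fh[which(etiology == "polygenic")[seq_len2(c0$polygenic_fh)]] <- TRUE
  rest_fh <- c0$phenotypic_fh - c0$monogenic_fh - c0$polygenic_fh
  if (rest_fh < 0) stop("inconsistent counts: phenotypic_fh below its etiology joints")
  fh[which(etiology == "none")[seq_len2(rest_fh)]] <- TRUE

  # LDL ladder: 255 (>=250), 240 (>=99th), 210 (>=190), 175 (>=95th), 160
  ldl <- rep(160, n)
  assign_band <- function(in_band_mono, band_total, value, ldl) {
    mono_idx <- which(etiology == "monogenic" & ldl == 160)[seq_len2(in_band_mono)]
    other_n <- band_total - in_band_mono
    other_idx <- which(etiology != "monogenic" & ldl == 160)[seq_len2(other_n)]
    ldl[c(mono_idx, other_idx)] <- value
    ldl
  }
  ldl <- assign_band(c0$monogenic_ldl_ge250, c0$ldl_ge250, 255, ldl)
  ldl <- assign_band(c0$monogenic_ldl_ge99 - c0$monogenic_ldl_ge250, c0$ldl_ge99 - c0$ldl_ge250, 240, ldl)
  ldl <- assign_band(c0$monogenic_ldl_ge190 - c0$monogenic_ldl_ge99, c0$ldl_ge190 - c0$ldl_ge99, 210, ldl)
  ldl <- assign_band(c0$monogenic_ldl_ge95 - c0$monogenic_ldl_ge190, c0$ldl_ge95 - c0$ldl_ge190, 175, ldl)

  panel <- snv_panel_table(config)
  genotypes <- matrix(0L, n, nrow(panel), dimnames = list(ids, panel$id))
  genotypes[etiology == "polygenic", ] <- 2L # raw score = 2 * sum(w) > threshold

  rv <- rare_variant_table(config)
  gene_variant <- function(gene) {
    v <- rv[rv$plp_intent & rv$gene == gene, , drop = FALSE]
    if (!nrow(v)) stop("variant catalogue has no P/LP record for ", gene)
    v$variant_id[1]
  }
  mono_ids <- ids[etiology == "monogenic"]
  gene_mix <- c(
    rep("LDLR", c0$ldlr_carriers), rep("APOB", c0$apob_carriers),
    rep("PCSK9", c0$pcsk9_carriers)
  )
  carriage <- if (length(mono_ids)) {
    data.frame(
      id = mono_ids,
      variant_id = vapply(gene_mix, gene_variant, character(1)),
      allele_count = 1L, stringsAsFactors = FALSE
    )
  } else {
    data.frame(id = character(), variant_id = character(), allele_count = integer())
  }

  date0 <- as.Date("2015-06-01")
  participants <- data.frame(
    id = ids, age = 50, sex = "male", race = "white", bmi = 29.5,
    diabetes = FALSE, hypertension = FALSE,
    premature_ascvd_relative = FALSE, relative_ldl_gt95 = FALSE,
    relative_xanthomata_or_arcus = FALSE, child_ldl_gt95 = FALSE,
    famhx_hypercholesterolemia = FALSE,
    tendon_xanthomata = fh, # 6 points: the minimal trigger for DLCN >= 6
    arcus_cornealis = FALSE, arcus_age = NA_real_,
    statin_type = NA_character_, statin_dose = NA_real_,
    statin_active_on_index = FALSE, eligible = TRUE,
    stringsAsFactors = FALSE
  )
  lipids <- data.frame(
    id = ids, date = date0, ldl = ldl, trig = 150, hdl = 55,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    id = ids, etiology_truth = ifelse(etiology == "polygenic", "polygenic_tail",
      ifelse(etiology == "monogenic", "monogenic", "neither")),
    raw_pgs = as.numeric(genotypes %*% panel$weight),
    genetic_ldl = 0, untreated_ldl = ldl, stringsAsFactors = FALSE
  )
  out <- structure(
    list(
      participants = participants, lipids = lipids,
      diagnoses = data.frame(id = character(), date = as.Date(character()),
        code = character(), age_at_event = numeric(), stringsAsFactors = FALSE),
      genotypes = genotypes,
      variants = rv[, setdiff(names(rv), c("mix", "plp_intent")), drop = FALSE],
      carriage = carriage, truth = truth, config = config
    ),
    class = "fh_cohort"
  )
  attr(out, "percentile_reference") <- data.frame(
    sex = c("male", "female"), age_min = 18, age_max = 70,
    p95 = 170, p99 = 235, stringsAsFactors = FALSE
  )
  out
}

# seq_len that tolerates 0 cleanly inside index assignment
seq_len2 <- function(k) if (k > 0) seq_len(k) else integer(0)
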