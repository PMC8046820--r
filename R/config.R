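#' Load the packaged default pipeline configuration
#'
#' The configuration carries every tunable used by the pipeline: cohort
#' selection criteria, the 12-SNV score panel, the DLCN point table, statin
#' dose-reduction coefficients, the age/sex LDL-C percentile reference,
#' ACMG engine settings, and the synthetic-cohort generator parameters.
#' All of it is data (YAML); nothing clinical is hard-coded.
#'
#' @return a validated `fh_config` list.
#' @seealso [load_config()] for reading a user-edited file.
#' @export
fh_default_config <- function() {
  load_config(system.file("extdata", "default_config.yaml",
    package = "fhetiology", mustWork = TRUE
  ))
}

#' Load and validate a pipeline configuration file
#'
#' @param path YAML configuration file, structured like the packaged
#'   default (`system.file("extdata", "default_config.yaml", package =
#'   "fhetiology")`).
#' @return a validated `fh_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks ranges, probabilities, monotonicity of statin coefficients,
#' percentile-reference consistency and panel invariants. Unknown top-level
#' sections are rejected so typos fail loudly instead of silently using a
#' default.
#'
#' @param cfg configuration list (parsed YAML).
#' @return the configuration, classed `fh_config`, invisibly usable onward.
#' @export
validate_config <- function(cfg) {
  known <- c(
    "seed", "selection", "pgs", "pathogenicity", "dlcn", "statins",
    "percentile_reference", "snv_panel", "generator"
  )
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(known, names(cfg))
  if (length(missing)) stop("missing configuration section(s): ", paste(missing, collapse = ", "))

  sel <- cfg$selection
  if (!is.numeric(sel$age_min) || !is.numeric(sel$age_max) || sel$age_min > sel$age_max) {
    stop_field("selection.age_min/age_max", "must be numeric with age_min <= age_max")
  }
  if (!is.numeric(sel$ldl_threshold_mgdl) || sel$ldl_threshold_mgdl <= 0) {
    stop_field("selection.ldl_threshold_mgdl", "must be positive")
  }
  if (!is.numeric(sel$window_days) || sel$window_days < 0) {
    stop_field("selection.window_days", "must be non-negative")
  }

  if (!is.numeric(cfg$pgs$threshold) || !is.finite(cfg$pgs$threshold)) {
    stop_field("pgs.threshold", "must be finite")
  }
  if (!cfg$pgs$missing_policy %in% c("impute", "strict")) {
    stop_field("pgs.missing_policy", "must be 'impute' or 'strict'")
  }

  ft <- cfg$pathogenicity$frequency_threshold
  if (!is.numeric(ft) || ft <= 0 || ft > 1) {
    stop_field("pathogenicity.frequency_threshold", "must be in (0, 1]")
  }

  # statin table: reductions in (0,1), non-decreasing in dose within type
  for (type in names(cfg$statins)) {
    tab <- cfg$statins[[type]]
    doses <- as.numeric(names(tab))
    r <- unlist(tab)
    if (any(is.na(doses))) stop_field(paste0("statins.", type), "doses must be numeric")
    if (any(r <= 0 | r >= 1)) stop_field(paste0("statins.", type), "reductions must be strictly in (0, 1)")
    if (is.unsorted(r[order(doses)])) {
      stop_field(paste0("statins.", type), "reduction must be non-decreasing in dose")
    }
  }

  ref <- percentile_reference_table(cfg)
  if (any(ref$p99 <= ref$p95)) stop_field("percentile_reference", "p99 must exceed p95 in every stratum")
  if (any(ref$p95 <= 0)) stop_field("percentile_reference", "cut points must be positive")

  panel <- snv_panel_table(cfg)
  if (anyDuplicated(panel$id)) stop_field("snv_panel", "SNV identifiers must be unique")
  if (any(!is.finite(panel$weight) | panel$weight <= 0)) {
    stop_field("snv_panel", "weights must be finite and strictly positive (effect allele = LDL-raising allele)")
  }
  if (any(panel$eaf <= 0 | panel$eaf >= 1)) stop_field("snv_panel", "effect-allele frequencies must be in (0, 1)")
  if (any(panel$effect_allele == panel$other_allele)) {
    stop_field("snv_panel", "effect and other allele must differ")
  }

  gen <- cfg$generator
  if (!is.numeric(gen$n_population) || gen$n_population < 1) {
    stop_field("generator.n_population", "must be >= 1")
  }
  check_prob(gen$plp_carrier_rate, "generator.plp_carrier_rate")
  check_prob(gen$vus_carrier_rate, "generator.vus_carrier_rate")
  check_prob(gen$male_fraction, "generator.male_fraction")
  check_prob(gen$white_fraction, "generator.white_fraction")
  for (nm in names(gen$prevalence)) check_prob(gen$prevalence[[nm]], paste0("generator.prevalence.", nm))
  for (nm in c("monogenic_shift_mean", "monogenic_shift_sd", "pgs_to_ldl_scale", "residual_sd")) {
    if (!is.numeric(gen[[nm]]) || !is.finite(gen[[nm]])) stop_field(paste0("generator.", nm), "must be finite")
  }
  if (gen$residual_sd < 0 || gen$monogenic_shift_sd < 0) {
    stop_field("generator.residual_sd/monogenic_shift_sd", "must be non-negative")
  }
  mixes <- vapply(gen$rare_variants, function(v) v$mix, numeric(1))
  if (any(mixes <= 0)) stop_field("generator.rare_variants", "sampling mix weights must be positive")

  structure(cfg, class = c("fh_config", "list"))
}

#' @export
print.fh_config <- function(x, ...) {
  cat("<fh_config>\n")
  cat("  SNV panel:", length(x$snv_panel), "variants, sum of weights",
    format(sum(vapply(x$snv_panel, function(s) s$weight, 1.0)), digits = 4), "\n")
  cat("  selection: LDL >=", x$selection$ldl_threshold_mgdl, "mg/dl, ages",
    x$selection$age_min, "-", x$selection$age_max, "\n")
  cat("  PGS threshold:", x$pgs$threshold, " DLCN phenotypic FH >=", x$dlcn$phenotypic_fh_min, "\n")
  cat("  generator: n =", x$generator$n_population,
    ", carrier rate", x$generator$plp_carrier_rate, "\n")
  invisible(x)
}

#' SNV panel as a data frame
#'
#' @param cfg an `fh_config` (default: packaged defaults).
#' @return data.frame with columns id, gene, chrom, pos, effect_allele,
#'   other_allele, eaf, weight.
#' @export
snv_panel_table <- function(cfg = fh_default_config()) {
  do.call(rbind, lapply(cfg$snv_panel, function(s) {
    data.frame(
      id = s$id, gene = s$gene, chrom = as.character(s$chrom), pos = as.integer(s$pos),
      effect_allele = s$effect_allele, other_allele = s$other_allele,
      eaf = s$eaf, weight = s$weight, stringsAsFactors = FALSE
    )
  }))
}

#' Percentile reference as a data frame
#'
#' @param cfg an `fh_config`.
#' @return data.frame with columns sex, age_min, age_max, p95, p99.
#' @export
percentile_reference_table <- function(cfg = fh_default_config()) {
  do.call(rbind, lapply(cfg$percentile_reference, function(s) {
    data.frame(
      sex = s$sex, age_min = s$age_min, age_max = s$age_max,
      p95 = s$p95, p99 = s$p99, stringsAsFactors = FALSE
    )
  }))
}

rare_variant_table <- function(cfg) {
  do.call(rbind, lapply(cfg$generator$rare_variants, function(v) {
    data.frame(
      variant_id = v$id, chrom = as.character(v$chrom), pos = as.integer(v$pos),
      ref = v$ref, alt = v$alt, gene = v$gene, consequence = v$consequence,
      ref_af = if (is.null(v$ref_af)) NA_real_ else v$ref_af,
      clnsig = if (is.null(v$clnsig)) NA_character_ else v$clnsig,
      pred_verdict = v$pred_verdict %||% "unknown",
      evidence = paste(unlist(v$evidence), collapse = ","),
      mix = v$mix, plp_intent = isTRUE(v$plp),
      stringsAsFactors = FALSE
    )
  }))
}
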