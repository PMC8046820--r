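#' Impute untreated LDL-C for statin users
#'
#' Statins lower LDL-C by an approximately fixed proportion `r` that depends
#' on drug and daily dose. The untreated level is recovered multiplicatively:
#' `untreated = observed / (1 - r)`. Participants not on a statin are
#' returned unchanged.
#'
#' @param observed observed LDL-C in mg/dl (vector).
#' @param statin_type statin name, `NA` for untreated (recycled).
#' @param statin_dose daily dose in mg (recycled).
#' @param statins coefficient table: named list (type) of named lists
#'   (dose as character) of proportional reductions, as in the packaged
#'   configuration's `statins` section.
#' @return untreated LDL-C in mg/dl.
#' @export
#' @examples
#' cfg <- fh_default_config()
#' impute_untreated_ldl(120, "atorvastatin", 40, cfg$statins) # 120 / 0.51
impute_untreated_ldl <- function(observed, statin_type, statin_dose, statins) {
  n <- length(observed)
  statin_type <- rep_len(statin_type, n)
  statin_dose <- rep_len(statin_dose, n)
  if (any(!is.finite(observed) | observed <= 0)) stop("observed LDL-C must be positive")
  r <- vapply(seq_len(n), function(i) {
    type <- statin_type[i]
    if (is.na(type) || type == "") return(0)
    tab <- statins[[type]]
    if (is.null(tab)) {
      stop(
        "unknown statin type '", type, "'; known: ",
        paste(names(statins), collapse = ", ")
      )
    }
    key <- as.character(statin_dose[i])
    # doses may parse as "10" vs "10.0"; match numerically
    doses <- as.numeric(names(tab))
    j <- which(doses == as.numeric(key))
    if (!length(j)) {
      stop(
        "unknown dose ", key, " mg for ", type, "; known doses: ",
        paste(names(tab), collapse = ", ")
      )
    }
    as.numeric(tab[[j]])
  }, numeric(1))
  observed / (1 - r)
}

#' Assign age/sex-specific LDL-C percentile strata
#'
#' Flags untreated LDL-C at or above the 95th and 99th percentile cut
#' points of the participant's (sex, age band) reference stratum.
#' Comparison is inclusive, and `ge99` implies `ge95` by the reference
#' invariant `p99 > p95`.
#'
#' @param untreated_ldl untreated LDL-C in mg/dl (vector).
#' @param age age in years (recycled).
#' @param sex `"male"` or `"female"` (recycled).
#' @param reference data.frame as from [percentile_reference_table()].
#' @return data.frame with logical columns `ge95`, `ge99`.
#' @export
assign_percentile_strata <- function(untreated_ldl, age, sex, reference) {
  n <- length(untreated_ldl)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  cuts <- lookup_percentile_cuts(age, sex, reference)
  data.frame(
    ge95 = untreated_ldl >= cuts$p95,
    ge99 = untreated_ldl >= cuts$p99
  )
}

lookup_percentile_cuts <- function(age, sex, reference) {
  idx <- vapply(seq_along(age), function(i) {
    j <- which(reference$sex == sex[i] &
      reference$age_min <= age[i] & age[i] <= reference$age_max)
    if (!length(j)) {
      stop(
        "no percentile reference stratum for sex=", sex[i], ", age=", age[i],
        " (coverage ", min(reference$age_min), "-", max(reference$age_max), ")"
      )
    }
    j[1]
  }, integer(1))
  reference[idx, c("p95", "p99")]
}
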