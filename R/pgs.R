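#' Compute the weighted 12-SNV polygenic score
#'
#' Raw score for each participant: sum over panel SNVs of per-allele
#' weight times effect-allele dosage, in the units of the panel weights
#' (mmol/l here; no unit conversion happens inside the score). Missing
#' dosages are imputed as twice the effect-allele frequency (expected
#' dosage under Hardy-Weinberg) under the default policy, or rejected
#' under the strict policy.
#'
#' @param dosages numeric matrix (participants x SNVs) of effect-allele
#'   dosages in `{0, 1, 2}` or `NA`; columns named by SNV identifier.
#' @param panel data.frame as from [snv_panel_table()].
#' @param missing_policy `"impute"` (default) or `"strict"`.
#' @param max_missing_fraction under `"impute"`, reject participants with
#'   more than this fraction of missing panel dosages (default 0.5).
#' @return numeric vector of raw scores.
#' @export
#' @examples
#' panel <- snv_panel_table()
#' d <- matrix(2, 1, nrow(panel), dimnames = list(NULL, panel$id))
#' compute_pgs(d, panel) # 2 * sum of weights
compute_pgs <- function(dosages, panel, missing_policy = "impute",
                        max_missing_fraction = 0.5) {
  if (is.null(dim(dosages))) {
    dosages <- matrix(dosages, nrow = 1, dimnames = list(NULL, names(dosages)))
  }
  if (is.null(colnames(dosages))) stop("dosage columns must be named by SNV identifier")
  unknown <- setdiff(colnames(dosages), panel$id)
  if (length(unknown)) stop("unknown SNV identifier(s): ", paste(unknown, collapse = ", "))
  missing_snv <- setdiff(panel$id, colnames(dosages))
  if (length(missing_snv)) stop("panel SNV(s) absent from dosages: ", paste(missing_snv, collapse = ", "))
  d <- dosages[, panel$id, drop = FALSE]
  ok <- is.na(d) | (d %in% c(0, 1, 2))
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  n_missing <- rowSums(is.na(d))
  if (missing_policy == "strict") {
    if (any(n_missing > 0)) stop("missing dosages not allowed under strict policy")
  } else if (missing_policy == "impute") {
    if (any(n_missing > max_missing_fraction * ncol(d))) {
      stop("more than ", 100 * max_missing_fraction, "% of panel dosages missing")
    }
    exp_d <- matrix(2 * panel$eaf, nrow(d), ncol(d), byrow = TRUE)
    d[is.na(d)] <- exp_d[is.na(d)]
  } else {
    stop("unknown missing policy: ", missing_policy)
  }
  as.numeric(d %*% panel$weight)
}

#' Flag polygenic etiology
#'
#' Polygenic hypercholesterolemia: raw score at or above the threshold
#' (default 1.16, the 90th percentile of the reference distribution) in a
#' participant *without* monogenic etiology — monogenic takes precedence.
#'
#' @param raw raw score vector.
#' @param monogenic logical vector (recycled).
#' @param threshold decision threshold on the raw score.
#' @return logical vector.
#' @export
classify_polygenic <- function(raw, monogenic, threshold = 1.16) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  raw >= threshold & !rep_len(monogenic, length(raw))
}

#' Percentile of a score in an empirical reference distribution
#'
#' `100 *` proportion of reference values strictly below the score;
#' monotone in the score, 0 below the reference minimum, 100 above the
#' maximum.
#'
#' @param raw score vector.
#' @param reference numeric vector of reference scores.
#' @return percentiles in `[0, 100]`.
#' @export
reference_percentile <- function(raw, reference) {
  if (!length(reference)) stop("reference distribution is empty")
  vapply(raw, function(x) 100 * mean(reference < x), numeric(1))
}
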