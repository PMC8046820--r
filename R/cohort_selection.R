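#' Find a participant's index date
#'
#' The index date is the earliest lipid-measure date on which LDL-C meets
#' the inclusion threshold (inclusive). Absence of any qualifying measure
#' is a value (`NA`), not an error.
#'
#' @param dates vector of measure dates (`Date` or ISO-8601 strings).
#' @param ldl LDL-C values in mg/dl, aligned with `dates`.
#' @param threshold inclusion threshold in mg/dl (default 155).
#' @return the index `Date`, or `NA` if no measure qualifies.
#' @export
#' @examples
#' find_index_date(c("2010-01-01", "2011-06-01"), c(150, 156)) # 2011-06-01
find_index_date <- function(dates, ldl, threshold = 155) {
  if (length(dates) != length(ldl)) stop("dates and ldl must align")
  if (!length(dates)) return(as.Date(NA))
  dates <- as.Date(dates)
  hit <- which(ldl >= threshold)
  if (!length(hit)) return(as.Date(NA))
  min(dates[hit])
}

#' Apply the study inclusion/exclusion funnel
#'
#' A participant is retained iff (in this order of attribution):
#' an eligibility flag (if present) is true; an index date exists
#' (some LDL-C at or above the threshold); age at index is within the
#' configured bounds (inclusive); and no configured secondary-cause
#' diagnosis is dated within the window around the index date
#' (symmetric, boundary-inclusive by default). Each excluded participant
#' is counted once, under its first failing rule.
#'
#' @param cohort an `fh_cohort` (see [generate_population()]), or any list
#'   with `participants` (columns `id`, `age`; optional `eligible`),
#'   `lipids` (`id`, `date`, `ldl`) and `diagnoses` (`id`, `date`, `code`).
#' @param criteria the `selection` configuration block: `age_min`,
#'   `age_max`, `ldl_threshold_mgdl`, `window_days`, `window_inclusive`,
#'   `secondary_causes`.
#' @return an `fh_selection`: `retained_ids`, per-participant `index_dates`,
#'   `exclusions` (named counts in attribution order), and `funnel`
#'   data.frame (`screened`, each exclusion, `retained`).
#' @export
apply_selection <- function(cohort, criteria = fh_default_config()$selection) {
  p <- cohort$participants
  if (is.null(p$id) || is.null(p$age)) stop("participants must have id and age columns")
  if (anyDuplicated(p$id)) stop("duplicate participant id(s): ", p$id[duplicated(p$id)][1])
  n <- nrow(p)
  lip <- cohort$lipids
  dx <- cohort$diagnoses

  lip_rows <- split(seq_len(nrow(lip)), factor(lip$id, levels = p$id))
  idx <- as.Date(rep(NA, n))
  for (i in seq_len(n)) {
    rows <- lip_rows[[i]]
    idx[i] <- find_index_date(lip$date[rows], lip$ldl[rows], criteria$ldl_threshold_mgdl)
  }

  reason <- rep(NA_character_, n)
  eligible <- if (!is.null(p$eligible)) p$eligible else rep(TRUE, n)
  reason[!eligible] <- "not_eligible"
  reason[is.na(reason) & is.na(idx)] <- "no_index_date"
  age_ok <- p$age >= criteria$age_min & p$age <= criteria$age_max
  reason[is.na(reason) & !age_ok] <- "age_out_of_range"

  half <- criteria$window_days
  inclusive <- isTRUE(criteria$window_inclusive %||% TRUE)
  dx2 <- dx[dx$code %in% criteria$secondary_causes, , drop = FALSE]
  dx_rows <- split(seq_len(nrow(dx2)), factor(dx2$id, levels = p$id))
  for (i in which(is.na(reason))) {
    rows <- dx_rows[[i]]
    if (length(rows)) {
      delta <- abs(as.numeric(as.Date(dx2$date[rows]) - idx[i]))
      hit <- if (inclusive) any(delta <= half) else any(delta < half)
      if (hit) reason[i] <- "secondary_cause_in_window"
    }
  }

  retained <- p$id[is.na(reason)]
  order_levels <- c("not_eligible", "no_index_date", "age_out_of_range", "secondary_cause_in_window")
  exclusions <- vapply(order_levels, function(r) sum(reason == r, na.rm = TRUE), integer(1))
  structure(
    list(
      retained_ids = retained,
      index_dates = data.frame(id = p$id, index_date = idx, excluded_reason = reason,
        stringsAsFactors = FALSE),
      exclusions = exclusions,
      funnel = data.frame(
        stage = c("screened", names(exclusions), "retained"),
        n = c(n, unname(exclusions), length(retained))
      )
    ),
    class = "fh_selection"
  )
}

#' @export
print.fh_selection <- function(x, ...) {
  cat("<fh_selection>\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}

# restrict a cohort to a set of participant ids (keeps all linked tables)
subset_cohort <- function(cohort, ids) {
  keep <- cohort$participants$id %in% ids
  out <- cohort
  out$participants <- cohort$participants[keep, , drop = FALSE]
  out$lipids <- cohort$lipids[cohort$lipids$id %in% ids, , drop = FALSE]
  out$diagnoses <- cohort$diagnoses[cohort$diagnoses$id %in% ids, , drop = FALSE]
  out$genotypes <- cohort$genotypes[rownames(cohort$genotypes) %in% ids, , drop = FALSE]
  out$carriage <- cohort$carriage[cohort$carriage$id %in% ids, , drop = FALSE]
  out$truth <- cohort$truth[cohort$truth$id %in% ids, , drop = FALSE]
  rownames(out$participants) <- NULL
  out
}
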