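#' Round half away from zero
#'
#' Presentation rounding used for every percentage the pipeline reports.
#' Unlike [base::round()] (banker's rounding), ties go up: `round_half_up(26.05, 1)`
#' is 26.1. Centralised so every report uses the same convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 10 / 142, 1) # 7.0
#' round_half_up(100 * 37 / 287, 1) # 12.9
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Convert LDL-C between mg/dl and mmol/l
#'
#' Uses the conventional factor 1 mmol/l = 38.67 mg/dl, so 4 mmol/l is
#' approximately the 155 mg/dl inclusion threshold.
#'
#' @param value numeric vector of concentrations.
#' @param from,to units, each one of `"mg/dl"` or `"mmol/l"`.
#' @return converted values.
#' @export
#' @examples
#' convert_units(4, "mmol/l", "mg/dl") # 154.68
convert_units <- function(value, from, to) {
  units <- c("mg/dl", "mmol/l")
  if (!from %in% units) stop("unknown unit: ", from)
  if (!to %in% units) stop("unknown unit: ", to)
  if (from == to) return(value)
  if (from == "mmol/l") value * MGDL_PER_MMOLL else value / MGDL_PER_MMOLL
}

MGDL_PER_MMOLL <- 38.67

# percentage record used throughout summary tables; denominator 0 => NA percent
#  ("undefined", never 0)
pct_row <- function(name, numerator, denominator) {
  pct <- if (denominator > 0) round_half_up(100 * numerator / denominator, 1) else NA_real_
  data.frame(
    name = name, numerator = numerator, denominator = denominator,
    percent = pct, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}
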