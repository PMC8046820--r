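#' Is an ASCVD event premature?
#'
#' Premature atherosclerotic cardiovascular disease: coronary heart
#' disease, cerebrovascular disease or peripheral artery disease occurring
#' strictly before age 55 in males and before age 65 in females.
#'
#' @param event_type one of `"CHD"`, `"cerebrovascular"`,
#'   `"peripheral_artery"` (vectors recycled).
#' @param age_at_event age in years at the event.
#' @param sex `"male"` or `"female"`.
#' @return logical vector.
#' @export
#' @examples
#' is_premature_ascvd("CHD", 54, "male") # TRUE
#' is_premature_ascvd("CHD", 55, "male") # FALSE
is_premature_ascvd <- function(event_type, age_at_event, sex) {
  valid <- c("CHD", "cerebrovascular", "peripheral_artery")
  if (any(!event_type %in% valid)) {
    stop(
      "unknown ASCVD event type: ",
      paste(setdiff(event_type, valid), collapse = ", ")
    )
  }
  if (any(age_at_event < 0)) stop("age_at_event must be >= 0")
  cutoff <- ifelse(sex == "male", 55, 65)
  age_at_event < cutoff
}

#' Map a DLCN total score to its category
#'
#' Categories: unlikely (< 3), possible (3-5), probable (6-8),
#' definite (>= 9).
#'
#' @param total integer total score(s).
#' @param breaks named list with cut points `possible`, `probable`,
#'   `definite` (defaults 3, 6, 9).
#' @return factor with levels unlikely < possible < probable < definite.
#' @export
dlcn_category <- function(total, breaks = list(possible = 3, probable = 6, definite = 9)) {
  cut(total,
    breaks = c(-Inf, breaks$possible, breaks$probable, breaks$definite, Inf),
    labels = c("unlikely", "possible", "probable", "definite"),
    right = FALSE, ordered_result = TRUE
  )
}

#' Compute the Dutch Lipid Clinic Network score
#'
#' Additive clinical score over five criterion groups (family history,
#' personal history, physical examination, untreated LDL-C band, DNA).
#' Within a group only the highest-scoring satisfied condition counts;
#' the total is the sum of group contributions. Phenotypic FH is a total
#' of 6 or more (probable or definite FH). The DNA criterion is excluded
#' by default so that the phenotype can be compared with genotype without
#' circularity.
#'
#' @param flags data.frame (one row per participant) of logical columns;
#'   recognised names: `premature_ascvd_relative`, `relative_ldl_gt95`,
#'   `relative_xanthomata_or_arcus`, `child_ldl_gt95`, `premature_chd`,
#'   `premature_cerebrovascular_or_pad`, `tendon_xanthomata`,
#'   `arcus_before_45`, `causative_variant`. Missing columns (or `NA`
#'   values) are treated as criterion-not-met.
#' @param untreated_ldl untreated LDL-C in mg/dl.
#' @param points DLCN point table (the `dlcn$points` configuration block).
#' @param include_dna include the DNA criterion group (default `FALSE`).
#' @param phenotypic_fh_min total defining phenotypic FH (default 6).
#' @param breaks category cut points, see [dlcn_category()].
#' @return data.frame of class `fh_dlcn`: per-group points, `total`,
#'   `category`, `phenotypic_fh`.
#' @export
#' @examples
#' cfg <- fh_default_config()
#' flags <- data.frame(premature_chd = TRUE, tendon_xanthomata = TRUE)
#' score_dlcn(flags, untreated_ldl = 195, points = cfg$dlcn$points)
score_dlcn <- function(flags, untreated_ldl, points,
                       include_dna = FALSE,
                       phenotypic_fh_min = 6,
                       breaks = list(possible = 3, probable = 6, definite = 9)) {
  n <- length(untreated_ldl)
  if (any(untreated_ldl < 0, na.rm = TRUE)) stop("untreated LDL-C must be >= 0")
  get_flag <- function(name) {
    v <- if (name %in% names(flags)) flags[[name]] else rep(FALSE, n)
    v <- rep_len(v, n)
    v & !is.na(v)
  }
  group_points <- function(group) {
    # max points over satisfied conditions within the group
    pts <- rep(0L, n)
    for (cond in names(group)) {
      p <- as.integer(group[[cond]])
      hit <- get_flag(cond)
      pts <- pmax(pts, ifelse(hit, p, 0L))
    }
    pts
  }
  fam <- group_points(points$family_history)
  per <- group_points(points$personal_history)
  phy <- group_points(points$physical_exam)
  dna <- if (include_dna) group_points(points$dna) else rep(0L, n)
  ldl <- ldl_band_points(untreated_ldl, points$ldl_mgdl)
  total <- fam + per + phy + dna + ldl
  out <- data.frame(
    family_history = fam, personal_history = per, physical_exam = phy,
    ldl_level = ldl, dna = dna, total = total,
    category = dlcn_category(total, breaks),
    phenotypic_fh = total >= phenotypic_fh_min
  )
  class(out) <- c("fh_dlcn", "data.frame")
  out
}

ldl_band_points <- function(untreated_ldl, bands) {
  mins <- vapply(bands, function(b) as.numeric(b$min), numeric(1))
  pts <- vapply(bands, function(b) as.integer(b$points), integer(1))
  o <- order(mins, decreasing = TRUE)
  mins <- mins[o]
  pts <- pts[o]
  out <- rep(0L, length(untreated_ldl))
  assigned <- rep(FALSE, length(untreated_ldl))
  for (k in seq_along(mins)) {
    hit <- !assigned & untreated_ldl >= mins[k]
    out[hit] <- pts[k]
    assigned <- assigned | hit
  }
  out
}
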