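#' Final etiology label per participant
#'
#' Monogenic (P/LP carrier) takes precedence; otherwise polygenic when the
#' score flag is set; otherwise none.
#'
#' @param monogenic,polygenic logical vectors.
#' @return character vector in `{monogenic, polygenic, none}`.
#' @export
classify_etiology <- function(monogenic, polygenic) {
  ifelse(monogenic, "monogenic", ifelse(polygenic, "polygenic", "none"))
}

#' Cross-tabulate genetic etiology against the FH phenotype
#'
#' Produces every summary the overlap analysis reports: marginal
#' percentages over the full cohort, conditional percentages within
#' phenotypic FH, within each etiology, and within each LDL stratum, each
#' carried with its numerator and denominator. Percentages use the shared
#' half-up one-decimal rounding; an empty denominator yields an undefined
#' (`NA`) percentage, never 0. The genetic share of phenotypic FH is
#' reported both directly and as the sum of the rounded monogenic and
#' polygenic components (the two can differ in the last decimal).
#'
#' @param calls data.frame with columns `etiology` (monogenic / polygenic
#'   / none), `phenotypic_fh` (logical), `ge190`, `ge250`, `ge95`, `ge99`
#'   (logical strata flags), and optionally `carrier_gene`.
#' @return an `fh_summary`: data.frame `name`, `numerator`, `denominator`,
#'   `percent`.
#' @export
crosstab_overlap <- function(calls) {
  if (!nrow(calls)) stop("empty cohort")
  stopifnot(all(calls$etiology %in% c("monogenic", "polygenic", "none")))
  n <- nrow(calls)
  mono <- calls$etiology == "monogenic"
  poly <- calls$etiology == "polygenic"
  genetic <- mono | poly
  fh <- calls$phenotypic_fh

  rows <- list(
    pct_row("monogenic", sum(mono), n),
    pct_row("polygenic", sum(poly), n),
    pct_row("genetic_etiology", sum(genetic), n),
    pct_row("phenotypic_fh", sum(fh), n),
    pct_row("ldl_ge190", sum(calls$ge190), n),
    pct_row("ldl_ge250", sum(calls$ge250), n),
    pct_row("ldl_ge95", sum(calls$ge95), n),
    pct_row("ldl_ge99", sum(calls$ge99), n),
    pct_row("monogenic_among_fh", sum(mono & fh), sum(fh)),
    pct_row("polygenic_among_fh", sum(poly & fh), sum(fh)),
    pct_row("genetic_among_fh", sum(genetic & fh), sum(fh)),
    pct_row("fh_among_genetic", sum(genetic & fh), sum(genetic)),
    pct_row("fh_among_monogenic", sum(mono & fh), sum(mono)),
    pct_row("fh_among_polygenic", sum(poly & fh), sum(poly)),
    pct_row("monogenic_among_ldl_ge190", sum(mono & calls$ge190), sum(calls$ge190)),
    pct_row("monogenic_among_ldl_ge250", sum(mono & calls$ge250), sum(calls$ge250)),
    pct_row("monogenic_among_ldl_ge95", sum(mono & calls$ge95), sum(calls$ge95)),
    pct_row("monogenic_among_ldl_ge99", sum(mono & calls$ge99), sum(calls$ge99)),
    pct_row("genetic_among_ldl_ge190", sum(genetic & calls$ge190), sum(calls$ge190))
  )
  out <- do.call(rbind, rows)

  # composite: sum of the rounded components, alongside the direct ratio
  comp <- sum(
    out$percent[out$name == "monogenic_among_fh"],
    out$percent[out$name == "polygenic_among_fh"]
  )
  out <- rbind(out, data.frame(
    name = "genetic_among_fh_sum_of_rounded",
    numerator = sum(genetic & fh), denominator = sum(fh),
    percent = if (sum(fh) > 0) comp else NA_real_
  ))

  if (!is.null(calls$carrier_gene) && any(mono)) {
    for (g in c("LDLR", "APOB", "PCSK9")) {
      out <- rbind(out, pct_row(
        paste0("carrier_gene_", tolower(g)),
        sum(calls$carrier_gene == g & mono, na.rm = TRUE), sum(mono)
      ))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("fh_summary", "data.frame")
  out
}

#' @export
print.fh_summary <- function(x, ...) {
  y <- x
  y$percent <- ifelse(is.na(y$percent), "undefined", sprintf("%.1f%%", y$percent))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Look up a percentage from a summary
#'
#' @param summary an `fh_summary`.
#' @param name row name.
#' @return the rounded percentage (`NA` when undefined).
#' @export
summary_pct <- function(summary, name) {
  i <- match(name, summary$name)
  if (is.na(i)) stop("no summary row named '", name, "'")
  summary$percent[i]
}

#' Compare groups with standard two-sided tests
#'
#' Chi-square for categorical counts, Welch's t-test for two numeric
#' groups, one-way ANOVA for three or more. Thin wrappers around
#' [stats::chisq.test()], [stats::t.test()] and [stats::aov()], with the
#' 0.05 significance convention flagged on the result.
#'
#' @param values for `kind = "chisq"` a contingency table or matrix of
#'   counts; otherwise a numeric vector.
#' @param groups grouping factor (ignored for `chisq`).
#' @param kind `"chisq"`, `"t"` or `"anova"`.
#' @return list `statistic`, `p_value`, `significant`, `method`.
#' @export
group_compare <- function(values, groups = NULL, kind = c("t", "anova", "chisq")) {
  kind <- match.arg(kind)
  if (kind == "chisq") {
    ht <- stats::chisq.test(values)
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value, method = "chi-square")
  } else {
    groups <- factor(groups)
    if (nlevels(groups) < 2) stop("need at least two groups")
    sizes <- table(groups)
    if (any(sizes < 2)) stop("degenerate group (n < 2)")
    if (kind == "t") {
      if (nlevels(groups) != 2) stop("t-test requires exactly two groups")
      if (any(tapply(values, groups, stats::var) == 0)) stop("degenerate group (zero variance)")
      ht <- stats::t.test(values ~ groups) # Welch by default
      res <- list(statistic = unname(ht$statistic), p_value = ht$p.value, method = "Welch t-test")
    } else {
      fit <- stats::aov(values ~ groups)
      s <- summary(fit)[[1]]
      res <- list(
        statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
        method = "one-way ANOVA"
      )
    }
  }
  res$significant <- res$p_value < 0.05
  res
}

#' Variance in LDL-C explained by genetic vs clinical factors
#'
#' Two separate ordinary-least-squares fits on untreated LDL-C: a genetic
#' model (raw polygenic score + monogenic indicator) and a clinical model
#' (age, sex, race, BMI, diabetes, family history of
#' hypercholesterolemia). Reports each model's R-squared. Constant or
#' collinear predictors are an error, not a silent drop.
#'
#' @param table data.frame with columns `untreated_ldl`, `raw_pgs`,
#'   `monogenic`, `age`, `sex`, `race`, `bmi`, `diabetes`,
#'   `famhx_hypercholesterolemia`.
#' @return list of class `fh_variance`: `r2_genetic`, `r2_clinical`, `n`,
#'   and the two coefficient tables.
#' @export
variance_explained <- function(table) {
  needed <- c(
    "untreated_ldl", "raw_pgs", "monogenic", "age", "sex", "race", "bmi",
    "diabetes", "famhx_hypercholesterolemia"
  )
  miss <- setdiff(needed, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  fit_block <- function(formula, label) {
    vars <- all.vars(formula)[-1]
    for (v in vars) {
      if (length(unique(table[[v]])) < 2) {
        stop(label, " model has constant predictor: ", v)
      }
    }
    mm <- stats::model.matrix(formula, table)
    if (qr(mm)$rank < ncol(mm)) stop(label, " model has collinear predictors")
    stats::lm(formula, data = table)
  }
  g <- fit_block(untreated_ldl ~ raw_pgs + monogenic, "genetic")
  cl <- fit_block(
    untreated_ldl ~ age + sex + race + bmi + diabetes + famhx_hypercholesterolemia,
    "clinical"
  )
  structure(
    list(
      r2_genetic = summary(g)$r.squared,
      r2_clinical = summary(cl)$r.squared,
      n = nrow(table),
      coef_genetic = summary(g)$coefficients,
      coef_clinical = summary(cl)$coefficients
    ),
    class = "fh_variance"
  )
}

#' @export
print.fh_variance <- function(x, ...) {
  cat("<fh_variance> n =", x$n, "\n")
  cat(sprintf("  genetic model R2:  %.4f\n", x$r2_genetic))
  cat(sprintf("  clinical model R2: %.4f\n", x$r2_clinical))
  invisible(x)
}
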