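#' Run the full etiology-attribution pipeline
#'
#' Stage order: select (inclusion funnel) -> adjust (statin imputation,
#' unit handling, percentile strata) -> DLCN scoring -> variant
#' classification and monogenic calls -> polygenic score -> etiology
#' labels, overlap cross-tabulation and variance-explained regression.
#' When `out_dir` is given, every stage writes its artifact (TSV), the
#' summary gets a machine-readable JSON twin, and a manifest records the
#' seed, configuration hash and per-stage record counts.
#'
#' @param cohort an `fh_cohort` (from [generate_population()],
#'   [fixture_from_counts()] or [read_cohort()]).
#' @param config an `fh_config`; defaults to the cohort's own.
#' @param out_dir optional output directory.
#' @return list of class `fh_result`: `selection`, `table` (merged
#'   per-participant analysis table), `classifications`, `summary`,
#'   `variance`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = cohort$config, out_dir = NULL) {
  stage <- "select"
  result <- tryCatch(
    {
      selection <- apply_selection(cohort, config$selection)
      kept <- subset_cohort(cohort, selection$retained_ids)
      idx <- selection$index_dates
      idx <- idx[match(kept$participants$id, idx$id), ]

      stage <- "adjust"
      p <- kept$participants
      # treated participants: impute from the highest observed LDL-C;
      # untreated: highest observed value as recorded
      max_ldl <- vapply(split(kept$lipids$ldl, factor(kept$lipids$id, levels = p$id)),
        max, numeric(1)
      )
      treated <- !is.na(p$statin_type) & p$statin_active_on_index
      untreated_ldl <- max_ldl
      if (any(treated)) {
        untreated_ldl[treated] <- impute_untreated_ldl(
          max_ldl[treated], p$statin_type[treated], p$statin_dose[treated],
          config$statins
        )
      }
      pref <- attr(cohort, "percentile_reference") %||% percentile_reference_table(config)
      strata <- assign_percentile_strata(untreated_ldl, p$age, p$sex, pref)

      stage <- "score-dlcn"
      flags <- dlcn_flags(kept)
      dlcn <- score_dlcn(flags, untreated_ldl,
        points = config$dlcn$points,
        include_dna = isTRUE(config$dlcn$include_dna),
        phenotypic_fh_min = config$dlcn$phenotypic_fh_min,
        breaks = config$dlcn$category_breaks
      )

      stage <- "classify-variants"
      classifications <- classify_variants(kept$variants, config$pathogenicity)
      mono <- call_monogenic(kept$carriage, classifications, p$id)

      stage <- "score-pgs"
      raw_pgs <- compute_pgs(kept$genotypes, snv_panel_table(config),
        missing_policy = config$pgs$missing_policy,
        max_missing_fraction = config$pgs$max_missing_fraction
      )
      polygenic <- classify_polygenic(raw_pgs, mono$monogenic, config$pgs$threshold)

      stage <- "summarize"
      table <- data.frame(
        id = p$id, age = p$age, sex = p$sex, race = p$race, bmi = p$bmi,
        diabetes = p$diabetes,
        famhx_hypercholesterolemia = p$famhx_hypercholesterolemia,
        index_date = idx$index_date,
        observed_ldl = max_ldl, untreated_ldl = untreated_ldl,
        ge190 = untreated_ldl >= 190, ge250 = untreated_ldl >= 250,
        ge95 = strata$ge95, ge99 = strata$ge99,
        dlcn_total = dlcn$total, dlcn_category = as.character(dlcn$category),
        phenotypic_fh = dlcn$phenotypic_fh,
        raw_pgs = raw_pgs, monogenic = mono$monogenic,
        carrier_gene = mono$carrier_gene, polygenic = polygenic,
        etiology = classify_etiology(mono$monogenic, polygenic),
        stringsAsFactors = FALSE
      )
      summary <- crosstab_overlap(table)
      variance <- tryCatch(variance_explained(table), error = function(e) {
        structure(list(
          r2_genetic = NA_real_, r2_clinical = NA_real_, n = nrow(table),
          note = conditionMessage(e)
        ), class = "fh_variance")
      })

      manifest <- list(
        package_version = as.character(utils::packageVersion("fhetiology")),
        seed = config$seed,
        config_hash = config_hash(config),
        counts = list(
          screened = nrow(cohort$participants),
          retained = length(selection$retained_ids),
          exclusions = as.list(selection$exclusions),
          plp_variants = sum(classifications$plp),
          monogenic = sum(table$monogenic),
          polygenic = sum(table$polygenic),
          phenotypic_fh = sum(table$phenotypic_fh)
        )
      )
      list(
        selection = selection, table = table, classifications = classifications,
        summary = summary, variance = variance, manifest = manifest
      )
    },
    error = function(e) {
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(result$selection$funnel, file.path(out_dir, "funnel.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(result$table, file.path(out_dir, "participants.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(result$classifications, file.path(out_dir, "variant_classifications.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(result$summary, file.path(out_dir, "summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(
      summary_to_json(result$summary, result$variance),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  class(result) <- "fh_result"
  result
}

dlcn_flags <- function(cohort) {
  p <- cohort$participants
  dx <- cohort$diagnoses
  prem <- function(codes) {
    hit <- dx[dx$code %in% codes, , drop = FALSE]
    if (!nrow(hit)) return(rep(FALSE, nrow(p)))
    sex <- p$sex[match(hit$id, p$id)]
    ok <- is_premature_ascvd(hit$code, hit$age_at_event, sex)
    p$id %in% hit$id[ok]
  }
  data.frame(
    premature_ascvd_relative = p$premature_ascvd_relative,
    relative_ldl_gt95 = p$relative_ldl_gt95,
    relative_xanthomata_or_arcus = p$relative_xanthomata_or_arcus,
    child_ldl_gt95 = p$child_ldl_gt95,
    premature_chd = prem("CHD"),
    premature_cerebrovascular_or_pad = prem(c("cerebrovascular", "peripheral_artery")),
    tendon_xanthomata = p$tendon_xanthomata,
    arcus_before_45 = p$arcus_cornealis & !is.na(p$arcus_age) & p$arcus_age < 45
  )
}

config_hash <- function(config) {
  # stable content hash without extra dependencies
  s <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 10)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

summary_to_json <- function(summary, variance) {
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    list(
      numerator = summary$numerator[i], denominator = summary$denominator[i],
      percent = if (is.na(summary$percent[i])) "undefined" else summary$percent[i]
    )
  })
  names(rows) <- summary$name
  list(
    percentages = rows,
    variance_explained = list(
      r2_genetic = variance$r2_genetic, r2_clinical = variance$r2_clinical,
      n = variance$n
    )
  )
}

#' @export
print.fh_result <- function(x, ...) {
  cat("<fh_result>\n")
  print(x$selection$funnel, row.names = FALSE)
  cat("\n")
  print(x$summary)
  cat("\n")
  print(x$variance)
  invisible(x)
}
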