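#' Functional-consequence filter for candidate variants
#'
#' Keeps protein-altering / splice-disrupting consequence classes:
#' missense, stop_gain, frameshift, splice_acceptor, splice_donor,
#' inframe_indel, start_lost, stop_lost.
#'
#' @param consequence character vector of consequence classes.
#' @return logical vector.
#' @export
functional_filter <- function(consequence) {
  consequence %in% c(
    "missense", "stop_gain", "frameshift", "splice_acceptor",
    "splice_donor", "inframe_indel", "start_lost", "stop_lost"
  )
}

#' Rare-frequency filter
#'
#' A variant is rare when its reference-population allele frequency is
#' strictly below the threshold, or absent (never observed implies rare).
#'
#' @param ref_af reference allele frequency, `NA` for absent.
#' @param threshold frequency threshold in (0, 1]; default 0.001 (0.1%).
#' @return logical vector.
#' @export
rare_filter <- function(ref_af, threshold = 0.001) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  is.na(ref_af) | ref_af < threshold
}

# null consequence classes for which PVS1 may apply (gene mechanism permitting)
NULL_CONSEQUENCES <- c("stop_gain", "frameshift", "splice_donor", "splice_acceptor", "start_lost")

ACMG_TAGS <- c(
  "PVS1",
  paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
  "BA1", paste0("BS", 1:4), paste0("BP", 1:7)
)

#' Assign automatable ACMG evidence tags to a variant
#'
#' Deterministic, annotation-derivable criteria only:
#' \describe{
#'   \item{PVS1}{null-consequence variant in a gene whose configured
#'     disease mechanism is loss of function (default: LDLR yes,
#'     APOB/PCSK9 no — their FH mechanisms are not simple LoF).}
#'   \item{PM2}{absent or rare in the reference population.}
#'   \item{PP3 / BP4}{computational-prediction verdict damaging / benign.}
#'   \item{PP5 / BP6}{clinical-database assertion pathogenic(/likely) /
#'     benign(/likely), when `use_pp5_bp6` is enabled.}
#' }
#' Evidence from manual review (functional studies, segregation,
#' literature) enters through `supplied`, mirroring the curation pathway
#' that cannot be automated.
#'
#' @param gene gene symbol (`LDLR`, `APOB`, `PCSK9`).
#' @param consequence consequence class.
#' @param ref_af reference allele frequency (`NA` = absent).
#' @param clnsig optional clinical-database class (e.g. `"pathogenic"`).
#' @param pred_verdict computational verdict: `"damaging"`, `"benign"`,
#'   `"unknown"`.
#' @param supplied character vector of directly supplied ACMG tags.
#' @param settings the `pathogenicity` configuration block.
#' @return character vector of evidence tags (an evidence set).
#' @export
assign_evidence <- function(gene, consequence, ref_af = NA, clnsig = NA,
                            pred_verdict = "unknown", supplied = character(),
                            settings = fh_default_config()$pathogenicity) {
  supplied <- supplied[nzchar(supplied)]
  bad <- setdiff(supplied, ACMG_TAGS)
  if (length(bad)) stop("unknown ACMG evidence tag(s): ", paste(bad, collapse = ", "))
  tags <- character()
  lof <- isTRUE(settings$lof_mechanism[[gene]])
  if (lof && consequence %in% NULL_CONSEQUENCES) tags <- c(tags, "PVS1")
  if (rare_filter(ref_af, settings$frequency_threshold)) tags <- c(tags, "PM2")
  if (identical(pred_verdict, "damaging")) tags <- c(tags, "PP3")
  if (identical(pred_verdict, "benign")) tags <- c(tags, "BP4")
  if (isTRUE(settings$use_pp5_bp6) && !is.na(clnsig)) {
    if (clnsig %in% c("pathogenic", "likely_pathogenic")) tags <- c(tags, "PP5")
    if (clnsig %in% c("benign", "likely_benign")) tags <- c(tags, "BP6")
  }
  if (identical(pred_verdict, "damaging") && "BP4" %in% supplied ||
    identical(pred_verdict, "benign") && "PP3" %in% supplied) {
    stop("contradictory evidence: computational verdict conflicts with supplied tag")
  }
  unique(c(tags, supplied))
}

#' Combine ACMG evidence into a five-tier classification
#'
#' Implements the full combining table of the ACMG/AMP framework.
#' Pathogenic-direction and benign-direction rules are evaluated
#' independently; when rules fire in both directions the call is
#' `uncertain` (conflicting evidence), as is any evidence set matched by
#' no rule.
#'
#' @param evidence character vector of ACMG tags (an evidence multiset;
#'   duplicate tags are counted once — criteria are per-tag, not per-report).
#' @return list of class `fh_acmg_call`: `class` (one of `pathogenic`,
#'   `likely_pathogenic`, `uncertain`, `likely_benign`, `benign`), `plp`
#'   flag, `rule` (identifier of the decisive rule), `evidence` echo.
#' @export
#' @examples
#' combine_acmg(c("PVS1", "PM2"))$class # likely_pathogenic
#' combine_acmg(c("PVS1", "PM2", "PP3"))$class # pathogenic
combine_acmg <- function(evidence) {
  evidence <- unique(evidence[nzchar(evidence)])
  bad <- setdiff(evidence, ACMG_TAGS)
  if (length(bad)) stop("unknown ACMG evidence tag(s): ", paste(bad, collapse = ", "))
  counts <- acmg_counts(evidence)
  res <- acmg_class_from_counts(
    counts["pvs"], counts["ps"], counts["pm"], counts["pp"],
    counts["ba"], counts["bs"], counts["bp"]
  )
  structure(
    list(
      class = res$class, plp = res$class %in% c("pathogenic", "likely_pathogenic"),
      rule = res$rule, evidence = evidence
    ),
    class = "fh_acmg_call"
  )
}

#' @export
print.fh_acmg_call <- function(x, ...) {
  cat("<ACMG call>", x$class, if (x$plp) "(P/LP)" else "",
    "\n  rule:", x$rule, "\n  evidence:", paste(x$evidence, collapse = " "), "\n")
  invisible(x)
}

acmg_counts <- function(evidence) {
  cat_of <- function(prefix) sum(startsWith(evidence, prefix))
  c(
    pvs = sum(evidence == "PVS1"),
    ps = cat_of("PS"),
    pm = cat_of("PM"),
    pp = cat_of("PP"),
    ba = sum(evidence == "BA1"),
    bs = cat_of("BS"),
    bp = cat_of("BP")
  )
}

# Core combining arithmetic on per-category evidence counts. Exposed for
# exhaustive property testing against an independent enumerator.
#' ACMG combining rules on per-category evidence counts
#'
#' Low-level entry point of the rule engine; [combine_acmg()] reduces tag
#' sets to these counts.
#'
#' @param pvs,ps,pm,pp,ba,bs,bp non-negative counts of very-strong,
#'   strong, moderate and supporting pathogenic evidence, and stand-alone,
#'   strong and supporting benign evidence.
#' @return list with `class` and decisive `rule`.
#' @export
acmg_class_from_counts <- function(pvs, ps, pm, pp, ba, bs, bp) {
  path_rule <- NA_character_
  if (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) {
    path_rule <- "P_PVS1_combo"
  } else if (ps >= 2) {
    path_rule <- "P_2PS"
  } else if (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4))) {
    path_rule <- "P_PS_combo"
  } else if (pvs >= 1 && pm >= 1) {
    path_rule <- "LP_PVS1_PM"
  } else if (ps == 1 && pm >= 1 && pm <= 2) {
    path_rule <- "LP_PS_1to2PM"
  } else if (ps == 1 && pp >= 2) {
    path_rule <- "LP_PS_2PP"
  } else if (pm >= 3) {
    path_rule <- "LP_3PM"
  } else if (pm == 2 && pp >= 2) {
    path_rule <- "LP_2PM_2PP"
  } else if (pm == 1 && pp >= 4) {
    path_rule <- "LP_PM_4PP"
  }

  benign_rule <- NA_character_
  if (ba >= 1) {
    benign_rule <- "B_BA1"
  } else if (bs >= 2) {
    benign_rule <- "B_2BS"
  } else if (bs >= 1 && bp >= 1) {
    benign_rule <- "LB_BS_BP"
  } else if (bp >= 2) {
    benign_rule <- "LB_2BP"
  }

  if (!is.na(path_rule) && !is.na(benign_rule)) {
    return(list(class = "uncertain", rule = "conflict"))
  }
  if (!is.na(path_rule)) {
    cls <- if (startsWith(path_rule, "P_")) "pathogenic" else "likely_pathogenic"
    return(list(class = cls, rule = path_rule))
  }
  if (!is.na(benign_rule)) {
    cls <- if (startsWith(benign_rule, "B_")) "benign" else "likely_benign"
    return(list(class = cls, rule = benign_rule))
  }
  list(class = "uncertain", rule = "no_rule")
}

#' Classify a table of annotated variants
#'
#' Applies the functional and rare filters with first-failure attribution,
#' assigns automatable evidence to the survivors and combines it.
#' Variants failing a filter are classified `uncertain` with the filter
#' named in `filter_status`.
#'
#' @param variants data.frame with columns `variant_id`, `gene`,
#'   `consequence`, `ref_af`, and optionally `clnsig`, `pred_verdict`,
#'   `evidence` (comma-separated supplied tags).
#' @param settings the `pathogenicity` configuration block.
#' @return data.frame with `variant_id`, `gene`, `filter_status`
#'   (`pass` / `fail_functional` / `fail_rare`), `class`, `plp`, `rule`,
#'   `evidence`.
#' @export
classify_variants <- function(variants, settings = fh_default_config()$pathogenicity) {
  if (any(variants$consequence %in% c("cnv", "copy_number"))) {
    stop("copy-number variant records are not supported")
  }
  n <- nrow(variants)
  clnsig <- variants$clnsig %||% rep(NA_character_, n)
  verdict <- variants$pred_verdict %||% rep("unknown", n)
  supplied <- variants$evidence %||% rep("", n)
  out <- data.frame(
    variant_id = variants$variant_id, gene = variants$gene,
    filter_status = "pass", class = "uncertain", plp = FALSE,
    rule = "not_evaluated", evidence = "", stringsAsFactors = FALSE
  )
  fun_ok <- functional_filter(variants$consequence)
  rare_ok <- rare_filter(variants$ref_af, settings$frequency_threshold)
  out$filter_status[!fun_ok] <- "fail_functional"
  out$filter_status[fun_ok & !rare_ok] <- "fail_rare"
  for (i in which(fun_ok & rare_ok)) {
    tags <- assign_evidence(
      gene = variants$gene[i], consequence = variants$consequence[i],
      ref_af = variants$ref_af[i], clnsig = clnsig[i],
      pred_verdict = verdict[i],
      supplied = strsplit(supplied[i] %||% "", ",")[[1]],
      settings = settings
    )
    call <- combine_acmg(tags)
    out$class[i] <- call$class
    out$plp[i] <- call$plp
    out$rule[i] <- call$rule
    out$evidence[i] <- paste(call$evidence, collapse = ",")
  }
  out
}

#' Call monogenic etiology per participant
#'
#' A participant has monogenic etiology when carrying at least one
#' alternate allele of at least one variant classified pathogenic or
#' likely pathogenic.
#'
#' @param carriage data.frame with columns `id`, `variant_id`,
#'   `allele_count` (1 or 2).
#' @param classifications output of [classify_variants()].
#' @param ids participant identifiers defining the output order (carriers
#'   absent from `carriage` are non-monogenic).
#' @return data.frame `id`, `monogenic` (logical), `carrier_gene` (first
#'   P/LP gene carried, `NA` otherwise).
#' @export
call_monogenic <- function(carriage, classifications, ids) {
  unknown <- setdiff(carriage$variant_id, classifications$variant_id)
  if (length(unknown)) {
    stop("genotype references unclassified variant(s): ", paste(unknown, collapse = ", "))
  }
  plp_ids <- classifications$variant_id[classifications$plp]
  hits <- carriage[carriage$variant_id %in% plp_ids & carriage$allele_count >= 1, , drop = FALSE]
  gene_of <- stats::setNames(classifications$gene, classifications$variant_id)
  first_gene <- tapply(gene_of[hits$variant_id], hits$id, function(g) g[1])
  data.frame(
    id = ids,
    monogenic = ids %in% hits$id,
    carrier_gene = as.character(first_gene[match(ids, names(first_gene))]),
    stringsAsFactors = FALSE
  )
}
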