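#' Write a cohort to disk
#'
#' Emits a VCF v4.2 with one record per panel SNV and per rare variant
#' (INFO keys `GENE`, `CSQCLASS`, `REFAF`, `CLNSIG`, `PREDVERDICT`,
#' `EVID`; per-sample `GT`), a tab-separated participant table, long
#' lipid and diagnosis tables and the truth labels, all plain text with
#' ISO-8601 dates. [read_cohort()] reproduces the cohort exactly.
#'
#' @param cohort an `fh_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!nrow(cohort$participants)) stop("refusing to write an empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_vcf(cohort, file.path(dir, "cohort.vcf"))
  wt <- function(df, name) {
    ok <- tryCatch(
      {
        utils::write.table(df, file.path(dir, name),
          sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
        )
        TRUE
      },
      error = function(e) stop("failed writing ", file.path(dir, name), ": ", conditionMessage(e))
    )
    invisible(ok)
  }
  wt(cohort$participants, "phenotypes.tsv")
  wt(cohort$lipids, "lipids.tsv")
  wt(cohort$diagnoses, "diagnoses.tsv")
  wt(cohort$truth, "truth.tsv")
  pr <- attr(cohort, "percentile_reference")
  if (!is.null(pr)) wt(pr, "percentile_reference.tsv")
  invisible(dir)
}

write_cohort_vcf <- function(cohort, path) {
  panel <- snv_panel_table(cohort$config)
  ids <- cohort$participants$id
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fhetiology",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=REFAF,Number=1,Type=Float,Description="Reference population allele frequency">',
    '##INFO=<ID=CLNSIG,Number=1,Type=String,Description="Clinical database assertion">',
    '##INFO=<ID=PREDVERDICT,Number=1,Type=String,Description="Computational prediction verdict">',
    '##INFO=<ID=EVID,Number=.,Type=String,Description="Supplied ACMG evidence tags">',
    '##INFO=<ID=PANEL,Number=0,Type=Flag,Description="Member of the polygenic score panel">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", ids),
      collapse = "\t"
    )
  )
  gt_string <- function(dosage) c("0/0", "0/1", "1/1")[dosage + 1L]
  lines <- character()
  for (j in seq_len(nrow(panel))) {
    s <- panel[j, ]
    # VCF REF/ALT: effect allele stored as ALT so dosage = alt-allele count
    dos <- cohort$genotypes[, s$id]
    lines <- c(lines, paste(
      c(s$chrom, s$pos, s$id, s$other_allele, s$effect_allele, ".", "PASS",
        sprintf("PANEL;REFAF=%g", s$eaf), "GT", gt_string(dos)),
      collapse = "\t"
    ))
  }
  v <- cohort$variants
  for (j in seq_len(nrow(v))) {
    dos <- rep(0L, length(ids))
    rows <- cohort$carriage$variant_id == v$variant_id[j]
    dos[match(cohort$carriage$id[rows], ids)] <- cohort$carriage$allele_count[rows]
    info <- paste0(
      "GENE=", v$gene[j], ";CSQCLASS=", v$consequence[j],
      if (!is.na(v$ref_af[j])) sprintf(";REFAF=%g", v$ref_af[j]) else "",
      if (!is.na(v$clnsig[j])) paste0(";CLNSIG=", v$clnsig[j]) else "",
      ";PREDVERDICT=", v$pred_verdict[j],
      if (nzchar(v$evidence[j])) paste0(";EVID=", v$evidence[j]) else ""
    )
    lines <- c(lines, paste(
      c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j], ".", "PASS",
        info, "GT", gt_string(dos)),
      collapse = "\t"
    ))
  }
  ok <- tryCatch(writeLines(c(header, lines), path),
    error = function(e) stop("failed writing ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}

#' Read genotypes and rare-variant annotations from a VCF
#'
#' Panel SNVs are matched by identifier (fallback: chrom+pos) and
#' converted to effect-allele dosages with explicit allele matching: the
#' panel's effect allele must equal either ALT (dosage = alt count) or
#' REF (dosage = 2 - alt count); anything else is an orientation error,
#' never a silent flip. Multi-allelic records are decomposed into
#' per-alternate records before matching. Missing genotypes (`./.`)
#' become `NA` dosages. Records that are not panel SNVs are parsed as
#' annotated rare variants from the INFO keys `GENE`, `CSQCLASS`,
#' `REFAF`, `CLNSIG`, `PREDVERDICT`, `EVID`.
#'
#' @param path VCF file (plain text or gzipped).
#' @param panel data.frame as from [snv_panel_table()].
#' @return list: `dosages` (matrix participants x panel SNVs), `variants`
#'   (annotated rare variants), `carriage` (`id`, `variant_id`,
#'   `allele_count`).
#' @export
read_genotypes <- function(path, panel) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  gt_idx <- function(fmt) which(strsplit(fmt, ":")[[1]] == "GT")

  # decompose multi-allelics: one logical record per ALT allele
  records <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt[i, -1]
    fmt_i <- gt_idx(gt[i, 1])
    simple <- c(
      "0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
      "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_
    )
    if (fmt_i == 1 && length(alts) == 1 && all(sub(":.*", "", gts) %in% names(simple))) {
      allele_lists <- NULL
      simple_counts <- unname(simple[sub(":.*", "", gts)])
    } else {
      allele_lists <- lapply(gts, function(g) {
        g <- strsplit(g, ":")[[1]][fmt_i]
        if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
        as.integer(strsplit(g, "[/|]")[[1]])
      })
    }
    for (k in seq_along(alts)) {
      counts <- if (is.null(allele_lists)) {
        simple_counts
      } else {
        vapply(allele_lists, function(a) {
          if (length(a) == 1 && is.na(a[1])) NA_integer_ else sum(a == k)
        }, integer(1))
      }
      records[[length(records) + 1]] <- list(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        id = if (length(alts) > 1) paste0(fix$ID[i], "_alt", k) else fix$ID[i],
        base_id = fix$ID[i],
        ref = fix$REF[i], alt = alts[k], info = fix$INFO[i], counts = counts
      )
    }
  }

  dosages <- matrix(NA_integer_, length(samples), nrow(panel),
    dimnames = list(samples, panel$id)
  )
  rare <- list()
  carriage <- list()
  for (rec in records) {
    j <- which(panel$id == rec$base_id)
    if (!length(j)) j <- which(panel$chrom == rec$chrom & panel$pos == rec$pos)
    if (length(j)) {
      j <- j[1]
      eff <- panel$effect_allele[j]
      if (eff == rec$alt) {
        dosages[, j] <- rec$counts
      } else if (eff == rec$ref) {
        dosages[, j] <- 2L - rec$counts
      } else {
        stop(
          "allele orientation error at panel SNV ", panel$id[j],
          ": effect allele ", eff, " matches neither REF (", rec$ref,
          ") nor ALT (", rec$alt, ")"
        )
      }
    } else {
      info <- parse_info(rec$info)
      rare[[length(rare) + 1]] <- data.frame(
        variant_id = rec$id, chrom = rec$chrom, pos = rec$pos,
        ref = rec$ref, alt = rec$alt,
        gene = info$GENE %||% NA_character_,
        consequence = info$CSQCLASS %||% "other",
        ref_af = as.numeric(info$REFAF %||% NA),
        clnsig = info$CLNSIG %||% NA_character_,
        pred_verdict = info$PREDVERDICT %||% "unknown",
        evidence = info$EVID %||% "",
        stringsAsFactors = FALSE
      )
      hit <- which(!is.na(rec$counts) & rec$counts > 0)
      if (length(hit)) {
        carriage[[length(carriage) + 1]] <- data.frame(
          id = samples[hit], variant_id = rec$id,
          allele_count = rec$counts[hit], stringsAsFactors = FALSE
        )
      }
    }
  }
  list(
    dosages = dosages,
    variants = if (length(rare)) do.call(rbind, rare) else NULL,
    carriage = if (length(carriage)) {
      do.call(rbind, carriage)
    } else {
      data.frame(id = character(), variant_id = character(), allele_count = integer())
    }
  )
}

parse_info <- function(info) {
  out <- list()
  for (field in strsplit(info, ";", fixed = TRUE)[[1]]) {
    kv <- strsplit(field, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- if (length(kv) > 1) kv[2] else TRUE
  }
  out
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @param config the configuration the cohort was generated under.
#' @return an `fh_cohort`.
#' @export
read_cohort <- function(dir, config = fh_default_config()) {
  rd <- function(name, dates = character()) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing cohort file: ", path)
    df <- utils::read.table(path,
      sep = "\t", header = TRUE, stringsAsFactors = FALSE,
      colClasses = NA, na.strings = "NA"
    )
    for (d in intersect(dates, names(df))) df[[d]] <- as.Date(as.character(df[[d]]))
    df
  }
  participants <- rd("phenotypes.tsv")
  participants$statin_dose <- as.numeric(participants$statin_dose)
  participants$statin_type <- as.character(participants$statin_type)
  participants$arcus_age <- as.numeric(participants$arcus_age)
  lipids <- rd("lipids.tsv", dates = "date")
  diagnoses <- rd("diagnoses.tsv", dates = "date")
  diagnoses$id <- as.character(diagnoses$id)
  diagnoses$code <- as.character(diagnoses$code)
  truth <- rd("truth.tsv")
  panel <- snv_panel_table(config)
  geno <- read_genotypes(file.path(dir, "cohort.vcf"), panel)
  dos <- geno$dosages[match(participants$id, rownames(geno$dosages)), , drop = FALSE]
  storage.mode(dos) <- "integer"
  variants <- geno$variants
  out <- structure(
    list(
      participants = participants, lipids = lipids, diagnoses = diagnoses,
      genotypes = dos, variants = variants,
      carriage = geno$carriage, truth = truth, config = config
    ),
    class = "fh_cohort"
  )
  pr_path <- file.path(dir, "percentile_reference.tsv")
  if (file.exists(pr_path)) attr(out, "percentile_reference") <- rd("percentile_reference.tsv")
  out
}
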