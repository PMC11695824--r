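# Readers/writers for allele-count tables, sample sheets and call sets.
# TSV dialect throughout: tab-separated, UTF-8, mandatory header row.

FILTER_LEVELS <- c("PASS", "LOW_COVERAGE", "BELOW_BASELINE", "BELOW_LOD",
                   "CHIP")

#' Validate an allele-count table
#'
#' A long-format table of per-sample, per-site sequencing evidence: total
#' read depth and alternate-allele read count at each panel site, from
#' which the variant allele fraction (VAF) is derived.
#'
#' @param counts data.frame with columns `sample_id`, `site_id`, `depth`,
#'   `alt_count`.
#' @param panel optional [hotspot_panel()] for referential-integrity
#'   checking (unknown `site_id`s are rejected).
#' @return the validated data.frame (class `allele_counts`).
#' @export
allele_counts <- function(counts, panel = NULL) {
  check_columns(counts, c("sample_id", "site_id", "depth", "alt_count"),
                "count table")
  counts$sample_id <- as.character(counts$sample_id)
  counts$site_id <- as.character(counts$site_id)
  counts$depth <- as.integer(counts$depth)
  counts$alt_count <- as.integer(counts$alt_count)
  if (nrow(counts)) {
    if (anyNA(counts$depth) || anyNA(counts$alt_count) ||
        any(counts$depth < 0L) || any(counts$alt_count < 0L))
      stopf("count table has missing or negative depth/alt_count")
    bad <- counts$alt_count > counts$depth
    if (any(bad))
      stopf("alt_count exceeds depth for sample %s at site %s",
            counts$sample_id[bad][1], counts$site_id[bad][1])
    key <- paste(counts$sample_id, counts$site_id)
    if (anyDuplicated(key))
      stopf("duplicate (sample_id, site_id) row: %s",
            key[duplicated(key)][1])
    if (!is.null(panel)) {
      unknown <- setdiff(counts$site_id, panel$site_id)
      if (length(unknown))
        stopf("count table references %d site_id(s) not in the panel (e.g. %s)",
              length(unknown), unknown[1])
    }
  }
  rownames(counts) <- NULL
  class(counts) <- c("allele_counts", "data.frame")
  counts
}

#' Read an allele-count table
#'
#' @inheritParams allele_counts
#' @param path TSV path (columns `sample_id`, `site_id`, `depth`,
#'   `alt_count`). An empty file with a header yields an empty table.
#' @return an `allele_counts` data.frame.
#' @export
read_counts <- function(path, panel = NULL) {
  if (!file.exists(path)) stopf("count file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  allele_counts(df, panel)
}

#' @rdname read_counts
#' @param counts an `allele_counts` table.
#' @export
write_counts <- function(counts, path) {
  counts <- counts[order_by_id(paste(counts$sample_id, counts$site_id)), ]
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

SAMPLE_GROUPS <- c("cancer", "control", "calibration_negative", "titration")
CANCER_TYPES <- c("breast", "colorectal", "gastric", "liver", "lung", "none")
STAGES <- c("I", "II", "IIIA", "unknown", "not_applicable")

#' Validate / read a sample sheet
#'
#' One row per sample: study group, cancer type, stage, age, sex, the
#' multimodal SPOT-MAS cancer-probability score (missing allowed; such
#' samples are excluded from fusion but not from hotspot-only
#' evaluation), and whether matched white-blood-cell counts exist.
#'
#' @param samples data.frame with columns `sample_id`, `group`,
#'   `cancer_type`, `stage`, `age`, `sex`, `spotmas_score`, `has_wbc`.
#' @return validated data.frame (class `sample_sheet`).
#' @export
sample_sheet <- function(samples) {
  check_columns(samples, c("sample_id", "group", "cancer_type", "stage",
                           "age", "sex", "spotmas_score", "has_wbc"),
                "sample sheet")
  samples$sample_id <- as.character(samples$sample_id)
  for (col in c("group", "cancer_type", "stage", "sex"))
    samples[[col]] <- as.character(samples[[col]])
  samples$age <- as.numeric(samples$age)
  samples$spotmas_score <- as.numeric(samples$spotmas_score)
  samples$has_wbc <- as.logical(samples$has_wbc)
  if (nrow(samples)) {
    if (anyDuplicated(samples$sample_id))
      stopf("duplicate sample_id in sample sheet")
    bad <- !samples$group %in% SAMPLE_GROUPS
    if (any(bad)) stopf("unknown group '%s'", samples$group[bad][1])
    bad <- !samples$cancer_type %in% CANCER_TYPES
    if (any(bad)) stopf("unknown cancer_type '%s'", samples$cancer_type[bad][1])
    bad <- !samples$stage %in% STAGES
    if (any(bad)) stopf("unknown stage '%s'", samples$stage[bad][1])
    if (any(samples$group == "cancer" & samples$cancer_type == "none"))
      stopf("cancer samples must have a cancer_type")
    if (any(samples$group == "control" & samples$stage != "not_applicable"))
      stopf("controls must have stage 'not_applicable'")
    sc <- samples$spotmas_score
    if (any(!is.na(sc) & (sc < 0 | sc > 1)))
      stopf("spotmas_score must lie in [0,1] when present")
  }
  rownames(samples) <- NULL
  class(samples) <- c("sample_sheet", "data.frame")
  samples
}

#' @rdname sample_sheet
#' @param path TSV path.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  sample_sheet(df)
}

#' @rdname sample_sheet
#' @export
write_samples <- function(samples, path) {
  samples <- samples[order_by_id(samples$sample_id), ]
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write call sets as per-sample VCFs plus a cohort summary TSV
#'
#' Each sample gets a VCF 4.2 file (`<sample_id>.vcf`) holding its
#' candidate mutations with VAF, depth, alt count and filter provenance
#' (`PASS`, `LOW_COVERAGE`, `BELOW_BASELINE`, `BELOW_LOD`, `CHIP`); a
#' sample with no candidates gets a header-only VCF. The cohort TSV
#' (`calls_summary.tsv`) has one row per sample: `sample_id`,
#' `hotspot_positive`, `mean_vaf`, `n_mutations`.
#'
#' @param calls a `cohort_calls` object from [call_cohort()].
#' @param dir output directory (created if needed).
#' @param panel the [hotspot_panel()] the calls refer to.
#' @return invisibly, the paths written.
#' @export
write_calls <- function(calls, dir, panel) {
  stopifnot(inherits(calls, "cohort_calls"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##FILTER=<ID=LOW_COVERAGE,Description=\"Amplicon depth below ",
           "minimum\">"),
    paste0("##FILTER=<ID=BELOW_LOD,Description=\"VAF below assay limit of ",
           "detection\">"),
    paste0("##FILTER=<ID=BELOW_BASELINE,Description=\"VAF below per-site ",
           "baseline cutoff\">"),
    paste0("##FILTER=<ID=CHIP,Description=\"Matched WBC evidence indicates ",
           "clonal hematopoiesis\">"),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt-allele read count\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  idx <- match(calls$calls$site_id, panel$site_id)
  paths <- character(0)
  for (sid in calls$summary$sample_id) {
    rows <- which(calls$calls$sample_id == sid)
    body <- character(0)
    if (length(rows)) {
      cc <- calls$calls[rows, ]
      pi <- idx[rows]
      ord <- order(pi)
      cc <- cc[ord, ]; pi <- pi[ord]
      body <- sprintf(
        "%s\t%d\t%s\t%s\t%s\t.\t%s\tVAF=%.6g;DP=%d;AD=%d;GENE=%s",
        panel$chrom[pi], panel$pos[pi], cc$site_id, panel$ref[pi],
        panel$alt[pi], cc$filter, cc$vaf, cc$depth, cc$alt_count,
        panel$gene[pi])
    }
    p <- file.path(dir, paste0(sid, ".vcf"))
    writeLines(c(hdr, body), p)
    paths <- c(paths, p)
  }
  summ <- calls$summary[order_by_id(calls$summary$sample_id), ]
  names(summ)[names(summ) == "n_pass"] <- "n_mutations"
  tsv <- file.path(dir, "calls_summary.tsv")
  utils::write.table(summ, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, tsv))
}
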