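#' Variant allele fraction
#'
#' `alt_count / depth`, the fraction of reads carrying the alternate
#' allele. Undefined (NA) at zero depth — such observations travel the
#' LOW_COVERAGE path rather than propagating NaN.
#'
#' @param depth,alt_count non-negative read counts (vectorized).
#' @return numeric vector of VAF fractions.
#' @export
compute_vaf <- function(depth, alt_count) {
  if (any(alt_count > depth, na.rm = TRUE))
    stopf("alt_count exceeds depth")
  if (any(depth < 0 | alt_count < 0, na.rm = TRUE))
    stopf("depth and alt_count must be non-negative")
  ifelse(depth > 0, alt_count / depth, NA_real_)
}

#' CHIP filtering against matched white-blood-cell counts
#'
#' Clonal hematopoiesis (CHIP) plants somatic mutations in blood cells
#' that contaminate plasma cfDNA; its signature is matched presence in
#' white-blood-cell genomic DNA. Any candidate PASS call whose WBC VAF
#' reaches the same effective site threshold used for cfDNA is
#' re-flagged `CHIP` and removed from the PASS set; all other calls are
#' unchanged.
#'
#' @param calls data.frame of candidate calls for one sample
#'   (`sample_id`, `site_id`, `vaf`, `depth`, `alt_count`, `filter`).
#' @param wbc_counts [allele_counts()] with the matched WBC evidence.
#' @param model a `hotspot_calibration`.
#' @return `calls` with CHIP re-flagging applied.
#' @export
chip_filter <- function(calls, wbc_counts, model) {
  pass <- which(calls$filter == "PASS")
  if (!length(pass)) return(calls)
  key <- paste(calls$sample_id[pass], calls$site_id[pass])
  wkey <- paste(wbc_counts$sample_id, wbc_counts$site_id)
  idx <- match(key, wkey)
  found <- !is.na(idx)
  wdepth <- wbc_counts$depth[idx[found]]
  wvaf <- ifelse(wdepth > 0,
                 wbc_counts$alt_count[idx[found]] / wdepth, 0)
  thr <- effective_threshold(model, calls$site_id[pass][found])
  is_chip <- wvaf >= thr
  calls$filter[pass[found][is_chip]] <- "CHIP"
  calls
}

# Vectorized core shared by call_cohort()/call_sample(): one pass of
# thresholding over the whole count table.
classify_candidates <- function(counts, model) {
  vaf <- compute_vaf(counts$depth, counts$alt_count)
  thr <- effective_threshold(model, counts$site_id)
  depth_ok <- counts$depth >= model$min_amplicon_depth
  filter <- rep("PASS", nrow(counts))
  filter[vaf < model$lod | is.na(vaf)] <- "BELOW_LOD"
  filter[!is.na(vaf) & vaf >= model$lod & vaf < thr] <- "BELOW_BASELINE"
  filter[!depth_ok] <- "LOW_COVERAGE"
  data.frame(sample_id = counts$sample_id, site_id = counts$site_id,
             vaf = vaf, depth = counts$depth,
             alt_count = counts$alt_count, filter = filter,
             stringsAsFactors = FALSE)
}

#' Call hotspot mutations across a cohort
#'
#' Applies the calibrated thresholds to every sample: an observation is
#' a PASS mutation iff its amplicon depth reaches the QC minimum and
#' its VAF reaches the effective site threshold `max(lod,
#' per_site_cutoff)` (inclusive). For candidate-positive samples with
#' matched WBC counts the CHIP filter is applied. A sample is ctDNA
#' positive iff it retains at least one PASS mutation; its mean VAF is
#' the arithmetic mean of the PASS-call VAFs.
#'
#' Candidate calls (any observation with at least one alternate read,
#' plus low-coverage observations) are retained with filter provenance:
#' `PASS`, `LOW_COVERAGE`, `BELOW_LOD`, `BELOW_BASELINE` or `CHIP`.
#'
#' @param counts [allele_counts()] for the cohort.
#' @param model a `hotspot_calibration`.
#' @param wbc optional [allele_counts()] of matched WBC evidence.
#' @param wbc_policy what to do when a candidate-positive sample lacks
#'   WBC data: `"flag"` (default) keeps its calls and records
#'   `wbc_checked = FALSE`; `"drop_sample"` sets its positivity to NA so
#'   evaluation excludes it.
#' @return a `cohort_calls`: list with `calls` (all candidate calls) and
#'   `summary` (per sample: `hotspot_positive`, `mean_vaf`, `n_pass`,
#'   `wbc_checked`).
#' @export
call_cohort <- function(counts, model, wbc = NULL,
                        wbc_policy = c("flag", "drop_sample")) {
  wbc_policy <- match.arg(wbc_policy)
  stopifnot(inherits(model, "hotspot_calibration"))
  calls <- classify_candidates(counts, model)
  # keep candidates: any alternate evidence, or a failed amplicon
  calls <- calls[calls$alt_count > 0L | calls$filter == "LOW_COVERAGE", ,
                 drop = FALSE]
  sample_ids <- unique(counts$sample_id)

  candidate_pos <- unique(calls$sample_id[calls$filter == "PASS"])
  wbc_checked <- stats::setNames(rep(NA, length(sample_ids)), sample_ids)
  if (length(candidate_pos)) {
    has_wbc_data <- if (is.null(wbc)) rep(FALSE, length(candidate_pos)) else
      candidate_pos %in% wbc$sample_id
    wbc_checked[candidate_pos] <- has_wbc_data
    if (any(has_wbc_data)) {
      with_data <- calls$sample_id %in% candidate_pos[has_wbc_data]
      calls[with_data, ] <- chip_filter(calls[with_data, , drop = FALSE],
                                        wbc, model)
    }
    if (any(!has_wbc_data))
      warnf("%d candidate-positive sample(s) lack matched WBC data (policy: %s)",
            sum(!has_wbc_data), wbc_policy)
  }

  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  n_pass <- stats::setNames(integer(length(sample_ids)), sample_ids)
  tab <- table(pass$sample_id)
  n_pass[names(tab)] <- as.integer(tab)
  mean_vaf <- stats::setNames(rep(NA_real_, length(sample_ids)), sample_ids)
  if (nrow(pass)) {
    mv <- tapply(pass$vaf, pass$sample_id, mean)
    mean_vaf[names(mv)] <- as.numeric(mv)
  }
  summary <- data.frame(sample_id = sample_ids,
                        hotspot_positive = unname(n_pass) >= 1L,
                        mean_vaf = unname(mean_vaf),
                        n_pass = unname(n_pass),
                        wbc_checked = unname(wbc_checked),
                        stringsAsFactors = FALSE)
  if (wbc_policy == "drop_sample") {
    dropped <- !is.na(summary$wbc_checked) & !summary$wbc_checked
    summary$hotspot_positive[dropped] <- NA
  }
  rownames(summary) <- NULL
  structure(list(calls = calls, summary = summary, model = model),
            class = "cohort_calls")
}

#' Call hotspot mutations for a single sample
#'
#' @inheritParams call_cohort
#' @param sample_id which sample to call; may be omitted when `counts`
#'   holds exactly one sample. A `sample_id` absent from the table is a
#'   lookup error.
#' @return a `sample_callset`: list with `calls`, `hotspot_positive`,
#'   `mean_vaf`, `n_pass`.
#' @export
call_sample <- function(counts, model, sample_id = NULL, wbc = NULL,
                        wbc_policy = c("flag", "drop_sample")) {
  if (!is.null(sample_id)) {
    if (!sample_id %in% counts$sample_id)
      stopf("sample '%s' not found in the count table", sample_id)
    counts <- counts[counts$sample_id == sample_id, , drop = FALSE]
  } else if (length(unique(counts$sample_id)) != 1L) {
    stopf("counts hold %d samples; pass sample_id",
          length(unique(counts$sample_id)))
  }
  cc <- call_cohort(counts, model, wbc = wbc, wbc_policy = wbc_policy)
  structure(list(sample_id = cc$summary$sample_id[1],
                 calls = cc$calls,
                 hotspot_positive = cc$summary$hotspot_positive[1],
                 mean_vaf = cc$summary$mean_vaf[1],
                 n_pass = cc$summary$n_pass[1]),
            class = "sample_callset")
}

#' @export
print.sample_callset <- function(x, ...) {
  cat(sprintf("Sample %s: %s (%d PASS mutation%s%s)\n", x$sample_id,
              if (isTRUE(x$hotspot_positive)) "ctDNA POSITIVE"
              else if (is.na(x$hotspot_positive)) "UNEVALUABLE"
              else "ctDNA negative",
              x$n_pass, if (x$n_pass == 1) "" else "s",
              if (x$n_pass >= 1)
                sprintf(", mean VAF %.3g", x$mean_vaf) else ""))
  if (nrow(x$calls)) print(x$calls, row.names = FALSE)
  invisible(x)
}

#' @export
print.cohort_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cohort hotspot calls: %d samples, %d ctDNA positive\n",
              nrow(s), sum(s$hotspot_positive, na.rm = TRUE)))
  tab <- table(factor(x$calls$filter, levels = FILTER_LEVELS))
  cat("  candidate filters:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname call_cohort
#' @param object a `hotspot_calibration` model.
#' @param ... passed on to [call_cohort()].
#' @export
predict.hotspot_calibration <- function(object, counts, wbc = NULL, ...) {
  call_cohort(counts, object, wbc = wbc, ...)
}
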