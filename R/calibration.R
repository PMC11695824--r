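#' Amplicon coverage QC
#'
#' Flags (sample, site) observations whose depth falls below the minimum
#' amplicon coverage — strictly below, i.e. a depth exactly at
#' `min_depth` is retained. Flagged rows are excluded from calling but
#' reported, never silently dropped.
#'
#' @param counts an [allele_counts()] table.
#' @param min_depth minimum amplicon depth in reads (default 10,000).
#' @return list with `counts` (retained rows), `failed` (flagged rows),
#'   `per_sample` (failure fraction and an `excluded` verdict for
#'   samples with no passing amplicon), class `amplicon_qc`.
#' @export
qc_amplicons <- function(counts, min_depth = 10000) {
  if (min_depth < 0) stopf("min_depth must be >= 0")
  fail <- counts$depth < min_depth
  per_sample <- stats::aggregate(fail, list(sample_id = counts$sample_id),
                                 mean)
  names(per_sample)[2] <- "failure_fraction"
  per_sample$excluded <- per_sample$failure_fraction >= 1
  per_sample <- per_sample[order_by_id(per_sample$sample_id), ]
  rownames(per_sample) <- NULL
  structure(list(counts = counts[!fail, , drop = FALSE],
                 failed = counts[fail, c("sample_id", "site_id", "depth")],
                 per_sample = per_sample, min_depth = min_depth),
            class = "amplicon_qc")
}

#' Estimate the assay limit of detection from a titration series
#'
#' The LOD is the smallest titration level at which (a) the detection
#' fraction across sites and replicates reaches `criterion` and (b) the
#' median observed VAF lies within `tolerance`-fold of the expected VAF.
#' A measurement counts as detected when it shows at least `min_alt`
#' alternate reads at passing depth. When a 0% blank is present, a
#' detection fraction at or above `criterion` in the blank aborts
#' estimation: the noise floor exceeds the assay's resolution.
#'
#' @param titration an [allele_counts()] table of titration samples.
#' @param expected named vector mapping each titration `sample_id` to
#'   its expected VAF fraction.
#' @param criterion required detection fraction (default 0.95).
#' @param tolerance allowed fold-deviation of median observed from
#'   expected VAF (default 2).
#' @param min_alt alternate reads needed to score a detection.
#' @param min_depth amplicon QC threshold applied first.
#' @return list with `lod` and `table` (per level: expected VAF, mean
#'   and median observed VAF, detection fraction, levels sorted
#'   descending), class `lod_estimate`.
#' @export
estimate_lod <- function(titration, expected, criterion = 0.95,
                         tolerance = 2, min_alt = 1L, min_depth = 10000) {
  if (is.null(names(expected)))
    stopf("'expected' must be a named vector: sample_id -> expected VAF")
  missing <- setdiff(unique(titration$sample_id), names(expected))
  if (length(missing))
    stopf("no expected VAF for titration sample(s): %s",
          paste(missing, collapse = ", "))
  expected <- expected[names(expected) %in% titration$sample_id]
  levels <- sort(unique(unname(expected)), decreasing = TRUE)
  if (!any(levels > 0)) stopf("titration needs at least one non-zero level")
  if (!any(levels == 0))
    warnf("no 0%% blank in the titration; noise floor not checked")
  qc <- qc_amplicons(titration, min_depth)
  counts <- qc$counts
  lev <- unname(expected[counts$sample_id])
  vaf <- ifelse(counts$depth > 0, counts$alt_count / counts$depth, NA_real_)
  detected <- counts$alt_count >= min_alt
  tab <- data.frame(level = levels)
  tab$mean_vaf <- vapply(levels, function(L) mean(vaf[lev == L]), 0)
  tab$median_vaf <- vapply(levels, function(L)
    stats::median(vaf[lev == L]), 0)
  tab$detection_fraction <- vapply(levels, function(L)
    mean(detected[lev == L]), 0)
  if (any(levels == 0) &&
      tab$detection_fraction[tab$level == 0] >= criterion)
    stopf(paste("0%% blank reaches the detection criterion: the noise floor",
                "exceeds the assay's resolution; increase depth or use",
                "cleaner input"))
  nz <- tab[tab$level > 0, ]
  ok <- nz$detection_fraction >= criterion &
    nz$median_vaf >= nz$level / tolerance &
    nz$median_vaf <= nz$level * tolerance
  if (!any(ok))
    stopf(paste("no titration level meets the detection criterion;",
                "higher-depth input required to establish an LOD"))
  structure(list(lod = min(nz$level[ok]), table = tab,
                 criterion = criterion, tolerance = tolerance,
                 min_alt = min_alt), class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat(sprintf("Limit of detection: %g (VAF fraction)\n", x$lod))
  cat(sprintf("  criterion: detection fraction >= %g, median VAF within %g-fold\n",
              x$criterion, x$tolerance))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fit per-site baseline VAF cutoffs from negative-control plasmas
#'
#' Learns, for every panel site, the background-noise cutoff above which
#' a VAF is considered signal. The default rule is mean + k*SD (k = 3)
#' of the negative-cohort VAFs at that site; the alternative is an
#' empirical quantile (q = 0.999). Sites with no alternate reads in any
#' negative get cutoff 0, so their effective threshold is the LOD; sites
#' with fewer than two QC-passing negatives fall back to the LOD with a
#' warning. The effective detection threshold at a site is always
#' `max(lod, per_site_cutoff)`.
#'
#' @param negatives [allele_counts()] for the negative-control plasmas.
#' @param panel the [hotspot_panel()].
#' @param method `"mean_sd"` or `"quantile"`.
#' @param k SD multiplier for `"mean_sd"`.
#' @param q quantile for `"quantile"`.
#' @param lod assay limit of detection (VAF fraction); default 5e-4, the
#'   lowest non-zero level of the standard titration design. Pass the
#'   value from [estimate_lod()] when titration data exist.
#' @param min_depth amplicon QC threshold.
#' @return a `hotspot_calibration` model.
#' @export
fit_baseline <- function(negatives, panel, method = c("mean_sd", "quantile"),
                         k = 3, q = 0.999, lod = 5e-4, min_depth = 10000) {
  method <- match.arg(method)
  if (lod < 0) stopf("lod must be >= 0")
  if (method == "mean_sd" && k < 0) stopf("k must be >= 0")
  if (method == "quantile" && (q <= 0 || q > 1)) stopf("q must be in (0,1]")
  qc <- qc_amplicons(negatives, min_depth)
  counts <- qc$counts
  counts <- counts[counts$depth > 0, , drop = FALSE]
  vaf <- counts$alt_count / counts$depth
  site <- factor(counts$site_id, levels = panel$site_id)
  n_per_site <- as.integer(table(site))
  cutoff <- rep(NA_real_, nrow(panel))
  if (nrow(counts)) {
    if (method == "mean_sd") {
      m <- tapply(vaf, site, mean)
      s <- tapply(vaf, site, stats::sd)
      cutoff <- as.numeric(m + k * ifelse(is.na(s), 0, s))
    } else {
      cutoff <- as.numeric(tapply(vaf, site, stats::quantile, probs = q,
                                  names = FALSE, type = 7))
    }
  }
  low_n <- n_per_site < 2L
  if (any(low_n)) {
    warnf("%d site(s) had < 2 QC-passing negatives; cutoff falls back to the LOD",
          sum(low_n))
    cutoff[low_n] <- NA_real_
  }
  # a site never observed above zero background keeps cutoff 0: the
  # effective threshold there is the LOD
  cutoff[!low_n & is.na(cutoff)] <- 0
  names(cutoff) <- panel$site_id
  structure(list(lod = lod, per_site_cutoff = cutoff,
                 min_amplicon_depth = min_depth,
                 calibration_n = length(unique(negatives$sample_id)),
                 n_per_site = stats::setNames(n_per_site, panel$site_id),
                 method = method,
                 k = if (method == "mean_sd") k else NULL,
                 q = if (method == "quantile") q else NULL),
            class = "hotspot_calibration")
}

#' Calibrate the hotspot-detection model
#'
#' The front door of the calibration stage: applies amplicon coverage
#' QC, estimates the limit of detection from a titration series when
#' one is supplied (otherwise uses `lod`, defaulting to 5e-4), and fits
#' per-site baseline VAF cutoffs from the negative-control cohort. The
#' returned model drives [call_cohort()] / `predict()`.
#'
#' @inheritParams fit_baseline
#' @param titration optional [allele_counts()] titration table.
#' @param expected named expected-VAF vector for `titration`.
#' @param criterion,tolerance LOD decision rule, see [estimate_lod()].
#' @return a `hotspot_calibration` model with `lod`, `per_site_cutoff`,
#'   `min_amplicon_depth`, method metadata and (when titrated) the
#'   `lod_estimate`.
#' @export
hotspot_calibration <- function(negatives, panel, titration = NULL,
                                expected = NULL,
                                method = c("mean_sd", "quantile"),
                                k = 3, q = 0.999, lod = 5e-4,
                                min_depth = 10000, criterion = 0.95,
                                tolerance = 2) {
  method <- match.arg(method)
  lod_est <- NULL
  if (!is.null(titration)) {
    if (is.null(expected))
      stopf("titration counts require an 'expected' VAF map")
    lod_est <- estimate_lod(titration, expected, criterion = criterion,
                            tolerance = tolerance, min_depth = min_depth)
    lod <- lod_est$lod
  }
  model <- fit_baseline(negatives, panel, method = method, k = k, q = q,
                        lod = lod, min_depth = min_depth)
  model$lod_estimate <- lod_est
  model
}

# Effective per-site detection threshold: max(lod, baseline cutoff);
# sites without a usable baseline use the LOD alone.
effective_threshold <- function(model, site_ids = NULL) {
  cut <- model$per_site_cutoff
  thr <- pmax(model$lod, ifelse(is.na(cut), 0, cut))
  names(thr) <- names(cut)
  if (is.null(site_ids)) thr else unname(thr[site_ids])
}

#' @export
print.hotspot_calibration <- function(x, ...) {
  cat("Hotspot detection calibration\n")
  cat(sprintf("  LOD: %g (VAF fraction)%s\n", x$lod,
              if (is.null(x$lod_estimate)) " [default]" else " [titrated]"))
  cat(sprintf("  baseline: %s%s on %d negative samples\n", x$method,
              if (x$method == "mean_sd") sprintf(" (k=%g)", x$k)
              else sprintf(" (q=%g)", x$q), x$calibration_n))
  cat(sprintf("  min amplicon depth: %d reads\n",
              as.integer(x$min_amplicon_depth)))
  cut <- x$per_site_cutoff
  cat(sprintf("  per-site cutoffs: %d sites, %d above the LOD\n",
              length(cut), sum(!is.na(cut) & cut > x$lod)))
  invisible(x)
}

#' @export
summary.hotspot_calibration <- function(object, ...) {
  print(object)
  thr <- effective_threshold(object)
  cat("  effective threshold quantiles (VAF):\n")
  print(signif(stats::quantile(thr, c(0, .5, .9, .99, 1)), 3))
  invisible(object)
}

#' @export
coef.hotspot_calibration <- function(object, ...) object$per_site_cutoff

#' Serialize / restore a calibration model (JSON)
#'
#' @param model a `hotspot_calibration`.
#' @param path JSON file path.
#' @export
write_calibration <- function(model, path) {
  obj <- list(lod = model$lod,
              min_amplicon_depth = model$min_amplicon_depth,
              calibration_n = model$calibration_n,
              method = model$method, k = model$k, q = model$q,
              per_site_cutoff = as.list(model$per_site_cutoff))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path)
  cut <- vapply(obj$per_site_cutoff,
                function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  structure(list(lod = obj$lod, per_site_cutoff = cut,
                 min_amplicon_depth = obj$min_amplicon_depth,
                 calibration_n = obj$calibration_n, method = obj$method,
                 k = obj$k, q = obj$q),
            class = "hotspot_calibration")
}
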