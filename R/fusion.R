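#' Wilson score interval for a binomial proportion
#'
#' Score-test inversion for a binomial proportion; better small-sample
#' and boundary behavior than the Wald interval. Center
#' \eqn{(\hat p + z^2/2n)/(1 + z^2/n)}, half-width
#' \eqn{z \sqrt{\hat p(1-\hat p)/n + z^2/4n^2}/(1 + z^2/n)}, clamped to
#' \[0, 1\]. Vectorized over `successes` and `n`.
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param confidence confidence level (default 0.95, z = qnorm(0.975) =
#'   1.959964).
#' @return data.frame with columns `lower`, `upper` (fractions).
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (any(n < 1)) stopf("wilson_interval is undefined for n = 0")
  if (any(successes < 0 | successes > n))
    stopf("need 0 <= successes <= n")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

QUADRANTS <- c("both", "hotspot_only", "spotmas_only", "neither",
               "unevaluable")

#' Combine hotspot calls with the SPOT-MAS score under the OR rule
#'
#' A sample is score-positive when its SPOT-MAS score strictly exceeds
#' `score_cutoff` (0.60), hotspot-positive per its call set (or, in
#' concordance mode with `maf_cutoff` set, when its mean VAF reaches
#' `maf_cutoff`), and combined-positive when either arm fires. Each
#' sample lands in a concordance quadrant; samples without a score are
#' `unevaluable` and excluded from fusion metrics.
#'
#' @param calls a `cohort_calls` from [call_cohort()], or its `summary`
#'   data.frame (`sample_id`, `hotspot_positive`, `mean_vaf`).
#' @param samples a [sample_sheet()] carrying `spotmas_score`.
#' @param score_cutoff SPOT-MAS positivity cutoff (strict `>`).
#' @param maf_cutoff optional mean-VAF cutoff replacing the calibrated
#'   hotspot flag (concordance mode; inclusive `>=`).
#' @return a `combined_calls` data.frame: per sample, both arm flags,
#'   `combined_positive` and `quadrant`.
#' @export
classify_combined <- function(calls, samples, score_cutoff = 0.60,
                              maf_cutoff = NULL) {
  if (inherits(calls, "cohort_calls")) calls <- calls$summary
  check_columns(calls, c("sample_id", "hotspot_positive", "mean_vaf"),
                "call summary")
  if (!is_prob(score_cutoff) || length(score_cutoff) != 1L)
    stopf("score_cutoff must be a single value in [0,1]")
  idx <- match(calls$sample_id, samples$sample_id)
  if (anyNA(idx))
    stopf("sample(s) missing from the sample sheet: %s",
          calls$sample_id[is.na(idx)][1])
  score <- samples$spotmas_score[idx]
  hot <- if (is.null(maf_cutoff)) calls$hotspot_positive else
    !is.na(calls$mean_vaf) & calls$mean_vaf >= maf_cutoff
  spot <- score > score_cutoff          # NA when score missing
  combined <- hot | spot                # three-valued OR
  quadrant <- ifelse(is.na(score) | is.na(hot), "unevaluable",
              ifelse(hot & spot, "both",
              ifelse(hot, "hotspot_only",
              ifelse(spot, "spotmas_only", "neither"))))
  n_miss <- sum(quadrant == "unevaluable")
  if (n_miss)
    message(sprintf("%d sample(s) unevaluable for fusion (missing score)",
                    n_miss))
  out <- data.frame(sample_id = calls$sample_id,
                    hotspot_positive = hot, mean_vaf = calls$mean_vaf,
                    spotmas_score = score, spotmas_positive = spot,
                    combined_positive = combined,
                    quadrant = factor(quadrant, levels = QUADRANTS),
                    stringsAsFactors = FALSE)
  class(out) <- c("combined_calls", "data.frame")
  out
}

arm_flag <- function(combined, arm) {
  switch(arm, hotspot = combined$hotspot_positive,
         spotmas = combined$spotmas_positive,
         combined = combined$combined_positive)
}

proportion_row <- function(positives, n, confidence) {
  if (n == 0)
    return(data.frame(n = 0L, positive = 0L, estimate = NA_real_,
                      lower = NA_real_, upper = NA_real_))
  ci <- wilson_interval(positives, n, confidence)
  data.frame(n = as.integer(n), positive = as.integer(positives),
             estimate = positives / n, lower = ci$lower, upper = ci$upper)
}

#' Sensitivity and specificity with Wilson intervals
#'
#' Per-stratum detection rates for one arm of the test (hotspot,
#' SPOT-MAS, or the OR-rule combination): overall sensitivity, per
#' cancer type, per stage (I, II, IIIA, unknown — the unknown-stage
#' patients form their own stratum and stay in the overall figure), and
#' specificity on the controls (never stage-stratified). Every
#' proportion carries a Wilson confidence interval. Samples whose arm
#' flag is NA (missing score for the SPOT-MAS/combined arms) are
#' excluded and counted.
#'
#' @param combined a `combined_calls` from [classify_combined()].
#' @param samples the [sample_sheet()].
#' @param arm `"hotspot"`, `"spotmas"` or `"combined"`.
#' @param confidence confidence level for the Wilson intervals.
#' @return a `performance_report`: list with `sensitivity` (data.frame
#'   over strata), `specificity` (one row), `arm`, `confidence`,
#'   `n_unevaluable`.
#' @export
evaluate_performance <- function(combined, samples,
                                 arm = c("combined", "hotspot", "spotmas"),
                                 confidence = 0.95) {
  arm <- match.arg(arm)
  idx <- match(combined$sample_id, samples$sample_id)
  if (anyNA(idx)) stopf("combined calls and sample sheet disagree")
  grp <- samples$group[idx]
  type <- samples$cancer_type[idx]
  stage <- samples$stage[idx]
  flag <- arm_flag(combined, arm)
  evaluable <- !is.na(flag)
  n_unev <- sum(!evaluable & grp %in% c("cancer", "control"))

  strata <- list(c("overall", "overall"))
  for (ct in intersect(setdiff(CANCER_TYPES, "none"), unique(type)))
    strata <- c(strata, list(c("cancer_type", ct)))
  for (st in c("I", "II", "IIIA", "unknown"))
    strata <- c(strata, list(c("stage", st)))
  sens <- do.call(rbind, lapply(strata, function(s) {
    in_s <- grp == "cancer" & evaluable &
      switch(s[1], overall = TRUE, cancer_type = type == s[2],
             stage = stage == s[2])
    cbind(data.frame(stratum_type = s[1], stratum = s[2],
                     stringsAsFactors = FALSE),
          proportion_row(sum(flag[in_s]), sum(in_s), confidence))
  }))
  ctl <- grp == "control" & evaluable
  spec <- cbind(data.frame(stratum_type = "controls", stratum = "overall",
                           stringsAsFactors = FALSE),
                proportion_row(sum(!flag[ctl]), sum(ctl), confidence))
  structure(list(arm = arm, sensitivity = sens, specificity = spec,
                 confidence = confidence, n_unevaluable = n_unev),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, digits = 1, ...) {
  pct <- function(v) ifelse(is.na(v), "-", sprintf("%.*f", digits, 100 * v))
  cat(sprintf("Performance (%s arm, %g%% Wilson CIs)\n", x$arm,
              100 * x$confidence))
  show <- function(df, label) {
    cat(label, "\n")
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-12s %-10s %3d/%3d  %s%% [%s-%s]\n",
                  df$stratum_type[i], df$stratum[i], df$positive[i],
                  df$n[i], pct(df$estimate[i]), pct(df$lower[i]),
                  pct(df$upper[i])))
  }
  show(x$sensitivity, "sensitivity")
  show(x$specificity, "specificity")
  if (x$n_unevaluable)
    cat(sprintf("  (%d sample(s) unevaluable for this arm)\n",
                x$n_unevaluable))
  invisible(x)
}

#' Concordance quadrants per cancer type
#'
#' Fractions of each cancer type detected by both arms, by hotspot
#' mutations only, by the SPOT-MAS score only, or by neither —
#' fractions over evaluable samples sum to 1 per type. Run
#' [classify_combined()] with `maf_cutoff` set for the concordance-mode
#' hotspot arm.
#'
#' @inheritParams evaluate_performance
#' @return data.frame: per cancer type, `n_evaluable`, `n_unevaluable`,
#'   and the four quadrant fractions.
#' @export
concordance_summary <- function(combined, samples) {
  idx <- match(combined$sample_id, samples$sample_id)
  keep <- samples$group[idx] == "cancer"
  type <- samples$cancer_type[idx][keep]
  quad <- combined$quadrant[keep]
  out <- do.call(rbind, lapply(sort(unique(type)), function(ct) {
    q <- quad[type == ct]
    ev <- q != "unevaluable"
    frac <- if (any(ev)) as.numeric(table(factor(
      as.character(q[ev]), levels = QUADRANTS[1:4]))) / sum(ev)
      else rep(NA_real_, 4)
    data.frame(cancer_type = ct, n_evaluable = sum(ev),
               n_unevaluable = sum(!ev),
               both = frac[1], hotspot_only = frac[2],
               spotmas_only = frac[3], neither = frac[4],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Gene-level prevalence and recurrent mutation sites
#'
#' For each panel gene, the number and fraction of cancer patients with
#' at least one PASS call in that gene (a patient counts once per
#' gene); and the list of recurrent sites — those with PASS calls in at
#' least two patients — annotated with the cancer types sharing them.
#'
#' @param calls a `cohort_calls` (PASS calls are used).
#' @param panel the [hotspot_panel()].
#' @param samples the [sample_sheet()].
#' @return list with `genes` (gene, n_patients, fraction) and
#'   `recurrent` (site_id, gene, protein_change, n_patients,
#'   cancer_types).
#' @export
gene_recurrence_summary <- function(calls, panel, samples) {
  if (inherits(calls, "cohort_calls")) calls <- calls$calls
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  idx <- match(pass$sample_id, samples$sample_id)
  pass <- pass[!is.na(idx) & samples$group[idx] == "cancer", , drop = FALSE]
  n_cancer <- sum(samples$group == "cancer")
  gene <- panel$gene[match(pass$site_id, panel$site_id)]

  per_gene <- unique(data.frame(gene = gene, sample_id = pass$sample_id,
                                stringsAsFactors = FALSE))
  counts <- table(factor(per_gene$gene, levels = sort(unique(panel$gene))))
  genes <- data.frame(gene = names(counts),
                      n_patients = as.integer(counts),
                      fraction = if (n_cancer) as.integer(counts) / n_cancer
                                 else NA_real_,
                      stringsAsFactors = FALSE)
  genes <- genes[order(-genes$n_patients, genes$gene), ]
  rownames(genes) <- NULL

  per_site <- unique(data.frame(site_id = pass$site_id,
                                sample_id = pass$sample_id,
                                stringsAsFactors = FALSE))
  site_n <- table(per_site$site_id)
  rec_sites <- names(site_n)[site_n >= 2L]
  recurrent <- do.call(rbind, lapply(rec_sites, function(s) {
    sids <- per_site$sample_id[per_site$site_id == s]
    ct <- sort(unique(samples$cancer_type[match(sids, samples$sample_id)]))
    pi <- match(s, panel$site_id)
    data.frame(site_id = s, gene = panel$gene[pi],
               protein_change = panel$protein_change[pi],
               n_patients = length(sids),
               cancer_types = paste(ct, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(recurrent))
    recurrent <- data.frame(site_id = character(0), gene = character(0),
                            protein_change = character(0),
                            n_patients = integer(0),
                            cancer_types = character(0))
  recurrent <- recurrent[order(-recurrent$n_patients, recurrent$site_id), ]
  rownames(recurrent) <- NULL
  list(genes = genes, recurrent = recurrent)
}

#' Cohort demographics: age and sex comparisons
#'
#' Two-sided Mann-Whitney U test on age (normal approximation with tie
#' correction) and a Yates-corrected Chi-squared test on the 2x2
#' group-by-sex table, cancer patients versus controls.
#'
#' @param samples a [sample_sheet()].
#' @return a `cohort_stats` list: `age_test` (p.value, statistic, the
#'   group medians, or a `skipped` notice when a group has no ages),
#'   `sex_test` and the `sex_table`.
#' @export
cohort_statistics <- function(samples) {
  grp <- samples$group
  if (!any(grp == "cancer") || !any(grp == "control"))
    stopf("need both cancer and control samples")
  keep <- grp %in% c("cancer", "control")
  g <- factor(grp[keep], levels = c("cancer", "control"))
  age <- samples$age[keep]
  sex <- samples$sex[keep]
  age_test <- if (all(is.na(age[g == "cancer"])) ||
                  all(is.na(age[g == "control"]))) {
    message("age comparison skipped: a group has no recorded ages")
    list(skipped = TRUE)
  } else {
    wt <- stats::wilcox.test(age ~ g, exact = FALSE)
    list(skipped = FALSE, p.value = wt$p.value, statistic = unname(wt$statistic),
         median_cancer = stats::median(age[g == "cancer"], na.rm = TRUE),
         median_control = stats::median(age[g == "control"], na.rm = TRUE))
  }
  sex_table <- table(group = g, sex = factor(sex))
  ct <- stats::chisq.test(sex_table, correct = TRUE)
  structure(list(age_test = age_test,
                 sex_test = list(p.value = ct$p.value,
                                 statistic = unname(ct$statistic),
                                 df = unname(ct$parameter)),
                 sex_table = sex_table),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("Cohort comparison (cancer vs control)\n")
  if (isTRUE(x$age_test$skipped)) {
    cat("  age: skipped (missing data)\n")
  } else {
    cat(sprintf("  age: Mann-Whitney U p = %.3g (medians %g vs %g)\n",
                x$age_test$p.value, x$age_test$median_cancer,
                x$age_test$median_control))
  }
  cat(sprintf("  sex: Chi-squared (Yates) X2 = %.3g, p = %.4g\n",
              x$sex_test$statistic, x$sex_test$p.value))
  print(x$sex_table)
  invisible(x)
}
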