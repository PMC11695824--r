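# Independent oracles and small in-code fixtures.

# Wilson interval by direct root-finding inversion of the score test:
# the bounds are the p solving (phat - p)^2 = z^2 p(1-p)/n.
wilson_by_inversion <- function(successes, n, confidence = 0.95) {
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- successes / n
  score <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # at phat 0/1 the trivial root p = phat must be excluded from the
  # bracket so that uniroot finds the score-test bound, not the cusp
  lo_hi <- if (phat >= 1) 1 - 1e-9 else phat
  up_lo <- if (phat <= 0) 1e-9 else phat
  lower <- if (successes == 0) 0 else
    uniroot(score, c(1e-15, lo_hi), tol = 1e-12)$root
  upper <- if (successes == n) 1 else
    uniroot(score, c(up_lo, 1 - 1e-15), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# Brute-force calling oracle: explicit nested loops over samples and
# sites applying the threshold rules one observation at a time.
brute_force_calls <- function(counts, model, wbc = NULL) {
  res <- list()
  for (sid in unique(counts$sample_id)) {
    rows <- counts[counts$sample_id == sid, ]
    pass_vafs <- c()
    for (i in seq_len(nrow(rows))) {
      site <- rows$site_id[i]
      cutoff <- model$per_site_cutoff[[site]]
      thr <- max(model$lod, if (is.na(cutoff)) 0 else cutoff)
      if (rows$depth[i] < model$min_amplicon_depth) next
      if (rows$depth[i] == 0) next
      vaf <- rows$alt_count[i] / rows$depth[i]
      if (vaf < thr) next
      # CHIP check
      chip <- FALSE
      if (!is.null(wbc)) {
        w <- wbc[wbc$sample_id == sid & wbc$site_id == site, ]
        if (nrow(w) == 1 && w$depth > 0 && w$alt_count / w$depth >= thr)
          chip <- TRUE
      }
      if (!chip) pass_vafs <- c(pass_vafs, vaf)
    }
    res[[sid]] <- data.frame(
      sample_id = sid, hotspot_positive = length(pass_vafs) >= 1,
      mean_vaf = if (length(pass_vafs)) mean(pass_vafs) else NA_real_,
      n_pass = length(pass_vafs), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# A tiny deterministic panel built in code.
tiny_panel <- function(n = 4) {
  hotspot_panel(data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    gene = rep(c("TP53", "KRAS"), length.out = n),
    chrom = rep("chr17", n), pos = 7577000 + seq_len(n),
    ref = rep("C", n), alt = rep("T", n),
    protein_change = sprintf("p.R%dH", 100 + seq_len(n)),
    actionable = rep(c(TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE))
}

# A calibration model with known thresholds, no fitting involved.
fixed_model <- function(panel, lod = 5e-4, cutoffs = 0,
                        min_depth = 10000) {
  structure(list(
    lod = lod,
    per_site_cutoff = setNames(rep_len(cutoffs, nrow(panel)),
                               panel$site_id),
    min_amplicon_depth = min_depth, calibration_n = 0L,
    method = "mean_sd", k = 3, q = NULL),
    class = "hotspot_calibration")
}

# Shrunken simulation config for fast property loops.
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_sites = 40L, n_genes = 10L,
             n_negative_calibration = 60L, n_controls = 40L,
             cancer_counts = c(breast = 10L, colorectal = 10L,
                               gastric = 10L, liver = 10L, lung = 10L),
             ...)
}

counts_df <- function(sample_id, site_id, depth, alt_count, panel = NULL) {
  allele_counts(data.frame(sample_id = sample_id, site_id = site_id,
                           depth = depth, alt_count = alt_count,
                           stringsAsFactors = FALSE), panel)
}

# Hand-built call summary + sample sheet with a given number of
# hotspot-positive samples per cancer type (and positive controls).
cohort_sheet <- function(pos_by_type, n_by_type, n_controls,
                         controls_positive = 0, scores_cancer = NA,
                         scores_control = NA, stages = NULL) {
  types <- names(n_by_type)
  n_can <- sum(n_by_type)
  ids <- c(sprintf("CAN%03d", seq_len(n_can)),
           sprintf("CTL%03d", seq_len(n_controls)))
  type <- c(rep(types, n_by_type), rep("none", n_controls))
  hot <- logical(n_can + n_controls)
  off <- 0L
  for (t in types) {
    hot[off + seq_len(pos_by_type[[t]])] <- TRUE
    off <- off + n_by_type[[t]]
  }
  hot[n_can + seq_len(controls_positive)] <- TRUE
  if (is.null(stages)) stages <- rep("unknown", n_can)
  samples <- sample_sheet(data.frame(
    sample_id = ids,
    group = rep(c("cancer", "control"), c(n_can, n_controls)),
    cancer_type = type,
    stage = c(stages, rep("not_applicable", n_controls)),
    age = 55, sex = "female",
    spotmas_score = c(rep_len(scores_cancer, n_can),
                      rep_len(scores_control, max(n_controls, 0))),
    has_wbc = FALSE, stringsAsFactors = FALSE))
  summary <- data.frame(sample_id = ids, hotspot_positive = hot,
                        mean_vaf = ifelse(hot, 0.01, NA_real_),
                        n_pass = as.integer(hot), stringsAsFactors = FALSE)
  list(samples = samples, summary = summary)
}
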