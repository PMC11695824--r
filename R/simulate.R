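#' Simulation configuration for synthetic liquid-biopsy cohorts
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study design the pipeline was built for: a
#' 700-site / 23-gene hotspot panel, 570 negative-control plasmas for
#' baseline calibration, 304 evaluation controls, and 255 cancer
#' patients across five types (breast 64, colorectal 59, gastric 62,
#' liver 29, lung 41) with type-specific ctDNA shedding probabilities
#' and stage composition, mean amplicon depth 100,000x, and
#' class-conditional SPOT-MAS scores calibrated so that thresholding at
#' 0.60 reproduces the configured per-class positive rates.
#'
#' @param seed integer RNG seed; identical configurations (seed
#'   included) yield byte-identical outputs.
#' @param n_sites,n_genes panel size.
#' @param n_negative_calibration,n_controls cohort sizes for the
#'   baseline-calibration plasmas and the evaluation controls.
#' @param cancer_counts named integer vector of patients per cancer type.
#' @param stage_probs named list (per cancer type) of probabilities over
#'   stages I, II, IIIA, unknown.
#' @param shedder_prob named vector: probability a patient of each type
#'   sheds detectable ctDNA (carries >= 1 planted panel mutation at VAF
#'   >= `vaf_min`).
#' @param vaf_min,vaf_max planted tumor-mutation VAFs are log-uniform on
#'   `[vaf_min, vaf_max]`; `vaf_min` defaults to the assay limit of
#'   detection 5e-4.
#' @param extra_mut_rate Poisson rate for planted mutations beyond the
#'   first in a shedder.
#' @param error_shape1,error_shape2 Beta parameters for per-site
#'   background error rates (defaults give mean 1e-4 with realistic
#'   site-to-site heterogeneity).
#' @param mean_depth,depth_dispersion negative-binomial amplicon depth
#'   model (mean reads, size parameter).
#' @param amplicon_fail_prob,fail_depth_mean probability an amplicon
#'   fails and the (Poisson) mean depth of a failed amplicon.
#' @param chip_rate probability a cancer or control sample carries a
#'   clonal-hematopoiesis (CHIP) mutation, mirrored in its matched
#'   white-blood-cell counts.
#' @param chip_vaf_range log-uniform range of CHIP cfDNA VAFs.
#' @param chip_wbc_ratio range of the cfDNA:WBC VAF ratio for CHIP sites.
#' @param score_rates named vector: target P(score > `score_cutoff`) per
#'   class (`control` plus each cancer type).
#' @param score_cutoff,score_concentration SPOT-MAS positivity cutoff
#'   and the Beta concentration (a+b) of the class-conditional score
#'   distributions.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 700L, n_genes = 23L,
                       n_negative_calibration = 570L, n_controls = 304L,
                       cancer_counts = c(breast = 64L, colorectal = 59L,
                                         gastric = 62L, liver = 29L,
                                         lung = 41L),
                       stage_probs = NULL,
                       shedder_prob = c(breast = 0.313, colorectal = 0.593,
                                        gastric = 0.419, liver = 0.965,
                                        lung = 0.537),
                       vaf_min = 5e-4, vaf_max = 0.2,
                       extra_mut_rate = 0.7,
                       error_shape1 = 4, error_shape2 = 39996,
                       mean_depth = 1e5, depth_dispersion = 20,
                       amplicon_fail_prob = 0.01, fail_depth_mean = 4000,
                       chip_rate = 0.05,
                       chip_vaf_range = c(0.002, 0.05),
                       chip_wbc_ratio = c(0.5, 2),
                       score_rates = c(control = 0.016, breast = 0.516,
                                       colorectal = 0.576, gastric = 0.629,
                                       liver = 0.966, lung = 0.80),
                       score_cutoff = 0.60,
                       score_concentration = 6) {
  if (is.null(stage_probs))
    stage_probs <- list(
      breast     = c(I = 10, II = 44, IIIA = 6,  unknown = 4)  / 64,
      colorectal = c(I = 4,  II = 19, IIIA = 13, unknown = 23) / 59,
      gastric    = c(I = 12, II = 16, IIIA = 22, unknown = 12) / 62,
      liver      = c(I = 9,  II = 12, IIIA = 8,  unknown = 0)  / 29,
      lung       = c(I = 1,  II = 1,  IIIA = 22, unknown = 17) / 41)
  cfg <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
              n_genes = as.integer(n_genes),
              n_negative_calibration = as.integer(n_negative_calibration),
              n_controls = as.integer(n_controls),
              cancer_counts = cancer_counts, stage_probs = stage_probs,
              shedder_prob = shedder_prob, vaf_min = vaf_min,
              vaf_max = vaf_max, extra_mut_rate = extra_mut_rate,
              error_shape1 = error_shape1, error_shape2 = error_shape2,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              amplicon_fail_prob = amplicon_fail_prob,
              fail_depth_mean = fail_depth_mean, chip_rate = chip_rate,
              chip_vaf_range = chip_vaf_range,
              chip_wbc_ratio = chip_wbc_ratio, score_rates = score_rates,
              score_cutoff = score_cutoff,
              score_concentration = score_concentration)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_sites) || !is_count(n_genes) ||
        n_sites < n_genes || n_genes < 1L)
      stopf("invalid panel size: need n_sites >= n_genes >= 1")
    if (!is_count(n_negative_calibration) || !is_count(n_controls))
      stopf("cohort sizes must be non-negative integers")
    if (any(cancer_counts < 0) || any(cancer_counts != floor(cancer_counts)))
      stopf("cancer_counts must be non-negative integers")
    types <- names(cancer_counts)
    if (is.null(types) || !all(types %in% setdiff(CANCER_TYPES, "none")))
      stopf("cancer_counts must be named with known cancer types")
    if (!all(types %in% names(shedder_prob)))
      stopf("shedder_prob must cover every cancer type in cancer_counts")
    if (!is_prob(shedder_prob) || !is_prob(chip_rate) ||
        !is_prob(amplicon_fail_prob))
      stopf("all probabilities must lie in [0,1]")
    for (ct in types) {
      p <- stage_probs[[ct]]
      if (is.null(p) || !is_prob(p) || abs(sum(p) - 1) > 1e-8)
        stopf("stage_probs[['%s']] must be probabilities summing to 1", ct)
    }
    if (!(vaf_min > 0 && vaf_max <= 1 && vaf_min <= vaf_max))
      stopf("need 0 < vaf_min <= vaf_max <= 1")
    if (!all(c("control", types) %in% names(score_rates)))
      stopf("score_rates must cover 'control' and every cancer type")
    if (!is_prob(score_rates))
      stopf("score_rates must lie in [0,1]")
  })
  invisible(cfg)
}

# Beta(a, b) with a + b = concentration whose upper tail beyond `cutoff`
# equals `rate`; solved for the mean by monotone root finding.
beta_score_params <- function(rate, cutoff = 0.6, concentration = 6) {
  if (!is_prob(rate)) stopf("score rate must lie in [0,1]")
  rate <- min(max(rate, 1e-9), 1 - 1e-9)
  f <- function(m) {
    1 - stats::pbeta(cutoff, m * concentration, (1 - m) * concentration) -
      rate
  }
  m <- stats::uniroot(f, c(1e-8, 1 - 1e-8), tol = 1e-12)$root
  c(shape1 = m * concentration, shape2 = (1 - m) * concentration)
}

# Per-site background error rates; a fixed property of a synthetic panel.
site_error_rates <- function(panel, config) {
  er <- attr(panel, "error_rates")
  if (!is.null(er) && length(er) == nrow(panel)) return(er)
  with_seed(config$seed + 7L, {
    er <- stats::rbeta(nrow(panel), config$error_shape1, config$error_shape2)
  })
  names(er) <- panel$site_id
  er
}

PANEL_GENES <- c("TP53", "KRAS", "PIK3CA", "APC", "TERT", "CTNNB1", "EGFR",
                 "AMER1", "BRAF", "NRAS", "ERBB2", "SMAD4", "FBXW7", "GNAS",
                 "PTEN", "STK11", "ARID1A", "RB1", "NFE2L2", "MET", "KIT",
                 "CDKN2A", "ALK")

#' Generate a synthetic hotspot panel
#'
#' Draws `n_sites` distinct mutation loci across `n_genes` genes
#' (cancer-gene symbols, always including TP53, KRAS, PIK3CA, APC, TERT,
#' CTNNB1, EGFR, AMER1 and BRAF when `n_genes >= 9`). Each synthetic
#' panel carries a per-site background error-rate profile (attribute
#' `error_rates`) drawn once from the configured Beta model.
#'
#' @param config a [sim_config()].
#' @return a [hotspot_panel()] with `error_rates` attribute.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_sites; g <- config$n_genes
  genes <- if (g <= length(PANEL_GENES)) PANEL_GENES[seq_len(g)] else
    c(PANEL_GENES, sprintf("GENE%02d", seq_len(g - length(PANEL_GENES))))
  panel <- with_seed(config$seed + 11L, {
    # each gene gets >= 1 site; remainder multinomial
    gene_of <- c(genes, sample(genes, n - g, replace = TRUE))
    gene_of <- gene_of[order(match(gene_of, genes))]
    chrom_of_gene <- paste0("chr", sample(c(1:22, "X"), g, replace = TRUE))
    names(chrom_of_gene) <- genes
    pos <- integer(n)
    for (gn in genes) {
      idx <- which(gene_of == gn)
      start <- sample.int(2e8, 1L)
      pos[idx] <- start + sort(sample.int(2e4, length(idx)))
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
    protein <- sprintf("p.%s%d%s", sample(aa, n, TRUE),
                       sample.int(1500, n, TRUE), sample(aa, n, TRUE))
    data.frame(
      site_id = sprintf("S%04d", seq_len(n)),
      gene = gene_of, chrom = unname(chrom_of_gene[gene_of]), pos = pos,
      ref = ref, alt = unname(alt), protein_change = protein,
      actionable = stats::runif(n) < 0.1, stringsAsFactors = FALSE)
  })
  panel <- hotspot_panel(panel)
  attr(panel, "error_rates") <- site_error_rates(panel, config)
  panel
}

# Depth draw shared by cfDNA, WBC and titration tables.
draw_depth <- function(n, config) {
  failed <- stats::runif(n) < config$amplicon_fail_prob
  d <- stats::rnbinom(n, size = config$depth_dispersion,
                      mu = config$mean_depth)
  d[failed] <- stats::rpois(sum(failed), config$fail_depth_mean)
  d
}

#' Generate a titration series of mutation reference standards
#'
#' Emulates serially diluted reference standards (Tru-Q style) measured
#' on the panel: for each dilution level and replicate, alternate-allele
#' counts are binomial around the expected VAF plus the per-site
#' background error; the 0% level carries background error only.
#'
#' @param config a [sim_config()].
#' @param panel a [hotspot_panel()] (synthetic panels carry their noise
#'   profile; otherwise one is drawn from `config`).
#' @param levels expected VAF fractions, e.g. `c(0.03, 0.005, 0.001,
#'   5e-4, 0)`.
#' @param replicates replicate samples per level.
#' @return list with `counts` (an `allele_counts` table), `expected`
#'   (named vector sample_id -> expected VAF) and `levels`.
#' @export
generate_titration_series <- function(config, panel,
                                      levels = c(0.03, 0.005, 0.001,
                                                 5e-4, 0),
                                      replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(levels)) stopf("titration needs at least one level")
  if (!is_prob(levels)) stopf("titration levels must lie in [0,1]")
  if (!is_count(replicates) || replicates < 1L)
    stopf("replicates must be a positive integer")
  er <- site_error_rates(panel, config)
  n_site <- nrow(panel)
  grid <- expand.grid(rep = seq_len(replicates), lev = seq_along(levels))
  sample_ids <- sprintf("TQ_L%d_R%d", grid$lev, grid$rep)
  expected <- stats::setNames(levels[grid$lev], sample_ids)
  counts <- with_seed(config$seed + 23L, {
    n <- n_site * length(sample_ids)
    depth <- draw_depth(n, config)
    p <- pmin(rep(expected, each = n_site) + rep(er, length(sample_ids)), 1)
    data.frame(
      sample_id = rep(sample_ids, each = n_site),
      site_id = rep(panel$site_id, length(sample_ids)),
      depth = depth,
      alt_count = stats::rbinom(n, depth, p),
      stringsAsFactors = FALSE)
  })
  list(counts = allele_counts(counts, panel), expected = expected,
       levels = sort(unique(levels), decreasing = TRUE))
}

#' Generate a full synthetic cohort with ground truth
#'
#' Emits the three study arms: `n_negative_calibration` baseline plasmas
#' (noise only), `n_controls` evaluation controls, and cancer patients
#' per `cancer_counts`. Each patient is a ctDNA shedder with its type's
#' configured probability; shedders carry >= 1 planted panel mutation at
#' VAF >= `vaf_min` (log-uniform up to `vaf_max`). A `chip_rate`
#' fraction of cancer and control samples carry a CHIP mutation planted
#' at correlated VAF in both the cfDNA and the matched WBC counts.
#' SPOT-MAS scores are drawn from class-conditional Beta distributions
#' calibrated so P(score > cutoff) equals each class's configured rate;
#' calibration plasmas get no score. Ground truth (shedder flags,
#' planted mutations, CHIP sites) is returned alongside the data, never
#' inside it.
#'
#' @param config a [sim_config()].
#' @param panel a [hotspot_panel()]; defaults to [generate_panel()].
#' @return a `synthetic_cohort`: list with `panel`, `samples`
#'   (sample sheet), `cfdna`, `wbc` (allele-count tables) and `truth`
#'   (`$samples`, `$mutations`, `$chip`).
#' @export
generate_cohort <- function(config, panel = generate_panel(config)) {
  stopifnot(inherits(config, "sim_config"))
  er <- site_error_rates(panel, config)
  n_site <- nrow(panel)
  types <- names(config$cancer_counts)

  with_seed(config$seed + 41L, {
    ## ---- sample sheet -------------------------------------------------
    n_cal <- config$n_negative_calibration
    n_ctl <- config$n_controls
    n_can <- sum(config$cancer_counts)
    cancer_type <- rep(types, config$cancer_counts)
    stage <- unlist(lapply(types, function(ct) {
      k <- config$cancer_counts[[ct]]
      if (!k) return(character(0))
      sample(names(config$stage_probs[[ct]]), k, replace = TRUE,
             prob = config$stage_probs[[ct]])
    }), use.names = FALSE)
    # female-dominated breast arm, male-skewed liver arm, as in practice
    p_male <- c(breast = 0.0, colorectal = 32 / 59, gastric = 33 / 62,
                liver = 25 / 29, lung = 25 / 41)
    sex_can <- ifelse(stats::runif(n_can) <
                        ifelse(cancer_type %in% names(p_male),
                               p_male[cancer_type], 0.5),
                      "male", "female")
    samples <- data.frame(
      sample_id = c(sprintf("NEG%04d", seq_len(n_cal)),
                    sprintf("CTL%04d", seq_len(n_ctl)),
                    sprintf("CAN%04d", seq_len(n_can))),
      group = rep(c("calibration_negative", "control", "cancer"),
                  c(n_cal, n_ctl, n_can)),
      cancer_type = c(rep("none", n_cal + n_ctl), cancer_type),
      stage = c(rep("not_applicable", n_cal + n_ctl), stage),
      age = c(round(40 + 39 * stats::rbeta(n_cal + n_ctl, 1, 2.9)),
              round(28 + 56 * stats::rbeta(n_can, 2.3, 1.7))),
      sex = c(ifelse(stats::runif(n_cal + n_ctl) < 136 / 304,
                     "male", "female"), sex_can),
      spotmas_score = NA_real_,
      has_wbc = rep(c(FALSE, TRUE, TRUE), c(n_cal, n_ctl, n_can)),
      stringsAsFactors = FALSE)

    ## ---- SPOT-MAS scores ---------------------------------------------
    cls <- ifelse(samples$group == "cancer", samples$cancer_type,
                  ifelse(samples$group == "control", "control", NA))
    for (k in unique(stats::na.omit(cls))) {
      sh <- beta_score_params(config$score_rates[[k]], config$score_cutoff,
                              config$score_concentration)
      idx <- which(!is.na(cls) & cls == k)
      samples$spotmas_score[idx] <- stats::rbeta(length(idx), sh[1], sh[2])
    }

    ## ---- truth: shedding, planted mutations, CHIP ---------------------
    is_cancer <- samples$group == "cancer"
    shedder <- logical(nrow(samples))
    shedder[is_cancer] <- stats::runif(n_can) <
      config$shedder_prob[samples$cancer_type[is_cancer]]
    n_mut <- integer(nrow(samples))
    n_mut[shedder] <- 1L + stats::rpois(sum(shedder), config$extra_mut_rate)
    n_mut <- pmin(n_mut, n_site)
    mut_sample <- rep(samples$sample_id, n_mut)
    mut_site <- unlist(lapply(n_mut[n_mut > 0L], function(k)
      sample(panel$site_id, k)), use.names = FALSE)
    mut_vaf <- exp(stats::runif(length(mut_sample), log(config$vaf_min),
                                log(config$vaf_max)))
    mutations <- data.frame(sample_id = mut_sample, site_id = mut_site,
                            vaf = mut_vaf, stringsAsFactors = FALSE)

    eligible <- samples$group %in% c("cancer", "control")
    has_chip <- eligible & stats::runif(nrow(samples)) < config$chip_rate
    chip <- data.frame(
      sample_id = samples$sample_id[has_chip],
      site_id = sample(panel$site_id, sum(has_chip), replace = TRUE),
      cf_vaf = exp(stats::runif(sum(has_chip),
                                log(config$chip_vaf_range[1]),
                                log(config$chip_vaf_range[2]))),
      stringsAsFactors = FALSE)
    chip$wbc_vaf <- pmin(chip$cf_vaf * stats::runif(nrow(chip),
                                                    config$chip_wbc_ratio[1],
                                                    config$chip_wbc_ratio[2]),
                         0.5)

    ## ---- count tables -------------------------------------------------
    signal_matrix <- function(ids, extra) {
      # per (sample, site) added VAF above background, sparse via match
      p <- rep(er, length(ids))
      if (nrow(extra)) {
        row <- match(extra$sample_id, ids)
        keep <- !is.na(row)
        at <- (row[keep] - 1L) * n_site +
          match(extra$site_id[keep], panel$site_id)
        add <- rowsum(extra[[3L]][keep], at)  # sum colliding signals
        at <- as.integer(rownames(add))
        p[at] <- p[at] + as.vector(add)
      }
      pmin(p, 1)
    }
    make_counts <- function(ids, extra) {
      n <- n_site * length(ids)
      depth <- draw_depth(n, config)
      p <- signal_matrix(ids, extra)
      data.frame(sample_id = rep(ids, each = n_site),
                 site_id = rep(panel$site_id, length(ids)),
                 depth = depth,
                 alt_count = stats::rbinom(n, depth, p),
                 stringsAsFactors = FALSE)
    }
    cf_extra <- rbind(mutations,
                      data.frame(sample_id = chip$sample_id,
                                 site_id = chip$site_id,
                                 vaf = chip$cf_vaf,
                                 stringsAsFactors = FALSE))
    cfdna <- make_counts(samples$sample_id, cf_extra)
    wbc_ids <- samples$sample_id[samples$has_wbc]
    wbc <- make_counts(wbc_ids,
                       data.frame(sample_id = chip$sample_id,
                                  site_id = chip$site_id,
                                  vaf = chip$wbc_vaf,
                                  stringsAsFactors = FALSE))

    truth_samples <- data.frame(
      sample_id = samples$sample_id, shedder = shedder,
      n_planted = n_mut, has_chip = has_chip,
      hotspot_positive = shedder, stringsAsFactors = FALSE)

    structure(list(panel = panel, samples = sample_sheet(samples),
                   cfdna = allele_counts(cfdna, panel),
                   wbc = allele_counts(wbc, panel),
                   truth = list(samples = truth_samples,
                                mutations = mutations, chip = chip),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$samples$group)
  cat("Synthetic liquid-biopsy cohort\n")
  cat(sprintf("  panel: %d sites, %d genes\n", nrow(x$panel),
              length(unique(x$panel$gene))))
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  shedders: %d of %d cancer samples\n",
              sum(x$truth$samples$shedder),
              sum(x$samples$group == "cancer")))
  cat(sprintf("  CHIP carriers: %d\n", sum(x$truth$samples$has_chip)))
  invisible(x)
}
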