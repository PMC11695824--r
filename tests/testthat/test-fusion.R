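test_that("wilson_interval matches the score-test inversion oracle", {
  for (n in c(1, 2, 7, 29, 50)) {
    for (s in 0:n) {
      got <- wilson_interval(s, n)
      want <- wilson_by_inversion(s, n)
      expect_equal(got$lower, unname(want["lower"]), tolerance = 1e-9)
      expect_equal(got$upper, unname(want["upper"]), tolerance = 1e-9)
    }
  }
  expect_error(wilson_interval(0, 0), "n = 0")
  expect_error(wilson_interval(5, 4), "successes")
  # boundary clamp
  expect_equal(wilson_interval(0, 10)$lower, 0)
  expect_equal(wilson_interval(10, 10)$upper, 1)
})

test_that("Wilson intervals reproduce the published confidence bounds", {
  ci <- function(s, n) round(100 * unlist(wilson_interval(s, n)), 1)
  expect_equal(ci(131, 255), c(lower = 45.3, upper = 57.4))
  expect_equal(ci(168, 255), c(lower = 59.9, upper = 71.4))
  expect_equal(ci(200, 255), c(lower = 73.0, upper = 83.0))
  expect_equal(ci(297, 304), c(lower = 95.3, upper = 98.9))
  expect_equal(ci(16, 36), c(lower = 29.5, upper = 60.4))
  expect_equal(ci(23, 36), c(lower = 47.6, upper = 77.5))
  expect_equal(ci(45, 92)[["upper"]], 59.0)
  expect_equal(ci(59, 92)[["upper"]], 73.2)
})

test_that("OR rule and score boundary: positive only when score exceeds 0.60", {
  co <- cohort_sheet(pos_by_type = c(liver = 1), n_by_type = c(liver = 3),
                     n_controls = 0,
                     scores_cancer = c(0.10, 0.61, 0.60))
  cc <- classify_combined(co$summary, co$samples)
  expect_equal(as.character(cc$quadrant),
               c("hotspot_only", "spotmas_only", "neither"))
  expect_equal(cc$combined_positive, c(TRUE, TRUE, FALSE))
  expect_equal(cc$spotmas_positive, c(FALSE, TRUE, FALSE))
})

test_that("missing scores are unevaluable and counted, not dropped silently", {
  co <- cohort_sheet(pos_by_type = c(liver = 1), n_by_type = c(liver = 2),
                     n_controls = 1, scores_cancer = NA)
  expect_message(cc <- classify_combined(co$summary, co$samples),
                 "unevaluable")
  expect_true(all(cc$quadrant[1:2] == "unevaluable"))
  # hotspot-positive with missing score is still combined-positive (OR)
  expect_true(cc$combined_positive[1])
  rep <- evaluate_performance(cc, co$samples, arm = "spotmas")
  expect_equal(rep$sensitivity$n[rep$sensitivity$stratum == "overall"], 0L)
  expect_equal(rep$n_unevaluable, 3L)
})

test_that("concordance-mode hotspot arm thresholds the mean VAF", {
  summary <- data.frame(sample_id = c("A", "B", "C"),
                        hotspot_positive = c(TRUE, TRUE, FALSE),
                        mean_vaf = c(0.06, 0.01, NA),
                        n_pass = c(1L, 1L, 0L))
  samples <- sample_sheet(data.frame(
    sample_id = c("A", "B", "C"), group = "cancer", cancer_type = "liver",
    stage = "I", age = 60, sex = "male", spotmas_score = c(0.9, 0.9, 0.1),
    has_wbc = FALSE))
  cc <- classify_combined(summary, samples, maf_cutoff = 0.05)
  expect_equal(as.character(cc$quadrant),
               c("both", "spotmas_only", "neither"))
  # inclusive boundary on the VAF side
  summary$mean_vaf[2] <- 0.05
  cc2 <- classify_combined(summary, samples, maf_cutoff = 0.05)
  expect_equal(as.character(cc2$quadrant)[2], "both")
})

test_that("evaluate reproduces the published per-class detection rates", {
  co <- cohort_sheet(
    pos_by_type = c(liver = 28, colorectal = 35, lung = 22, gastric = 26,
                    breast = 20),
    n_by_type = c(liver = 29, colorectal = 59, lung = 41, gastric = 62,
                  breast = 64),
    n_controls = 304, controls_positive = 2)
  cc <- classify_combined(co$summary, co$samples)
  rep <- evaluate_performance(cc, co$samples, arm = "hotspot")
  s <- rep$sensitivity
  get <- function(st) s$estimate[s$stratum == st]
  expect_equal(get("overall"), 131 / 255)
  expect_equal(round(100 * get("overall"), 1), 51.4)
  expect_equal(round(100 * get("colorectal"), 1), 59.3)
  expect_equal(round(100 * get("lung"), 1), 53.7)
  expect_equal(round(100 * get("gastric"), 1), 41.9)
  expect_equal(rep$specificity$estimate, 302 / 304)
  expect_equal(round(100 * rep$specificity$estimate, 1), 99.3)
  # stage strata cover the cancer cohort exactly
  st <- s[s$stratum_type == "stage", ]
  expect_equal(sum(st$n), 255L)
})

test_that("degenerate cohorts evaluate without errors", {
  co <- cohort_sheet(pos_by_type = c(liver = 3), n_by_type = c(liver = 3),
                     n_controls = 2, controls_positive = 2)
  cc <- classify_combined(co$summary, co$samples)
  rep <- evaluate_performance(cc, co$samples, arm = "hotspot")
  expect_equal(rep$sensitivity$estimate[
    rep$sensitivity$stratum == "overall"], 1)
  expect_equal(rep$specificity$estimate, 0)
  # empty stratum: n = 0, no CI, no exception
  br <- rep$sensitivity[rep$sensitivity$stratum == "I", ]
  expect_equal(br$n, 0L)
  expect_true(is.na(br$estimate) && is.na(br$lower))
})

test_that("quadrant fractions partition each cancer type", {
  co <- generate_cohort(small_config(seed = 51))
  neg <- co$cfdna[grepl("^NEG", co$cfdna$sample_id), ]
  model <- hotspot_calibration(neg, co$panel)
  cc <- suppressWarnings(
    call_cohort(co$cfdna[!grepl("^NEG", co$cfdna$sample_id), ], model,
                wbc = co$wbc))
  comb <- classify_combined(cc, co$samples, maf_cutoff = 0.05)
  conc <- concordance_summary(comb, co$samples)
  ev <- conc$n_evaluable > 0
  sums <- rowSums(conc[ev, c("both", "hotspot_only", "spotmas_only",
                             "neither")])
  expect_equal(unname(sums), rep(1, sum(ev)))
  expect_setequal(conc$cancer_type,
                  c("breast", "colorectal", "gastric", "liver", "lung"))
})

test_that("single dual-positive sample yields quadrant 'both' = 1", {
  co <- cohort_sheet(pos_by_type = c(liver = 1), n_by_type = c(liver = 1),
                     n_controls = 0, scores_cancer = 0.9)
  cc <- classify_combined(co$summary, co$samples)
  conc <- concordance_summary(cc, co$samples)
  expect_equal(conc$both, 1)
  # all scores missing: explicit empty summary
  co2 <- cohort_sheet(pos_by_type = c(liver = 1), n_by_type = c(liver = 2),
                      n_controls = 0)
  cc2 <- classify_combined(co2$summary, co2$samples)
  conc2 <- concordance_summary(cc2, co2$samples)
  expect_equal(conc2$n_evaluable, 0L)
  expect_true(is.na(conc2$both))
})

test_that("near-perfect dual shedding recovers the configured 'both' rate", {
  # liver-like arm: certain hotspot shedding, score rate 0.966
  hits <- 0L; n <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_sites = 30L, n_genes = 9L,
                      n_negative_calibration = 30L, n_controls = 5L,
                      cancer_counts = c(liver = 29L),
                      shedder_prob = c(liver = 1),
                      vaf_min = 0.06, vaf_max = 0.2)
    co <- generate_cohort(cfg)
    neg <- co$cfdna[grepl("^NEG", co$cfdna$sample_id), ]
    model <- hotspot_calibration(neg, co$panel)
    cc <- suppressWarnings(
      call_cohort(co$cfdna[!grepl("^NEG", co$cfdna$sample_id), ], model,
                  wbc = co$wbc))
    comb <- classify_combined(cc, co$samples, maf_cutoff = 0.05)
    conc <- concordance_summary(comb, co$samples)
    hits <- hits + round(conc$both * conc$n_evaluable)
    n <- n + conc$n_evaluable
  }
  se <- sqrt(0.966 * (1 - 0.966) / n)
  expect_lt(abs(hits / n - 0.966), 3 * se)
})

test_that("gene-level prevalence counts each patient once per gene", {
  panel <- tiny_panel(4)  # S01,S03: TP53; S02,S04: KRAS
  calls <- data.frame(
    sample_id = c("P1", "P1", "P2", "P3"),
    site_id = c("S01", "S03", "S01", "S02"),
    vaf = 0.01, depth = 100000L, alt_count = 1000L,
    filter = c("PASS", "PASS", "PASS", "BELOW_LOD"))
  samples <- sample_sheet(data.frame(
    sample_id = c("P1", "P2", "P3"), group = "cancer",
    cancer_type = c("breast", "gastric", "liver"), stage = "unknown",
    age = 60, sex = "female", spotmas_score = NA, has_wbc = FALSE))
  gs <- gene_recurrence_summary(calls, panel, samples)
  tp53 <- gs$genes[gs$genes$gene == "TP53", ]
  expect_equal(tp53$n_patients, 2L)          # P1 counted once
  expect_equal(tp53$fraction, 2 / 3)
  expect_equal(gs$genes$n_patients[gs$genes$gene == "KRAS"], 0L)  # not PASS
  # recurrent sites need >= 2 patients; S03 (1 patient) excluded
  expect_equal(gs$recurrent$site_id, "S01")
  expect_equal(gs$recurrent$n_patients, 2L)
  expect_equal(gs$recurrent$cancer_types, "breast,gastric")
})

test_that("published TP53 prevalence arithmetic reproduces", {
  # 59 of 255 patients with >= 1 TP53 PASS call
  panel <- tiny_panel(2)
  samples <- sample_sheet(data.frame(
    sample_id = sprintf("P%03d", 1:255), group = "cancer",
    cancer_type = "breast", stage = "unknown", age = 50, sex = "female",
    spotmas_score = NA, has_wbc = FALSE))
  calls <- data.frame(sample_id = sprintf("P%03d", 1:59), site_id = "S01",
                      vaf = 0.01, depth = 100000L, alt_count = 1000L,
                      filter = "PASS")
  gs <- gene_recurrence_summary(calls, panel, samples)
  expect_equal(round(100 * gs$genes$fraction[gs$genes$gene == "TP53"], 1),
               23.1)
})

test_that("cohort statistics: null, published-table and separated cases", {
  mk <- function(age_can, age_ctl, sex_can, sex_ctl) {
    sample_sheet(data.frame(
      sample_id = sprintf("S%04d", seq_len(length(age_can) + length(age_ctl))),
      group = rep(c("cancer", "control"),
                  c(length(age_can), length(age_ctl))),
      cancer_type = rep(c("liver", "none"),
                        c(length(age_can), length(age_ctl))),
      stage = rep(c("unknown", "not_applicable"),
                  c(length(age_can), length(age_ctl))),
      age = c(age_can, age_ctl), sex = c(sex_can, sex_ctl),
      spotmas_score = NA, has_wbc = FALSE))
  }
  # identical age distributions -> p ~ 1
  s1 <- mk(rep(40:59, 2), rep(40:59, 2), rep("male", 40), rep("male", 40))
  st1 <- cohort_statistics(s1)
  expect_gt(st1$age_test$p.value, 0.9)
  # the published 2x2 sex table: Yates statistic ~ 0, p ~ 1
  s2 <- mk(rep(50, 255), rep(50, 304),
           rep(c("male", "female"), c(115, 140)),
           rep(c("male", "female"), c(136, 168)))
  st2 <- cohort_statistics(s2)
  expect_lt(st2$sex_test$statistic, 1e-4)
  expect_gt(st2$sex_test$p.value, 0.999)
  # disjoint age ranges -> vanishing p
  s3 <- mk(seq(70, 89), seq(30, 49), rep("male", 20), rep("male", 20))
  st3 <- cohort_statistics(s3)
  expect_lt(st3$age_test$p.value, 1e-6)
  # a group with no ages is skipped with a notice
  s4 <- mk(rep(NA_real_, 5), 40:44, rep("male", 5), rep("male", 5))
  expect_message(st4 <- cohort_statistics(s4), "skipped")
  expect_true(st4$age_test$skipped)
})

test_that("OR-rule dominance holds on every simulated cohort", {
  for (seed in 1:5) {
    co <- generate_cohort(small_config(seed = seed))
    neg <- co$cfdna[grepl("^NEG", co$cfdna$sample_id), ]
    model <- hotspot_calibration(neg, co$panel)
    cc <- suppressWarnings(
      call_cohort(co$cfdna[!grepl("^NEG", co$cfdna$sample_id), ], model,
                  wbc = co$wbc))
    comb <- classify_combined(cc, co$samples)
    sens <- sapply(c("hotspot", "spotmas", "combined"), function(a) {
      r <- evaluate_performance(comb, co$samples, arm = a)
      r$sensitivity$estimate[r$sensitivity$stratum == "overall"]
    })
    spec <- sapply(c("hotspot", "spotmas", "combined"), function(a)
      evaluate_performance(comb, co$samples, arm = a)$specificity$estimate)
    expect_gte(sens[["combined"]], max(sens[["hotspot"]], sens[["spotmas"]]))
    expect_lte(spec[["combined"]], min(spec[["hotspot"]], spec[["spotmas"]]))
  }
})
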