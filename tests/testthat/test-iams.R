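test_that("light/heavy ratio and S/N follow the hand-computed arithmetic", {
  rec <- tr_well("S1", "sample", "APOA4", light = 2000, heavy = 1000,
                 bg_light = 100, bg_heavy = 100)
  r <- compute_peptide_ratio(rec)
  expect_equal(r$sn_light, 20)
  expect_equal(r$sn_heavy, 10)
  expect_true(r$passed_sn)
  expect_equal(r$ratio, 2.0)

  # identical light and heavy areas give ratio exactly 1
  r1 <- compute_peptide_ratio(tr_well("S1", "sample", "CD5L", 5e5, 5e5))
  expect_equal(r1$ratio, 1.0)
})

test_that("S/N <= 5 on either label blocks the ratio without an error", {
  rec <- tr_well("S1", "sample", "APOA4", light = 400, heavy = 1000,
                 bg_light = 100, bg_heavy = 100)  # light S/N = 4
  r <- compute_peptide_ratio(rec)
  expect_false(r$passed_sn)
  expect_true(is.na(r$ratio))
  expect_equal(r$flag, "sn_fail")

  # exactly at the threshold is not strictly greater, so it fails
  at5 <- tr_well("S1", "sample", "APOA4", light = 500, heavy = 1000,
                 bg_light = 100, bg_heavy = 100)
  expect_false(compute_peptide_ratio(at5)$passed_sn)
})

test_that("zero backgrounds and missing labels are handled as specified", {
  inf_sn <- tr_well("S1", "sample", "APOA4", 1000, 1000,
                    bg_light = 0, bg_heavy = 0)
  r <- compute_peptide_ratio(inf_sn)
  expect_true(r$passed_sn)            # positive area over zero background
  expect_equal(r$ratio, 1.0)

  both_zero <- tr_well("S1", "sample", "APOA4", 0, 0,
                       bg_light = 0, bg_heavy = 0)
  expect_equal(compute_peptide_ratio(both_zero)$flag, "missing")

  only_light <- tr_row("S1", "sample", "APOA4", "light", 1000, 10)
  expect_equal(compute_peptide_ratio(only_light)$flag, "missing")
})

test_that("multiple transitions per peptide are summed before ratioing", {
  rec <- rbind(
    tr_row("S1", "sample", "APOA4", "light", 600, 20),
    tr_row("S1", "sample", "APOA4", "light", 400, 20),
    tr_row("S1", "sample", "APOA4", "heavy", 500, 20)
  )
  r <- compute_peptide_ratio(rec)
  expect_equal(r$light_area, 1000)
  expect_equal(r$ratio, 2.0)
})

test_that("effective plasma concentration reproduces the calibrator worked examples", {
  expect_equal(effective_plasma_concentration(18.3, 50, 10), 91.5)
  expect_equal(effective_plasma_concentration(3.2, 25, 25), 3.2)
  # formula value for the lowest calibrator (the printed table rounds differently)
  expect_equal(effective_plasma_concentration(0.178, 50, 10), 0.890)
  expect_error(effective_plasma_concentration(1, 0, 10), "positive")
  expect_error(effective_plasma_concentration(1, 50, -1), "positive")
})

test_that("calibration averages replicate ratios and enforces the CV gate", {
  rf <- calibrate(c(2, 2, 2, 2), 91.5, protein = "APOA4")
  expect_equal(rf$mean_calibrator_ratio, 2)
  expect_equal(rf$replicate_cv, 0)

  rf2 <- calibrate(c(1.9, 2.0, 2.1, 2.0), 91.5, protein = "APOA4")
  expect_equal(rf2$mean_calibrator_ratio, 2)
  expect_equal(rf2$replicate_cv, 0.0408248, tolerance = 1e-6)

  # an S/N-failed replicate simply drops out: mean over the remaining three
  rf3 <- calibrate(c(1.9, 2.0, 2.1), 91.5)
  expect_equal(rf3$n, 3)
  expect_equal(rf3$mean_calibrator_ratio, 2)

  expect_error(calibrate(c(2), 91.5, protein = "CD5L"), "calibration failure")
  expect_error(calibrate(c(1, 2, 3, 4), 91.5, protein = "CD5L"), "CV")
})

test_that("quantification is proportional to the ratio and flags the working range", {
  rf <- calibrate(c(2, 2, 2), 91.5, protein = "APOA4")
  row_at_cal <- compute_peptide_ratio(
    tr_well("S1", "sample", "APOA4", 2e6, 1e6))
  q <- quantify(row_at_cal, rf, range_lo = 37.5, range_hi = 200)
  expect_equal(q$concentration, 91.5)   # ratio equal to calibrator mean
  expect_equal(q$flags, "")

  half <- compute_peptide_ratio(tr_well("S1", "sample", "APOA4", 1e6, 1e6))
  expect_equal(quantify(half, rf)$concentration, 91.5 / 2)

  # 210 ug/mL is above the 37.5-200 plasma working range
  hot <- compute_peptide_ratio(
    tr_well("S2", "sample", "APOA4", 2e6 * 210 / 91.5, 1e6))
  qh <- quantify(hot, rf, range_lo = 37.5, range_hi = 200)
  expect_equal(qh$concentration, 210)
  expect_match(qh$flags, "above_range")

  low <- compute_peptide_ratio(
    tr_well("S3", "sample", "APOA4", 2e6 * 20 / 91.5, 1e6))
  expect_match(quantify(low, rf, 37.5, 200)$flags, "below_lod")

  failed <- compute_peptide_ratio(
    tr_well("S4", "sample", "APOA4", 100, 1e6, bg_light = 100))
  qf <- quantify(failed, rf, 37.5, 200)
  expect_true(is.na(qf$concentration))
  expect_equal(qf$flags, "sn_fail")
})

test_that("batch concentrations are invariant to global and per-sample heavy rescaling", {
  batch <- tiny_iams_batch(sample_ratios = c(S1 = 0.4, S2 = 0.9, S3 = 1.6))
  reg <- analyte_registry()[1, ]
  base <- quantify_iams_batch(batch, registry = reg)

  # multiply every area in the batch by a constant
  scaled <- batch
  scaled$total_area <- scaled$total_area * 7.3
  scaled$total_background <- scaled$total_background * 7.3
  expect_equal(quantify_iams_batch(scaled, registry = reg)$concentration,
               base$concentration)

  # multiply one sample's light AND heavy by k: concentration unchanged
  k <- 2.5
  one <- batch
  i <- one$sample == "S2"
  one$total_area[i] <- one$total_area[i] * k
  expect_equal(quantify_iams_batch(one, registry = reg)$concentration,
               base$concentration)

  # multiply only its light area by k: concentration scales by k
  lonly <- batch
  j <- lonly$sample == "S2" & lonly$label == "light"
  lonly$total_area[j] <- lonly$total_area[j] * k
  got <- quantify_iams_batch(lonly, registry = reg)
  expect_equal(got$concentration[got$sample == "S2"],
               k * base$concentration[base$sample == "S2"])
  expect_equal(got$concentration[got$sample != "S2"],
               base$concentration[base$sample != "S2"])
})

test_that("batch quantification equals a brute-force recomputation from raw areas", {
  spec <- cohort_spec(n_subjects = 20, seed = 11)
  truth <- generate_cohort(spec)
  batch <- simulate_iams_batch(truth, seed = 99)
  reg <- analyte_registry()
  got <- quantify_iams_batch(batch, registry = reg)

  # independent oracle: plain loops over the raw table
  for (i in seq_len(nrow(reg))) {
    prot <- reg$protein[i]
    sub <- batch[batch$protein == prot, ]
    ratio_of <- function(s) {
      la <- sum(sub$total_area[sub$sample == s & sub$label == "light"])
      lb <- sum(sub$total_background[sub$sample == s & sub$label == "light"])
      ha <- sum(sub$total_area[sub$sample == s & sub$label == "heavy"])
      hb <- sum(sub$total_background[sub$sample == s & sub$label == "heavy"])
      if (la / lb > 5 && ha / hb > 5) la / ha else NA_real_
    }
    cal <- vapply(paste0("CAL_", 1:4), ratio_of, numeric(1))
    cal_mean <- mean(cal[!is.na(cal)])
    for (s in truth$subject) {
      expected <- reg$cal_effective_conc[i] * ratio_of(s) / cal_mean
      expect_equal(got$concentration[got$sample == s & got$protein == prot],
                   expected)
    }
  }
})
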