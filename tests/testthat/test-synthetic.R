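test_that("cohort generation is deterministic and validates its spec", {
  spec <- cohort_spec(n_subjects = 50, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # a different seed changes the draw
  expect_false(identical(a, generate_cohort(cohort_spec(n_subjects = 50,
                                                        seed = 6))))

  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(medians = c(APOA4 = -1, CD5L = 3, IBP3 = 0.4)),
               "medians")
  expect_error(cohort_spec(gcvs = c(APOA4 = 1.2, CD5L = 0.4, IBP3 = 0.4)),
               "gcvs")
  expect_error(cohort_spec(bias_mode = c(APOA4 = "weird", CD5L = "additive",
                                         IBP3 = "multiplicative")),
               "bias_mode")
})

test_that("sampled concentration distributions match the spec at n = 100", {
  spec <- cohort_spec(n_subjects = 100, seed = 9)
  truth <- generate_cohort(spec)
  for (a in names(spec$medians)) {
    x <- truth[[tolower(a)]]
    expect_true(all(x > 0))
    sample_gcv <- sqrt(exp(stats::var(log(x))) - 1)
    expect_lt(abs(sample_gcv - spec$gcvs[[a]]) / spec$gcvs[[a]], 0.30)
    expect_lt(abs(log(stats::median(x) / spec$medians[[a]])), 0.15)
  }
})

test_that("noiseless IAMS simulation gives exact calibrator ratios", {
  spec <- cohort_spec(n_subjects = 3, seed = 2)
  truth <- generate_cohort(spec)
  resp <- noiseless_response()
  batch <- simulate_iams_batch(truth, response = resp, seed = 1)
  reg <- analyte_registry()
  rr <- peptide_ratios(batch)
  for (i in seq_len(nrow(reg))) {
    prot <- reg$protein[i]
    cal <- rr[rr$protein == prot & rr$role == "calibrator", ]
    expect_equal(cal$ratio,
                 rep(reg$cal_effective_conc[i] * resp$slope[[prot]], 4))
    # sample ratios equal slope x truth exactly
    smp <- rr[rr$protein == prot & rr$role == "sample", ]
    expect_equal(smp$ratio[match(truth$subject, smp$sample)],
                 resp$slope[[prot]] * truth[[tolower(prot)]])
  }
})

test_that("blank and double-blank wells carry no light signal above background", {
  spec <- cohort_spec(n_subjects = 2, seed = 3)
  batch <- simulate_iams_batch(generate_cohort(spec), seed = 4)
  rr <- peptide_ratios(batch)
  blanks <- rr[rr$role %in% c("blank", "double_blank"), ]
  expect_true(all(!blanks$passed_sn))
  expect_true(all(blanks$sn_light < 5))
})

test_that("simulated batches respect the 96-well capacity", {
  spec <- cohort_spec(n_subjects = 90, seed = 1)
  expect_error(simulate_iams_batch(generate_cohort(spec)), "overflow")
  expect_error(iams_layout(v_cal = 0), "positive")
})

test_that("full IAMS simulate-quantify loop recovers truth within 3x the simulated CV", {
  spec <- cohort_spec(n_subjects = 80, seed = 31)
  truth <- generate_cohort(spec)
  batch <- simulate_iams_batch(truth,
                               response = iams_response(ratio_cv = 0.05),
                               seed = 32)
  q <- quantify_iams_batch(batch)
  q <- q[q$role == "sample", ]
  for (a in c("apoa4", "cd5l", "ibp3")) {
    got <- q$concentration[q$protein == toupper(a)][
      match(truth$subject, q$sample[q$protein == toupper(a)])]
    rel_err <- got / truth[[a]] - 1
    # per-sample errors stay within 3 CVs of zero almost surely at n=80
    expect_lt(stats::median(abs(rel_err)), 3 * 0.05)
    expect_gt(stats::cor(got, truth[[a]]), 0.97)
  }
})

test_that("ELISA plates carry 7 standards and the analyte's dilution factor", {
  conc <- c(S1 = 60, S2 = 110)
  plate <- simulate_elisa_plate(conc, "APOA4", od_sd = 0, seed = 1)
  expect_equal(sum(plate$role == "standard"), 7)
  smp <- plate[plate$role == "sample", ]
  expect_equal(unique(smp$dilution_factor), 400)
  # assay-level concentration is plasma / 400: reconstruct from the OD
  curve <- fit_4pl(data.frame(
    nominal_conc = plate$nominal_conc[plate$role == "standard"],
    od450 = plate$od450[plate$role == "standard"]), analyte = "APOA4")
  assay <- invert_4pl(curve, smp$od450)
  expect_equal(assay * 400 / 1000, unname(conc), tolerance = 1e-6)
  expect_error(simulate_elisa_plate(conc, "NOPE"), "unknown analyte")
})

test_that("stability arm simulation honours effects, pairing and conditions", {
  arms <- simulate_stability_arms(seed = 12)
  expect_setequal(unique(arms$condition), c("4C_24h", "RT_24h", "FT2", "FT3"))
  # duplicates of 3 independent samples in both arms of every condition
  counts <- table(arms$condition, arms$arm)
  expect_true(all(counts == 6))
  expect_identical(arms, simulate_stability_arms(seed = 12))
  expect_error(simulate_stability_arms(conditions = "boiled"), "unknown")

  # noiseless zero effect: stressed mean equals baseline mean exactly
  quiet <- simulate_stability_arms(cv = 0, seed = 1)
  for (cond in unique(quiet$condition))
    expect_equal(mean(quiet$conc[quiet$condition == cond &
                                   quiet$arm == "stressed"]),
                 mean(quiet$conc[quiet$condition == cond &
                                   quiet$arm == "baseline"]))
})

test_that("paired-cohort simulation is deterministic and reflects the bias modes", {
  spec <- cohort_spec(n_subjects = 100, seed = 77)
  s1 <- simulate_paired_cohort(spec)
  s2 <- simulate_paired_cohort(spec)
  expect_identical(s1, s2)
  m <- s1$measurements
  # additive analytes: difference roughly constant; multiplicative: ratio
  d_apoa4 <- m$iams_conc[m$analyte == "APOA4"] - m$elisa_conc[m$analyte == "APOA4"]
  expect_equal(mean(d_apoa4), 47.93, tolerance = 0.15)
  r_ibp3 <- m$elisa_conc[m$analyte == "IBP3"] / m$iams_conc[m$analyte == "IBP3"]
  expect_equal(exp(mean(log(r_ibp3))), 9.52, tolerance = 0.15)
})
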