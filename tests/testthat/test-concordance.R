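test_that("Bland-Altman on identical pairs is degenerate with t = 0, p = 1", {
  x <- c(10, 12, 14, 16)
  add <- bland_altman(x, x, mode = "additive")
  expect_equal(add$bias, 0)
  expect_equal(add$t_statistic, 0)
  expect_equal(add$p_value, 1)
  mul <- bland_altman(x, x, mode = "multiplicative")
  expect_equal(mul$bias_factor, 1)
  expect_equal(mul$p_value, 1)
})

test_that("Bland-Altman matches the hand-computed constant-offset case", {
  ref <- c(10, 12, 14); comp <- c(8, 10, 12)
  ba <- bland_altman(ref, comp, mode = "additive")
  expect_equal(ba$bias, 2.0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa, c(2, 2))       # degenerate: LoA collapse onto the bias
  expect_true(is.infinite(ba$t_statistic))
  expect_equal(ba$p_value, 0)
})

test_that("Bland-Altman agrees with a brute-force recomputation", {
  set.seed(8)
  ref <- rlnorm(40, log(50), 0.3)
  comp <- ref - 5 + rnorm(40, 0, 2)
  ba <- bland_altman(ref, comp, mode = "additive")
  d <- ref - comp
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa, mean(d) + c(-1.96, 1.96) * sd(d))
  expect_equal(ba$t_statistic, mean(d) / (sd(d) / sqrt(40)))
  expect_equal(ba$p_value, t.test(d)$p.value)

  compm <- ref * 3 * exp(rnorm(40, 0, 0.05))
  bam <- bland_altman(ref, compm, mode = "multiplicative")
  ld <- log(compm) - log(ref)
  expect_equal(bam$bias_factor, exp(mean(ld)))
  expect_equal(bam$p_value, t.test(log(ref) - log(compm))$p.value)
})

test_that("multiplicative mode refuses non-positive values, naming the pairs", {
  ref <- c(10, 12, 0, 14); comp <- c(8, 10, 12, 14)
  expect_error(bland_altman(ref, comp, mode = "multiplicative"),
               "strictly positive")
  expect_error(bland_altman(c(3, 4, 5), c(1, 2), mode = "additive"),
               "pairs|length")
})

test_that("adjustment restores exact equality for constant biases", {
  iams <- c(80, 120, 160, 95)
  # ELISA uniformly 47.93 below the IAMS values
  elisa <- iams - 47.93
  ba <- bland_altman(iams, elisa, mode = "additive", analyte = "APOA4")
  expect_equal(ba$bias, 47.93)
  expect_equal(apply_adjustment(elisa, ba), iams)

  # ELISA uniformly 9.52x the IAMS values
  elisa2 <- iams * 9.52
  ba2 <- bland_altman(iams, elisa2, mode = "multiplicative")
  expect_equal(ba2$bias_factor, 9.52)
  expect_equal(apply_adjustment(elisa2, ba2), iams)

  # zero bias leaves the input untouched
  ba0 <- bland_altman(iams, iams, mode = "additive")
  expect_equal(apply_adjustment(elisa, ba0), elisa)

  expect_error(apply_adjustment(elisa, ba, analyte = "CD5L"), "applied to")
})

test_that("post-adjustment bias is zero to 1e-10 on noisy cohorts", {
  set.seed(17)
  for (mode in c("additive", "multiplicative")) {
    ref <- rlnorm(100, log(100), 0.3)
    comp <- if (mode == "additive") ref - 40 + rnorm(100, 0, 5)
            else ref * 9 * exp(rnorm(100, 0, 0.05))
    ba <- bland_altman(ref, comp, mode = mode)
    adj <- apply_adjustment(comp, ba)
    ba2 <- bland_altman(ref, adj, mode = mode)
    if (mode == "additive") expect_lt(abs(ba2$bias), 1e-10)
    else expect_lt(abs(log(ba2$bias_factor)), 1e-10)
  }
})

test_that("injected biases are recovered within 2 SE on n = 100 cohorts", {
  spec <- cohort_spec(n_subjects = 100, seed = 55)
  sim <- simulate_paired_cohort(spec)
  m <- sim$measurements
  for (a in c("APOA4", "CD5L")) {
    p <- m[m$analyte == a, ]
    ba <- bland_altman(p$iams_conc, p$elisa_conc, mode = "additive")
    se <- ba$sd_diff / sqrt(ba$n)
    expect_lt(abs(ba$bias - (-spec$bias[[a]])), 2 * se)
  }
  p <- m[m$analyte == "IBP3", ]
  ba <- bland_altman(p$iams_conc, p$elisa_conc, mode = "multiplicative")
  se <- ba$sd_diff / sqrt(ba$n)
  expect_lt(abs(log(ba$bias_factor) - log(spec$bias[["IBP3"]])), 2 * se)
})

test_that("risk scores follow the logistic form and its limits", {
  null_model <- risk_model(intercept = 0, apoa4 = 0, cd5l = 0, ibp3 = 0,
                           age = 0, hdl = 0, egfr = 0)
  inp <- list(apoa4 = 100, cd5l = 3, ibp3 = 0.5)
  cov <- list(age = 65, hdl = 1.3, egfr = 75)
  expect_equal(risk_score(inp, cov, null_model), 50.0)

  low <- risk_model(intercept = -1e6, apoa4 = 0, cd5l = 0, ibp3 = 0,
                    age = 0, hdl = 0, egfr = 0)
  expect_equal(risk_score(inp, cov, low), 0)

  # strictly increasing in an input with positive coefficient
  mdl <- risk_model()
  sweep <- vapply(seq(1, 8, by = 0.5), function(v)
    risk_score(list(apoa4 = 100, cd5l = v, ibp3 = 0.5), cov, mdl),
    numeric(1))
  expect_true(all(diff(sweep) > 0))
  # and decreasing in one with negative coefficient
  sweep2 <- vapply(seq(40, 120, by = 10), function(v)
    risk_score(list(apoa4 = 100, cd5l = 3, ibp3 = 0.5),
               list(age = 65, hdl = 1.3, egfr = v), mdl), numeric(1))
  expect_true(all(diff(sweep2) < 0))

  expect_error(risk_score(list(apoa4 = 100, cd5l = 3), cov, mdl), "ibp3")
  expect_error(predict(mdl, data.frame(apoa4 = 1, cd5l = 1, ibp3 = 1,
                                       age = NA, hdl = 1, egfr = 1)),
               "age")
})

test_that("concordance applies the strict >90% within-5-points rule", {
  set.seed(3)
  a <- runif(100, 5, 60)
  same <- concordance_summary(a, a)
  expect_equal(same$r, 1)
  expect_equal(same$fraction_within, 1)
  expect_equal(same$verdict, "pass")

  # 89 within / 11 outside fails; 91 within / 9 outside passes
  b89 <- a; b89[1:11] <- a[1:11] + 6
  expect_equal(concordance_summary(a, b89)$verdict, "fail")
  b91 <- a; b91[1:9] <- a[1:9] + 6
  expect_equal(concordance_summary(a, b91)$verdict, "pass")

  # fraction invariant to adding a common constant to both lists
  s <- concordance_summary(a, b91)
  s2 <- concordance_summary(a + 12.5, b91 + 12.5)
  expect_equal(s2$fraction_within, s$fraction_within)

  # zero variance: R undefined, verdict still computed
  z <- concordance_summary(rep(10, 5), rep(10, 5))
  expect_true(is.na(z$r))
  expect_equal(z$verdict, "pass")
})
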