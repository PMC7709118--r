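# Small in-code fixtures shared across the suite.

# one light + one heavy transition row
tr_row <- function(sample, role, protein, label, area, bg,
                   peptide = paste0(protein, "_P1")) {
  data.frame(sample = sample, role = role, protein = protein,
             peptide = peptide, label = label,
             total_area = area, total_background = bg,
             stringsAsFactors = FALSE)
}

# a well = light + heavy pair with given areas/backgrounds
tr_well <- function(sample, role, protein, light, heavy,
                    bg_light = light / 50, bg_heavy = heavy / 50) {
  rbind(tr_row(sample, role, protein, "light", light, bg_light),
        tr_row(sample, role, protein, "heavy", heavy, bg_heavy))
}

# a tiny exact IAMS batch: calibrators at ratio cal_ratio, samples at
# given ratios, heavy area fixed at 1e6
tiny_iams_batch <- function(protein = "APOA4", cal_ratio = 1,
                            sample_ratios = c(S1 = 0.5, S2 = 1.2),
                            n_cal = 4) {
  rows <- list()
  for (r in seq_len(n_cal))
    rows[[length(rows) + 1L]] <-
      tr_well(sprintf("CAL_%d", r), "calibrator", protein,
              light = cal_ratio * 1e6, heavy = 1e6)
  for (s in names(sample_ratios))
    rows[[length(rows) + 1L]] <-
      tr_well(s, "sample", protein,
              light = sample_ratios[[s]] * 1e6, heavy = 1e6)
  do.call(rbind, rows)
}

# a noiseless response model (ratios exact)
noiseless_response <- function(...) {
  crossmark::iams_response(heavy_cv = 0, ratio_cv = 0, ...)
}

# exact 7-point standards for a 4PL curve
exact_standards <- function(p = c(a = 0.06, b = 1.1, c = 53.1, d = 1.86),
                            top = 425) {
  x <- top / 2^(6:0)
  data.frame(nominal_conc = x,
             od450 = crossmark::fourpl(x, p["a"], p["b"], p["c"], p["d"]))
}
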