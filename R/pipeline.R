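#' Run the full cross-platform pipeline on a synthetic cohort
#'
#' End-to-end, reproducible run driven by a [default_config()]:
#' \enumerate{
#'   \item generate the cohort truth and covariates;
#'   \item simulate IAMS batches (96-well capacity, 4 calibrators, 4
#'     reference-plasma wells, blanks per batch), quantify each via
#'     S/N-filtered light/heavy ratios and the calibrator response factor,
#'     and gate each batch on the reference plasma against the rolling
#'     mean +/- 2 SD ledger;
#'   \item simulate one ELISA plate set per analyte on the ELISA's own
#'     (biased) scale, fit 7-point 4PL curves, check plate QC, quantify
#'     wells and rescale to plasma;
#'   \item merge per-subject paired concentrations, estimate the
#'     inter-platform bias per analyte with [bland_altman()] in the
#'     configured mode, test it against zero, and adjust the ELISA values;
#'   \item compute risk scores per subject on both platforms (adjusted
#'     ELISA) and summarise concordance against the allowable-difference
#'     rule.
#' }
#' Deterministic for a fixed config: every stage draws from a substream of
#' the config seed.
#'
#' @param config a `"crossmark_config"`
#' @param out_dir optional directory; when given, concentration tables, the
#'   QC ledger, Bland-Altman summaries and the concordance report are
#'   written there as delimited text
#' @return list of class `"crossmark_run"` with elements truth,
#'   iams_concentrations, elisa_concentrations, qc (ledger + decisions),
#'   plates, bland_altman (per analyte), paired, scores, concordance
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "crossmark_config"))
  reg <- config$registry
  spec <- config$cohort
  truth <- generate_cohort(spec)
  ref_concs <- spec$medians

  ## --- IAMS batches -------------------------------------------------------
  cap <- config$layout$n_wells - config$layout$n_cal - config$layout$n_ref -
    config$layout$n_blank - 1L
  idx <- split(seq_len(nrow(truth)), ceiling(seq_len(nrow(truth)) / cap))
  history <- qc_history(reg$protein)
  decisions <- list()
  iams_rows <- list()
  for (b in seq_along(idx)) {
    batch <- simulate_iams_batch(truth[idx[[b]], , drop = FALSE],
                                 layout = config$layout,
                                 response = iams_response(
                                   ratio_cv = spec$iams_cv,
                                   registry = reg),
                                 registry = reg, ref_concs = ref_concs,
                                 seed = substream(config$seed, 10L + b))
    q <- quantify_iams_batch(batch, registry = reg,
                             sn_threshold = config$sn_threshold,
                             cal_cv_limit = config$cal_cv_limit)
    ref <- q[q$role == "reference_plasma" & !is.na(q$concentration), ]
    dec <- gate_batch(history, split(ref$concentration, ref$protein),
                      batch_id = sprintf("B%02d", b),
                      k = config$qc_k, min_history = config$qc_min_history)
    history <- update_history(history, dec)
    decisions[[b]] <- dec
    q$batch_id <- sprintf("B%02d", b)
    iams_rows[[b]] <- q
  }
  iams_all <- do.call(rbind, iams_rows)
  iams_smp <- iams_all[iams_all$role == "sample", , drop = FALSE]

  ## --- ELISA plates -------------------------------------------------------
  apparent <- elisa_apparent(truth, spec)
  elisa_rows <- list(); plates <- list()
  for (i in seq_len(nrow(reg))) {
    a <- reg$protein[i]
    pc <- stats::setNames(apparent[[tolower(a)]] *
                            lnoise_seeded(nrow(truth), spec$elisa_cv,
                                          substream(config$seed, 30L + i)),
                          truth$subject)
    plate <- simulate_elisa_plate(pc, a, config$curves[[a]],
                                  od_sd = config$od_sd, registry = reg,
                                  seed = substream(config$seed, 40L + i))
    res <- quantify_elisa_plate(plate)
    plates[[a]] <- res
    elisa_rows[[a]] <- res$concentrations
  }
  elisa_all <- do.call(rbind, elisa_rows)

  ## --- harmonisation ------------------------------------------------------
  ba <- list(); paired <- list()
  for (a in reg$protein) {
    im <- iams_smp[iams_smp$protein == a, c("sample", "concentration")]
    el <- elisa_all[elisa_all$protein == a, c("sample", "concentration")]
    names(im)[2] <- "iams_conc"; names(el)[2] <- "elisa_conc"
    p <- merge(im, el, by = "sample")
    p <- p[is.finite(p$iams_conc) & is.finite(p$elisa_conc) &
             p$iams_conc > 0 & p$elisa_conc > 0, ]
    fit <- bland_altman(p$iams_conc, p$elisa_conc,
                        mode = config$bias_mode[[a]], analyte = a)
    p$elisa_adjusted <- apply_adjustment(p$elisa_conc, fit, analyte = a)
    p$analyte <- a
    ba[[a]] <- fit; paired[[a]] <- p
  }
  paired_all <- do.call(rbind, paired)

  ## --- risk scores and concordance ---------------------------------------
  wide <- function(col) {
    w <- stats::reshape(paired_all[c("sample", "analyte", col)],
                        idvar = "sample", timevar = "analyte",
                        direction = "wide")
    names(w) <- sub(paste0(col, "."), "", names(w), fixed = TRUE)
    names(w) <- tolower(names(w))
    w
  }
  cov <- truth[c("subject", "age", "hdl", "egfr")]
  names(cov)[1] <- "sample"
  mk_scores <- function(col) {
    w <- merge(wide(col), cov, by = "sample")
    w <- w[stats::complete.cases(w), ]
    data.frame(sample = w$sample,
               score = predict(config$risk_model, w),
               stringsAsFactors = FALSE)
  }
  s_iams <- mk_scores("iams_conc")
  s_elisa <- mk_scores("elisa_adjusted")
  scores <- merge(s_iams, s_elisa, by = "sample",
                  suffixes = c("_iams", "_elisa"))
  conc <- concordance_summary(scores$score_iams, scores$score_elisa,
                              allowable_diff = config$allowable_diff,
                              pass_threshold = config$pass_threshold)

  run <- structure(
    list(config = config, truth = truth,
         iams_concentrations = iams_all,
         elisa_concentrations = elisa_all,
         plates = plates,
         qc = list(history = history, decisions = decisions),
         bland_altman = ba, paired = paired_all,
         scores = scores, concordance = conc),
    class = "crossmark_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# seeded multiplicative noise helper for pipeline sub-streams
lnoise_seeded <- function(n, cv, seed) with_seed(seed, lnoise(n, cv))

#' Write the artifacts of a pipeline run
#'
#' @param run a `"crossmark_run"`
#' @param out_dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    iams = file.path(out_dir, "iams_concentrations.tsv"),
    elisa = file.path(out_dir, "elisa_concentrations.tsv"),
    paired = file.path(out_dir, "paired_adjusted.tsv"),
    scores = file.path(out_dir, "risk_scores.tsv"),
    qc = file.path(out_dir, "qc_history.tsv"),
    report = file.path(out_dir, "report.txt")
  )
  write_concentration_table(run$iams_concentrations, paths["iams"])
  write_concentration_table(run$elisa_concentrations, paths["elisa"])
  write_concentration_table(run$paired, paths["paired"])
  write_concentration_table(run$scores, paths["scores"])
  write_qc_history(run$qc$history, paths["qc"])
  con <- file(paths["report"], "w"); on.exit(close(con))
  sink(con); print(run); sink()
  invisible(paths)
}

#' @export
print.crossmark_run <- function(x, ...) {
  cat("crossmark pipeline run (seed", x$config$seed, ")\n")
  cat(sprintf("  cohort: %d subjects\n", nrow(x$truth)))
  for (d in x$qc$decisions)
    cat(sprintf("  QC %s: %s\n", d$batch_id, d$decision))
  for (a in names(x$bland_altman)) {
    b <- x$bland_altman[[a]]
    if (b$mode == "additive")
      cat(sprintf("  %s: additive bias %+.3f ug/mL (p = %.3g)\n",
                  a, b$bias, b$p_value))
    else
      cat(sprintf("  %s: bias factor %.3f (p = %.3g)\n",
                  a, b$bias_factor, b$p_value))
  }
  print(x$concordance)
  invisible(x)
}
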