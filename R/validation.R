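cv_pct <- function(x) 100 * stats::sd(x) / mean(x)

#' Linearity of a dilution series
#'
#' Ordinary least squares of measured on nominal concentration across a
#' recombinant-protein dilution series, with per-level mean accuracy
#' (measured/nominal, %) and per-level CV.
#'
#' @param nominal nominal concentrations (one entry per replicate)
#' @param measured measured concentrations, same length
#' @param min_levels minimum number of distinct levels (default 5)
#' @return list: r_squared, slope, intercept, per_level (data.frame with
#'   nominal, n, accuracy_pct, cv_pct)
#' @export
linearity <- function(nominal, measured, min_levels = 5L) {
  stopifnot(length(nominal) == length(measured))
  lv <- sort(unique(nominal))
  if (length(lv) < min_levels)
    stop("linearity needs >= ", min_levels, " distinct levels (got ",
         length(lv), ")")
  fit <- stats::lm(measured ~ nominal)
  per <- do.call(rbind, lapply(lv, function(l) {
    m <- measured[nominal == l]
    data.frame(nominal = l, n = length(m),
               accuracy_pct = 100 * mean(m) / l,
               cv_pct = if (length(m) > 1) cv_pct(m) else NA_real_)
  }))
  list(r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       per_level = per)
}

#' Estimate LOD and LOQ from a dilution series
#'
#' The paper-style tables report LODs without a formula, so the rules used
#' here are explicit and returned with the estimates:
#' \itemize{
#'   \item LOD: the lowest level at which every replicate is detected.
#'     Detection is (a) a supplied logical, or (b) signal S/N above
#'     `sn_threshold` when `signal` and `background` are given (MRM-style),
#'     or (c) signal above mean(blanks) + 3 SD(blanks) when `blanks` are
#'     given (ELISA-style). With no detection information all levels count
#'     as detected, so LOD is the lowest tested level.
#'   \item LOQ: the lowest level quantified with mean accuracy within
#'     `accuracy_tol` of nominal and replicate CV below `cv_tol` (FDA
#'     ligand-binding 20%/20% defaults).
#' }
#'
#' @param nominal,measured dilution series (one entry per replicate)
#' @param detected optional logical per replicate
#' @param signal,background optional per-replicate raw signal and background
#' @param blanks optional vector of blank signals
#' @param sn_threshold S/N detection threshold (default 5)
#' @param accuracy_tol,cv_tol LOQ criteria as fractions (default 0.20)
#' @return list: lod, loq (NA with note "above tested range" when no level
#'   qualifies), lod_rule, loq_rule
#' @export
estimate_lod_loq <- function(nominal, measured, detected = NULL,
                             signal = NULL, background = NULL, blanks = NULL,
                             sn_threshold = 5,
                             accuracy_tol = 0.20, cv_tol = 0.20) {
  stopifnot(length(nominal) == length(measured))
  if (is.null(detected)) {
    if (!is.null(blanks) && !is.null(signal)) {
      thr <- mean(blanks) + 3 * stats::sd(blanks)
      detected <- signal > thr
      lod_rule <- sprintf("signal > mean(blank) + 3 SD = %.4g", thr)
    } else if (!is.null(signal) && !is.null(background)) {
      detected <- signal / background > sn_threshold
      lod_rule <- sprintf("S/N > %g", sn_threshold)
    } else {
      detected <- rep(TRUE, length(nominal))
      lod_rule <- "all levels detected (no blank/noise information)"
    }
  } else lod_rule <- "caller-supplied detection"
  lv <- sort(unique(nominal))
  det_lv <- vapply(lv, function(l) all(detected[nominal == l]), logical(1))
  lod <- if (any(det_lv)) min(lv[det_lv]) else NA_real_

  ok_lv <- vapply(lv, function(l) {
    m <- measured[nominal == l]
    acc_ok <- abs(mean(m) / l - 1) <= accuracy_tol
    cv_ok <- length(m) < 2 || cv_pct(m) < 100 * cv_tol
    acc_ok && cv_ok
  }, logical(1))
  loq <- if (any(ok_lv)) min(lv[ok_lv]) else NA_real_
  list(
    lod = lod, loq = loq,
    lod_rule = if (is.na(lod)) paste(lod_rule, "- above tested range") else lod_rule,
    loq_rule = sprintf("accuracy within %.0f%% and CV < %.0f%%%s",
                       100 * accuracy_tol, 100 * cv_tol,
                       if (is.na(loq)) " - above tested range" else "")
  )
}

#' Intra- and inter-assay precision
#'
#' Intra-assay CV is the average of the within-batch CVs (the "average % CV"
#' convention); inter-assay CV is the CV of the batch means. Both are
#' returned in percent. A single batch yields no inter-assay estimate.
#'
#' @param batches list of numeric vectors (replicate concentrations per
#'   batch) or a data.frame with columns `batch` and `value`
#' @return list: intra_cv_pct, inter_cv_pct (NA for one batch), n_batches
#' @export
precision <- function(batches) {
  if (is.data.frame(batches)) batches <- split(batches$value, batches$batch)
  if (any(vapply(batches, length, 1L) < 2L))
    stop("every batch needs >= 2 replicates")
  within <- vapply(batches, cv_pct, numeric(1))
  means <- vapply(batches, mean, numeric(1))
  list(
    intra_cv_pct = mean(within),
    inter_cv_pct = if (length(batches) >= 2L) 100 * stats::sd(means) / mean(means)
                   else NA_real_,
    n_batches = length(batches)
  )
}

#' Compare a stressed stability arm with its baseline
#'
#' %difference = 100 x (stressed mean - baseline mean) / baseline mean.
#' Verdict "pass" under the FDA ligand-binding criteria: absolute
#' %difference at most `accuracy_tol_pct` and both arms' CV below
#' `cv_tol_pct`.
#'
#' @param baseline,stressed numeric vectors of replicate concentrations
#'   (>= 2 each)
#' @param accuracy_tol_pct,cv_tol_pct criteria in percent (default 20)
#' @return list: pct_difference, cv_baseline_pct, cv_stressed_pct, verdict
#'   ("pass"/"fail")
#' @export
stability_compare <- function(baseline, stressed,
                              accuracy_tol_pct = 20, cv_tol_pct = 20) {
  if (length(baseline) < 2L || length(stressed) < 2L)
    stop("each arm needs >= 2 replicates")
  mb <- mean(baseline)
  if (mb == 0) stop("baseline mean is zero; %difference undefined")
  pct <- 100 * (mean(stressed) - mb) / mb
  cvb <- cv_pct(baseline); cvs <- cv_pct(stressed)
  list(
    pct_difference = pct, cv_baseline_pct = cvb, cv_stressed_pct = cvs,
    verdict = if (abs(pct) <= accuracy_tol_pct &&
                  cvb < cv_tol_pct && cvs < cv_tol_pct) "pass" else "fail"
  )
}

#' Average CV across freeze-thaw cycles
#'
#' ELISA-style freeze-thaw summary: for each plasma sample, the CV of its
#' measurements across the 0x..3x cycle arms; reported as the average over
#' samples.
#'
#' @param measurements data.frame with columns `sample`, `cycle`, `value`
#' @return average CV in percent
#' @export
freeze_thaw_cv <- function(measurements) {
  per <- vapply(split(measurements$value, measurements$sample), cv_pct,
                numeric(1))
  mean(per)
}

#' Assemble a validation report for one analyte
#'
#' Bundles linearity, LOD/LOQ, precision and stability verdicts into a
#' single structure with a readable print method.
#'
#' @param analyte analyte name
#' @param linearity result of [linearity()]
#' @param lod_loq result of [estimate_lod_loq()]
#' @param precision result of [precision()]
#' @param stability named list of [stability_compare()] results (one per
#'   condition)
#' @param working_range numeric length-2 plasma working range (ug/mL)
#' @return object of class `"validation_report"`
#' @export
validation_report <- function(analyte, linearity = NULL, lod_loq = NULL,
                              precision = NULL, stability = NULL,
                              working_range = NULL) {
  structure(
    list(analyte = analyte, linearity = linearity, lod_loq = lod_loq,
         precision = precision, stability = stability,
         working_range = working_range),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Assay validation:", x$analyte, "\n")
  if (!is.null(x$linearity))
    cat(sprintf("  linearity: R^2 = %.4f, slope = %.3f\n",
                x$linearity$r_squared, x$linearity$slope))
  if (!is.null(x$lod_loq))
    cat(sprintf("  LOD = %.4g (%s); LOQ = %.4g (%s)\n",
                x$lod_loq$lod, x$lod_loq$lod_rule,
                x$lod_loq$loq, x$lod_loq$loq_rule))
  if (!is.null(x$precision))
    cat(sprintf("  precision: intra %.1f%%, inter %s (n=%d batches)\n",
                x$precision$intra_cv_pct,
                if (is.na(x$precision$inter_cv_pct)) "NA"
                else sprintf("%.1f%%", x$precision$inter_cv_pct),
                x$precision$n_batches))
  if (!is.null(x$stability))
    for (nm in names(x$stability))
      cat(sprintf("  stability [%s]: %+.1f%% (%s)\n", nm,
                  x$stability[[nm]]$pct_difference, x$stability[[nm]]$verdict))
  if (!is.null(x$working_range))
    cat(sprintf("  working range: %.4g-%.4g ug/mL\n",
                x$working_range[1], x$working_range[2]))
  invisible(x)
}
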