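#' Bland-Altman agreement between two measurement platforms
#'
#' Additive mode works on paired differences d = reference - comparator
#' (here IAMS - ELISA): bias = mean(d), limits of agreement
#' bias +/- 1.96 sd(d), and the reported bias is the amount to ADD to the
#' comparator to centre it on the reference. Multiplicative mode works on
#' log-scale differences; the reported `bias_factor` is the geometric mean
#' of comparator/reference, i.e. the factor to DIVIDE the comparator by.
#' A two-sided one-sample t-test of mean difference = 0 is attached
#' (t = mean / (sd/sqrt(n)), df = n - 1). With zero-variance differences
#' the statistic degenerates: identical pairs give t = 0, p = 1; a constant
#' non-zero difference gives |t| = Inf, p = 0.
#'
#' @param reference,comparator paired concentration vectors (ug/mL);
#'   `reference` is the platform the comparator is adjusted towards
#' @param mode "additive" or "multiplicative"
#' @param analyte label carried through for reporting
#' @param conf_k half-width of the limits of agreement in SDs (default 1.96)
#' @return object of class `"bland_altman"`: analyte, mode, n, bias (additive
#'   ug/mL) or bias_factor (dimensionless), sd_diff, loa (length 2,
#'   back-transformed in multiplicative mode), t_statistic, p_value, and the
#'   per-pair differences and means for plotting
#' @export
bland_altman <- function(reference, comparator,
                         mode = c("additive", "multiplicative"),
                         analyte = NA_character_, conf_k = 1.96) {
  mode <- match.arg(mode)
  if (length(reference) != length(comparator))
    stop("reference and comparator must have the same length (paired design)")
  ok <- is.finite(reference) & is.finite(comparator)
  reference <- reference[ok]; comparator <- comparator[ok]
  n <- length(reference)
  if (n < 3L) stop("Bland-Altman needs >= 3 complete pairs (got ", n, ")")
  if (mode == "multiplicative") {
    bad <- which(reference <= 0 | comparator <= 0)
    if (length(bad))
      stop("multiplicative mode needs strictly positive values; offending pairs: ",
           paste(utils::head(bad, 10), collapse = ", "))
    d <- log(reference) - log(comparator)
  } else {
    d <- reference - comparator
  }
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t_stat <- m / (s / sqrt(n))
  }
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  res <- list(
    analyte = analyte, mode = mode, n = n,
    sd_diff = s,
    t_statistic = t_stat, p_value = p,
    differences = d,
    pair_means = if (mode == "multiplicative")
      exp((log(reference) + log(comparator)) / 2)
    else (reference + comparator) / 2
  )
  if (mode == "additive") {
    res$bias <- m
    res$loa <- m + c(-1, 1) * conf_k * s
  } else {
    # factor to divide the comparator by: geometric mean comparator/reference
    res$bias_factor <- exp(-m)
    res$loa <- exp(-m + c(-1, 1) * conf_k * s)
  }
  structure(res, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman [%s], %s mode, n = %d\n",
              x$analyte, x$mode, x$n))
  if (x$mode == "additive")
    cat(sprintf("  bias (add to comparator): %+.4g; LoA [%.4g, %.4g]\n",
                x$bias, x$loa[1], x$loa[2]))
  else
    cat(sprintf("  bias factor (divide comparator by): %.4g; LoA [%.4g, %.4g]\n",
                x$bias_factor, x$loa[1], x$loa[2]))
  cat(sprintf("  t = %.3g, p = %.3g (H0: zero mean difference)\n",
              x$t_statistic, x$p_value))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  d <- if (x$mode == "additive") x$differences else exp(-x$differences)
  centre <- if (x$mode == "additive") x$bias else x$bias_factor
  graphics::plot(x$pair_means, d,
                 xlab = "pair mean concentration",
                 ylab = if (x$mode == "additive") "difference (ref - comp)"
                        else "ratio (comp / ref)",
                 main = paste("Bland-Altman", x$analyte), ...)
  graphics::abline(h = centre, lty = 1)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Adjust comparator concentrations onto the reference scale
#'
#' Additive: adjusted = comparator + bias; multiplicative: adjusted =
#' comparator / bias_factor. After adjustment the mean difference (log-mean
#' in multiplicative mode) against the reference is zero by construction.
#'
#' @param comparator concentrations to adjust (ug/mL)
#' @param ba a `"bland_altman"` fitted on the same analyte
#' @param analyte optional analyte name, checked against `ba`
#' @return adjusted concentrations
#' @export
apply_adjustment <- function(comparator, ba, analyte = NULL) {
  stopifnot(inherits(ba, "bland_altman"))
  if (!is.null(analyte) && !is.na(ba$analyte) && !identical(analyte, ba$analyte))
    stop("adjustment fitted for ", ba$analyte, " applied to ", analyte)
  if (ba$mode == "additive") comparator + ba$bias
  else comparator / ba$bias_factor
}

#' Composite kidney-disease risk model
#'
#' A logistic model combining the three plasma biomarkers with age,
#' HDL-cholesterol and eGFR into a 0-100 risk score:
#' score = 100 x plogis(intercept + sum(coef_i x input_i)).
#' The published production coefficients are proprietary and not shipped;
#' the defaults below are a synthetic, documented placeholder with
#' clinically sensible directions (risk rises with age, CD5L and IGFBP3,
#' falls with APOA4, HDL and eGFR) intended for simulation and concordance
#' work, and can be replaced via the arguments or the run config.
#'
#' @param intercept,apoa4,cd5l,ibp3,age,hdl,egfr linear-predictor
#'   coefficients; concentrations in ug/mL, age in years, HDL in mmol/L,
#'   eGFR in mL/min/1.73m^2
#' @return object of class `"risk_model"`
#' @export
risk_model <- function(intercept = -2.0, apoa4 = -0.01, cd5l = 0.30,
                       ibp3 = 1.0, age = 0.03, hdl = -0.5, egfr = -0.02) {
  structure(
    list(coefficients = c(intercept = intercept, apoa4 = apoa4, cd5l = cd5l,
                          ibp3 = ibp3, age = age, hdl = hdl, egfr = egfr)),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Composite risk model (logistic link, 0-100 scale)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$coefficients

#' Compute risk scores
#'
#' @param model a `"risk_model"`
#' @param newdata data.frame with columns apoa4, cd5l, ibp3 (ug/mL), age,
#'   hdl, egfr; all must be present and finite
#' @param ... unused
#' @return numeric vector of scores in [0, 100]
#' @export
predict.risk_model <- function(object, newdata, ...) {
  need <- c("apoa4", "cd5l", "ibp3", "age", "hdl", "egfr")
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("missing input(s): ", paste(miss, collapse = ", "))
  for (f in need)
    if (any(!is.finite(newdata[[f]])))
      stop("non-finite values in input: ", f)
  b <- object$coefficients
  lp <- b["intercept"] +
    as.matrix(newdata[need]) %*% b[need]
  as.numeric(100 * stats::plogis(lp))
}

#' Risk score for one subject
#'
#' Convenience scalar interface over [predict.risk_model()].
#'
#' @param concs named vector/list with apoa4, cd5l, ibp3 (ug/mL)
#' @param covariates named vector/list with age, hdl, egfr
#' @param model a `"risk_model"`
#' @return score in [0, 100]
#' @export
risk_score <- function(concs, covariates, model = risk_model()) {
  df <- as.data.frame(c(as.list(concs), as.list(covariates)))
  names(df) <- tolower(names(df))
  predict(model, df)
}

#' Concordance of paired risk scores
#'
#' Pearson correlation of the paired scores and the fraction of subjects
#' whose absolute score difference is within `allowable_diff` percentage
#' points (scores live on a 0-100 scale, so "within 5%" is read as 5
#' absolute points). Verdict passes when that fraction, in percent, strictly
#' exceeds `pass_threshold`. Zero variance in either list leaves the
#' correlation undefined (NA) but the verdict is still computed.
#'
#' @param scores_a,scores_b paired score vectors (equal length, n >= 3)
#' @param allowable_diff allowable absolute difference in points (default 5)
#' @param pass_threshold required percentage of subjects within the
#'   allowable difference (default 90, strict inequality)
#' @return list of class `"concordance_summary"`: r, abs_differences,
#'   fraction_within, allowable_diff, pass_threshold, verdict
#' @export
concordance_summary <- function(scores_a, scores_b, allowable_diff = 5,
                                pass_threshold = 90) {
  stopifnot(length(scores_a) == length(scores_b))
  n <- length(scores_a)
  if (n < 3L) stop("concordance needs >= 3 paired scores")
  r <- if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) NA_real_
       else stats::cor(scores_a, scores_b)
  d <- abs(scores_a - scores_b)
  frac <- mean(d <= allowable_diff)
  structure(
    list(r = r, abs_differences = d, fraction_within = frac,
         allowable_diff = allowable_diff, pass_threshold = pass_threshold,
         n = n,
         verdict = if (100 * frac > pass_threshold) "pass" else "fail"),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Score concordance (n = %d): R = %s\n", x$n,
              if (is.na(x$r)) "undefined" else sprintf("%.3f", x$r)))
  cat(sprintf("  %.1f%% of subjects within %g points (need > %g%%): %s\n",
              100 * x$fraction_within, x$allowable_diff, x$pass_threshold,
              toupper(x$verdict)))
  invisible(x)
}
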