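#' Four-parameter logistic response
#'
#' OD = d + (a - d) / (1 + (x/c)^b). With b > 0 the curve rises from the
#' lower asymptote `a` at x = 0 to the upper asymptote `d`; `c` is the
#' inflection concentration (OD midway between the asymptotes).
#'
#' @param x concentration (ng/mL), non-negative
#' @param a,b,c,d 4PL parameters
#' @return predicted OD
#' @export
fourpl <- function(x, a, b, c, d) {
  d + (a - d) / (1 + (x / c)^b)
}

#' Fit a 4PL standard curve
#'
#' Unweighted least squares on OD via Levenberg-Marquardt
#' ([minpack.lm::nlsLM]). Starting values: a = min OD, d = max OD, c =
#' geometric mean of the standard concentrations, b = 1. At least five
#' distinct concentration levels are required; non-convergence raises an
#' error naming the analyte.
#'
#' @param standards data.frame with columns `nominal_conc` (ng/mL) and
#'   `od450`, or two numeric vectors via `nominal_conc`/`od450`
#' @param analyte analyte label for reporting
#' @return object of class `"std_curve"`: coefficients (a, b, c, d),
#'   `r_squared` on the standards, the standard data, and the working range
#'   (range of the standard concentrations)
#' @export
#' @examples
#' std <- data.frame(nominal_conc = 425 / 2^(6:0))
#' std$od450 <- fourpl(std$nominal_conc, 0.06, 1.1, 53, 1.86)
#' fit_4pl(std, analyte = "APOA4")
fit_4pl <- function(standards, analyte = NA_character_) {
  stopifnot(is.data.frame(standards),
            all(c("nominal_conc", "od450") %in% names(standards)))
  x <- standards$nominal_conc; y <- standards$od450
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("standards must be finite")
  if (length(unique(x)) < 5L)
    stop("fit_4pl needs >= 5 distinct concentration levels (got ",
         length(unique(x)), ")")
  start <- list(a = min(y), b = 1, c = exp(mean(log(x[x > 0]))), d = max(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(od450 ~ fourpl(nominal_conc, a, b, c, d),
                      data = standards, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("4PL fit failed for ", analyte, ": ",
                             conditionMessage(e))
  )
  p <- stats::coef(fit)
  resid <- y - fourpl(x, p["a"], p["b"], p["c"], p["d"])
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(
    list(analyte = analyte, coefficients = p, r_squared = r2,
         standards = standards,
         working_range = range(x[x > 0])),
    class = "std_curve"
  )
}

#' @export
coef.std_curve <- function(object, ...) object$coefficients

#' @export
print.std_curve <- function(x, ...) {
  p <- x$coefficients
  cat(sprintf("4PL standard curve [%s]\n", x$analyte))
  cat(sprintf("  a=%.4g  b=%.4g  c=%.4g ng/mL  d=%.4g   R^2=%.5f\n",
              p["a"], p["b"], p["c"], p["d"], x$r_squared))
  cat(sprintf("  working range: %.4g-%.4g ng/mL (%d standards)\n",
              x$working_range[1], x$working_range[2], nrow(x$standards)))
  invisible(x)
}

#' @export
predict.std_curve <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$standards$nominal_conc
       else if (is.data.frame(newdata)) newdata$nominal_conc
       else newdata
  p <- object$coefficients
  fourpl(x, p["a"], p["b"], p["c"], p["d"])
}

#' @export
plot.std_curve <- function(x, ...) {
  s <- x$standards
  xs <- exp(seq(log(min(s$nominal_conc[s$nominal_conc > 0]) / 2),
                log(max(s$nominal_conc) * 2), length.out = 200))
  graphics::plot(s$nominal_conc, s$od450, log = "x",
                 xlab = "concentration (ng/mL)", ylab = "OD450",
                 main = paste("4PL standard curve", x$analyte), ...)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' Invert a 4PL curve: OD to concentration
#'
#' Closed-form inverse x = c * ((a - d)/(od - d) - 1)^(1/b). ODs outside
#' the open interval between the asymptotes cannot be inverted and return
#' NA (the caller flags the well as out-of-curve).
#'
#' @param curve a `"std_curve"` (or a named vector with a, b, c, d)
#' @param od450 numeric vector of optical densities
#' @return concentrations (ng/mL), NA where od450 is out of curve
#' @export
invert_4pl <- function(curve, od450) {
  p <- if (inherits(curve, "std_curve")) curve$coefficients else curve
  lo <- min(p["a"], p["d"]); hi <- max(p["a"], p["d"])
  ok <- is.finite(od450) & od450 > lo & od450 < hi
  x <- rep(NA_real_, length(od450))
  x[ok] <- p["c"] * ((p["a"] - p["d"]) / (od450[ok] - p["d"]) - 1)^(1 / p["b"])
  x
}

#' Quantify one ELISA sample well
#'
#' Assay concentration is interpolated from the plate's standard curve and
#' scaled to plasma: plasma ug/mL = assay ng/mL x dilution_factor / 1000.
#' Wells whose OD falls outside the curve get an `out_of_curve` flag and no
#' value; assay concentrations outside the assay working range are flagged
#' (`below_lod` / `above_range`) but reported.
#'
#' @param curve a `"std_curve"`
#' @param well one-row data.frame with `od450` and `dilution_factor` (and
#'   `sample` if available)
#' @return one-row data.frame: sample, protein, assay_conc (ng/mL),
#'   concentration (plasma ug/mL), flags
#' @export
quantify_well <- function(curve, well) {
  assay <- invert_4pl(curve, well$od450)
  flags <- character(0)
  conc <- NA_real_
  if (is.na(assay)) {
    flags <- "out_of_curve"
  } else {
    if (assay < curve$working_range[1]) flags <- c(flags, "below_lod")
    if (assay > curve$working_range[2]) flags <- c(flags, "above_range")
    conc <- assay * well$dilution_factor / 1000
  }
  data.frame(
    sample = if ("sample" %in% names(well)) well$sample else NA_character_,
    protein = curve$analyte,
    assay_conc = assay, concentration = conc,
    flags = paste(flags, collapse = ","), stringsAsFactors = FALSE
  )
}

#' Check plate QC wells against their nominals
#'
#' The plate passes when every QC well back-calculates to within
#' `tolerance` (default +/-20%, the FDA ligand-binding accuracy criterion)
#' of its nominal concentration.
#'
#' @param curve a `"std_curve"`
#' @param qc_wells data.frame of wells with role `qc_low`/`qc_high`,
#'   columns `od450` and `nominal_conc` (ng/mL)
#' @param tolerance maximum fractional recovery error (default 0.20)
#' @return list: pass (logical), recoveries (fraction of nominal per well),
#'   tolerance
#' @export
check_plate_qc <- function(curve, qc_wells, tolerance = 0.20) {
  if (!all(c("qc_low", "qc_high") %in% qc_wells$role))
    stop("plate QC requires at least one qc_low and one qc_high well")
  back <- invert_4pl(curve, qc_wells$od450)
  rec <- back / qc_wells$nominal_conc
  pass <- all(is.finite(rec)) && all(abs(rec - 1) <= tolerance)
  list(pass = pass, recoveries = stats::setNames(rec, qc_wells$role),
       tolerance = tolerance)
}

#' Quantify a full ELISA plate
#'
#' Fits the 7-point standard curve from the plate's standard wells, checks
#' the low/high QC wells, then interpolates every sample well and converts
#' to plasma concentration with that analyte's dilution factor.
#'
#' @param plate plate table (see [read_plate_table()]) for one analyte
#' @param qc_tolerance QC recovery tolerance (default 0.20)
#' @param r2_min minimum standard-curve R^2 for the plate to pass
#'   (default 0.99)
#' @return list of class `"elisa_plate_result"`: curve, qc, plate_pass,
#'   concentrations (data.frame)
#' @export
quantify_elisa_plate <- function(plate, qc_tolerance = 0.20, r2_min = 0.99) {
  analyte <- unique(plate$analyte)
  if (length(analyte) != 1L) stop("one plate must carry a single analyte")
  std <- plate[plate$role == "standard", , drop = FALSE]
  curve <- fit_4pl(data.frame(nominal_conc = std$nominal_conc,
                              od450 = std$od450), analyte = analyte)
  qc <- check_plate_qc(curve, plate[plate$role %in% c("qc_low", "qc_high"), ,
                                    drop = FALSE],
                       tolerance = qc_tolerance)
  smp <- plate[plate$role == "sample", , drop = FALSE]
  concs <- do.call(rbind, lapply(seq_len(nrow(smp)), function(j)
    quantify_well(curve, smp[j, ])))
  rownames(concs) <- NULL
  structure(
    list(curve = curve, qc = qc,
         plate_pass = qc$pass && curve$r_squared >= r2_min,
         concentrations = concs),
    class = "elisa_plate_result"
  )
}

#' @export
print.elisa_plate_result <- function(x, ...) {
  print(x$curve)
  cat(sprintf("  QC recoveries: %s -> %s\n",
              paste(sprintf("%s %.0f%%", names(x$qc$recoveries),
                            100 * x$qc$recoveries), collapse = ", "),
              if (x$plate_pass) "plate PASS" else "plate FAIL"))
  cat(sprintf("  %d sample wells quantified\n", nrow(x$concentrations)))
  invisible(x)
}
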