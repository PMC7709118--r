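#' Effective plasma concentration represented by a calibrator well
#'
#' A calibrator solution processed at a larger volume than the plasma
#' samples represents a proportionally higher plasma-equivalent
#' concentration: `conc * v_cal / v_plasma`. With the standard layout
#' (50 uL calibrator vs 10 uL plasma) an 18.3 ug/mL APOA4 solution
#' represents 91.5 ug/mL in plasma.
#'
#' @param cal_solution_conc calibrator solution concentration (ug/mL)
#' @param v_cal calibrator volume processed (uL)
#' @param v_plasma plasma volume processed (uL)
#' @return plasma-equivalent concentration (ug/mL)
#' @export
#' @examples
#' effective_plasma_concentration(18.3, 50, 10)  # 91.5
effective_plasma_concentration <- function(cal_solution_conc, v_cal, v_plasma) {
  if (any(!is.finite(v_cal)) || any(v_cal <= 0))
    stop("v_cal must be positive")
  if (any(!is.finite(v_plasma)) || any(v_plasma <= 0))
    stop("v_plasma must be positive")
  cal_solution_conc * v_cal / v_plasma
}

# S/N of an integrated peak: Total Area / Total Background. Zero background
# with positive area is treated as infinite S/N (passes); 0/0 is NaN and
# handled upstream as a missing record.
.sn <- function(area, background) {
  ifelse(background > 0, area / background,
         ifelse(area > 0, Inf, NaN))
}

#' Light/heavy peptide ratio for one sample x peptide
#'
#' Aggregates the transition records of a single sample and peptide: areas
#' and backgrounds are summed per label (robust when several transitions are
#' monitored per peptide), S/N = total area / total background is computed
#' per label, and the unlabelled:labelled (light/heavy) area ratio is
#' reported only when both labels clear the S/N threshold.
#'
#' A missing light or heavy record yields a row flagged `missing`, never an
#' error, so a single dropped peak does not abort a batch.
#'
#' @param records data.frame of transition records for one sample x peptide
#'   with columns `sample`, `role`, `protein`, `peptide`, `label`
#'   ("light"/"heavy"), `total_area`, `total_background`
#' @param sn_threshold minimum S/N for both labels (default 5)
#' @return one-row data.frame: sample, role, protein, light_area, heavy_area,
#'   sn_light, sn_heavy, passed_sn, ratio (NA unless passed), flag
#'   ("" | "sn_fail" | "missing")
#' @export
compute_peptide_ratio <- function(records, sn_threshold = 5) {
  stopifnot(is.data.frame(records))
  if (any(records$total_area < 0) || any(records$total_background < 0))
    stop("areas and backgrounds must be non-negative")
  out <- data.frame(
    sample = records$sample[1], role = records$role[1],
    protein = records$protein[1],
    light_area = NA_real_, heavy_area = NA_real_,
    sn_light = NA_real_, sn_heavy = NA_real_,
    passed_sn = FALSE, ratio = NA_real_, flag = "missing",
    stringsAsFactors = FALSE
  )
  light <- records[records$label == "light", , drop = FALSE]
  heavy <- records[records$label == "heavy", , drop = FALSE]
  if (nrow(light) == 0L || nrow(heavy) == 0L) return(out)

  la <- sum(light$total_area);  lb <- sum(light$total_background)
  ha <- sum(heavy$total_area);  hb <- sum(heavy$total_background)
  sl <- .sn(la, lb); sh <- .sn(ha, hb)
  if (is.nan(sl) || is.nan(sh)) return(out)  # both area and background zero

  out$light_area <- la; out$heavy_area <- ha
  out$sn_light <- sl; out$sn_heavy <- sh
  if (sl > sn_threshold && sh > sn_threshold) {
    out$passed_sn <- TRUE
    out$ratio <- la / ha
    out$flag <- ""
  } else {
    out$flag <- "sn_fail"
  }
  out
}

#' Light/heavy ratios for a whole transition table
#'
#' Applies [compute_peptide_ratio()] to every (sample, peptide) group of a
#' transition report.
#'
#' @inheritParams compute_peptide_ratio
#' @param transitions full transition table (see [read_transition_report()])
#' @return data.frame with one row per sample x protein
#' @export
peptide_ratios <- function(transitions, sn_threshold = 5) {
  key <- interaction(transitions$sample, transitions$peptide, drop = TRUE)
  rows <- lapply(split(transitions, key), compute_peptide_ratio,
                 sn_threshold = sn_threshold)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$protein, out$sample), , drop = FALSE]
}

#' Calibrate a response factor from calibrator replicate ratios
#'
#' Calibrator replicate light/heavy ratios are averaged; the mean ratio
#' together with the calibrator's effective plasma concentration defines the
#' response factor used to convert sample ratios to concentrations. Fewer
#' than two S/N-passing replicates, or a replicate CV at or above
#' `cv_limit`, is a calibration failure that aborts the batch.
#'
#' @param ratios numeric vector of S/N-passing calibrator replicate ratios
#' @param effective_conc calibrator effective plasma concentration (ug/mL)
#' @param protein analyte name (carried through for reporting)
#' @param cv_limit maximum acceptable replicate CV (default 0.20, the FDA
#'   ligand-binding precision criterion)
#' @return list of class `"response_factor"`: protein,
#'   calibrator_effective_conc, mean_calibrator_ratio, replicate_cv, n
#' @export
calibrate <- function(ratios, effective_conc, protein = NA_character_,
                      cv_limit = 0.20) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2L)
    stop("calibration failure for ", protein,
         ": fewer than 2 S/N-passing calibrator replicates")
  m <- mean(ratios)
  cv <- stats::sd(ratios) / m
  if (cv >= cv_limit)
    stop(sprintf("calibration failure for %s: replicate CV %.1f%% >= %.0f%%",
                 protein, 100 * cv, 100 * cv_limit))
  structure(
    list(protein = protein,
         calibrator_effective_conc = effective_conc,
         mean_calibrator_ratio = m,
         replicate_cv = cv,
         n = length(ratios)),
    class = "response_factor"
  )
}

#' @export
print.response_factor <- function(x, ...) {
  cat(sprintf("Response factor [%s]: mean calibrator ratio %.4g (CV %.1f%%, n=%d) at %.4g ug/mL\n",
              x$protein, x$mean_calibrator_ratio, 100 * x$replicate_cv,
              x$n, x$calibrator_effective_conc))
  invisible(x)
}

#' Convert one peptide ratio to a plasma concentration
#'
#' concentration = effective calibrator concentration x (sample ratio /
#' mean calibrator ratio): the heavy peptide normalises signal across wells
#' and the calibrator anchors the scale. Results outside the analyte's
#' plasma working range are flagged (`below_lod` / `above_range`) but
#' reported, so downstream method-agreement analyses keep the values while
#' the flags carry the uncertainty. S/N-failed or missing inputs yield a
#' flagged result with no concentration.
#'
#' @param ratio_row one row as returned by [compute_peptide_ratio()]
#' @param rf a `"response_factor"`
#' @param range_lo,range_hi plasma working range bounds (ug/mL); NA disables
#'   the corresponding flag
#' @return one-row data.frame: sample, role, protein, concentration, flags
#'   (comma-separated subset of below_lod, above_range, sn_fail, missing)
#' @export
quantify <- function(ratio_row, rf, range_lo = NA_real_, range_hi = NA_real_) {
  stopifnot(inherits(rf, "response_factor"))
  out <- data.frame(
    sample = ratio_row$sample, role = ratio_row$role,
    protein = ratio_row$protein,
    concentration = NA_real_, flags = "", stringsAsFactors = FALSE
  )
  if (!isTRUE(ratio_row$passed_sn)) {
    out$flags <- ratio_row$flag   # sn_fail or missing
    return(out)
  }
  conc <- rf$calibrator_effective_conc * ratio_row$ratio / rf$mean_calibrator_ratio
  flags <- character(0)
  if (!is.na(range_lo) && conc < range_lo) flags <- c(flags, "below_lod")
  if (!is.na(range_hi) && conc > range_hi) flags <- c(flags, "above_range")
  out$concentration <- conc
  out$flags <- paste(flags, collapse = ",")
  out
}

#' Quantify a full IAMS transition report
#'
#' For each analyte: compute light/heavy ratios, calibrate the response
#' factor from the calibrator wells, then convert every non-calibrator
#' well's ratio to a plasma concentration with working-range flags.
#' Blank wells are quantified like samples and a warning is raised when a
#' blank's apparent concentration exceeds the analyte LOD.
#'
#' @param transitions transition table (see [read_transition_report()])
#' @param registry analyte registry ([analyte_registry()])
#' @param sn_threshold S/N acceptance threshold (default 5)
#' @param cal_cv_limit calibrator replicate CV limit (default 0.20)
#' @return data.frame of per-well concentrations with roles and flags; the
#'   response factors are attached as attribute `"response_factors"`
#' @export
quantify_iams_batch <- function(transitions, registry = analyte_registry(),
                                sn_threshold = 5, cal_cv_limit = 0.20) {
  ratios <- peptide_ratios(transitions, sn_threshold = sn_threshold)
  res <- list(); rfs <- list()
  for (i in seq_len(nrow(registry))) {
    prot <- registry$protein[i]
    rr <- ratios[ratios$protein == prot, , drop = FALSE]
    cal <- rr[rr$role == "calibrator" & rr$passed_sn, , drop = FALSE]
    rf <- calibrate(cal$ratio, registry$cal_effective_conc[i],
                    protein = prot, cv_limit = cal_cv_limit)
    rfs[[prot]] <- rf
    rest <- rr[rr$role != "calibrator", , drop = FALSE]
    q <- do.call(rbind, lapply(seq_len(nrow(rest)), function(j)
      quantify(rest[j, ], rf,
               range_lo = registry$iams_range_lo[i],
               range_hi = registry$iams_range_hi[i])))
    blank_hot <- q$role %in% c("blank", "double_blank") &
      !is.na(q$concentration) & q$concentration > registry$iams_lod[i]
    if (any(blank_hot))
      warning(sprintf("%s: %d blank well(s) above LOD (%.3g ug/mL)",
                      prot, sum(blank_hot), registry$iams_lod[i]))
    res[[prot]] <- q
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "response_factors") <- rfs
  out
}
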