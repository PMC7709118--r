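#' Analyte registry for the three-protein panel
#'
#' Returns the per-analyte constants the pipeline runs on: the peptide used
#' for MRM readout, the calibrator solution concentration and the effective
#' plasma concentration it represents (50 uL calibrator processed alongside
#' 10 uL plasma), the plasma working range and LOD of the immunoaffinity-MS
#' (IAMS) assay, and the ELISA assay working range (ng/mL), plasma dilution
#' factor and resulting plasma working range.
#'
#' All plasma concentrations are ug/mL; ELISA assay-level concentrations are
#' ng/mL. The registry is a plain data frame so an extended panel can be
#' passed anywhere a `registry` argument is accepted.
#'
#' @param v_cal calibrator volume processed per well (uL)
#' @param v_plasma plasma volume processed per well (uL)
#' @return data.frame with one row per analyte.
#' @export
#' @examples
#' analyte_registry()
analyte_registry <- function(v_cal = 50, v_plasma = 10) {
  reg <- data.frame(
    protein          = c("APOA4", "CD5L", "IBP3"),
    peptide          = c("APOA4_P1", "CD5L_P1", "IBP3_P1"),
    cal_solution_conc = c(18.3, 0.686, 0.178),   # ug/mL in the calibrator mix
    iams_range_lo    = c(37.5, 0.104, 0.0104),   # plasma ug/mL
    iams_range_hi    = c(200, 10.0, 1.00),
    iams_lod         = c(9.40, 0.100, 0.010),
    elisa_assay_lo   = c(6.64, 0.16, 0.63),      # assay ng/mL
    elisa_assay_hi   = c(425, 10, 40),
    dilution_factor  = c(400L, 1600L, 200L),
    stringsAsFactors = FALSE
  )
  reg$cal_effective_conc <- effective_plasma_concentration(
    reg$cal_solution_conc, v_cal, v_plasma
  )
  # plasma-equivalent ELISA working range implied by assay range x dilution
  reg$elisa_plasma_lo <- reg$elisa_assay_lo * reg$dilution_factor / 1000
  reg$elisa_plasma_hi <- reg$elisa_assay_hi * reg$dilution_factor / 1000
  reg
}

#' Default run configuration
#'
#' Bundles every tunable the pipeline consumes: the analyte registry, IAMS
#' plate layout, simulation/noise settings, S/N threshold, QC-gate
#' parameters, per-analyte Bland-Altman bias modes and the risk model.
#' Individual entries can be overridden via `...` (matched by name) or the
#' whole object loaded from a YAML file with [read_config()].
#'
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it (see [substream()])
#' @param ... named overrides of the defaults
#' @return a list of class `"crossmark_config"`
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed          = as.integer(seed),
    registry      = analyte_registry(),
    layout        = iams_layout(),
    sn_threshold  = 5,
    cal_cv_limit  = 0.20,
    cohort        = cohort_spec(seed = as.integer(seed)),
    curves        = default_curve_params(),
    od_sd         = 0.01,
    qc_min_history = 5L,
    qc_k          = 2,
    bias_mode     = c(APOA4 = "additive", CD5L = "additive",
                      IBP3 = "multiplicative"),
    risk_model    = risk_model(),
    allowable_diff = 5,
    pass_threshold = 90
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "crossmark_config"
  cfg
}

#' Derive a reproducible sub-seed from the master seed
#'
#' Stages of the pipeline (cohort generation, each IAMS batch, each ELISA
#' plate, ...) must draw from independent, reproducible streams. Streams are
#' indexed by small integers; the derived seed stays within 32-bit range.
#'
#' @param seed master seed (integer)
#' @param index stream index (non-negative integer)
#' @return an integer seed
#' @export
substream <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

#' Default 4PL curve parameters used to simulate ELISA plates
#'
#' One (a, b, c, d) set per analyte: `a` lower-asymptote OD, `d` upper, `c`
#' the inflection concentration (ng/mL, placed at the geometric centre of
#' the 7-point standard range), `b` the slope. The curves rise from about
#' 0.06 to 1.8 absorbance units across the standards.
#'
#' @return named list of numeric vectors `c(a, b, c, d)`
#' @export
default_curve_params <- function() {
  reg <- analyte_registry()
  out <- lapply(seq_len(nrow(reg)), function(i) {
    c(a = 0.06, b = 1.1,
      c = sqrt(reg$elisa_assay_lo[i] * reg$elisa_assay_hi[i]),
      d = 1.86)
  })
  names(out) <- reg$protein
  out
}
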