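# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# log-normal sigma for a given geometric CV
gcv_sigma <- function(gcv) sqrt(log(1 + gcv^2))

# multiplicative log-normal noise with unit median
lnoise <- function(n, cv) if (cv <= 0) rep(1, n) else
  stats::rlnorm(n, meanlog = 0, sdlog = gcv_sigma(cv))

#' Specification of a synthetic paired-platform cohort
#'
#' Describes the cohort the generator emulates: per-analyte true plasma
#' concentration distributions (log-normal, given as median and geometric
#' CV), clinical covariate distributions, per-platform measurement noise
#' and the per-analyte inter-platform bias (how the ELISA's own scale
#' relates to the reference IAMS scale: additive offset or multiplicative
#' factor applied to truth to give the ELISA-apparent concentration).
#'
#' Defaults place the medians near the middle of the assays' plasma working
#' ranges and the biases at the magnitudes the platform comparison is
#' designed around (ELISA-apparent = truth - 47.93 for APOA4, truth - 0.53
#' for CD5L, truth x 9.52 for IGFBP3).
#'
#' @param n_subjects number of subjects (>= 2)
#' @param medians,gcvs named per-analyte log-normal medians (ug/mL) and
#'   geometric CVs (fractions in (0,1))
#' @param age_mean,age_sd,hdl_median,hdl_gcv,egfr_mean,egfr_sd covariate
#'   distributions (age years, HDL mmol/L, eGFR mL/min/1.73m^2)
#' @param iams_cv,elisa_cv per-platform measurement CV (fraction)
#' @param bias_mode named per-analyte "additive" or "multiplicative"
#' @param bias named per-analyte magnitude: ug/mL offset added to truth
#'   (additive) or factor multiplying truth (multiplicative) to give the
#'   ELISA-apparent concentration
#' @param seed integer RNG seed
#' @return list of class `"cohort_spec"`
#' @export
cohort_spec <- function(n_subjects = 100L,
                        medians = c(APOA4 = 110, CD5L = 3.0, IBP3 = 0.45),
                        gcvs = c(APOA4 = 0.30, CD5L = 0.40, IBP3 = 0.40),
                        age_mean = 65, age_sd = 10,
                        hdl_median = 1.3, hdl_gcv = 0.25,
                        egfr_mean = 75, egfr_sd = 20,
                        iams_cv = 0.05, elisa_cv = 0.05,
                        bias_mode = c(APOA4 = "additive", CD5L = "additive",
                                      IBP3 = "multiplicative"),
                        bias = c(APOA4 = -47.93, CD5L = -0.53, IBP3 = 9.52),
                        seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("invalid cohort spec: n_subjects must be >= 2")
  if (any(medians <= 0)) stop("invalid cohort spec: medians must be > 0")
  if (any(gcvs <= 0 | gcvs >= 1))
    stop("invalid cohort spec: gcvs must lie in (0, 1)")
  for (cv in c(iams_cv, elisa_cv))
    if (cv < 0 || cv >= 1) stop("invalid cohort spec: platform CVs must lie in [0, 1)")
  if (!setequal(names(medians), names(gcvs)) ||
      !setequal(names(medians), names(bias_mode)) ||
      !setequal(names(medians), names(bias)))
    stop("invalid cohort spec: analyte names must agree across medians, gcvs, bias_mode, bias")
  if (!all(bias_mode %in% c("additive", "multiplicative")))
    stop("invalid cohort spec: bias_mode must be additive or multiplicative")
  structure(
    list(n_subjects = as.integer(n_subjects), medians = medians, gcvs = gcvs,
         age_mean = age_mean, age_sd = age_sd,
         hdl_median = hdl_median, hdl_gcv = hdl_gcv,
         egfr_mean = egfr_mean, egfr_sd = egfr_sd,
         iams_cv = iams_cv, elisa_cv = elisa_cv,
         bias_mode = bias_mode, bias = bias, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a cohort with known ground truth
#'
#' Draws each subject's true plasma concentrations (log-normal per analyte)
#' and clinical covariates. Age and eGFR are normal draws truncated to
#' plausible clinical ranges; HDL is log-normal. Deterministic for a fixed
#' spec (the spec carries the seed).
#'
#' @param spec a [cohort_spec()]
#' @return data.frame: subject, one column per analyte (true ug/mL, lower
#'   case names), age, hdl, egfr
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(substream(spec$seed, 1L), {
    out <- data.frame(subject = sprintf("S%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (a in names(spec$medians))
      out[[tolower(a)]] <- stats::rlnorm(n, log(spec$medians[[a]]),
                                         gcv_sigma(spec$gcvs[[a]]))
    out$age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd), 30), 95)
    out$hdl <- stats::rlnorm(n, log(spec$hdl_median), gcv_sigma(spec$hdl_gcv))
    out$egfr <- pmin(pmax(stats::rnorm(n, spec$egfr_mean, spec$egfr_sd), 10), 140)
    out
  })
}

#' ELISA-apparent plasma concentrations implied by the inter-platform bias
#'
#' Applies the spec's per-analyte bias to the true concentrations: additive
#' biases shift truth by the stated offset (floored at zero, since a
#' concentration cannot be negative), multiplicative biases scale it.
#'
#' @param truth cohort truth ([generate_cohort()])
#' @param spec the [cohort_spec()]
#' @return data.frame like `truth` with biased analyte columns
#' @export
elisa_apparent <- function(truth, spec) {
  out <- truth
  for (a in names(spec$bias)) {
    col <- tolower(a)
    out[[col]] <- if (spec$bias_mode[[a]] == "additive")
      pmax(truth[[col]] + spec$bias[[a]], 0)
    else truth[[col]] * spec$bias[[a]]
  }
  out
}

#' Standard IAMS 96-well batch layout
#'
#' Four calibrator replicates at 50 uL, four reference-plasma replicates at
#' 10 uL, PBS blanks, one double blank (no antibody beads), and up to the
#' remaining wells of 10 uL plasma samples; 400 fmol of each heavy peptide
#' is spiked into every digested well.
#'
#' @param n_cal,n_ref,n_blank replicate counts
#' @param v_cal,v_plasma,v_blank volumes (uL)
#' @param heavy_spike_fmol heavy peptide spike per well
#' @param n_wells plate capacity
#' @return list of class `"iams_layout"`
#' @export
iams_layout <- function(n_cal = 4L, n_ref = 4L, n_blank = 2L,
                        v_cal = 50, v_plasma = 10, v_blank = 50,
                        heavy_spike_fmol = 400, n_wells = 96L) {
  if (any(c(v_cal, v_plasma, v_blank) <= 0)) stop("volumes must be positive")
  structure(list(n_cal = n_cal, n_ref = n_ref, n_blank = n_blank,
                 n_double_blank = 1L,
                 v_cal = v_cal, v_plasma = v_plasma, v_blank = v_blank,
                 heavy_spike_fmol = heavy_spike_fmol, n_wells = n_wells),
            class = "iams_layout")
}

#' MRM response model for the simulator
#'
#' Maps a plasma concentration to an expected light/heavy area ratio,
#' linear through the origin (ratio = slope x concentration), as the
#' single-point calibrator normalisation presumes. Default slopes put the
#' calibrator ratio at 1. Heavy areas are drawn log-normally around a
#' nominal area; ratio noise is multiplicative log-normal on the light
#' area; backgrounds are drawn so typical S/N is far above the threshold.
#'
#' @param slope named per-analyte ratio per (ug/mL); NULL = 1/calibrator
#'   effective concentration
#' @param heavy_nominal_area nominal heavy peak area (arbitrary units)
#' @param heavy_cv CV of the heavy area between wells
#' @param ratio_cv CV of the measured ratio (the platform's analytical CV)
#' @param typical_sn typical signal-to-noise of real peaks
#' @param registry analyte registry
#' @return list of class `"iams_response"`
#' @export
iams_response <- function(slope = NULL, heavy_nominal_area = 1e6,
                          heavy_cv = 0.10, ratio_cv = 0.05,
                          typical_sn = 50, registry = analyte_registry()) {
  if (is.null(slope))
    slope <- stats::setNames(1 / registry$cal_effective_conc, registry$protein)
  structure(list(slope = slope, heavy_nominal_area = heavy_nominal_area,
                 heavy_cv = heavy_cv, ratio_cv = ratio_cv,
                 typical_sn = typical_sn),
            class = "iams_response")
}

# one well's light/heavy transition rows for every analyte
.iams_well_rows <- function(sample, role, concs, response, registry) {
  rows <- list()
  # chemical noise floor, independent of the analyte signal
  bg_floor <- response$heavy_nominal_area / (response$typical_sn * 10)
  for (i in seq_len(nrow(registry))) {
    prot <- registry$protein[i]
    heavy <- response$heavy_nominal_area * lnoise(1, response$heavy_cv)
    true_ratio <- response$slope[[prot]] * concs[[prot]]
    light <- true_ratio * heavy * lnoise(1, response$ratio_cv)
    bg_l <- bg_floor * stats::runif(1, 0.6, 1.4) + light / response$typical_sn
    bg_h <- bg_floor * stats::runif(1, 0.6, 1.4) + heavy / response$typical_sn
    # blank-type wells: light peak is just integrated background
    if (concs[[prot]] == 0) light <- bg_l * stats::runif(1, 0.5, 1.5)
    rows[[prot]] <- data.frame(
      sample = sample, role = role, protein = prot,
      peptide = registry$peptide[i],
      label = c("light", "heavy"),
      total_area = c(light, heavy),
      total_background = c(bg_l, bg_h),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate one IAMS batch as a transition-level report
#'
#' Emits one light and one heavy transition record per analyte for every
#' well of the layout: calibrators at their effective plasma
#' concentrations, reference-plasma replicates, blanks and the double
#' blank (near-background light signal), and one well per subject of
#' `truth`. With all noise terms at zero the light/heavy ratio equals
#' slope x concentration exactly.
#'
#' @param truth cohort truth rows to run on this plate (subject + analyte
#'   columns, lower case)
#' @param layout an [iams_layout()]
#' @param response an [iams_response()]
#' @param registry analyte registry
#' @param ref_concs named per-analyte reference-plasma concentrations
#'   (ug/mL); defaults to the registry medians used by [cohort_spec()]
#' @param seed RNG seed for this batch
#' @return transition table (data.frame) in the reader dialect of
#'   [read_transition_report()]
#' @export
simulate_iams_batch <- function(truth, layout = iams_layout(),
                                response = iams_response(),
                                registry = analyte_registry(),
                                ref_concs = c(APOA4 = 110, CD5L = 3.0,
                                              IBP3 = 0.45),
                                seed = 1L) {
  n_used <- nrow(truth) + layout$n_cal + layout$n_ref + layout$n_blank +
    layout$n_double_blank
  if (n_used > layout$n_wells)
    stop("layout overflow: ", n_used, " wells needed, plate holds ",
         layout$n_wells)
  cal_eff <- stats::setNames(
    effective_plasma_concentration(registry$cal_solution_conc,
                                   layout$v_cal, layout$v_plasma),
    registry$protein)
  zero <- stats::setNames(rep(0, nrow(registry)), registry$protein)
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(layout$n_cal))
      rows[[length(rows) + 1L]] <-
        .iams_well_rows(sprintf("CAL_%d", r), "calibrator", cal_eff,
                        response, registry)
    for (r in seq_len(layout$n_ref))
      rows[[length(rows) + 1L]] <-
        .iams_well_rows(sprintf("REF_%d", r), "reference_plasma", ref_concs,
                        response, registry)
    for (r in seq_len(layout$n_blank))
      rows[[length(rows) + 1L]] <-
        .iams_well_rows(sprintf("BLANK_%d", r), "blank", zero,
                        response, registry)
    rows[[length(rows) + 1L]] <-
      .iams_well_rows("DBLANK_1", "double_blank", zero, response, registry)
    for (j in seq_len(nrow(truth))) {
      concs <- stats::setNames(
        vapply(registry$protein, function(p) truth[[tolower(p)]][j],
               numeric(1)),
        registry$protein)
      rows[[length(rows) + 1L]] <-
        .iams_well_rows(truth$subject[j], "sample", concs, response, registry)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate one ELISA plate for one analyte
#'
#' Lays out a 7-point two-fold standard series spanning the analyte's assay
#' working range, low/high QC wells, a blank, and one well per subject at
#' the analyte's plasma dilution. OD450 = 4PL(assay concentration) +
#' additive Gaussian noise (floored at zero). Sample wells whose diluted
#' concentration falls outside the curve's support are still emitted; the
#' quantifier flags them.
#'
#' @param plasma_conc named vector of plasma concentrations (ug/mL) on the
#'   ELISA's own scale, names = subject ids
#' @param analyte analyte name (must be in the registry)
#' @param curve_params named numeric c(a, b, c, d)
#' @param od_sd additive OD noise SD (default 0.01)
#' @param registry analyte registry (supplies dilution and assay range)
#' @param seed RNG seed for this plate
#' @param plate_id plate identifier
#' @return plate table (data.frame) in the dialect of [read_plate_table()]
#' @export
simulate_elisa_plate <- function(plasma_conc, analyte,
                                 curve_params = default_curve_params()[[analyte]],
                                 od_sd = 0.01,
                                 registry = analyte_registry(),
                                 seed = 1L, plate_id = paste0("P_", analyte)) {
  i <- match(analyte, registry$protein)
  if (is.na(i)) stop("unknown analyte: ", analyte)
  dil <- registry$dilution_factor[i]
  std_conc <- registry$elisa_assay_hi[i] / 2^(6:0)   # 7-point two-fold series
  qc_conc <- c(qc_low = std_conc[2], qc_high = std_conc[6])
  p <- curve_params
  mk <- function(well, role, nominal, assay_conc, dilution = NA_integer_,
                 sample = NA_character_) {
    data.frame(plate_id = plate_id, well_id = well, role = role,
               analyte = analyte, sample = sample,
               dilution_factor = dilution, nominal_conc = nominal,
               assay_true_conc = assay_conc, stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    wells <- rbind(
      do.call(rbind, lapply(seq_along(std_conc), function(k)
        mk(sprintf("STD_%d", k), "standard", std_conc[k], std_conc[k]))),
      mk("QCL", "qc_low", qc_conc[["qc_low"]], qc_conc[["qc_low"]]),
      mk("QCH", "qc_high", qc_conc[["qc_high"]], qc_conc[["qc_high"]]),
      mk("BLK", "blank", NA_real_, 0),
      do.call(rbind, lapply(seq_along(plasma_conc), function(j)
        mk(sprintf("SMP_%d", j), "sample", NA_real_,
           plasma_conc[j] * 1000 / dil, dilution = dil,
           sample = names(plasma_conc)[j])))
    )
    od <- fourpl(wells$assay_true_conc, p["a"], p["b"], p["c"], p["d"])
    if (od_sd > 0) od <- od + stats::rnorm(nrow(wells), 0, od_sd)
    wells$od450 <- pmax(od, 0)
    wells$assay_true_conc <- NULL
    rownames(wells) <- NULL
    wells
  })
}

#' Simulate a paired two-platform cohort directly
#'
#' The short route from truth to paired per-subject concentrations used by
#' the method-agreement stages: IAMS measurement = truth x log-normal noise
#' at the IAMS CV; ELISA measurement = biased (ELISA-apparent) truth x
#' log-normal noise at the ELISA CV. Plate- and transition-level structure
#' is bypassed; use the batch/plate simulators when the quantifiers
#' themselves are under test.
#'
#' @param spec a [cohort_spec()]
#' @return list: truth, measurements (long data.frame: subject, analyte,
#'   iams_conc, elisa_conc), covariates
#' @export
simulate_paired_cohort <- function(spec) {
  truth <- generate_cohort(spec)
  apparent <- elisa_apparent(truth, spec)
  n <- nrow(truth)
  with_seed(substream(spec$seed, 2L), {
    meas <- do.call(rbind, lapply(names(spec$medians), function(a) {
      col <- tolower(a)
      data.frame(subject = truth$subject, analyte = a,
                 iams_conc = truth[[col]] * lnoise(n, spec$iams_cv),
                 elisa_conc = apparent[[col]] * lnoise(n, spec$elisa_cv),
                 stringsAsFactors = FALSE)
    }))
    list(truth = truth,
         measurements = meas,
         covariates = truth[c("subject", "age", "hdl", "egfr")])
  })
}

#' Simulate paired stability arms
#'
#' Emulates the stability design: duplicates of three independent plasma
#' samples per condition, a baseline arm (1 h at temperature, or a single
#' freeze-thaw) against a stressed arm (24 h, or extra freeze-thaw
#' cycles). `effect_model` gives the fractional concentration shift the
#' stress induces (default 0 for every condition).
#'
#' @param base_concs numeric vector of true concentrations of the
#'   independent plasma samples (default 3 samples)
#' @param conditions condition labels, a subset of
#'   `c("4C_24h", "RT_24h", "FT2", "FT3")`
#' @param effect_model named fractional shifts per condition (e.g.
#'   `c(FT3 = -0.25)`); unnamed conditions default to 0
#' @param cv measurement CV per replicate (default 0.05)
#' @param n_rep replicates per sample per arm (default 2, the duplicate
#'   design)
#' @param seed RNG seed
#' @return data.frame: condition, arm ("baseline"/"stressed"), sample,
#'   replicate, conc
#' @export
simulate_stability_arms <- function(base_concs = c(95, 110, 125),
                                    conditions = c("4C_24h", "RT_24h",
                                                   "FT2", "FT3"),
                                    effect_model = numeric(0),
                                    cv = 0.05, n_rep = 2L, seed = 1L) {
  known <- c("4C_24h", "RT_24h", "FT2", "FT3")
  bad <- setdiff(conditions, known)
  if (length(bad))
    stop("unknown stability condition(s): ", paste(bad, collapse = ", "))
  eff <- stats::setNames(rep(0, length(conditions)), conditions)
  eff[names(effect_model)[names(effect_model) %in% conditions]] <-
    effect_model[names(effect_model) %in% conditions]
  with_seed(seed, {
    rows <- list()
    for (cond in conditions) {
      for (arm in c("baseline", "stressed")) {
        shift <- if (arm == "stressed") 1 + eff[[cond]] else 1
        for (s in seq_along(base_concs)) {
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond, arm = arm, sample = sprintf("PL%d", s),
            replicate = seq_len(n_rep),
            conc = base_concs[s] * shift * lnoise(n_rep, cv),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
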