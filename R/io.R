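# Column-name normalisation: tabular inputs arrive with vendor-flavoured
# headers ("Total Area", "Total.Area", "total_area" ...); order is never
# significant.
.norm_names <- function(x) {
  n <- tolower(gsub("[ .]+", "_", names(x)))
  n[n == "totalarea"] <- "total_area"
  n[n == "totalbackground"] <- "total_background"
  names(x) <- n
  x
}

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("malformed input ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read a transition-level MRM report
#'
#' Accepts a delimited text export with (case/spacing-insensitive) columns
#' sample, role, protein, peptide, label, Total Area, Total Background.
#'
#' @param path file path
#' @param sep field separator (default tab)
#' @return data.frame in the internal transition dialect
#' @export
read_transition_report <- function(path, sep = "\t") {
  df <- .norm_names(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE))
  df <- .require_cols(df, c("sample", "role", "protein", "peptide", "label",
                            "total_area", "total_background"), path)
  if (any(!df$label %in% c("light", "heavy")))
    stop("malformed input ", path, ": label must be light/heavy (row ",
         which(!df$label %in% c("light", "heavy"))[1], ")")
  df
}

#' Write a transition table
#' @param transitions transition data.frame
#' @param path file path
#' @export
write_transition_report <- function(transitions, path) {
  utils::write.table(transitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read an ELISA plate table
#'
#' Delimited text with columns plate_id, well_id, role, analyte, sample,
#' dilution_factor, nominal_conc, od450.
#'
#' @inheritParams read_transition_report
#' @return data.frame in the internal plate dialect
#' @export
read_plate_table <- function(path, sep = "\t") {
  df <- .norm_names(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE))
  .require_cols(df, c("plate_id", "well_id", "role", "analyte",
                      "dilution_factor", "nominal_conc", "od450"), path)
}

#' Write an ELISA plate table
#' @param plate plate data.frame
#' @param path file path
#' @export
write_plate_table <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample manifest with clinical covariates
#'
#' Requires subject, age, hdl and egfr columns and validates them before
#' any computation starts.
#'
#' @inheritParams read_transition_report
#' @return data.frame
#' @export
read_manifest <- function(path, sep = "\t") {
  df <- .norm_names(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE))
  df <- .require_cols(df, c("subject", "age", "hdl", "egfr"), path)
  for (col in c("age", "hdl", "egfr"))
    if (any(!is.finite(df[[col]])))
      stop("malformed input ", path, ": non-numeric or missing values in ",
           col, " (row ", which(!is.finite(df[[col]]))[1], ")")
  df
}

#' Write a per-sample concentration table
#' @param concs concentration data.frame
#' @param path file path
#' @export
write_concentration_table <- function(concs, path) {
  utils::write.table(concs, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-sample concentration table
#' @inheritParams read_transition_report
#' @return data.frame
#' @export
read_concentration_table <- function(path, sep = "\t") {
  .norm_names(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE))
}

#' Read/write the QC history ledger
#' @param path ledger file path
#' @return data.frame ledger
#' @export
read_qc_history <- function(path) {
  if (!file.exists(path)) return(qc_history())
  .norm_names(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_qc_history
#' @param history ledger data.frame
#' @export
write_qc_history <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Load a run configuration from YAML
#'
#' Scalar fields of [default_config()] (seed, sn_threshold, od_sd, QC and
#' concordance parameters, bias modes, risk-model coefficients, cohort
#' settings) can be overridden from a YAML file; unspecified fields keep
#' their defaults.
#'
#' @param path YAML file
#' @return a `"crossmark_config"`
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1L
  cfg <- default_config(seed = seed)
  for (f in c("sn_threshold", "cal_cv_limit", "od_sd", "qc_min_history",
              "qc_k", "allowable_diff", "pass_threshold"))
    if (!is.null(y[[f]])) cfg[[f]] <- y[[f]]
  if (!is.null(y$bias_mode)) cfg$bias_mode[names(y$bias_mode)] <- unlist(y$bias_mode)
  if (!is.null(y$risk_model)) cfg$risk_model <- do.call(risk_model, y$risk_model)
  if (!is.null(y$cohort)) cfg$cohort <- do.call(cohort_spec,
                                                c(y$cohort, list(seed = seed)))
  cfg
}
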