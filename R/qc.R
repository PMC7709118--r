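#' Create an empty reference-plasma QC history
#'
#' The history ledger holds, per accepted batch, the mean reference-plasma
#' concentration of each analyte; the gate compares every new batch to the
#' rolling mean +/- 2 SD of this ledger.
#'
#' @param analytes analyte names
#' @return zero-row data.frame with columns batch_id, analyte, mean_conc
#' @export
qc_history <- function(analytes = c("APOA4", "CD5L", "IBP3")) {
  data.frame(batch_id = character(0), analyte = character(0),
             mean_conc = numeric(0), stringsAsFactors = FALSE)
}

#' Gate an IAMS batch on its reference-plasma results
#'
#' The batch is accepted when, for every analyte, the mean of the current
#' reference-plasma replicates lies within `k` standard deviations of the
#' rolling mean over all prior accepted batches. With fewer than
#' `min_history` prior batches the SD is too unstable for a hard gate, so
#' the decision is "provisional" (accepted with a warning reason). Rejected
#' batches are not meant to enter the rolling statistics; use
#' [update_history()] which appends only accept/provisional decisions.
#'
#' @param history ledger as from [qc_history()] / [update_history()]
#' @param current named list of numeric vectors: per-analyte reference
#'   plasma replicate concentrations (>= 2 each)
#' @param batch_id identifier for the batch being gated
#' @param k gate width in SDs (default 2)
#' @param min_history minimum prior batches for a hard gate (default 5)
#' @return list of class `"batch_decision"`: batch_id, decision
#'   ("accept"/"reject"/"provisional"), per-analyte z, means, reason
#' @export
gate_batch <- function(history, current, batch_id = "batch",
                       k = 2, min_history = 5L) {
  if (length(current) == 0L) stop("current batch has no reference-plasma data")
  if (any(vapply(current, length, 1L) < 2L))
    stop("need >= 2 reference-plasma replicates per analyte")
  cur_means <- vapply(current, mean, numeric(1))
  n_prior <- length(unique(history$batch_id))
  z <- rep(NA_real_, length(cur_means)); names(z) <- names(cur_means)
  if (n_prior >= 2L) {
    for (a in names(cur_means)) {
      h <- history$mean_conc[history$analyte == a]
      if (length(h) >= 2L) z[a] <- (cur_means[a] - mean(h)) / stats::sd(h)
    }
  }
  if (n_prior < min_history) {
    decision <- "provisional"
    reason <- sprintf("only %d prior batch(es) (< %d): accepted with warning",
                      n_prior, min_history)
  } else if (any(abs(z) > k, na.rm = TRUE)) {
    bad <- names(z)[!is.na(z) & abs(z) > k]
    decision <- "reject"
    reason <- sprintf("reference plasma outside mean +/- %g SD for %s (|z| = %s)",
                      k, paste(bad, collapse = ", "),
                      paste(sprintf("%.2f", abs(z[bad])), collapse = ", "))
  } else {
    decision <- "accept"
    reason <- sprintf("all analytes within mean +/- %g SD", k)
  }
  structure(list(batch_id = batch_id, decision = decision, z = z,
                 means = cur_means, reason = reason),
            class = "batch_decision")
}

#' @export
print.batch_decision <- function(x, ...) {
  cat(sprintf("Batch %s: %s (%s)\n", x$batch_id, toupper(x$decision), x$reason))
  if (any(is.finite(x$z)))
    cat("  z:", paste(sprintf("%s %.2f", names(x$z), x$z), collapse = ", "), "\n")
  invisible(x)
}

#' Append an accepted batch to the QC history
#'
#' Rejected batches are excluded so a drifting process cannot widen its own
#' acceptance band.
#'
#' @param history existing ledger
#' @param decision a `"batch_decision"`
#' @return the updated ledger
#' @export
update_history <- function(history, decision) {
  if (decision$decision == "reject") return(history)
  rbind(history,
        data.frame(batch_id = decision$batch_id,
                   analyte = names(decision$means),
                   mean_conc = unname(decision$means),
                   stringsAsFactors = FALSE))
}
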