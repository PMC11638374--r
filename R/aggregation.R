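#' Impedance aggregometry trace
#'
#' One whole-blood aggregation recording: impedance (arbitrary aggregometer
#' units) against time over the 6-minute measurement window. The summary
#' statistic is the area under the curve by the trapezoid rule on the raw
#' sampling grid; negative impedance readings are clipped to zero before
#' integration, as aggregometers report non-negative aggregation.
#'
#' @param time_s strictly increasing sampling times (s).
#' @param impedance impedance readings, same length.
#' @return object of class `aggregation_trace`: list with `time_s`,
#'   `impedance`, `auc`.
#' @export
aggregation_trace <- function(time_s, impedance) {
  if (length(time_s) != length(impedance))
    stop("time and impedance must have equal length")
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  auc <- pracma::trapz(time_s, pmax(impedance, 0))
  structure(list(time_s = time_s, impedance = impedance, auc = auc),
            class = "aggregation_trace")
}

#' @export
print.aggregation_trace <- function(x, ...) {
  cat(sprintf("Aggregation trace: %d points over %.0f s, AUC = %.1f\n",
              length(x$time_s), max(x$time_s) - min(x$time_s), x$auc))
  invisible(x)
}

#' Aggregation percentage relative to a blank trace
#'
#' \deqn{\mathrm{aggregation}\,[\%] = \frac{\mathrm{AUC\ of\ test}}
#'   {\mathrm{AUC\ of\ blank}} \times 100} with both areas taken by the
#' trapezoid rule over the common time window of the two traces. The
#' statistic is invariant to the impedance unit (any common scale factor
#' cancels).
#'
#' @param test,blank [aggregation_trace()] objects.
#' @return aggregation percentage (scalar).
#' @export
aggregation_percent <- function(test, blank) {
  stopifnot(inherits(test, "aggregation_trace"),
            inherits(blank, "aggregation_trace"))
  lo <- max(min(test$time_s), min(blank$time_s))
  hi <- min(max(test$time_s), max(blank$time_s))
  if (lo >= hi) stop("traces have no common time window")
  window_auc <- function(tr) {
    keep <- tr$time_s >= lo & tr$time_s <= hi
    pracma::trapz(tr$time_s[keep], pmax(tr$impedance[keep], 0))
  }
  blank_auc <- window_auc(blank)
  if (blank_auc <= 0) stop("blank AUC must be positive")
  100 * window_auc(test) / blank_auc
}

#' Chelator concentration expected to abolish aggregation
#'
#' Stoichiometric matching of the diluted blood metal: a chelator forming an
#' s:1 complex must be present at `s * blood_metal_conc * dilution_factor`
#' in the cuvette to sequester the metal completely. With blood calcium at
#' 2 mM, 1:1 dilution with saline and a 1:1 chelator this is 1 mM.
#'
#' @param blood_metal_conc metal concentration in undiluted blood (M).
#' @param dilution_factor fraction of blood in the final cuvette volume
#'   (0.5 for 1:1 dilution with saline).
#' @param s chelator:metal stoichiometry.
#' @return required final chelator concentration (M).
#' @examples
#' predict_full_inhibition_conc(2e-3, 0.5, s = 1)  # 1 mM
#' @export
predict_full_inhibition_conc <- function(blood_metal_conc, dilution_factor,
                                         s = 1) {
  if (blood_metal_conc <= 0 || dilution_factor <= 0 || s <= 0)
    stop("all inputs must be positive")
  s * blood_metal_conc * dilution_factor
}

#' Aggregation inhibition across a chelator concentration ladder
#'
#' Quantifies every trace against the blank and summarizes aggregation
#' percentage per chelator concentration (mean and SD over replicates). The
#' smallest tested concentration with mean aggregation below
#' `full_inhibition_pct` (default 10% of blank, the operational definition
#' of full inhibition) is reported as the threshold.
#'
#' @param conc_ladder chelator concentrations (M), >= 3 values.
#' @param traces list parallel to `conc_ladder`; each element one
#'   [aggregation_trace()] or a list of replicate traces.
#' @param blank the uninhibited reference [aggregation_trace()].
#' @param full_inhibition_pct cutoff (% of blank) defining full inhibition.
#' @return list with `table` (data.frame conc, mean_pct, sd_pct, n) and
#'   `threshold_conc` (M, `NA` when never reached).
#' @export
inhibition_curve <- function(conc_ladder, traces, blank,
                             full_inhibition_pct = 10) {
  if (length(conc_ladder) < 3) stop("ladder must cover >= 3 concentrations")
  if (length(traces) != length(conc_ladder))
    stop("one trace (or replicate list) per concentration required")
  if (missing(blank) || !inherits(blank, "aggregation_trace"))
    stop("a blank trace is required")
  rows <- lapply(seq_along(conc_ladder), function(i) {
    tr <- traces[[i]]
    if (inherits(tr, "aggregation_trace")) tr <- list(tr)
    pct <- vapply(tr, aggregation_percent, numeric(1), blank = blank)
    data.frame(conc = conc_ladder[i], mean_pct = mean(pct),
               sd_pct = if (length(pct) > 1) stats::sd(pct) else NA_real_,
               n = length(pct))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$conc), ]
  rownames(tab) <- NULL
  hit <- tab$conc[tab$mean_pct < full_inhibition_pct]
  list(table = tab,
       threshold_conc = if (length(hit)) min(hit) else NA_real_)
}
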