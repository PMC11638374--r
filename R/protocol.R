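#' Microplate assay protocol
#'
#' Captures the dispensing scheme of the competitive screen in 96-well
#' plates: 50 uL of metal-ion solution, 150 uL of buffer, 50 uL of test
#' agent (or its solvent) and 50 uL of indicator, 300 uL per well in total.
#' Final concentrations follow by dilution: with a 3 mM ion stock the final
#' metal concentration is 500 uM, and with a 4 mM indicator stock the final
#' indicator concentration is 667 uM. Defaults mirror that protocol; all
#' volumes are uL and all concentrations molar.
#'
#' @param ion_volume,buffer_volume,agent_volume,indicator_volume aliquot
#'   volumes (uL), all positive.
#' @param ion_stock,indicator_stock stock concentrations (M).
#' @param final_metal,final_indicator final in-well concentrations (M);
#'   computed from stocks and volumes when `NULL`.
#' @param pH buffer pH of the well.
#' @param path_length optical path length (cm) of the filled well.
#' @param noise_sd photometric noise standard deviation (absorbance units),
#'   additive Gaussian, independent per well and wavelength.
#' @param n_replicates replicates per condition.
#' @param wavelengths measurement wavelength grid (nm).
#' @return an object of class `assay_protocol`.
#' @examples
#' p <- assay_protocol()
#' p$final_indicator  # 6.67e-4 M from the 4 mM stock
#' @export
assay_protocol <- function(ion_volume = 50, buffer_volume = 150,
                           agent_volume = 50, indicator_volume = 50,
                           ion_stock = 3e-3, indicator_stock = 4e-3,
                           final_metal = NULL, final_indicator = NULL,
                           pH = 7.5, path_length = 0.9,
                           noise_sd = 0.005, n_replicates = 3L,
                           wavelengths = seq(350, 650, by = 2)) {
  vols <- c(ion = ion_volume, buffer = buffer_volume,
            agent = agent_volume, indicator = indicator_volume)
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop_validation("all aliquot volumes must be positive")
  if (ion_stock < 0 || indicator_stock < 0)
    stop_validation("stock concentrations must be non-negative")
  if (noise_sd < 0) stop_validation("noise_sd must be non-negative")
  if (path_length <= 0) stop_validation("path_length must be positive")
  if (!length(wavelengths)) stop_validation("wavelength grid is empty")
  total <- sum(vols)
  structure(
    list(volumes = vols, total_volume = total,
         ion_stock = ion_stock, indicator_stock = indicator_stock,
         final_metal = final_metal %||% (ion_stock * ion_volume / total),
         final_indicator = final_indicator %||%
           (indicator_stock * indicator_volume / total),
         pH = pH, path_length = path_length, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates),
         wavelengths = sort(unique(wavelengths))),
    class = "assay_protocol")
}

#' @export
print.assay_protocol <- function(x, ...) {
  cat("Assay protocol (", x$total_volume, " uL/well, pH ", x$pH, ")\n", sep = "")
  cat(sprintf("  volumes (uL): ion %g, buffer %g, agent %g, indicator %g\n",
              x$volumes["ion"], x$volumes["buffer"], x$volumes["agent"],
              x$volumes["indicator"]))
  cat(sprintf("  final metal %.3g M, final indicator %.3g M; noise SD %.3g AU; %d replicates\n",
              x$final_metal, x$final_indicator, x$noise_sd, x$n_replicates))
  invisible(x)
}

#' Validate an assay protocol against its own dilution arithmetic
#'
#' Recomputes the final metal and indicator concentrations from the stock
#' concentrations and aliquot volumes and errors when a stated final
#' concentration departs from the recomputed value by more than
#' `tolerance` (relative). A consistent protocol is returned unchanged.
#'
#' @param protocol an [assay_protocol()].
#' @param tolerance maximum relative mismatch between stated and recomputed
#'   final concentrations (default 1%).
#' @return the checked protocol, invisibly classed as before.
#' @export
validate_protocol <- function(protocol, tolerance = 0.01) {
  stopifnot(inherits(protocol, "assay_protocol"))
  total <- sum(protocol$volumes)
  expect <- c(metal = protocol$ion_stock * protocol$volumes[["ion"]] / total,
              indicator = protocol$indicator_stock *
                protocol$volumes[["indicator"]] / total)
  got <- c(metal = protocol$final_metal, indicator = protocol$final_indicator)
  for (what in names(expect)) {
    ref <- max(expect[[what]], .Machine$double.eps)
    if (abs(got[[what]] - expect[[what]]) / ref > tolerance)
      stop_validation(sprintf(
        "final %s concentration %.4g M inconsistent with stock x volume (%.4g M)",
        what, got[[what]], expect[[what]]))
  }
  protocol
}
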