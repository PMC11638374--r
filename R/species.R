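#' Define an absorbing species as a sum of Gaussian bands
#'
#' A species' molar absorptivity spectrum is modelled as a sum of Gaussian
#' components \eqn{\epsilon(\lambda) = \sum_i a_i \exp(-(\lambda-c_i)^2 /
#' (2 w_i^2))} with centers \eqn{c_i} (nm), widths \eqn{w_i} (nm, the
#' Gaussian sigma) and amplitudes \eqn{a_i} (M^-1 cm^-1).
#'
#' @param name species label.
#' @param peaks data.frame with columns `center`, `width`, `amplitude`.
#' @return an object of class `spectral_species`.
#' @export
spectral_species <- function(name, peaks) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "width", "amplitude") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  if (any(peaks$amplitude < 0)) stop("peak amplitudes must be non-negative")
  if (any(peaks$center < 200 | peaks$center > 800))
    stop("peak centers must lie within 200-800 nm")
  structure(list(name = name, peaks = peaks), class = "spectral_species")
}

#' Molar absorptivity of a species on a wavelength grid
#'
#' @param species a [spectral_species()].
#' @param wavelengths numeric vector, nm.
#' @return epsilon(lambda) in M^-1 cm^-1.
#' @export
molar_absorptivity <- function(species, wavelengths) {
  stopifnot(inherits(species, "spectral_species"))
  eps <- numeric(length(wavelengths))
  for (i in seq_len(nrow(species$peaks))) {
    p <- species$peaks[i, ]
    eps <- eps + p$amplitude * exp(-((wavelengths - p$center)^2) / (2 * p$width^2))
  }
  eps
}

#' Default assay chemistry for the o-CC indicator and its Ca/Mg complexes
#'
#' Bundles the spectral and binding parameters the simulator uses for one
#' metal. The free indicator absorbs with a major band at 574 nm and a minor
#' band at 388 nm (minor amplitude 5% of major). Complexation causes a small
#' hypsochromic shift of the major band (573 nm for calcium, 568 nm for
#' magnesium; minor band 388 and 386 nm respectively) and roughly threefold
#' intensification. The indicator's metal binding is conditioned on two
#' phenolic deprotonations (pKa 7.2 each), which makes complexation strong
#' at pH 7.5, weak at pH 6.8 and essentially absent at pH 5.5 and below.
#'
#' Exact molar absorptivities and the indicator:metal formation constant of
#' o-CC under these buffer conditions are not published; these defaults are
#' stated model assumptions chosen to reproduce the qualitative spectral and
#' pH behaviour of the assay, and every element can be overridden.
#'
#' @param metal `"Ca"` or `"Mg"`.
#' @param beta_MD formation constant (M^-1) of the 1:1 indicator complex.
#' @param pKa_indicator acid constants gating indicator binding.
#' @return list with elements `metal`, `beta_MD`, `pKa_indicator`,
#'   `indicator` (free-indicator [spectral_species()]) and `complex`
#'   (metal-indicator complex [spectral_species()]).
#' @export
assay_chemistry <- function(metal = c("Ca", "Mg"),
                            beta_MD = 2e5,
                            pKa_indicator = c(7.2, 7.2)) {
  metal <- match.arg(metal)
  indicator <- spectral_species(
    "o-CC",
    data.frame(center = c(574, 388), width = c(40, 22),
               amplitude = c(1200, 60)))
  cmplx <- if (metal == "Ca") {
    spectral_species(
      "o-CC:Ca",
      data.frame(center = c(573, 388), width = c(40, 22),
                 amplitude = c(3600, 300)))
  } else {
    spectral_species(
      "o-CC:Mg",
      data.frame(center = c(568, 386), width = c(40, 22),
                 amplitude = c(3600, 300)))
  }
  list(metal = metal, beta_MD = beta_MD, pKa_indicator = pKa_indicator,
       indicator = indicator, complex = cmplx)
}
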