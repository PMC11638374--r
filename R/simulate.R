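#' Simulate an absorbance scan of a mixture of absorbing species
#'
#' Beer-Lambert superposition: \eqn{A(\lambda) = b \sum_i
#' \epsilon_i(\lambda) c_i + N(0, \sigma^2)}, with independent Gaussian
#' photometric noise per wavelength. Deterministic for a fixed `seed`.
#'
#' @param species_mix list of `list(species = <spectral_species>, conc =
#'   <molar>)` entries.
#' @param wavelengths wavelength grid (nm), non-empty.
#' @param noise_sd photometric noise SD (AU).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param path_length optical path (cm).
#' @return data.frame with columns `wavelength_nm`, `absorbance`.
#' @export
simulate_spectrum <- function(species_mix, wavelengths, noise_sd = 0,
                              seed = NULL, path_length = 1) {
  if (!length(wavelengths)) stop("wavelength grid is empty")
  concs <- vapply(species_mix, function(x) x$conc, numeric(1))
  if (any(concs < 0)) stop("species concentrations must be non-negative")
  a <- numeric(length(wavelengths))
  for (entry in species_mix)
    a <- a + path_length * entry$conc * molar_absorptivity(entry$species, wavelengths)
  if (noise_sd > 0)
    a <- a + with_seed(seed, stats::rnorm(length(a), sd = noise_sd))
  data.frame(wavelength_nm = wavelengths, absorbance = a)
}

# Absorbance of one well from solved speciation: free indicator plus
# metal-indicator complex (the chelator and its metal complex are taken as
# transparent over 350-650 nm).
well_absorbance <- function(spec, chem, protocol, wavelengths) {
  path <- protocol$path_length
  path * (spec$free_D * molar_absorptivity(chem$indicator, wavelengths) +
            spec$conc_MD * molar_absorptivity(chem$complex, wavelengths))
}

#' Simulate a metal calibration ladder read on a plate
#'
#' For every metal concentration in `conc_ladder` and every replicate, the
#' metal/indicator equilibrium is solved at the protocol pH (no chelator)
#' and the well absorbance is generated over the protocol wavelength grid
#' with additive photometric noise. A zero-concentration blank level is
#' always included.
#'
#' @param protocol an [assay_protocol()]; its `final_indicator`, `pH`,
#'   `noise_sd`, `n_replicates` and `wavelengths` are used.
#' @param metal `"Ca"` or `"Mg"`.
#' @param conc_ladder non-negative, sorted final metal concentrations (M).
#' @param chemistry an [assay_chemistry()]; defaults to the metal's default.
#' @param seed integer seed for reproducibility.
#' @return a `calibration_series`: data.frame with columns `metal`, `conc`,
#'   `replicate`, `wavelength_nm`, `absorbance`, with the protocol and
#'   chemistry attached as attributes.
#' @export
simulate_calibration <- function(protocol, metal = c("Ca", "Mg"),
                                 conc_ladder, chemistry = NULL, seed = NULL) {
  metal <- match.arg(metal)
  stopifnot(inherits(protocol, "assay_protocol"))
  if (any(conc_ladder < 0)) stop("concentration ladder must be non-negative")
  if (is.unsorted(conc_ladder)) stop("concentration ladder must be sorted")
  chem <- chemistry %||% assay_chemistry(metal)
  ladder <- unique(c(0, conc_ladder))
  wl <- protocol$wavelengths
  out <- with_seed(seed, {
    rows <- vector("list", length(ladder) * protocol$n_replicates)
    k <- 0
    for (conc in ladder) {
      sys <- speciation_system(
        M_total = conc, D_total = protocol$final_indicator, L_total = 0,
        beta_MD = chem$beta_MD, beta_MLs = 0, s = 1L, pH = protocol$pH,
        pKa_indicator = chem$pKa_indicator)
      spec <- solve_speciation(sys)
      clean <- well_absorbance(spec, chem, protocol, wl)
      for (rep in seq_len(protocol$n_replicates)) {
        k <- k + 1
        a <- clean
        if (protocol$noise_sd > 0)
          a <- a + stats::rnorm(length(wl), sd = protocol$noise_sd)
        rows[[k]] <- data.frame(metal = metal, conc = conc, replicate = rep,
                                wavelength_nm = wl, absorbance = a)
      }
    }
    do.call(rbind, rows)
  })
  structure(out, class = c("calibration_series", "data.frame"),
            protocol = protocol, chemistry = chem)
}

#' Simulate a 96-well chelation titration plate
#'
#' Lays out negative controls (indicator only), positive controls (metal +
#' indicator) and sample wells (metal + chelator + indicator, one group of
#' replicates per chelator:metal ratio) row-major on an 8x12 plate, solves
#' the competitive equilibrium for every well and generates absorbances at
#' the requested wavelengths and timepoints. Timepoints are modelled as
#' independent equilibrium reads (no kinetics), so the immediate and 5-min
#' readings differ only by noise.
#'
#' @param protocol an [assay_protocol()].
#' @param metal `"Ca"` or `"Mg"`.
#' @param chelator list with `beta_MLs` (overall formation constant, M^-s),
#'   `s` (stoichiometry, 1-3) and optionally `pKa` (acid constant of the
#'   chelating hydroxyl) and `name`.
#' @param ratio_ladder non-negative chelator:metal molar ratios; the
#'   chelator total in a sample well is `ratio * final_metal`.
#' @param wavelengths measurement wavelengths (nm); default is the complex
#'   peak of the metal (573 nm for Ca, 568 nm for Mg).
#' @param timepoints read times (min), default immediate and 5 min.
#' @param chemistry an [assay_chemistry()] override.
#' @param plate_id identifier stored in the output.
#' @param seed integer seed.
#' @return a [plate_reading()] in long format.
#' @export
simulate_chelation_plate <- function(protocol, metal = c("Ca", "Mg"),
                                     chelator, ratio_ladder,
                                     wavelengths = NULL,
                                     timepoints = c(0, 5),
                                     chemistry = NULL,
                                     plate_id = "simulated",
                                     seed = NULL) {
  metal <- match.arg(metal)
  stopifnot(inherits(protocol, "assay_protocol"))
  if (any(ratio_ladder < 0)) stop("ratios must be non-negative")
  chem <- chemistry %||% assay_chemistry(metal)
  wl <- wavelengths %||% if (metal == "Ca") 573 else 568
  n_rep <- protocol$n_replicates
  n_wells <- (length(ratio_ladder) + 2L) * n_rep
  if (n_wells > 96L)
    stop_validation("plate layout needs ", n_wells, " wells; only 96 available")
  compound <- chelator$name %||% "chelator"
  s <- as.integer(chelator$s %||% 1L)
  pka_L <- chelator$pKa

  conditions <- rbind(
    data.frame(role = "negative_control", ratio = NA_real_),
    data.frame(role = "positive_control", ratio = NA_real_),
    data.frame(role = "sample", ratio = ratio_ladder))
  wells <- well_names_row_major(n_wells)

  out <- with_seed(seed, {
    rows <- list(); k <- 0; w <- 0
    for (i in seq_len(nrow(conditions))) {
      role <- conditions$role[i]; ratio <- conditions$ratio[i]
      M_tot <- if (role == "negative_control") 0 else protocol$final_metal
      L_tot <- if (role == "sample") ratio * protocol$final_metal else 0
      sys <- speciation_system(
        M_total = M_tot, D_total = protocol$final_indicator, L_total = L_tot,
        beta_MD = chem$beta_MD, beta_MLs = chelator$beta_MLs, s = s,
        pH = protocol$pH, pKa_indicator = chem$pKa_indicator,
        pKa_chelator = pka_L)
      spec <- solve_speciation(sys)
      clean <- well_absorbance(spec, chem, protocol, wl)
      for (rep in seq_len(n_rep)) {
        w <- w + 1
        for (tp in timepoints) {
          a <- clean
          if (protocol$noise_sd > 0)
            a <- a + stats::rnorm(length(wl), sd = protocol$noise_sd)
          k <- k + 1
          rows[[k]] <- data.frame(
            plate_id = plate_id, well = wells[w], role = role,
            compound = if (role == "sample") compound else "",
            ratio = ratio, wavelength_nm = wl, timepoint_min = tp,
            absorbance = a)
        }
      }
    }
    do.call(rbind, rows)
  })
  plate_reading(out)
}

#' Simulate an impedance aggregometry trace
#'
#' Platelet aggregation is modelled as a logistic rise of impedance over
#' time whose plateau is scaled by a Hill function of the free calcium
#' concentration, \eqn{\theta = [Ca]^h / (K^h + [Ca]^h)} with default
#' K = 0.2 mM and h = 4: physiological free calcium gives a full-amplitude
#' trace while stoichiometric sequestration of calcium abolishes the
#' response. Additive Gaussian noise emulates instrument jitter.
#'
#' @param free_Ca free calcium concentration in the cuvette (M).
#' @param duration trace length (s), default the 6-min aggregometer window.
#' @param dt sampling interval (s).
#' @param amplitude full-aggregation plateau (arbitrary impedance units).
#' @param K_Ca,h Hill constant (M) and coefficient of the calcium dependence.
#' @param t50,tau logistic midpoint and time constant of the rise (s).
#' @param noise_sd additive noise SD (impedance units).
#' @param seed integer seed.
#' @return an [aggregation_trace()].
#' @export
simulate_aggregation_trace <- function(free_Ca, duration = 360, dt = 2,
                                       amplitude = 100, K_Ca = 2e-4, h = 4,
                                       t50 = 90, tau = 30,
                                       noise_sd = 0.5, seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (free_Ca < 0) stop("free_Ca must be non-negative")
  time <- seq(0, duration, by = dt)
  plateau <- if (free_Ca == 0) 0 else free_Ca^h / (K_Ca^h + free_Ca^h)
  imp <- amplitude * plateau / (1 + exp(-(time - t50) / tau))
  if (noise_sd > 0)
    imp <- imp + with_seed(seed, stats::rnorm(length(time), sd = noise_sd))
  aggregation_trace(time, imp)
}

# Well coordinates A1..H12 in row-major order.
well_names_row_major <- function(n = 96L) {
  all <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  if (n > 96L) stop_validation("a 96-well plate has at most 96 wells")
  all[seq_len(n)]
}
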