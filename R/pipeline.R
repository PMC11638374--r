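#' Demo compound panel for the simulated screen
#'
#' Five archetypes spanning the screen's four potency tiers: an
#' aminopolycarboxylate-like very strong 1:1 chelator, a quinoline-like
#' very strong 3:1 chelator, and moderate, weak and inactive compounds.
#' Formation constants are conditional at the assay pH.
#'
#' @return named list of chelator parameter lists (`beta_MLs`, `s`, `name`).
#' @export
demo_panel <- function() {
  list(
    aminopolycarboxylate = list(name = "aminopolycarboxylate",
                                beta_MLs = 1e12, s = 1L),
    quinoline_3to1 = list(name = "quinoline_3to1", beta_MLs = 1e15, s = 3L),
    moderate = list(name = "moderate", beta_MLs = 5e5, s = 1L),
    weak = list(name = "weak", beta_MLs = 1e4, s = 1L),
    inactive = list(name = "inactive", beta_MLs = 10, s = 1L))
}

# One chelation titration: simulate plate, quantify, fit, classify.
screen_compound <- function(protocol, metal, chelator, ratios, seed) {
  plate <- simulate_chelation_plate(protocol, metal = metal,
                                    chelator = chelator,
                                    ratio_ladder = ratios, seed = seed)
  chel <- plate_chelation(plate)
  curve <- tryCatch(fit_chelation_curve(chel$ratio, chel$chelation_pct),
                    error = function(e) NULL)
  cls <- classify_potency(chel$ratio, chel$chelation_pct)
  list(plate = plate, chelation = chel, curve = curve, classification = cls)
}

#' Run the full simulated screening workflow
#'
#' Executes the workflow in assay order — spectra, wavelength optimization,
#' calibration, limit of detection, chelation screen, potency
#' classification, pKa structure-activity regression, and platelet
#' aggregation — entirely on synthetic data, and returns one summary per
#' stage. Deterministic for a fixed seed; when `out_dir` is given, a
#' machine-readable JSON report (including the seed) and the simulated
#' plate CSVs are written there.
#'
#' @param seed integer master seed; every stage derives its own sub-seed
#'   from it.
#' @param out_dir optional output directory; created if missing. Existing
#'   files are only overwritten when `overwrite = TRUE`.
#' @param metal metal for the chelation screen stages.
#' @param overwrite allow overwriting an existing report.
#' @return list of class `chelascreen_report` with elements `seed` and the
#'   eight stage summaries `spectra`, `wavelengths`, `calibration`, `lod`,
#'   `screen`, `classification`, `sar`, `aggregation`.
#' @export
run_end_to_end <- function(seed = 1L, out_dir = NULL, metal = c("Ca", "Mg"),
                           overwrite = FALSE) {
  metal <- match.arg(metal)
  seed <- as.integer(seed)
  sub <- function(k) as.integer((as.numeric(seed) * 131 + k) %% 2147483647)

  # 1. spectra of the indicator and both complexes, with peak detection
  chem_ca <- assay_chemistry("Ca"); chem_mg <- assay_chemistry("Mg")
  wl_fine <- seq(350, 650, by = 0.5)
  scan_free <- simulate_spectrum(
    list(list(species = chem_ca$indicator, conc = 4.5e-4)),
    wl_fine, noise_sd = 0.002, seed = sub(1L))
  # complex scans at metal excess: nearly all indicator is complexed, so
  # the detected peak is the complex band
  scan_ca <- simulate_spectrum(
    list(list(species = chem_ca$indicator, conc = 3e-5),
         list(species = chem_ca$complex, conc = 4.2e-4)),
    wl_fine, noise_sd = 0.002, seed = sub(2L))
  scan_mg <- simulate_spectrum(
    list(list(species = chem_mg$indicator, conc = 3e-5),
         list(species = chem_mg$complex, conc = 4.2e-4)),
    wl_fine, noise_sd = 0.002, seed = sub(3L))
  top_peak <- function(scan) detect_peaks(scan, min_prominence = 0.05)$center_nm[1]
  spectra <- list(
    free_major_nm = top_peak(scan_free),
    ca_complex_major_nm = top_peak(scan_ca),
    mg_complex_major_nm = top_peak(scan_mg))

  # 2-3. calibration ladders and optimal wavelength per metal
  cal_protocol <- assay_protocol(final_indicator = 4.5e-4,
                                 wavelengths = seq(350, 650, by = 2))
  ladder <- seq(2e-5, 1.95e-4, length.out = 8)
  cal <- lapply(c(Ca = "Ca", Mg = "Mg"), function(m) {
    series <- simulate_calibration(cal_protocol, metal = m,
                                   conc_ladder = ladder,
                                   seed = sub(if (m == "Ca") 10L else 11L))
    opt <- optimize_wavelength(series)
    sc <- opt$scores[opt$scores$wavelength_nm == opt$optimal_nm, ]
    list(series = series, optimal_nm = opt$optimal_nm,
         r_squared = sc$R2, slope = sc$slope)
  })
  wavelengths <- list(ca_optimal_nm = cal$Ca$optimal_nm,
                      mg_optimal_nm = cal$Mg$optimal_nm)
  calibration <- list(
    ca = list(optimal_nm = cal$Ca$optimal_nm, r_squared = cal$Ca$r_squared,
              slope_au_per_m = cal$Ca$slope),
    mg = list(optimal_nm = cal$Mg$optimal_nm, r_squared = cal$Mg$r_squared,
              slope_au_per_m = cal$Mg$slope))

  # 4. limit of detection on a micromolar ladder at the optimal wavelength
  lod_protocol <- assay_protocol(final_indicator = 4.5e-4, n_replicates = 6L,
                                 wavelengths = cal[[metal]]$optimal_nm)
  lod_ladder <- c(5e-7, 1e-6, 2e-6, 2.5e-6, 5e-6)
  lod_series <- simulate_calibration(lod_protocol, metal = metal,
                                     conc_ladder = lod_ladder, seed = sub(20L))
  blank <- lod_series$absorbance[lod_series$conc == 0]
  reps <- split(lod_series$absorbance[lod_series$conc > 0],
                lod_series$conc[lod_series$conc > 0])
  lod <- limit_of_detection(blank, reps)

  # 5-6. chelation screen of the demo panel with classification
  protocol <- assay_protocol()
  ratios <- c(0.25, 0.5, 0.75, 1, 2, 3, 5, 10)
  panel <- demo_panel()
  screen <- lapply(seq_along(panel), function(i)
    screen_compound(protocol, metal, panel[[i]], ratios, seed = sub(30L + i)))
  names(screen) <- names(panel)
  classification <- data.frame(
    compound = names(screen),
    category = vapply(screen, function(x) x$classification$category, ""),
    s = vapply(screen, function(x)
      as.integer(x$classification$s %||% NA_integer_), integer(1)),
    mean_at_top = vapply(screen, function(x)
      x$classification$mean_at_top, numeric(1)))

  # 7. pKa structure-activity panel (quinoline-like, shared beta, varying
  # hydroxyl acidity) read out at the 1:1 ratio
  pka_grid <- c(6.5, 7.2, 7.9, 8.6, 9.3, 10.0)
  sar_chel <- vapply(seq_along(pka_grid), function(i) {
    plate <- simulate_chelation_plate(
      protocol, metal = metal,
      chelator = list(name = sprintf("quinoline_pka_%.1f", pka_grid[i]),
                      beta_MLs = 1e7, s = 1L, pKa = pka_grid[i]),
      ratio_ladder = 1, seed = sub(50L + i))
    mean(plate_chelation(plate)$chelation_pct)
  }, numeric(1))
  sar <- sar_regression(pka_grid, sar_chel)
  sar_summary <- list(pKa = pka_grid, chelation_pct = sar_chel,
                      slope = sar$slope, r_squared = sar$r_squared,
                      p_value = sar$p_value)

  # 8. platelet aggregation: predicted and simulated full-inhibition dose
  blood_ca <- 2e-3; dilution <- 0.5
  cuvette_ca <- blood_ca * dilution
  predicted <- predict_full_inhibition_conc(blood_ca, dilution, s = 1)
  agg_ladder <- c(8e-5, 2.5e-4, 5e-4, 1e-3, 2e-3)
  blank_trace <- simulate_aggregation_trace(cuvette_ca, seed = sub(70L))
  traces <- lapply(seq_along(agg_ladder), function(i) {
    sys <- speciation_system(M_total = cuvette_ca, D_total = 0,
                             L_total = agg_ladder[i], beta_MD = 0,
                             beta_MLs = 1e10, s = 1L)
    free_ca <- solve_speciation(sys)$free_M
    lapply(1:3, function(r)
      simulate_aggregation_trace(free_ca, seed = sub(70L + 3L * i + r)))
  })
  inh <- inhibition_curve(agg_ladder, traces, blank_trace)
  aggregation <- list(predicted_conc_m = predicted,
                      threshold_conc_m = inh$threshold_conc,
                      table = inh$table)

  report <- structure(
    list(seed = seed, metal = metal,
         spectra = spectra, wavelengths = wavelengths,
         calibration = calibration, lod = list(lod_m = lod$lod,
                                               table = lod$table),
         screen = lapply(screen, function(x) list(
           logec50 = if (is.null(x$curve)) NA_real_ else x$curve$logec50,
           k = if (is.null(x$curve)) NA_real_ else x$curve$k,
           Y_1to1 = if (is.null(x$curve)) NA_real_ else x$curve$Y_1to1)),
         classification = classification,
         sar = sar_summary, aggregation = aggregation),
    class = "chelascreen_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    report_path <- file.path(out_dir, "report.json")
    if (file.exists(report_path) && !overwrite)
      stop("refusing to overwrite ", report_path, " (use overwrite = TRUE)")
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    for (nm in names(screen))
      write_plate_csv(screen[[nm]]$plate,
                      file.path(out_dir, paste0("plate_", nm, ".csv")))
    write_scan_csv(scan_free, file.path(out_dir, "scan_indicator.csv"))
  }
  report
}

#' @export
print.chelascreen_report <- function(x, ...) {
  cat("Simulated chelation screen (seed ", x$seed, ", metal ", x$metal,
      ")\n", sep = "")
  cat(sprintf("  indicator peak %g nm; complex peaks Ca %g nm, Mg %g nm\n",
              x$spectra$free_major_nm, x$spectra$ca_complex_major_nm,
              x$spectra$mg_complex_major_nm))
  cat(sprintf("  optimal wavelengths: Ca %g nm (R2 %.3f), Mg %g nm (R2 %.3f)\n",
              x$calibration$ca$optimal_nm, x$calibration$ca$r_squared,
              x$calibration$mg$optimal_nm, x$calibration$mg$r_squared))
  cat(sprintf("  limit of detection: %s\n",
              if (is.na(x$lod$lod_m)) "not detected"
              else sprintf("%.2g M", x$lod$lod_m)))
  cat("  classification:\n")
  print(x$classification, row.names = FALSE)
  cat(sprintf("  SAR slope %.2f %%/pKa unit (R2 %.3f, p %.3g)\n",
              x$sar$slope, x$sar$r_squared, x$sar$p_value))
  cat(sprintf("  aggregation: predicted full-inhibition %g M, observed threshold %g M\n",
              x$aggregation$predicted_conc_m, x$aggregation$threshold_conc_m))
  invisible(x)
}
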