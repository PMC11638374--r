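#' Detect absorption peaks in a spectral scan
#'
#' Local maxima with at least `min_prominence` prominence, reported on the
#' measurement grid (no interpolation). Thin wrapper over
#' [pracma::findpeaks()].
#'
#' @param scan data.frame with `wavelength_nm`, `absorbance`, sorted by
#'   wavelength.
#' @param min_prominence minimum peak prominence (AU).
#' @return data.frame with columns `center_nm`, `height`, sorted by
#'   decreasing height; zero rows when no peak qualifies.
#' @export
detect_peaks <- function(scan, min_prominence = 0.01) {
  if (nrow(scan) < 3) stop("scan must contain at least 3 points")
  if (is.unsorted(scan$wavelength_nm)) stop("scan must be sorted by wavelength")
  pk <- pracma::findpeaks(scan$absorbance, minpeakheight = -Inf, nups = 1,
                          ndowns = 1)
  if (is.null(pk)) return(data.frame(center_nm = numeric(), height = numeric()))
  # prominence: height above the higher of the two flanking minima
  prom <- apply(pk, 1, function(row) {
    i <- row[2]
    left_min <- min(scan$absorbance[seq_len(i)])
    right_min <- min(scan$absorbance[i:nrow(scan)])
    row[1] - max(left_min, right_min)
  })
  keep <- prom >= min_prominence
  out <- data.frame(center_nm = scan$wavelength_nm[pk[keep, 2]],
                    height = pk[keep, 1])
  out[order(-out$height), , drop = FALSE]
}

# Per-wavelength OLS of mean absorbance on concentration for a
# calibration_series; returns one row per wavelength.
wavelength_scores <- function(series, use_means = TRUE) {
  stopifnot(inherits(series, "calibration_series"))
  if (length(unique(series$conc)) < 3)
    stop("need at least 3 distinct concentrations")
  split_wl <- split(series, series$wavelength_nm)
  out <- do.call(rbind, lapply(split_wl, function(d) {
    if (use_means) {
      agg <- stats::aggregate(absorbance ~ conc, data = d, FUN = mean)
      fit <- stats::lm(absorbance ~ conc, data = agg)
    } else {
      fit <- stats::lm(absorbance ~ conc, data = d)
    }
    # noiseless input gives an exact fit; the perfect-fit warning is expected
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(wavelength_nm = d$wavelength_nm[1],
               R2 = if (is.finite(r2)) r2 else 0,
               slope = unname(stats::coef(fit)[2]))
  }))
  rownames(out) <- NULL
  out[order(out$wavelength_nm), ]
}

#' Select the optimal detection wavelength from a calibration series
#'
#' At every wavelength an ordinary least-squares line of mean absorbance
#' against metal concentration yields a linearity score (R^2) and a
#' sensitivity (the slope, AU per M). Wavelengths with R^2 above `r2_min`
#' are admissible; among them the one with the largest absolute slope is
#' optimal. Ties are broken toward the wavelength nearest the global
#' absolute-slope maximum, then toward the lowest wavelength.
#'
#' @param series a `calibration_series` (see [simulate_calibration()] or a
#'   user-built data.frame with the same columns and class).
#' @param r2_min linearity admissibility bound (default 0.9).
#' @param use_means regress on per-concentration replicate means (default)
#'   rather than pooled replicates.
#' @return list with `optimal_nm`, `scores` (data.frame wavelength_nm, R2,
#'   slope) and `admissible_nm`.
#' @export
optimize_wavelength <- function(series, r2_min = 0.9, use_means = TRUE) {
  scores <- wavelength_scores(series, use_means = use_means)
  adm <- scores[scores$R2 > r2_min, , drop = FALSE]
  if (!nrow(adm))
    stop(sprintf("no wavelength reaches R2 > %.3g (best R2 = %.4f at %g nm)",
                 r2_min, max(scores$R2), scores$wavelength_nm[which.max(scores$R2)]))
  global_best <- scores$wavelength_nm[which.max(abs(scores$slope))]
  best_slope <- max(abs(adm$slope))
  cand <- adm[abs(adm$slope) == best_slope, , drop = FALSE]
  cand <- cand[order(abs(cand$wavelength_nm - global_best),
                     cand$wavelength_nm), , drop = FALSE]
  list(optimal_nm = cand$wavelength_nm[1], scores = scores,
       admissible_nm = adm$wavelength_nm)
}

#' Limit of detection by t-tests against the blank
#'
#' Each concentration level is compared with the blank by a two-sample,
#' two-sided t test (equal variances by default, matching the classical
#' unpaired test; Welch via `welch = TRUE`). The limit of detection is the
#' smallest tested concentration that is significant at `alpha` AND whose
#' larger tested concentrations are all significant too — a monotone rule
#' that stops an isolated false positive from defining the limit. No
#' multiple-testing correction is applied across the ladder (each level is
#' reported at its nominal p), which is a known caveat of the blank-
#' comparison definition.
#'
#' @param blank_reps numeric vector of blank absorbances (>= 2 values).
#' @param ladder_reps named list: one numeric vector of replicate
#'   absorbances per concentration; names are molar concentrations.
#' @param alpha significance level.
#' @param welch use Welch's unequal-variance test.
#' @return object of class `lod_result`: list with `lod` (molar, `NA` when
#'   nothing is detected), `table` (conc, mean, p_value, significant) and
#'   `alpha`.
#' @export
limit_of_detection <- function(blank_reps, ladder_reps, alpha = 0.05,
                               welch = FALSE) {
  if (length(blank_reps) < 2) stop("need >= 2 blank replicates")
  concs <- as.numeric(names(ladder_reps))
  if (anyNA(concs)) stop("ladder_reps must be named by concentration")
  ord <- order(concs)
  concs <- concs[ord]; ladder_reps <- ladder_reps[ord]
  p <- vapply(ladder_reps, function(x) {
    if (length(x) < 2) stop("need >= 2 replicates per concentration")
    if (stats::sd(x) == 0 && stats::sd(blank_reps) == 0 &&
        mean(x) == mean(blank_reps)) return(1)
    stats::t.test(x, blank_reps, var.equal = !welch)$p.value
  }, numeric(1))
  sig <- p < alpha
  # monotone rule: significant here and at every larger concentration
  all_above <- rev(cumprod(rev(sig))) == 1
  lod <- if (any(all_above)) concs[which(all_above)[1]] else NA_real_
  structure(list(
    lod = lod,
    table = data.frame(conc = concs,
                       mean = vapply(ladder_reps, mean, numeric(1)),
                       p_value = unname(p), significant = unname(sig)),
    alpha = alpha), class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  if (is.na(x$lod)) cat("Limit of detection: not detected (alpha =",
                        x$alpha, ")\n")
  else cat(sprintf("Limit of detection: %.3g M (alpha = %g)\n", x$lod, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Long-term stability and temperature-confounder check
#'
#' For a series of measurement days, compares stored-reagent against
#' fresh-reagent absorbances with a paired t test, reports the Pearson
#' correlation of absorbance with measurement temperature (the potential
#' confounder), and flags drift whenever the mean stored/fresh ratio
#' departs from 1 by more than `ratio_tol`.
#'
#' @param stored,fresh paired absorbance series (same length, one value per
#'   visit).
#' @param temperature measurement temperatures, same length.
#' @param ratio_tol allowed departure of mean(stored/fresh) from 1.
#' @return list with `paired_p`, `ratio`, `drift_flag`,
#'   `temperature_cor`, `temperature_p` (both `NA` when not assessable,
#'   e.g. constant series), and `n`.
#' @export
stability_check <- function(stored, fresh, temperature, ratio_tol = 0.1) {
  if (length(stored) != length(fresh) || length(stored) != length(temperature))
    stop("stored, fresh and temperature must be paired series")
  if (length(stored) < 3) stop("need >= 3 paired visits")
  ratio <- mean(stored / fresh)
  paired_p <- if (stats::sd(stored - fresh) == 0) 1 else
    stats::t.test(stored, fresh, paired = TRUE)$p.value
  abs_all <- c(stored, fresh); temp_all <- c(temperature, temperature)
  if (stats::sd(abs_all) == 0 || stats::sd(temp_all) == 0) {
    cor_r <- NA_real_; cor_p <- NA_real_
  } else {
    ct <- stats::cor.test(abs_all, temp_all)
    cor_r <- unname(ct$estimate); cor_p <- ct$p.value
  }
  list(paired_p = paired_p, ratio = ratio,
       drift_flag = abs(ratio - 1) > ratio_tol,
       temperature_cor = cor_r, temperature_p = cor_p, n = length(stored))
}
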