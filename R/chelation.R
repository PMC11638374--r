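#' Chelation percentage from sample and control absorbances
#'
#' The screen's central statistic. With \eqn{\bar A_N} the mean
#' negative-control absorbance (indicator only), \eqn{\bar A_P} the mean
#' positive-control absorbance (metal + indicator) and \eqn{A_x} a sample
#' absorbance (metal + chelator + indicator),
#' \deqn{\mathrm{chelation}\,[\%] = \left(1 - \frac{A_x - \bar A_N}
#'   {\bar A_P - \bar A_N}\right) \times 100.}
#' The statistic is affine-invariant: adding a constant to every absorbance
#' leaves it unchanged. Values are reported unclipped; values outside
#' [-10, 110] are flagged rather than truncated, since clipping would bias
#' curve fits near 0 and 100%.
#'
#' @param A_x sample absorbance(s); vectorized.
#' @param negative_reps replicate absorbances of the negative control.
#' @param positive_reps replicate absorbances of the positive control.
#' @param window_floor minimum |mean(positive) - mean(negative)| assay
#'   window (AU) below which the statistic is undefined.
#' @return object of class `chelation_measurement`: list with `A_x`,
#'   `A_N_bar`, `A_P_bar`, `chelation_pct` (same length as `A_x`) and
#'   `flagged` (logical, outside [-10, 110]).
#' @examples
#' chelation_percent(0.6, negative_reps = c(0.19, 0.21),
#'                   positive_reps = c(0.99, 1.01))  # 50%
#' @export
chelation_percent <- function(A_x, negative_reps, positive_reps,
                              window_floor = 0.05) {
  A_N <- mean(negative_reps); A_P <- mean(positive_reps)
  if (abs(A_P - A_N) <= window_floor)
    stop(sprintf(
      "no assay window: |mean positive - mean negative| = %.3g AU <= %.3g",
      abs(A_P - A_N), window_floor))
  pct <- (1 - (A_x - A_N) / (A_P - A_N)) * 100
  structure(list(A_x = A_x, A_N_bar = A_N, A_P_bar = A_P,
                 chelation_pct = pct,
                 flagged = pct < -10 | pct > 110),
            class = "chelation_measurement")
}

#' Chelation percentages for every sample well of a plate
#'
#' Applies [chelation_percent()] to each sample well of a long-format
#' [plate_reading()] at one wavelength and timepoint, using the plate's own
#' negative and positive control wells.
#'
#' @param plate a [plate_reading()].
#' @param wavelength wavelength to use (nm); default the plate's first.
#' @param timepoint timepoint to use (min); default the earliest
#'   (immediate) read — the assay also reads at 5 min, selectable here.
#' @param window_floor passed to [chelation_percent()].
#' @return data.frame with columns `well`, `compound`, `ratio`,
#'   `chelation_pct`, `flagged`.
#' @export
plate_chelation <- function(plate, wavelength = NULL, timepoint = NULL,
                            window_floor = 0.05) {
  stopifnot(inherits(plate, "plate_reading"))
  wavelength <- wavelength %||% plate$wavelength_nm[1]
  timepoint <- timepoint %||% min(plate$timepoint_min)
  d <- plate[plate$wavelength_nm == wavelength &
               plate$timepoint_min == timepoint, ]
  if (!nrow(d)) stop("no reads at the requested wavelength/timepoint")
  neg <- d$absorbance[d$role == "negative_control"]
  pos <- d$absorbance[d$role == "positive_control"]
  smp <- d[d$role == "sample", ]
  meas <- chelation_percent(smp$absorbance, neg, pos,
                            window_floor = window_floor)
  data.frame(well = smp$well, compound = smp$compound, ratio = smp$ratio,
             chelation_pct = meas$chelation_pct, flagged = meas$flagged)
}

#' Fit a logistic chelation curve over the chelator:metal ratio
#'
#' Fits \deqn{Y(x) = \frac{100}{1 + 10^{(\mathrm{LogEC50} - x)\,k}}}
#' by least squares, where \eqn{x = \log_{10}(\mathrm{ratio})},
#' \eqn{\mathrm{LogEC50}} is the log10 ratio producing 50% chelation and
#' \eqn{k} the slope of the chelation curve. The expected chelation at the
#' 1:1 ratio is this curve at \eqn{x = 0}:
#' \eqn{Y_{1:1} = 100 / (1 + 10^{\mathrm{LogEC50}\cdot k})}, so a
#' more-negative LogEC50 means higher expected chelation; `y_sign = -1`
#' selects the opposite sign convention for this evaluation.
#' Ratio-zero points (solvent-only, identical to positive controls) carry
#' no ratio information on the log scale and are dropped from the fit.
#'
#' @param ratios chelator:metal molar ratios, replicate-level (same length
#'   as `chelation_pct`).
#' @param chelation_pct chelation percentages.
#' @param y_sign +1 (default) or -1; sign convention used when evaluating
#'   the 1:1 expectation from the fitted parameters.
#' @return object of class `chelation_curve`: list with `logec50`, `k`,
#'   their standard errors, `ci95` (2x2 matrix), `Y_1to1`, `data`
#'   (data.frame ratio, chelation_pct), `fitted_fn` (function of ratio),
#'   `vcov`, `df`, and `converged`.
#' @export
fit_chelation_curve <- function(ratios, chelation_pct, y_sign = 1) {
  stopifnot(length(ratios) == length(chelation_pct))
  keep <- is.finite(ratios) & is.finite(chelation_pct) & ratios > 0
  d <- data.frame(x = log10(ratios[keep]), y = chelation_pct[keep])
  if (length(unique(d$x)) < 4)
    stop("need >= 4 distinct non-zero ratios with finite chelation values")
  if (stats::sd(d$y) == 0)
    stop("curve not identifiable: chelation values are flat")
  # start values: midpoint crossing by interpolation, unit slope
  agg <- stats::aggregate(y ~ x, data = d, FUN = mean)
  start_le <- tryCatch(
    stats::approx(agg$y, agg$x, xout = 50, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(start_le)) start_le <- stats::median(agg$x)
  # Levenberg-Marquardt with the analytic Jacobian; nls()'s numeric
  # derivatives degenerate when LogEC50 sits near zero or residuals vanish
  resid_fn <- function(p) d$y - 100 / (1 + 10^((p[1] - d$x) * p[2]))
  jac_fn <- function(p) {
    u <- 10^((p[1] - d$x) * p[2])
    cm <- -100 * u * log(10) / (1 + u)^2
    -cbind(cm * p[2], cm * (p[1] - d$x))  # d(residual)/d(par)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(logec50 = start_le, k = 1), fn = resid_fn,
                       jac = jac_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    stop("curve not identifiable: logistic fit did not converge")
  est <- fit$par
  df <- nrow(d) - 2L
  sigma2 <- fit$deviance / df
  V <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(V))
    stop("curve not identifiable: parameter covariance is singular")
  dimnames(V) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(V), 0))
  tq <- stats::qt(0.975, df)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  logec50 <- unname(est["logec50"]); k <- unname(est["k"])
  structure(list(
    logec50 = logec50, k = k, se = se, ci95 = ci,
    Y_1to1 = 100 / (1 + 10^(y_sign * logec50 * k)),
    data = data.frame(ratio = ratios[keep], chelation_pct = chelation_pct[keep]),
    fitted_fn = function(r) 100 / (1 + 10^((logec50 - log10(r)) * k)),
    vcov = V, df = df, converged = TRUE, y_sign = y_sign),
    class = "chelation_curve")
}

#' @export
print.chelation_curve <- function(x, ...) {
  cat("Chelation curve fit\n")
  cat(sprintf("  LogEC50 = %.3f [%.3f, %.3f], k = %.3f [%.3f, %.3f]\n",
              x$logec50, x$ci95["logec50", 1], x$ci95["logec50", 2],
              x$k, x$ci95["k", 1], x$ci95["k", 2]))
  cat(sprintf("  expected chelation at 1:1 = %.1f%%\n", x$Y_1to1))
  invisible(x)
}

# Pointwise 95% confidence band for a fitted chelation_curve on a log-ratio
# grid, by the delta method on (logec50, k).
curve_confidence_band <- function(curve, x_grid) {
  le <- curve$logec50; k <- curve$k
  yhat <- 100 / (1 + 10^((le - x_grid) * k))
  # partial derivatives of Y wrt (logec50, k)
  u <- 10^((le - x_grid) * k)
  common <- -100 * u * log(10) / (1 + u)^2
  g_le <- common * k
  g_k <- common * (le - x_grid)
  G <- cbind(g_le, g_k)
  var_y <- rowSums((G %*% curve$vcov) * G)
  tq <- stats::qt(0.975, curve$df)
  data.frame(x = x_grid, fit = yhat,
             lower = yhat - tq * sqrt(var_y),
             upper = yhat + tq * sqrt(var_y))
}

#' Infer complex stoichiometry from a near-complete chelation titration
#'
#' For a very strong chelator the titration approaches the complete-binding
#' template \eqn{Y_s(r) = 100 \min(r/s, 1)}: chelation rises linearly with
#' the chelator:metal ratio and saturates at the equivalence ratio `s`. The
#' per-ratio mean chelation is compared with each candidate template by sum
#' of squared errors; the best candidate is returned when its SSE is within
#' the acceptance threshold, twice the replicate-variance benchmark. The
#' benchmark adds, per ratio, the variance of the replicate mean and a
#' fixed template tolerance (`template_tol_pct`, default 5 percentage
#' points) that absorbs the soft shoulder a finite formation constant
#' produces near the equivalence point, where the idealized template has a
#' sharp corner.
#'
#' @param ratios replicate-level chelator:metal ratios.
#' @param chelation_pct matching chelation percentages.
#' @param candidates candidate stoichiometries (default 1:3).
#' @param completeness_pct required maximum mean chelation (default 95) for
#'   the titration to count as complete; otherwise no stoichiometry is
#'   inferable.
#' @param template_tol_pct per-ratio template tolerance (percentage points).
#' @return list with `s` (integer, or `NA` when not inferable), `sse`
#'   (named per candidate), `threshold`, `accepted`, and `reason`.
#' @export
infer_stoichiometry <- function(ratios, chelation_pct, candidates = 1:3,
                                completeness_pct = 95,
                                template_tol_pct = 5) {
  stopifnot(length(ratios) == length(chelation_pct))
  keep <- is.finite(ratios) & is.finite(chelation_pct)
  r <- ratios[keep]; y <- chelation_pct[keep]
  means <- tapply(y, r, mean)
  vars <- tapply(y, r, function(v) if (length(v) > 1) stats::var(v) else 0)
  ns <- tapply(y, r, length)
  rr <- as.numeric(names(means))
  if (max(means) < completeness_pct)
    return(list(s = NA_integer_, sse = NULL, threshold = NA_real_,
                accepted = FALSE,
                reason = sprintf("titration incomplete: max mean chelation %.1f%% < %g%%",
                                 max(means), completeness_pct)))
  sse <- vapply(candidates, function(s) {
    template <- 100 * pmin(rr / s, 1)
    sum((means - template)^2)
  }, numeric(1))
  names(sse) <- candidates
  threshold <- 2 * sum(vars / ns + template_tol_pct^2)
  best <- candidates[which.min(sse)]
  accepted <- min(sse) <= threshold
  list(s = if (accepted) as.integer(best) else NA_integer_,
       sse = sse, threshold = threshold, accepted = accepted,
       reason = if (accepted) "template accepted"
       else sprintf("best template SSE %.1f exceeds threshold %.1f",
                    min(sse), threshold))
}

#' Classify chelator potency into the screen's four tiers
#'
#' Tiers, assessed on replicate-level chelation percentages over the ratio
#' ladder:
#' * `very_strong` — the complete-binding stoichiometry is inferable: the
#'   template fit of [infer_stoichiometry()] is accepted and mean chelation
#'   reaches `complete_pct` (95%) at some ratio no larger than
#'   `max(3, 2 s)` for the inferred stoichiometry `s` — i.e. the titration
#'   saturates essentially at its own equivalence point (ratio `s`), with
#'   one tested step of slack for the soft shoulder a finite formation
#'   constant produces there;
#' * `moderate` — chelation is complete at the 10:1 ratio (mean >=
#'   `complete_pct`, or its 95% CI contains 100) but the stoichiometry is
#'   not inferable;
#' * `weak` — chelation at 10:1 is significantly above zero (one-sample t
#'   test, one-sided, p < `alpha`) but not complete;
#' * `inactive` — otherwise.
#'
#' When the ladder lacks a 10:1 ratio the largest tested ratio substitutes
#' for it and the result is flagged (`at_max_ratio = TRUE`), mirroring
#' compounds whose solubility caps the testable range.
#'
#' @param ratios replicate-level ratios.
#' @param chelation_pct matching chelation percentages.
#' @param alpha significance level for the weak-tier test.
#' @param complete_pct completeness threshold (% chelation).
#' @return list with `category` (factor level as character), `s` (inferred
#'   stoichiometry, `NA` unless very_strong), `stoichiometry` (full
#'   [infer_stoichiometry()] result), `ratio_used`, `at_max_ratio`,
#'   `mean_at_top`, `p_at_top`.
#' @export
classify_potency <- function(ratios, chelation_pct, alpha = 0.05,
                             complete_pct = 95) {
  stopifnot(length(ratios) == length(chelation_pct))
  keep <- is.finite(ratios) & is.finite(chelation_pct)
  r <- ratios[keep]; y <- chelation_pct[keep]
  if (!length(r)) stop("no finite chelation data")
  has10 <- any(r == 10)
  top_ratio <- if (has10) 10 else max(r)
  y_top <- y[r == top_ratio]
  mean_top <- mean(y_top)
  # very strong: complete at a low ratio and template-consistent
  sto <- infer_stoichiometry(r, y, completeness_pct = complete_pct)
  means <- tapply(y, r, mean)
  low_ratio_cap <- if (sto$accepted) max(3, 2 * sto$s) else 3
  low_complete <- any(means[as.numeric(names(means)) <= low_ratio_cap] >=
                        complete_pct)
  if (sto$accepted && low_complete) {
    return(list(category = "very_strong", s = sto$s, stoichiometry = sto,
                ratio_used = top_ratio, at_max_ratio = !has10,
                mean_at_top = mean_top, p_at_top = NA_real_))
  }
  # moderate: complete at the top ratio
  ci_hi <- if (length(y_top) > 1 && stats::sd(y_top) > 0)
    mean_top + stats::qt(0.975, length(y_top) - 1) *
      stats::sd(y_top) / sqrt(length(y_top))
  else mean_top
  if (mean_top >= complete_pct || ci_hi >= 100) {
    return(list(category = "moderate", s = NA_integer_, stoichiometry = sto,
                ratio_used = top_ratio, at_max_ratio = !has10,
                mean_at_top = mean_top, p_at_top = NA_real_))
  }
  # weak: significantly above zero at the top ratio
  p_top <- if (length(y_top) > 1 && stats::sd(y_top) > 0)
    stats::t.test(y_top, mu = 0, alternative = "greater")$p.value
  else if (mean_top > 0) 0 else 1
  category <- if (p_top < alpha) "weak" else "inactive"
  list(category = category, s = NA_integer_, stoichiometry = sto,
       ratio_used = top_ratio, at_max_ratio = !has10,
       mean_at_top = mean_top, p_at_top = p_top)
}

#' Compare two chelation curves through their 95% confidence bands
#'
#' Pointwise 95% bands of both fitted curves are evaluated on a shared
#' log-ratio grid. Curve A is called stronger when its lower band exceeds
#' B's upper band over a contiguous run covering more than half of the
#' shared range (and symmetrically for B); otherwise the curves are
#' indistinguishable.
#'
#' @param curve_a,curve_b [fit_chelation_curve()] objects.
#' @param n_grid grid resolution.
#' @return list with `verdict` (`"a_stronger"`, `"b_stronger"` or
#'   `"indistinguishable"`) and `fraction_separated` (named, per direction).
#' @export
compare_curves <- function(curve_a, curve_b, n_grid = 101L) {
  ra <- range(log10(curve_a$data$ratio)); rb <- range(log10(curve_b$data$ratio))
  lo <- max(ra[1], rb[1]); hi <- min(ra[2], rb[2])
  if (lo >= hi) stop("curves have disjoint ratio ranges")
  x <- seq(lo, hi, length.out = n_grid)
  band_a <- curve_confidence_band(curve_a, x)
  band_b <- curve_confidence_band(curve_b, x)
  longest_run <- function(flag) {
    r <- rle(flag)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  }
  frac_a <- longest_run(band_a$lower > band_b$upper) / n_grid
  frac_b <- longest_run(band_b$lower > band_a$upper) / n_grid
  verdict <- if (frac_a > 0.5) "a_stronger"
  else if (frac_b > 0.5) "b_stronger"
  else "indistinguishable"
  list(verdict = verdict,
       fraction_separated = c(a = frac_a, b = frac_b))
}

#' Structure-activity regression of chelation on hydroxyl acidity
#'
#' Ordinary least squares of chelation percentage at a fixed ratio on the
#' (externally computed) pKa of the chelating hydroxyl across a compound
#' panel. A negative slope means a more acidic — more ionized — hydroxyl
#' chelates better at neutral pH.
#'
#' @param pKa numeric vector, one per compound.
#' @param chelation_pct matching chelation percentages.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value` (slope t
#'   test) and the underlying `lm` fit.
#' @export
sar_regression <- function(pKa, chelation_pct) {
  stopifnot(length(pKa) == length(chelation_pct))
  keep <- is.finite(pKa) & is.finite(chelation_pct)
  if (sum(keep) < 3) stop("need >= 3 compounds with both pKa and chelation")
  if (stats::sd(pKa[keep]) == 0) stop("degenerate pKa spread")
  fit <- stats::lm(chelation_pct[keep] ~ pKa[keep])
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) >= 2 && ncol(sm$coefficients) >= 4 &&
           sm$df[2] > 0) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, fit = fit)
}
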