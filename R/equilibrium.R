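#' Conditional (apparent) formation constant at a given pH
#'
#' Corrects a thermodynamic formation constant for competing protonation of
#' the ligand donor groups. Each acid constant in `pKa` contributes a side
#' reaction coefficient `(1 + 10^(pKa - pH))`, so the apparent constant is
#' `beta / prod(1 + 10^(pKa - pH))`. With no protonating groups the constant
#' is returned unchanged. The apparent constant is non-decreasing in pH,
#' which is the mechanism behind the loss of indicator-metal complexation in
#' acidic buffers.
#'
#' @param beta formation constant (M^-n), non-negative.
#' @param pH solution pH.
#' @param pKa numeric vector of acid dissociation constants of the donor
#'   groups that must be deprotonated for binding; may be empty.
#' @return the conditional formation constant, same units as `beta`.
#' @examples
#' conditional_constant(1e6, 7.0, pKa = 7.0)   # half-deprotonated: beta/2
#' conditional_constant(1e6, 7.4, pKa = numeric())  # no protonation: 1e6
#' @export
conditional_constant <- function(beta, pH, pKa = numeric()) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0)
    stop("`beta` must be a single non-negative number")
  if (!is.numeric(pH) || length(pH) != 1L || is.na(pH))
    stop("`pH` must be a single number")
  pKa <- as.numeric(pKa)
  if (length(pKa) && any(!is.finite(pKa)))
    stop("`pKa` values must be finite")
  beta / prod(1 + 10^(pKa - pH))
}

#' Buffer pH from the Henderson-Hasselbalch relation
#'
#' @param base_conc molar concentration of the conjugate base (> 0).
#' @param acid_conc molar concentration of the free acid (> 0).
#' @param pKa acid dissociation constant of the buffer couple.
#' @return pH = pKa + log10(base/acid).
#' @examples
#' buffer_ph(0.015, 0.0027, pKa = 4.76)  # acetate buffer, ~pH 5.5
#' buffer_ph(0.015, 0.0143, pKa = 7.48)  # HEPES buffer, ~pH 7.5
#' @export
buffer_ph <- function(base_conc, acid_conc, pKa) {
  if (!is.numeric(base_conc) || base_conc <= 0)
    stop("`base_conc` must be positive")
  if (!is.numeric(acid_conc) || acid_conc <= 0)
    stop("`acid_conc` must be positive")
  pKa + log10(base_conc / acid_conc)
}

#' Define a competitive metal / indicator / chelator equilibrium system
#'
#' Describes one well of the competitive assay: a divalent metal ion M
#' (calcium or magnesium), the metallochromic indicator D
#' (o-cresolphthalein complexone) forming a 1:1 complex MD, and a chelator L
#' forming a single dominant complex ML_s with `s` chelator molecules per
#' metal ion. Formation constants are thermodynamic; protonation of the
#' indicator and of the chelating hydroxyl is folded in through conditional
#' constants at the system pH (see [conditional_constant()]).
#'
#' @param M_total,D_total,L_total total molar concentrations of metal,
#'   indicator and chelator (>= 0).
#' @param beta_MD formation constant of the 1:1 metal-indicator complex
#'   (M^-1).
#' @param beta_MLs overall formation constant of the s:1 chelator:metal
#'   complex (M^-s).
#' @param s stoichiometry, chelator molecules per metal ion; one of 1, 2, 3.
#' @param pH solution pH in [0, 14].
#' @param pKa_indicator acid constants of the indicator donor groups
#'   governing its conditional metal binding (may be empty).
#' @param pKa_chelator optional acid constant of the chelating hydroxyl;
#'   applied once per chelator molecule in the complex (`s` times in total).
#' @return an object of class `speciation_system`.
#' @seealso [solve_speciation()]
#' @export
speciation_system <- function(M_total, D_total, L_total,
                              beta_MD, beta_MLs, s = 1L,
                              pH = 7.5,
                              pKa_indicator = numeric(),
                              pKa_chelator = NULL) {
  totals <- c(M_total = M_total, D_total = D_total, L_total = L_total)
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("total concentrations must be finite and non-negative")
  if (!is.finite(beta_MD) || beta_MD < 0 || !is.finite(beta_MLs) || beta_MLs < 0)
    stop("formation constants must be finite and non-negative")
  s <- as.integer(s)
  if (!s %in% 1:3) stop("`s` must be 1, 2 or 3")
  if (!is.finite(pH) || pH < 0 || pH > 14) stop("`pH` must lie in [0, 14]")
  structure(
    list(M_total = M_total, D_total = D_total, L_total = L_total,
         beta_MD = beta_MD, beta_MLs = beta_MLs, s = s, pH = pH,
         pKa_indicator = as.numeric(pKa_indicator),
         pKa_chelator = if (is.null(pKa_chelator)) NULL else as.numeric(pKa_chelator)),
    class = "speciation_system")
}

#' @export
print.speciation_system <- function(x, ...) {
  cat("Competitive speciation system\n")
  cat(sprintf("  totals (M): metal %.3g, indicator %.3g, chelator %.3g\n",
              x$M_total, x$D_total, x$L_total))
  cat(sprintf("  beta_MD = %.3g M^-1, beta_ML%d = %.3g M^-%d, pH = %.2f\n",
              x$beta_MD, x$s, x$beta_MLs, x$s, x$pH))
  invisible(x)
}

# Conditional constants of a system at its own pH. The chelating hydroxyl
# pKa applies once per chelator molecule bound, i.e. s times for ML_s.
system_conditional <- function(sys) {
  bD <- conditional_constant(sys$beta_MD, sys$pH, sys$pKa_indicator)
  pka_L <- if (is.null(sys$pKa_chelator)) numeric() else rep(sys$pKa_chelator, sys$s)
  bL <- conditional_constant(sys$beta_MLs, sys$pH, pka_L)
  list(bD = bD, bL = bL)
}

# Mass-balance residuals (absolute) for free concentrations m, d, l.
speciation_residuals <- function(m, d, l, bD, bL, s, M, D, L) {
  c(M = m + bD * m * d + bL * m * l^s - M,
    D = d + bD * m * d - D,
    L = l + s * bL * m * l^s - L)
}

#' Solve the competitive mass-action equilibrium
#'
#' Solves the three mass balances of a [speciation_system()] for the free
#' concentrations of metal, indicator and chelator:
#' \deqn{M_t = [M] + [MD] + [ML_s], \quad D_t = [D] + [MD], \quad
#'       L_t = [L] + s[ML_s]}
#' with \eqn{[MD] = \beta'_{MD}[M][D]} and
#' \eqn{[ML_s] = \beta'_{ML_s}[M][L]^s}, where the primed constants are the
#' conditional constants at the system pH. The solution is unique for
#' non-negative concentrations.
#'
#' A damped Newton iteration on log-transformed free concentrations is used
#' (positivity is automatic on the log scale and convergence is fast even in
#' the stiff strong-binding regimes of the best chelators); if it fails to
#' converge, the solver falls back to bisection on free metal with exact
#' inner solves for indicator and chelator.
#'
#' @param system a [speciation_system()].
#' @param tol absolute convergence tolerance on log free concentrations.
#' @param max_iter maximum Newton iterations before falling back.
#' @return an object of class `speciation_result`: list with `free_M`,
#'   `free_D`, `free_L`, `conc_MD`, `conc_MLs` (molar), `residuals`
#'   (relative mass-balance errors), `iterations`, and `method`
#'   (`"newton"` or `"bisection"`).
#' @examples
#' sys <- speciation_system(5e-4, 6.7e-4, 5e-4, beta_MD = 1e5,
#'                          beta_MLs = 1e12, s = 1)
#' solve_speciation(sys)
#' @export
solve_speciation <- function(system, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(system, "speciation_system"))
  M <- system$M_total; D <- system$D_total; L <- system$L_total
  s <- system$s
  bb <- system_conditional(system)
  bD <- bb$bD; bL <- bb$bL
  # species absent from the system (zero total) stay at zero concentration
  if (D == 0) bD_eff <- 0 else bD_eff <- bD
  if (L == 0) bL_eff <- 0 else bL_eff <- bL
  if (M == 0) {
    return(new_speciation_result(0, D, L, bD, bL, s, M, D, L, 0L, "closed_form"))
  }
  out <- speciation_newton(M, D, L, bD_eff, bL_eff, s, tol, max_iter)
  if (is.null(out)) {
    out <- speciation_bisect(M, D, L, bD_eff, bL_eff, s)
    res <- new_speciation_result(out$m, out$d, out$l, bD, bL, s, M, D, L,
                                 out$iterations, "bisection")
  } else {
    res <- new_speciation_result(out$m, out$d, out$l, bD, bL, s, M, D, L,
                                 out$iterations, "newton")
  }
  if (max(abs(res$residuals)) > 1e-9)
    stop(sprintf(
      "speciation solver did not converge: max relative residual %.3g",
      max(abs(res$residuals))))
  res
}

new_speciation_result <- function(m, d, l, bD, bL, s, M, D, L,
                                  iterations, method) {
  conc_MD <- bD * m * d
  conc_MLs <- bL * m * l^s
  abs_res <- speciation_residuals(m, d, l, bD, bL, s, M, D, L)
  rel <- abs_res / pmax(c(M, D, L), .Machine$double.eps)
  structure(
    list(free_M = m, free_D = d, free_L = l,
         conc_MD = conc_MD, conc_MLs = conc_MLs,
         residuals = rel, iterations = iterations, method = method),
    class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Speciation result (", x$method, ", ", x$iterations, " iterations)\n",
      sep = "")
  cat(sprintf("  free  M %.4g  D %.4g  L %.4g (M)\n",
              x$free_M, x$free_D, x$free_L))
  cat(sprintf("  bound MD %.4g  MLs %.4g (M)\n", x$conc_MD, x$conc_MLs))
  cat(sprintf("  max |relative residual| %.2g\n", max(abs(x$residuals))))
  invisible(x)
}

# Damped Newton on u = log(free concentrations) for species with positive
# totals. Returns NULL on failure so the caller can fall back.
speciation_newton <- function(M, D, L, bD, bL, s, tol, max_iter) {
  act <- c(M > 0, D > 0, L > 0)  # M > 0 guaranteed by caller
  tot <- c(M, D, L)
  # initial guess: half of each total
  conc <- ifelse(act, tot / 2, 0)
  resid_norm <- function(conc) {
    f <- speciation_residuals(conc[1], conc[2], conc[3], bD, bL, s, M, D, L)
    sqrt(sum((f / pmax(tot, .Machine$double.eps))[act]^2))
  }
  u <- log(conc[act])
  for (it in seq_len(max_iter)) {
    m <- if (act[1]) exp(u[cumsum(act)[1]]) else 0
    d <- if (act[2]) exp(u[cumsum(act)[2]]) else 0
    l <- if (act[3]) exp(u[cumsum(act)[3]]) else 0
    f <- speciation_residuals(m, d, l, bD, bL, s, M, D, L)
    J <- rbind(
      c(1 + bD * d + bL * l^s, bD * m,     s * bL * m * l^max(s - 1, 0)),
      c(bD * d,                1 + bD * m, 0),
      c(s * bL * l^s,          0,          1 + s^2 * bL * m * l^max(s - 1, 0)))
    # chain rule to the log scale: dF/du_j = dF/dc_j * c_j
    Ju <- J[act, act, drop = FALSE] *
      rep(c(m, d, l)[act], each = sum(act))
    step <- tryCatch(solve(Ju, -f[act]), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # cap the log step to keep the iteration in a sane region
    cap <- 4
    if (max(abs(step)) > cap) step <- step * cap / max(abs(step))
    base_norm <- resid_norm(c(m, d, l))
    lambda <- 1
    repeat {
      u_new <- u + lambda * step
      conc_new <- c(0, 0, 0); conc_new[act] <- exp(u_new)
      if (all(is.finite(conc_new)) && resid_norm(conc_new) <= base_norm) break
      lambda <- lambda / 2
      if (lambda < 1e-8) return(NULL)
    }
    u <- u + lambda * step
    if (max(abs(lambda * step)) < tol) {
      conc <- c(0, 0, 0); conc[act] <- exp(u)
      return(list(m = conc[1], d = conc[2], l = conc[3], iterations = it))
    }
  }
  NULL
}

# Robust fallback: bisection on free metal in log space. For a trial free
# metal the indicator balance is closed-form and the chelator balance is a
# monotone scalar equation solved by inner bisection; the metal balance is
# then strictly increasing in free metal.
speciation_bisect <- function(M, D, L, bD, bL, s, n_iter = 220L) {
  free_l <- function(m) {
    if (L == 0 || bL == 0) return(L)
    if (s == 1) return(L / (1 + bL * m))
    lo <- 0; hi <- L
    for (i in seq_len(160L)) {
      mid <- (lo + hi) / 2
      if (mid + s * bL * m * mid^s - L > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  g <- function(m) {
    d <- if (D == 0) 0 else D / (1 + bD * m)
    l <- free_l(m)
    m + bD * m * d + bL * m * l^s - M
  }
  lo <- log(M) - 60 * log(10); hi <- log(M)
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (g(exp(mid)) > 0) hi <- mid else lo <- mid
  }
  m <- exp((lo + hi) / 2)
  list(m = m, d = if (D == 0) 0 else D / (1 + bD * m), l = free_l(m),
       iterations = n_iter)
}

#' Read or write a speciation system as a YAML key-value config
#'
#' The on-disk representation uses the keys `m_total`, `d_total`, `l_total`,
#' `beta_md`, `beta_mls`, `s`, `ph`, `pka_indicator`, `pka_chelator`.
#'
#' @param path file path.
#' @return `read_speciation_config()` returns a [speciation_system()];
#'   `write_speciation_config()` returns `path` invisibly.
#' @export
read_speciation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("m_total", "d_total", "l_total", "beta_md", "beta_mls", "s", "ph")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config is missing keys: ", paste(missing, collapse = ", "))
  speciation_system(
    M_total = cfg$m_total, D_total = cfg$d_total, L_total = cfg$l_total,
    beta_MD = cfg$beta_md, beta_MLs = cfg$beta_mls, s = cfg$s, pH = cfg$ph,
    pKa_indicator = if (is.null(cfg$pka_indicator)) numeric() else cfg$pka_indicator,
    pKa_chelator = cfg$pka_chelator)
}

#' @rdname read_speciation_config
#' @param system a [speciation_system()].
#' @export
write_speciation_config <- function(system, path) {
  stopifnot(inherits(system, "speciation_system"))
  yaml::write_yaml(
    list(m_total = system$M_total, d_total = system$D_total,
         l_total = system$L_total, beta_md = system$beta_MD,
         beta_mls = system$beta_MLs, s = system$s, ph = system$pH,
         pka_indicator = system$pKa_indicator,
         pka_chelator = system$pKa_chelator),
    path)
  invisible(path)
}
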