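# Independent brute-force speciation oracle: nested bisection in log space,
# written against the mass-balance definitions only (no package internals).
# Free indicator is closed-form given free metal; free chelator is found by
# inner bisection; free metal by outer bisection on the metal balance,
# which is strictly increasing in free metal.
oracle_speciation <- function(M, D, L, bD, bL, s) {
  if (M == 0) return(list(free_M = 0, free_D = D, free_L = L))
  free_l_given_m <- function(m) {
    if (L == 0 || bL == 0 || m == 0) return(L)
    lo <- 0; hi <- L
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mid + s * bL * m * mid^s > L) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  metal_total_at <- function(m) {
    d <- if (D == 0) 0 else D / (1 + bD * m)
    l <- free_l_given_m(m)
    m + bD * m * d + bL * m * l^s
  }
  lo <- log(M) - 80 * log(10); hi <- log(M)
  for (i in 1:260) {
    mid <- (lo + hi) / 2
    if (metal_total_at(exp(mid)) > M) hi <- mid else lo <- mid
  }
  m <- exp((lo + hi) / 2)
  list(free_M = m,
       free_D = if (D == 0) 0 else D / (1 + bD * m),
       free_L = free_l_given_m(m))
}

# Two-species (metal + indicator) closed form from the quadratic
# m^2 bD + m (1 + bD (D - M)) - M = 0.
closed_form_md <- function(M, D, bD) {
  if (bD == 0) return(list(free_M = M, free_D = D, conc_MD = 0))
  a <- bD; b <- 1 + bD * (D - M); cc <- -M
  m <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  d <- D / (1 + bD * m)
  list(free_M = m, free_D = d, conc_MD = bD * m * d)
}

# Textbook pooled-variance two-sample t statistic.
textbook_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
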