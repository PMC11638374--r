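# Shared fixture shortcuts for the simulated assay.
default_chem <- function(metal = "Ca") assay_chemistry(metal)

quiet_protocol <- function(...) assay_protocol(noise_sd = 0, ...)

# Simulate one chelation titration and return replicate-level chelation data.
simulated_titration <- function(beta, s, ratios, seed, metal = "Ca",
                                protocol = assay_protocol(), pKa = NULL) {
  plate <- simulate_chelation_plate(
    protocol, metal = metal,
    chelator = list(beta_MLs = beta, s = s, pKa = pKa),
    ratio_ladder = ratios, seed = seed)
  plate_chelation(plate)
}

# Replicate-level draws from the logistic chelation model with known
# parameters, for parameter-recovery checks.
logistic_draws <- function(logec50, k, ratios, n_rep = 3, noise_sd = 2,
                           seed = 1) {
  with_fixed_seed(seed, {
    r <- rep(ratios, each = n_rep)
    y <- 100 / (1 + 10^((logec50 - log10(r)) * k)) +
      rnorm(length(r), sd = noise_sd)
    data.frame(ratio = r, chelation_pct = y)
  })
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
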