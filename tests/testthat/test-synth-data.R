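test_that("spectra follow Beer-Lambert superposition of Gaussian bands", {
  chem <- default_chem("Ca")
  wl <- seq(350, 650, by = 1)
  # all concentrations zero, no noise: identically zero
  blank <- simulate_spectrum(list(list(species = chem$indicator, conc = 0)),
                             wl, noise_sd = 0)
  expect_true(all(blank$absorbance == 0))
  # single species, no noise: argmax at the largest-amplitude peak center
  one <- simulate_spectrum(list(list(species = chem$indicator, conc = 4.5e-4)),
                           wl, noise_sd = 0)
  expect_equal(one$wavelength_nm[which.max(one$absorbance)], 574)
  # linear in concentration and path length
  two <- simulate_spectrum(list(list(species = chem$indicator, conc = 9e-4)),
                           wl, noise_sd = 0)
  expect_equal(two$absorbance, 2 * one$absorbance, tolerance = 1e-12)
  expect_error(simulate_spectrum(list(), numeric()), "empty")
})

test_that("identical seeds give bit-identical synthetic data", {
  chem <- default_chem("Ca")
  wl <- seq(350, 650, by = 2)
  a <- simulate_spectrum(list(list(species = chem$indicator, conc = 4e-4)),
                         wl, noise_sd = 0.01, seed = 11)
  b <- simulate_spectrum(list(list(species = chem$indicator, conc = 4e-4)),
                         wl, noise_sd = 0.01, seed = 11)
  expect_identical(a, b)
  p <- assay_protocol()
  p1 <- simulate_chelation_plate(p, "Mg", list(beta_MLs = 1e10, s = 1),
                                 c(0.5, 1, 2, 10), seed = 5)
  p2 <- simulate_chelation_plate(p, "Mg", list(beta_MLs = 1e10, s = 1),
                                 c(0.5, 1, 2, 10), seed = 5)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  t1 <- simulate_aggregation_trace(1e-3, seed = 3)
  t2 <- simulate_aggregation_trace(1e-3, seed = 3)
  expect_identical(t1, t2)
})

test_that("noiseless calibration is monotone and blanks match indicator-only", {
  p <- quiet_protocol(final_indicator = 4.5e-4)
  ladder <- seq(2e-5, 1.95e-4, length.out = 8)
  series <- simulate_calibration(p, "Ca", ladder)
  at_peak <- series[series$wavelength_nm == 572 & series$replicate == 1, ]
  expect_true(all(diff(at_peak$absorbance[order(at_peak$conc)]) > 0))
  # blanks-only ladder equals the indicator-only absorbance
  blanks <- simulate_calibration(p, "Ca", 0)
  chem <- default_chem("Ca")
  ref <- simulate_spectrum(list(list(species = chem$indicator, conc = 4.5e-4)),
                           p$wavelengths, noise_sd = 0,
                           path_length = p$path_length)
  expect_equal(mean(blanks$absorbance[blanks$wavelength_nm == 574]),
               ref$absorbance[ref$wavelength_nm == 574], tolerance = 1e-6)
})

test_that("seeded noisy magnesium calibration is linear at 568 nm", {
  p <- assay_protocol(final_indicator = 4.5e-4)
  series <- simulate_calibration(p, "Mg", seq(2e-5, 1.95e-4, length.out = 8),
                                 seed = 42)
  at568 <- series[series$wavelength_nm == 568, ]
  means <- aggregate(absorbance ~ conc, data = at568, FUN = mean)
  r2 <- summary(lm(absorbance ~ conc, data = means))$r.squared
  expect_gte(r2, 0.99)
})

test_that("plate layout, roles and capacity behave", {
  p <- assay_protocol()
  plate <- simulate_chelation_plate(p, "Ca", list(beta_MLs = 1e12, s = 1),
                                    c(0.25, 0.5, 1, 10), seed = 1)
  expect_s3_class(plate, "plate_reading")
  wells <- plate[!duplicated(plate$well), ]
  expect_equal(sum(wells$role == "negative_control"), 3)
  expect_equal(sum(wells$role == "positive_control"), 3)
  expect_equal(sum(wells$role == "sample"), 12)
  # two timepoints per well at one wavelength
  expect_equal(nrow(plate), 18 * 2)
  # overfull plate rejected
  expect_error(
    simulate_chelation_plate(p, "Ca", list(beta_MLs = 1e12, s = 1),
                             seq(0.1, 10, length.out = 40)),
    "96")
})

test_that("ratio-zero sample wells coincide with positive controls", {
  p <- quiet_protocol()
  plate <- simulate_chelation_plate(p, "Ca", list(beta_MLs = 1e12, s = 1),
                                    c(0, 1, 2, 5), seed = 2)
  d <- plate[plate$timepoint_min == 0, ]
  pos <- d$absorbance[d$role == "positive_control"]
  zero <- d$absorbance[d$role == "sample" & d$ratio == 0]
  expect_equal(unique(zero), unique(pos), tolerance = 1e-12)
})

test_that("a strong 1:1 chelator in excess bleaches to the negative control", {
  p <- quiet_protocol()
  plate <- simulate_chelation_plate(p, "Ca", list(beta_MLs = 1e12, s = 1),
                                    c(0.5, 1, 2, 10), seed = 2)
  d <- plate[plate$timepoint_min == 0, ]
  neg <- mean(d$absorbance[d$role == "negative_control"])
  r10 <- mean(d$absorbance[d$role == "sample" & d$ratio == 10])
  window <- mean(d$absorbance[d$role == "positive_control"]) - neg
  expect_lt(abs(r10 - neg) / window, 0.01)
})

test_that("strong 1:1 titration follows the 100*min(r,1) speciation template", {
  chel <- simulated_titration(1e12, 1, c(0.25, 0.5, 0.75, 1, 2, 10),
                              seed = 7,
                              protocol = assay_protocol(noise_sd = 0.002))
  means <- tapply(chel$chelation_pct, chel$ratio, mean)
  expected <- 100 * pmin(as.numeric(names(means)), 1)
  expect_true(all(abs(means - expected) < 3))
})

test_that("acidic pH collapses the calibration slope", {
  slope_at <- function(ph, seed) {
    p <- assay_protocol(final_indicator = 4.5e-4, pH = ph,
                        wavelengths = c(568, 572))
    series <- simulate_calibration(p, "Ca",
                                   seq(2e-5, 1.95e-4, length.out = 6),
                                   seed = seed)
    d <- series[series$wavelength_nm == 572, ]
    means <- aggregate(absorbance ~ conc, data = d, FUN = mean)
    unname(coef(lm(absorbance ~ conc, data = means))[2])
  }
  s75 <- slope_at(7.5, 31)
  expect_lt(abs(slope_at(5.5, 32)) / s75, 0.05)
  expect_lt(abs(slope_at(4.5, 33)) / s75, 0.05)
  # intermediate pH: reduced but present
  expect_lt(slope_at(6.8, 34) / s75, 1)
})

test_that("simulated chelation falls monotonically with chelator pKa", {
  pkas <- c(6.5, 7.5, 8.5, 9.5, 10.5)
  chel <- vapply(seq_along(pkas), function(i) {
    d <- simulated_titration(1e7, 1, 1, seed = 100 + i, pKa = pkas[i],
                             protocol = quiet_protocol())
    mean(d$chelation_pct)
  }, numeric(1))
  expect_true(all(diff(chel) < 0))
})

test_that("aggregation traces scale with free calcium through the Hill term", {
  flat <- simulate_aggregation_trace(0, noise_sd = 0)
  expect_equal(flat$auc, 0)
  full <- simulate_aggregation_trace(1e-2, noise_sd = 0)
  half <- simulate_aggregation_trace(2e-4, noise_sd = 0)  # at K_Ca
  expect_equal(half$auc / full$auc, 0.5, tolerance = 1e-6)
  expect_error(simulate_aggregation_trace(1e-3, duration = -1), "positive")
})
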