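test_that("chelation percentage matches its defining formula", {
  expect_equal(chelation_percent(0.6, c(0.19, 0.21), c(0.99, 1.01))$chelation_pct,
               50)
  # sample at the positive-control mean: no chelation
  expect_equal(chelation_percent(1.0, c(0.2), c(1.0))$chelation_pct, 0)
  # sample at the negative-control mean: complete chelation
  expect_equal(chelation_percent(0.2, c(0.2), c(1.0))$chelation_pct, 100)
  # out-of-range values are kept but flagged
  m <- chelation_percent(c(0.1, 0.6, 1.15), c(0.2), c(1.0))
  expect_equal(m$chelation_pct, c(112.5, 50, -18.75))
  expect_equal(m$flagged, c(TRUE, FALSE, TRUE))
  expect_error(chelation_percent(0.5, c(0.50), c(0.52)), "no assay window")
})

test_that("chelation percentage is invariant to an absorbance offset", {
  set.seed(1)
  for (i in 1:20) {
    ax <- runif(1, 0.2, 1.2)
    neg <- runif(3, 0.15, 0.25); pos <- runif(3, 0.9, 1.1)
    shift <- runif(1, -0.5, 0.5)
    expect_equal(
      chelation_percent(ax, neg, pos)$chelation_pct,
      chelation_percent(ax + shift, neg + shift, pos + shift)$chelation_pct,
      tolerance = 1e-9)
  }
})

test_that("logistic fit reproduces the 1:1 expectation identity", {
  # LogEC50 = 0 forces 50% at 1:1 for any slope
  for (k in c(0.5, 1, 3)) {
    d <- logistic_draws(0, k, c(0.1, 0.3, 1, 3, 10), noise_sd = 0.5,
                        seed = round(10 * k))
    fit <- fit_chelation_curve(d$ratio, d$chelation_pct)
    expect_equal(100 / (1 + 10^(fit$logec50 * fit$k)), fit$Y_1to1,
                 tolerance = 1e-12)
  }
  # hand evaluation: LogEC50 = -1, k = 1 gives 100/(1 + 10^-1)
  d <- logistic_draws(-1, 1, c(0.03, 0.1, 0.3, 1, 3, 10), noise_sd = 0,
                      seed = 3)
  fit <- fit_chelation_curve(d$ratio, d$chelation_pct)
  expect_equal(fit$logec50, -1, tolerance = 1e-6)
  expect_equal(fit$Y_1to1, 100 / (1 + 10^-1), tolerance = 1e-4)
  expect_equal(fit$Y_1to1, 90.909091, tolerance = 1e-6)
  # opposite sign convention is selectable
  flipped <- fit_chelation_curve(d$ratio, d$chelation_pct, y_sign = -1)
  expect_equal(flipped$Y_1to1, 100 / (1 + 10^(1 * 1)), tolerance = 1e-4)
})

test_that("degenerate curve inputs are rejected informatively", {
  expect_error(fit_chelation_curve(c(1, 2, 10), c(10, 50, 90)),
               "4 distinct")
  expect_error(fit_chelation_curve(rep(c(0.5, 1, 5, 10), 2), rep(40, 8)),
               "flat")
})

test_that("fitted LogEC50 recovers the generating value on synthetic curves", {
  d <- logistic_draws(-0.3, 2, c(0.25, 0.5, 0.75, 1, 2, 5, 10),
                      noise_sd = 2, seed = 17)
  fit <- fit_chelation_curve(d$ratio, d$chelation_pct)
  expect_gt(-0.3, fit$ci95["logec50", 1])
  expect_lt(-0.3, fit$ci95["logec50", 2])
  # and against the simulator: a strong 1:1 chelator crosses 50% near
  # ratio 0.5, i.e. LogEC50 near log10(0.5)
  chel <- simulated_titration(1e12, 1, c(0.25, 0.5, 0.75, 1, 2, 10),
                              seed = 6)
  fit2 <- fit_chelation_curve(chel$ratio, chel$chelation_pct)
  expect_lt(abs(fit2$logec50 - log10(0.5)), 0.1)
})

test_that("stoichiometry inference identifies exact binding templates", {
  r1 <- rep(c(0.5, 1, 2, 10), each = 3)
  y1 <- 100 * pmin(r1 / 1, 1)
  expect_equal(infer_stoichiometry(r1, y1)$s, 1L)
  r3 <- rep(c(1, 3, 6, 10), each = 3)
  y3 <- 100 * pmin(r3 / 3, 1)
  expect_equal(infer_stoichiometry(r3, y3)$s, 3L)
  # incomplete titration: no stoichiometry
  low <- infer_stoichiometry(r1, y1 * 0.6)
  expect_true(is.na(low$s))
  expect_match(low$reason, "incomplete")
})

test_that("stoichiometry inference recovers the generator truth from plates", {
  s1 <- simulated_titration(1e12, 1, c(0.25, 0.5, 0.75, 1, 2, 10), seed = 11)
  expect_equal(infer_stoichiometry(s1$ratio, s1$chelation_pct)$s, 1L)
  s3 <- simulated_titration(1e15, 3, c(0.5, 1, 2, 3, 5, 10), seed = 11)
  expect_equal(infer_stoichiometry(s3$ratio, s3$chelation_pct)$s, 3L)
})

test_that("stoichiometry recovery holds across repeated seeded simulations", {
  rec1 <- vapply(1:20, function(i) {
    d <- simulated_titration(1e12, 1, c(0.25, 0.5, 0.75, 1, 2, 10),
                             seed = 700 + i)
    identical(infer_stoichiometry(d$ratio, d$chelation_pct)$s, 1L)
  }, logical(1))
  rec3 <- vapply(1:20, function(i) {
    d <- simulated_titration(1e15, 3, c(0.5, 1, 2, 3, 5, 10),
                             seed = 800 + i)
    identical(infer_stoichiometry(d$ratio, d$chelation_pct)$s, 3L)
  }, logical(1))
  expect_gte(mean(rec1), 0.95)
  expect_gte(mean(rec3), 0.95)
})

test_that("potency classification reproduces the four tiers", {
  ratios <- c(0.25, 0.5, 0.75, 1, 2, 3, 5, 10)
  # flat zero: inactive
  flat <- with_fixed_seed(99, classify_potency(rep(ratios, each = 3),
                                               rnorm(24, 0, 0.3)))
  expect_equal(flat$category, "inactive")
  # exact template at low ratio: very strong
  r <- rep(ratios, each = 3)
  vs <- classify_potency(r, 100 * pmin(r, 1))
  expect_equal(vs$category, "very_strong")
  expect_equal(vs$s, 1L)
  # complete only at 10: moderate
  mod <- simulated_titration(5e5, 1, ratios, seed = 13)
  expect_equal(classify_potency(mod$ratio, mod$chelation_pct)$category,
               "moderate")
  # partial at 10: weak
  wk <- simulated_titration(1e4, 1, ratios, seed = 13)
  cls_wk <- classify_potency(wk$ratio, wk$chelation_pct)
  expect_equal(cls_wk$category, "weak")
  expect_lt(cls_wk$p_at_top, 0.05)
  # quinoline-like 3:1 very strong chelator
  q <- simulated_titration(1e15, 3, c(0.5, 1, 2, 3, 5, 10), seed = 13)
  cls_q <- classify_potency(q$ratio, q$chelation_pct)
  expect_equal(cls_q$category, "very_strong")
  expect_equal(cls_q$s, 3L)
})

test_that("potency category never demotes as the formation constant grows", {
  rank <- c(inactive = 1, weak = 2, moderate = 3, very_strong = 4)
  ratios <- c(0.25, 0.5, 0.75, 1, 2, 3, 5, 10)
  betas <- c(1e1, 1e3, 1e4, 1e5, 5e5, 1e8, 1e12)
  cats <- vapply(seq_along(betas), function(i) {
    d <- simulated_titration(betas[i], 1, ratios, seed = 200 + i)
    classify_potency(d$ratio, d$chelation_pct)$category
  }, character(1))
  expect_true(all(diff(rank[cats]) >= 0))
})

test_that("confidence-band comparison separates chelators 100x apart", {
  ratios <- c(0.5, 1, 2, 3, 5, 10)
  strong <- simulated_titration(1e7, 1, ratios, seed = 31)
  weaker <- simulated_titration(1e5, 1, ratios, seed = 32)
  ca <- fit_chelation_curve(strong$ratio, strong$chelation_pct)
  cb <- fit_chelation_curve(weaker$ratio, weaker$chelation_pct)
  expect_equal(compare_curves(ca, cb)$verdict, "a_stronger")
  expect_equal(compare_curves(cb, ca)$verdict, "b_stronger")
  # a curve against itself is indistinguishable
  expect_equal(compare_curves(ca, ca)$verdict, "indistinguishable")
})

test_that("SAR regression finds the negative pKa-chelation relationship", {
  pkas <- c(6.0, 6.8, 7.6, 8.4, 9.2, 10.0)
  chel <- vapply(seq_along(pkas), function(i) {
    d <- simulated_titration(1e7, 1, 1, seed = 300 + i, pKa = pkas[i])
    mean(d$chelation_pct)
  }, numeric(1))
  fit <- sar_regression(pkas, chel)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.05)
  # exact line: R2 = 1 (summary.lm warns about the perfect fit)
  exact <- suppressWarnings(sar_regression(c(6, 7, 8), c(90, 70, 50)))
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_error(sar_regression(rep(7, 4), c(1, 2, 3, 4)), "degenerate")
  expect_error(sar_regression(c(6, 7), c(1, 2)), "3 compounds")
})
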