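test_that("noiseless binding curves are generated and fit exactly", {
  spec <- binding_curve_spec(K05 = 1, h = 2, cv = 0, replicates = 1)
  cur <- simulate_binding_curve(spec)
  # zero dose sits at the top plateau; dose = K0.5 is exactly half-maximal
  expect_equal(cur$signal[cur$concentration == 0], 1)
  expect_equal(cur$signal[cur$concentration == 1], 0.5)
  # expected signal is monotone non-increasing with dose
  expect_true(all(diff(cur$signal[order(cur$concentration)]) <= 1e-12))
  fit <- fit_dose_response(cur, bootstrap_n = 0)
  expect_equal(fit$K05, 1, tolerance = 1e-6)
  expect_equal(fit$h, 2, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
})

test_that("fitted K0.5 matches the half-max crossing on dense noiseless data", {
  spec <- binding_curve_spec(K05 = 0.61, h = 1.7, cv = 0, replicates = 1,
                             concentrations = c(0, exp(seq(log(0.01),
                                                           log(20), length.out = 60))))
  cur <- simulate_binding_curve(spec)
  ord <- order(cur$concentration)
  crossing <- cofilinscreen:::halfmax_crossing(
    cur$concentration[ord], cur$signal[ord], 1, min(cur$signal))
  fit <- fit_dose_response(cur, bootstrap_n = 0)
  # the interpolation oracle carries grid discretization error (~0.2%)
  expect_equal(fit$K05, crossing, tolerance = 5e-3)
  expect_equal(fit$K05, 0.61, tolerance = 1e-6)
})

test_that("K0.5 and slope are invariant to signal scaling", {
  spec <- binding_curve_spec(K05 = 2, h = 1.5, cv = 0.03, seed = 8)
  cur <- simulate_binding_curve(spec)
  f1 <- fit_dose_response(cur, bootstrap_n = 0)
  cur2 <- cur
  cur2$signal <- cur$signal * 37
  f2 <- fit_dose_response(cur2, bootstrap_n = 0)
  expect_equal(f2$K05, f1$K05, tolerance = 1e-6)
  expect_equal(f2$h, f1$h, tolerance = 1e-6)
  expect_equal(f2$top, f1$top * 37, tolerance = 1e-6)
})

test_that("invalid binding specifications are rejected", {
  expect_error(binding_curve_spec(K05 = -1), "positive")
  expect_error(binding_curve_spec(h = 0), "positive")
  expect_error(binding_curve_spec(cv = -0.1), "CV")
  expect_error(binding_curve_spec(preset = "nope"), "unknown")
  flat <- data.frame(concentration = c(0, 1, 2, 4, 8), signal = 1)
  expect_error(fit_dose_response(flat), "flat")
  few <- data.frame(concentration = c(0, 1, 1, 2), signal = c(1, .5, .5, .2))
  expect_error(fit_dose_response(few), "5 distinct")
})

test_that("standard-curve calibration is closed-form least squares", {
  std <- data.frame(nCi = c(2.5, 5, 10), signal = c(25, 50, 100))
  cal <- calibrate_standard_curve(std)
  expect_equal(cal$slope, 10)
  expect_equal(cal$to_nCi(50), 5)
  # noisy points: slope equals sum(xy)/sum(x^2)
  std2 <- data.frame(nCi = c(2.5, 5, 10), signal = c(27, 48, 103))
  expect_equal(calibrate_standard_curve(std2)$slope,
               sum(std2$signal * std2$nCi) / sum(std2$nCi^2))
  expect_warning(cal1 <- calibrate_standard_curve(
    data.frame(nCi = 2.5, signal = 25)), "single")
  expect_equal(cal1$slope, 10)
  expect_error(calibrate_standard_curve(data.frame(nCi = 0, signal = 0)),
               "zero-variance")
})

test_that("kinase time courses obey initial-rate linearity and emit standards", {
  spec <- kinase_curve_spec("WT", cv = 0)
  kin <- simulate_kinase_timecourse(spec)
  tc <- kin$timecourse
  for (s in unique(tc$substrate_uM)) {
    p5 <- tc$product_uM[tc$substrate_uM == s & tc$time_min == 5]
    p10 <- tc$product_uM[tc$substrate_uM == s & tc$time_min == 10]
    expect_equal(p10, 2 * p5, tolerance = 1e-12)
  }
  expect_equal(kin$standards$nCi, c(2.5, 5, 10))
  # zero substrate would give zero product at all times
  spec0 <- kinase_curve_spec(kcat = 0.2, KM = 9, substrate_uM = c(1e-12, 5, 50))
  kin0 <- simulate_kinase_timecourse(spec0)
  expect_true(all(kin0$timecourse$product_uM[
    kin0$timecourse$substrate_uM == 1e-12] < 1e-12))
  # violating the initial-rate bound is an error
  expect_error(simulate_kinase_timecourse(
    kinase_curve_spec(kcat = 5, KM = 1, timepoints_min = c(60, 600))),
    "initial-rate")
})

test_that("Michaelis-Menten fits recover noiseless parameters exactly", {
  kin <- simulate_kinase_timecourse(kinase_curve_spec("G4F", cv = 0))
  fit <- fit_michaelis_menten(kin)
  expect_equal(fit$kcat, 0.55, tolerance = 1e-6)
  expect_equal(fit$KM, 12, tolerance = 1e-6)
  expect_true(fit$initial_rate_ok)
  # half-saturation identity: fitted rate at S = KM is kcat * E / 2
  E <- kin$enzyme_nM / 1000
  v_at_km <- fit$Vmax * fit$KM / (fit$KM + fit$KM)
  expect_equal(v_at_km, fit$kcat * E / 2, tolerance = 1e-9)
})

test_that("two-point noiseless data reproduce the Lineweaver-Burk solution", {
  # closed form from two exact (S, v) pairs via the double-reciprocal line
  kcat <- 0.3; KM <- 5; E <- 0.002
  S2 <- c(2, 20)
  v <- kcat * E * S2 / (KM + S2)
  inv_fit <- lm(I(1 / v) ~ I(1 / S2))
  KM_lb <- unname(coef(inv_fit)[2] / coef(inv_fit)[1])
  Vmax_lb <- unname(1 / coef(inv_fit)[1])
  S <- c(2, 8, 20)
  tc <- expand.grid(substrate_uM = S, time_min = c(5, 10))
  tc$product_uM <- kcat * E * tc$substrate_uM /
    (KM + tc$substrate_uM) * tc$time_min * 60
  fit <- fit_michaelis_menten(list(timecourse = tc, enzyme_nM = 2))
  expect_equal(fit$KM, KM_lb, tolerance = 1e-6)
  expect_equal(fit$Vmax, Vmax_lb, tolerance = 1e-6)
  expect_error(fit_michaelis_menten(list(
    timecourse = tc[tc$substrate_uM == 2, ], enzyme_nM = 2)), "fewer than 3")
})

test_that("rates normalize to wild type and phospho-fractions are band ratios", {
  rates <- c(WT = 2.0, mutant = 0.8)
  rel <- normalize_rate_to_wt(rates)
  expect_equal(unname(rel["WT"]), 1)
  expect_equal(unname(rel["mutant"]), 0.4)
  expect_error(normalize_rate_to_wt(c(mutant = 1)), "reference")
  expect_error(normalize_rate_to_wt(c(WT = 0, mutant = 1)), "positive")
  expect_equal(phospho_fraction(0, 10), 0)
  expect_equal(phospho_fraction(5, 5), 0.5)
  expect_equal(phospho_fraction(30, 70), 0.3)
  expect_error(phospho_fraction(0, 0), "zero")
  expect_error(phospho_fraction(-1, 2), ">= 0")
})

test_that("noisy seeded simulations recover parameters with calibrated intervals", {
  # median relative error of K0.5 and kcat stays under 10% at CV 5%,
  # and the interval estimates cover the generating truth
  n_seeds <- 30
  k05_err <- k05_cov <- kcat_err <- kcat_cov <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    bf <- fit_dose_response(
      simulate_binding_curve(binding_curve_spec("WT", cv = 0.05, seed = s)),
      bootstrap_n = 200, seed = s)
    k05_err[s] <- abs(bf$K05 - 0.61) / 0.61
    k05_cov[s] <- bf$K05_ci[1] <= 0.61 && 0.61 <= bf$K05_ci[2]
    mf <- fit_michaelis_menten(simulate_kinase_timecourse(
      kinase_curve_spec("WT", cv = 0.05, seed = s)))
    kcat_err[s] <- abs(mf$kcat - 0.20) / 0.20
    kcat_cov[s] <- abs(mf$kcat - 0.20) <= 1.96 * mf$kcat_se
  }
  expect_lt(median(k05_err), 0.10)
  expect_lt(median(kcat_err), 0.10)
  expect_gte(mean(k05_cov), 0.85)
  expect_gte(mean(kcat_cov), 0.85)
})
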