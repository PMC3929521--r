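# replicate pair with a prescribed sample mean and SD (n = 2)
pair_with <- function(m, s) m + c(-1, 1) * s / sqrt(2)

test_that("calibration regression reproduces closed-form least squares", {
  # exact line
  cal <- fit_calibration(c(0.1, 0.5, 1, 2), 5 * c(0.1, 0.5, 1, 2))
  expect_equal(cal$slope, 5)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r.squared, 1)
  expect_equal(cal$response_factors, rep(5, 4))
  # two points: exact interpolating line
  cal2 <- fit_calibration(c(1, 2), c(3, 7))
  expect_equal(unname(coef(cal2)), c(-1, 4))
  expect_equal(cal2$r.squared, 1)
  expect_equal(cal2$sigma, 0)
  # noisy 8-point curve against the closed-form OLS oracle
  sim <- simulate_calibration(250, 3, noise_sd = 0.5, seed = 21)
  cal3 <- fit_calibration(sim$conc, sim$signal)
  sxx <- sum((sim$conc - mean(sim$conc))^2)
  slope_hat <- sum((sim$conc - mean(sim$conc)) *
                     (sim$signal - mean(sim$signal))) / sxx
  expect_equal(cal3$slope, slope_hat)
  expect_equal(cal3$intercept, mean(sim$signal) - slope_hat * mean(sim$conc))
  expect_gte(cal3$r.squared, 0.999)
  expect_error(fit_calibration(rep(1, 4), 1:4), "degenerate")
})

test_that("back-calculation inverts the calibration line", {
  cal <- fit_calibration(c(0.1, 0.5, 1, 2), 2 + 5 * c(0.1, 0.5, 1, 2))
  expect_equal(invert_calibration(cal, predict(cal, c(0.3, 1.7))),
               c(0.3, 1.7))
})

test_that("LOD and LOQ follow the 3.3 and 10 sigma/S rules", {
  expect_equal(unname(lod_loq(0, 5)), c(0, 0))
  expect_equal(unname(lod_loq(0.33, 33)), c(0.033, 0.1))
  lim <- lod_loq(0.017, 412)
  expect_equal(unname(lim["loq"] / lim["lod"]), 10 / 3.3)
  expect_error(lod_loq(0.1, 0), "slope")
  expect_error(lod_loq(-1, 5), "sigma")
  # from a calibration fit directly
  sim <- simulate_calibration(400, 0, levels = c(0.005, 0.01, 0.02, 0.03,
                                                 0.035, 0.040),
                              noise_sd = 0.2, seed = 5)
  cal <- fit_calibration(sim$conc, sim$signal)
  expect_equal(unname(lod_loq(cal)),
               unname(lod_loq(cal$sigma, cal$slope)))
})

test_that("%RSD uses the sample SD and matches the printed QC table", {
  expect_equal(round(precision_rsd(pair_with(1.985, 0.110)), 2), 5.54)
  expect_equal(round(precision_rsd(pair_with(1.920, 0.135)), 2), 7.03)
  expect_equal(precision_rsd(rep(3, 5)), 0)
  # scale invariance
  set.seed(2); x <- rlnorm(6)
  expect_equal(precision_rsd(17 * x), precision_rsd(x))
  expect_error(precision_rsd(1.5), "at least 2")
  expect_error(precision_rsd(c(-2, 2)), "mean must be positive")
})

test_that("%accuracy is the exact observed/nominal ratio", {
  expect_equal(accuracy_pct(1.592, 1.6), 99.5)
  expect_equal(accuracy_pct(1.920, 2.0), 96)
  expect_equal(accuracy_pct(0.77, 0.77), 100)
  expect_equal(stability_accuracy(1.944, 2.0), 97.2)
  expect_equal(stability_accuracy(1.995, 2.0), 99.75)
  expect_error(accuracy_pct(1, 0), "positive")
})

test_that("every printed accuracy cell is reproduced within truncation", {
  qc <- load_table(fbd_fixture("table4_qc.csv"), "qc")
  expect_true(all(abs(accuracy_pct(qc$mean, qc$nominal) - qc$accuracy_pct)
                  <= 0.01 + 1e-9))
  # RSD cells recomputed from printed mean and SD
  rsd <- 100 * qc$sd / qc$mean
  expect_true(all(abs(rsd - qc$rsd_pct) <= 0.01 + 1e-9))
  stab <- utils::read.csv(fbd_fixture("table5_stability.csv"))
  expect_true(all(abs(stability_accuracy(stab$measured, stab$spiked) -
                        stab$accuracy_pct) <= 0.01 + 1e-9))
})

test_that("acceptance thresholds are 15% (20% at the LLOQ)", {
  good <- pair_with(1.985, 0.110)  # RSD 5.54, accuracy 99.25 vs 2.0
  expect_true(acceptance_check(good, 2.0)$pass)
  noisy <- pair_with(1.0, 0.16)    # RSD 16
  expect_false(acceptance_check(noisy, 1.0)$pass)
  expect_true(acceptance_check(noisy, 1.0, is_lloq = TRUE)$pass)
  biased <- pair_with(0.79, 0.001) # accuracy 79 -> bias 21
  expect_false(acceptance_check(biased, 1.0, is_lloq = TRUE)$pass)
  expect_match(acceptance_check(biased, 1.0, is_lloq = TRUE)$reasons,
               "bias")
})

test_that("system suitability metrics follow the USP formulas", {
  # symmetric peak: tailing factor exactly 1
  sym <- list(tr = 4.39, w_base = 0.4, w_half = 0.2, w_05 = 0.3,
              f_05 = 0.15, t0 = 0.9)
  s <- system_suitability(sym)
  expect_equal(s$tailing, 1)
  expect_equal(s$k_prime, (4.39 - 0.9) / 0.9)
  expect_equal(s$n_base, 16 * (4.39 / 0.4)^2)
  expect_equal(s$n_half, 5.54 * (4.39 / 0.2)^2)
  # Gaussian with sigma chosen for a known plate count
  n_true <- 5318
  sigma <- 4.39 / sqrt(n_true)
  g <- list(tr = 4.39, w_half = 2 * sigma * sqrt(2 * log(2)))
  expect_lt(abs(system_suitability(g)$n_half - n_true) / n_true, 0.01)
  # identical co-eluting peaks: resolution zero
  expect_equal(system_suitability(sym, reference = sym)$rs, 0)
  # no reference peak: Rs simply absent
  expect_null(system_suitability(sym)$rs)
  bad <- sym; bad$f_05 <- 0.35
  expect_error(system_suitability(bad), "half-width")
})

test_that("validation report assembles limits and QC flags", {
  sim <- simulate_calibration(412, 0, noise_sd = 1, seed = 8)
  low <- simulate_calibration(412, 0, levels = c(0.005, 0.01, 0.02, 0.03,
                                                 0.035, 0.04),
                              noise_sd = 0.3, seed = 9)
  cal <- fit_calibration(sim$conc, sim$signal)
  lowcal <- fit_calibration(low$conc, low$signal)
  rep <- validation_report(
    cal, lod_calibration = lowcal,
    qc = list(list(nominal = 0.1, replicates = pair_with(0.094, 0.002)),
              list(nominal = 2.0, replicates = pair_with(1.985, 0.110))),
    lloq_level = 0.1)
  expect_gt(rep$loq, rep$lod)
  expect_equal(rep$loq / rep$lod, 10 / 3.3)
  expect_true(all(rep$qc$pass))
  expect_equal(rep$qc$lloq, c(TRUE, FALSE))
  expect_output(print(rep), "LOD")
  expect_type(as.list(rep), "list")
})
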