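test_that("dense single-exponential profiles approach the closed forms", {
  k <- 0.1; c0 <- 10
  t <- seq(0, 120, by = 0.25)
  res <- nca(t, c0 * exp(-k * t))
  expect_lt(abs(res$auc_inf - c0 / k) / (c0 / k), 0.001)
  expect_lt(abs(res$mrt - 1 / k) / (1 / k), 0.005)
  expect_equal(res$lambda_z, k, tolerance = 1e-6)
  expect_equal(res$t_half, log(2) / res$lambda_z)
})

test_that("NCA identities hold on simulated oral profiles", {
  times <- c(0, 1, 2, 4, 6, 8, 12, seq(24, 240, by = 24))
  for (seed in 1:5) {
    p <- simulate_oral_pk(1.5, 0.07, 10, 15, times, cv = 0.08,
                          n_subjects = 1, seed = seed)
    res <- nca(p$time, p$conc)
    expect_equal(res$mrt, res$aumc_inf / res$auc_inf)
    expect_equal(res$t_half * res$lambda_z, log(2))
    expect_gte(res$auc_inf, res$auc_last)
    expect_true(res$tmax %in% p$time)
    expect_gte(res$diagnostics$n_terminal, 3)
  }
})

test_that("lambda-z recovers the elimination rate on noise-free profiles", {
  times <- c(0, 1, 2, 4, 6, 8, 12, seq(24, 240, by = 24))
  p <- simulate_oral_pk(ka = 1.5, ke = 0.07, v_over_f = 10, dose = 15,
                        times = times)
  res <- nca(p$time, p$conc)
  expect_lt(abs(res$lambda_z - 0.07) / 0.07, 0.02)
  # Cmax/tmax sit at the sampled point nearest the analytic optimum
  truth <- attr(p, "truth")
  expect_equal(res$tmax, times[which.min(abs(times - truth$tmax))])
  expect_lte(res$cmax, truth$cmax)
})

test_that("trapezoidal AUC is additive over a partition", {
  t <- c(0, 1, 2.5, 4, 7, 12, 24)
  cc <- c(0, 4, 6, 5, 3, 1.5, 0.4)
  trap <- function(i) sum(diff(t[i]) * (head(cc[i], -1) + tail(cc[i], -1)) / 2)
  whole <- trap(1:7)
  expect_equal(trap(1:4) + trap(4:7), whole)
})

test_that("degenerate terminal phases are rejected", {
  expect_error(nca(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)),
               "lambda-z undefined|after tmax")
  expect_error(nca(c(0, 1, 2), c(0, 5, 1)), "3 positive")
  expect_error(nca(c(0, 1, 2, 3), c(1, 5, 4, 3), terminal = c(2.5, 3)),
               "fewer than 3")
})

test_that("explicit terminal windows override the best-fit rule", {
  t <- c(0, 1, 2, 4, 8, 12, 24, 48, 72)
  cc <- 10 * exp(-0.05 * t); cc[1] <- 0; cc[2] <- 8
  res <- nca(t, cc, terminal = c(12, 72))
  expect_equal(res$diagnostics$n_terminal, 4)
  expect_equal(res$lambda_z, 0.05, tolerance = 1e-8)
})

test_that("concentrations below the LOQ are dropped after the first sample", {
  t <- c(0, 1, 2, 4, 8, 12, 24, 48)
  cc <- c(0, 6, 8, 6, 3, 1.5, 0.4, 0.02)
  res <- nca(t, cc, loq = 0.05)
  expect_equal(max(res$time), 24)  # the 0.02 point is excluded
})

test_that("half-life follows ln2 over the rate constant", {
  expect_equal(t_half(log(2)), 1)
  expect_equal(t_half(0.0741), log(2) / 0.0741)  # 9.354 h
  expect_equal(t_half(0.2), 2 * t_half(0.4))
  expect_error(t_half(0), "positive")
})

test_that("Welch comparison matches the published formulas to 1e-10", {
  a <- c(1.2, 1.9, 2.4, 3.1, 2.2)
  b <- c(4.0, 5.5, 4.8, 6.1)
  cmp <- welch_t_test(a, b)
  # direct-formula oracle
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_or <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_or <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_or <- 2 * pt(abs(t_or), df_or, lower.tail = FALSE)
  expect_equal(cmp$t, t_or, tolerance = 1e-10)
  expect_equal(cmp$df, df_or, tolerance = 1e-10)
  expect_equal(cmp$p, p_or, tolerance = 1e-10)
  expect_lte(cmp$df, length(a) + length(b) - 2)
  # symmetry and identity conventions
  swap <- welch_t_test(b, a)
  expect_equal(swap$t, -cmp$t)
  expect_equal(swap$p, cmp$p)
  same <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # exactly equal variances and n: Welch collapses to the pooled test
  set.seed(4)
  x <- rnorm(8); y <- x + 1.3  # shifted copy: identical sample variance
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(welch_t_test(x, y)$p, pooled$p.value, tolerance = 1e-10)
})

test_that("group summaries aggregate per-subject NCA results", {
  times <- c(0, 1, 2, 4, 6, 8, 12, seq(24, 240, by = 24))
  cohort <- simulate_oral_pk(1.5, 0.07, 10, 15, times, cv = 0.1,
                             n_subjects = 6, seed = 30)
  results <- lapply(split(cohort, cohort$subject),
                    function(d) nca(d$time, d$conc))
  tab <- summarize_group(results)
  vals <- vapply(results, function(r) r$auc_inf, numeric(1))
  expect_equal(tab$mean[tab$parameter == "auc_inf"], mean(vals))
  expect_equal(tab$sd[tab$parameter == "auc_inf"], sd(vals))
  expect_equal(unique(tab$n), 6)
  # identical subjects collapse to zero SD; two subjects give the midpoint
  twin <- simulate_oral_pk(1.5, 0.07, 10, 15, times, cv = 0, n_subjects = 2)
  rtwin <- lapply(split(twin, twin$subject), function(d) nca(d$time, d$conc))
  ttab <- summarize_group(rtwin)
  expect_equal(ttab$sd, rep(0, nrow(ttab)))
  expect_equal(ttab$mean[1], (rtwin[[1]]$cmax + rtwin[[2]]$cmax) / 2)
  expect_error(summarize_group(rtwin[1]), "at least 2")
})
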