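test_that("noise-free synthetic surfaces are recovered exactly", {
  factors <- study_factors()
  for (nc in c(1L, 5L)) {
    d <- fccd_design(factors, n_centre = nc)
    truth <- c(4.931, 1.203, 0.231, 0.852, 3.539, 0.674)
    y <- simulate_rsm_response(truth, d, noise_sd = 0)
    fit <- fit_rsm(d, y, "synthetic")
    expect_equal(unname(coef(fit)), truth, tolerance = 1e-10)
    expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  }
})

test_that("fitted coefficients match the normal-equations oracle on real data", {
  ccd <- ccd_fixture()
  m <- design_matrix(ccd)
  for (r in c("Y1", "Y2", "Y3")) {
    fit <- fit_rsm(ccd, ccd[[r]], r)
    oracle <- normal_eq_quadratic(m[, 1], m[, 2], ccd[[r]])
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-9)
  }
})

test_that("linear coefficients obey FCCD orthogonality", {
  ccd <- ccd_fixture()
  m <- design_matrix(ccd)
  fit <- fit_rsm(ccd, ccd$Y1, "Y1")
  # closed form Sum(xi*y)/Sum(xi^2) on an orthogonal design
  expect_equal(unname(coef(fit)["b1"]),
               sum(m[, 1] * ccd$Y1) / sum(m[, 1]^2))
  expect_equal(unname(coef(fit)["b2"]),
               sum(m[, 2] * ccd$Y1) / sum(m[, 2]^2))
  # unchanged when the quadratic terms are dropped (independent lm route)
  red <- stats::lm(ccd$Y1 ~ m[, 1] + m[, 2] + I(m[, 1] * m[, 2]))
  expect_equal(unname(coef(fit)[c("b1", "b2")]),
               unname(stats::coef(red)[2:3]))
})

test_that("R-squared does not decrease when a term is added", {
  ccd <- ccd_fixture()
  m <- design_matrix(ccd)
  full <- fit_rsm(ccd, ccd$Y2, "Y2")
  red <- stats::lm(ccd$Y2 ~ m[, 1] + m[, 2] + I(m[, 1] * m[, 2]) + I(m[, 1]^2))
  expect_gte(full$r.squared, summary(red)$r.squared - 1e-12)
})

test_that("rank deficiency is reported with the aliased terms", {
  d <- data.frame(A = c(-1, 1, -1, 1, 0, 0, 0), B = c(-1, 1, -1, 1, 0, 0, 0))
  expect_error(fit_rsm(d, rnorm(7)), "aliased")
})

test_that("prediction evaluates the polynomial exactly", {
  ccd <- ccd_fixture()
  fit <- fit_rsm(ccd, ccd$Y1, "Y1")
  expect_equal(unname(predict(fit, c(0, 0))), unname(coef(fit)["b0"]))
  # toy model with only a linear term
  toy <- fit
  toy$coefficients[] <- c(0, 2, 0, 0, 0, 0)
  expect_equal(unname(predict(toy, c(1, 0))), 2)
  # intercept vs centre-point mean: quadratic intercept sits close to but
  # above the replicate mean for this convex surface
  expect_lt(abs(predict(fit, c(0, 0)) - mean(ccd$Y1[ccd$point_type == "centre"])),
            0.2)
  expect_error(predict(fit, c(0, 0, 0)), "factors")
  expect_warning(predict(fit, c(1.5, 0)), "extrapolation")
})

test_that("ANOVA identities and lack-of-fit degrees of freedom hold", {
  ccd <- ccd_fixture()
  for (r in c("Y1", "Y2")) {
    fit <- fit_rsm(ccd, ccd[[r]], r)
    a <- anova(fit)
    ss <- a$`Sum Sq`; names(ss) <- rownames(a)
    expect_equal(ss[["Model"]] + ss[["Residual"]], ss[["Total"]])
    expect_equal(ss[["Lack of fit"]] + ss[["Pure error"]], ss[["Residual"]])
    expect_equal(a["Pure error", "Df"], 4)   # 5 centre replicates
    expect_equal(a["Lack of fit", "Df"], 3)  # 13 - 6 - 4
    # pure-error SS against a direct replicate-group oracle
    centre <- ccd[[r]][ccd$point_type == "centre"]
    expect_equal(ss[["Pure error"]], sum((centre - mean(centre))^2))
    expect_equal(a["Lack of fit", "F value"],
                 (ss[["Lack of fit"]] / 3) / (ss[["Pure error"]] / 4))
  }
})

test_that("perfect-fit data give zero residual SS and R2 = 1", {
  d <- fccd_design(study_factors(), 5)
  y <- simulate_rsm_response(c(1, 2, 3, 4, 5, 6), d, noise_sd = 0)
  fit <- fit_rsm(d, y)
  a <- anova(fit)
  expect_equal(a["Residual", "Sum Sq"], 0, tolerance = 1e-20)
  expect_equal(fit$r.squared, 1)
})

test_that("ANOVA on noisy replicated data verifies the SS split", {
  d <- fccd_design(study_factors(), 5)
  y <- simulate_rsm_response(c(5, 1, 0.5, 0.2, 2, 1), d, noise_sd = 0.3,
                             seed = 99)
  fit <- fit_rsm(d, y)
  a <- anova(fit)
  m <- design_matrix(d)
  key <- apply(m, 1, paste, collapse = ",")
  pe <- sum(unlist(lapply(split(as.numeric(y), key), function(g)
    if (length(g) > 1) (g - mean(g))^2 else numeric())))
  expect_equal(a["Pure error", "Sum Sq"], pe)
  expect_equal(a["Model", "Sum Sq"] + a["Residual", "Sum Sq"],
               a["Total", "Sum Sq"])
})

test_that("without replicates the lack-of-fit rows are omitted", {
  d <- fccd_design(study_factors(), 1)
  y <- simulate_rsm_response(c(1, 1, 1, 1, 1, 1), d, noise_sd = 0.1, seed = 3)
  a <- anova(fit_rsm(d, y))
  expect_false("Lack of fit" %in% rownames(a))
  expect_true(all(c("Model", "Residual", "Total") %in% rownames(a)))
})

test_that("surface grid equals pointwise prediction", {
  ccd <- ccd_fixture()
  fit <- fit_rsm(ccd, ccd$Y2, "Y2")
  g <- surface_grid(fit, resolution = 5)
  expect_equal(g$pred, unname(predict(fit, as.matrix(g[, 1:2]))))
  g2 <- surface_grid(fit, resolution = 2)
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  expect_setequal(round(g2$pred, 10),
                  round(unname(predict(fit, corners)), 10))
  # constant surface -> constant grid
  cf <- fit; cf$coefficients[] <- c(7, 0, 0, 0, 0, 0)
  expect_equal(unique(surface_grid(cf, resolution = 4)$pred), 7)
})
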