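test_that("noise-free series are recovered exactly by both fit routes", {
  conc <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 4, 8)
  for (truth in list(c(k_c = 0.1, gi = 5), c(k_c = 2, gi = 3.5))) {
    ser <- make_isotherm_series(truth[["k_c"]], truth[["gi"]], conc)
    # OLS route (uncertainties absent)
    f_ols <- fit_langmuir(ser)
    expect_identical(f_ols$method, "ols")
    expect_equal(f_ols$k_c, truth[["k_c"]], tolerance = 1e-6)
    expect_equal(f_ols$gamma_inf, truth[["gi"]], tolerance = 1e-6)
    # ODR route (uncertainties present, data still on the curve)
    ser$sd_c0 <- 0.05 * ser$c0_mol_l
    ser$sd_gamma <- 0.05 * ser$gamma_nm2
    f_odr <- fit_langmuir(ser)
    expect_identical(f_odr$method, "odr")
    expect_equal(f_odr$k_c, truth[["k_c"]], tolerance = 1e-6)
    expect_equal(f_odr$gamma_inf, truth[["gi"]], tolerance = 1e-6)
    # K identity holds exactly
    expect_equal(f_odr$K, f_odr$k_c * f_odr$gamma_inf)
  }
})

test_that("degenerate series are rejected with informative errors", {
  expect_error(fit_langmuir(isotherm_series(c(0.1, 0.2), c(0.5, 0.9))),
               "under-determined")
  expect_error(fit_langmuir(isotherm_series(c(0.1, 0.2, 0.4), c(0, 0, 0))),
               "zero")
  expect_error(fit_langmuir(
    isotherm_series(1:4 / 10, 1:4 / 10, sd_c0 = 0, sd_gamma = 0.01),
    weighting = "odr"), "zero/absent")
})

test_that("x- and y-dominated uncertainties give different, unbiased ODR fits", {
  k_c <- 0.5; gi <- 4; K <- k_c * gi
  conc <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 4, 8)
  diffs <- 0
  errs_x <- errs_y <- numeric(0)
  for (seed in 1:40) {
    ser <- make_isotherm_series(k_c, gi, conc, noise_x = 0.06,
                                noise_y = 0.06, seed = seed)
    ser_x <- ser; ser_x$sd_c0 <- 0.10 * ser$c0_mol_l
    ser_x$sd_gamma <- 0.01 * pmax(ser$gamma_nm2, 1e-6)
    ser_y <- ser; ser_y$sd_c0 <- 0.01 * ser$c0_mol_l
    ser_y$sd_gamma <- 0.10 * pmax(ser$gamma_nm2, 1e-6)
    fx <- fit_langmuir(ser_x); fy <- fit_langmuir(ser_y)
    diffs <- diffs + (abs(fx$K - fy$K) > 1e-8)
    errs_x <- c(errs_x, abs(fx$K - K) / K)
    errs_y <- c(errs_y, abs(fy$K - K) / K)
  }
  expect_gt(diffs, 35)              # weighting direction matters
  expect_lt(median(errs_x), 0.15)   # both remain consistent with truth
  expect_lt(median(errs_y), 0.15)
})

test_that("saturation window focuses the fit on low concentrations", {
  conc <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 20, 50)
  ser <- make_isotherm_series(2, 4, conc)
  f <- fit_langmuir(ser)           # k_c * c up to 60: deep saturation
  expect_lt(f$n_used, length(conc))
  expect_lt(max(f$fit_window), 20)
  # recovery is still exact on the windowed noise-free data
  expect_equal(f$k_c, 2, tolerance = 1e-6)
  f_all <- fit_langmuir(ser, saturation_cut = Inf)
  expect_identical(f_all$n_used, length(conc))
})

test_that("henry_predict is the tangent line of the Langmuir curve", {
  f <- fake_fit(k_c = 0.5, gamma_inf = 1)   # K = 0.5 nm
  expect_identical(henry_predict(f, 0), 0)
  expect_equal(henry_predict(f, 1), 0.5 * 0.602214076, tolerance = 1e-12)
  # relative deficit at k_c c = 0.1 is 1 - 1/1.1 ~ 9.1%
  c_at <- conc_to_mol_l(0.1 / f$k_c)
  gap <- 1 - langmuir_gamma(0.1 / f$k_c, f$k_c, f$gamma_inf) /
    henry_predict(f, c_at)
  expect_equal(gap, 1 - 1 / 1.1, tolerance = 1e-12)
  # first-order tangency at the origin
  eps <- 1e-7
  expect_equal(langmuir_gamma(eps, f$k_c, f$gamma_inf) / (f$K * eps), 1,
               tolerance = 1e-6)
})

test_that("fitted Langmuir curves are monotone, concave and bounded", {
  ser <- make_isotherm_series(0.8, 5, c(0.05, 0.1, 0.3, 1, 3, 8),
                              noise_x = 0.05, noise_y = 0.05, seed = 11)
  ser$sd_c0 <- 0.05 * ser$c0_mol_l
  ser$sd_gamma <- 0.05 * ser$gamma_nm2
  f <- fit_langmuir(ser)
  c_grid <- conc_to_nm3(seq(0.001, 50, length.out = 400))
  gam <- langmuir_gamma(c_grid, f$k_c, f$gamma_inf)
  expect_true(all(diff(gam) > 0))           # monotone increasing
  expect_true(all(diff(diff(gam)) < 1e-12)) # concave
  expect_true(all(gam >= 0 & gam < f$gamma_inf))
})

test_that("K is recovered within 10% under 5% biaxial noise (median, seeded)", {
  k_c <- 0.8; gi <- 5; K <- k_c * gi
  conc <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 4)
  errs <- vapply(1:30, function(seed) {
    ser <- make_isotherm_series(k_c, gi, conc, noise_x = 0.05,
                                noise_y = 0.05, seed = seed)
    abs(fit_langmuir(ser)$K - K) / K
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
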