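test_that("cross-section ratios equal the geometric limits", {
  expect_identical(cross_section_ratio("sphere"), 0.25)
  expect_equal(cross_section_ratio("cylinder"), 1 / pi)
  # the spherical ratio is scale-free: computing it from areas at any
  # radius gives the same value
  for (R in c(0.2, 2.0)) {
    expect_equal((pi * R^2) / (4 * pi * R^2), cross_section_ratio("sphere"))
  }
  expect_silent(cross_section_ratio("custom_ratio", ratio = 0.28))
  expect_warning(cross_section_ratio("custom_ratio", ratio = 0.40),
                 "interval")
  expect_warning(cross_section_ratio("custom_ratio", ratio = 0.20),
                 "interval")
})

test_that("continuum adsorption free energy and its wetting form agree", {
  expect_equal(as.numeric(adsorption_free_energy(0, 0, 0, 1, 0.25)), 0)
  # dewetting term alone: DG = -A_c gamma_mw < 0
  dg <- adsorption_free_energy(gamma_mw = 30, gamma_sm = 0, gamma_sw = 0,
                               A_c = 1.2, A_c_star = 0.3)
  expect_equal(attr(dg, "mN_m_nm2"), -1.2 * 30)
  expect_lt(as.numeric(dg), 0)
  # substituting the Young relation gamma_sw = gamma_sv - gamma cos(theta)
  # reproduces DG = DG0 + A_c* gamma cos(theta) for random tensions
  set.seed(4)
  for (i in 1:20) {
    gmw <- runif(1, 10, 60); gsm <- runif(1, 5, 50)
    gsv <- runif(1, 5, 50); gam <- runif(1, 40, 75)
    ct <- runif(1, -1, 1)
    A_c <- runif(1, 0.5, 2); A_cs <- 0.25 * A_c
    gsw <- gsv - gam * ct
    direct <- attr(adsorption_free_energy(gmw, gsm, gsw, A_c, A_cs),
                   "mN_m_nm2")
    dg0 <- A_cs * (gsm - gsv) - A_c * gmw
    expect_equal(direct, dg0 + A_cs * gam * ct, tolerance = 1e-12)
  }
})

test_that("adsorption coefficient responds exponentially to the wetting coefficient", {
  gam <- 60
  wm <- wetting_model(Ks0 = 2, gamma = gam)
  A_m <- 4 * kBT() / gam   # makes beta gamma A_c* = 1 with the sphere ratio
  expect_equal(ks_of_costheta(0, wm, A_m), 2)               # definition
  expect_equal(ks_of_costheta(-1, wm, A_m) / 2, exp(1),
               tolerance = 1e-12)                            # e at cos = -1
  # ln K_s is exactly affine in cos(theta) and strictly decreasing
  ct <- seq(-0.7, 0.7, length.out = 15)
  lnK <- log(ks_of_costheta(ct, wm, A_m = 1.5))
  expect_true(all(diff(lnK) < 0))
  expect_equal(diff(diff(lnK)), rep(0, length(ct) - 2), tolerance = 1e-10)
  expect_error(ks_of_costheta(1.2, wm, 1), "cos")
})

test_that("free-energy route and wetting-coefficient law are the same model", {
  # K_s from b_s exp(-beta DG(theta)) with DG = DG0 + A_c* gamma cos(theta)
  # equals Ks0 exp(-beta gamma A_c* cos theta) with Ks0 = b_s exp(-beta DG0)
  b_s <- 0.07; gam <- 57.8; A_m <- 1.4; A_cs <- 0.25 * A_m; dG0 <- -8
  Ks0 <- b_s * exp(-dG0 / kBT())
  wm <- wetting_model(Ks0 = Ks0, gamma = gam)
  for (ct in seq(-1, 1, by = 0.25)) {
    dG <- dG0 + A_cs * gam * ct
    expect_equal(b_s * exp(-dG / kBT()), ks_of_costheta(ct, wm, A_m),
                 tolerance = 1e-12)
  }
})

test_that("area scaling fit recovers effective molecular surface tensions", {
  # two exact points determine the exponential exactly
  b <- 0.05; gt <- 30
  A_m <- c(0.8, 1.6)
  K <- b * exp(gt * A_m / kBT())
  f <- fit_area_scaling(A_m, K)
  expect_equal(f$b, b, tolerance = 1e-10)
  expect_equal(f$gt, gt, tolerance = 1e-10)
  # equal coefficients: zero effective tension
  expect_equal(fit_area_scaling(c(0.5, 1, 2), rep(3, 3))$gt, 0,
               tolerance = 1e-12)
  expect_error(fit_area_scaling(c(1, 2), c(1, -1)), "> 0")
  # noisy 3-point sets: median recovery within 15% over 200 seeds
  A3 <- c(0.75, 1.45, 2.2)
  K3 <- b * exp(gt * A3 / kBT())
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    Kn <- K3 * (1 + 0.05 * rnorm(3))
    abs(fit_area_scaling(A3, Kn)$gt - gt) / gt
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("K_s-K_v correlation is the exact composition of the scaling laws", {
  set.seed(11)
  for (i in 1:50) {
    wm <- wetting_model(b_s = runif(1, 0.01, 0.2),
                        b_v = runif(1, 0.01, 0.2),
                        gt_s = runif(1, 15, 35), gt_v = runif(1, 20, 40),
                        gamma = runif(1, 45, 75))
    A_m <- runif(1, 0.5, 2.5)
    ct <- runif(1, -1, 1)
    K_v <- wm$b_v * exp(wm$gt_v * A_m / wm$kBT)            # area law, vapor
    Ks0 <- wm$b_s * exp(wm$gt_s * A_m / wm$kBT)            # area law, solid
    wm$Ks0 <- Ks0
    direct <- ks_of_costheta(ct, wm, A_m)                  # wetting law
    via_corr <- ks_kv_correlation(K_v, ct, wm)
    expect_equal(as.numeric(via_corr), direct, tolerance = 1e-10)
  }
})

test_that("correlation prefactor decreases linearly with the wetting coefficient", {
  wm <- wetting_model(b_s = 0.05, b_v = 0.04, gt_s = 25.6, gt_v = 32.7,
                      gamma = 57.8)
  ct <- seq(-0.8, 0.8, by = 0.2)
  pref <- vapply(ct, function(x)
    attr(ks_kv_correlation(10, x, wm), "prefactor"), numeric(1))
  expect_true(all(diff(pref) < 0))
  expect_equal(diff(diff(pref)), rep(0, length(ct) - 2), tolerance = 1e-12)
  # symmetric case: prefactor 1 and b_s = b_v collapse onto K_s = K_v
  wm2 <- wetting_model(b_s = 0.05, b_v = 0.05, gt_s = 30, gt_v = 25,
                       gamma = 60)
  ct_sym <- (wm2$gt_s - wm2$gt_v) / (wm2$gamma * wm2$ratio)
  for (K_v in c(0.8, 21, 410)) {
    expect_equal(as.numeric(ks_kv_correlation(K_v, ct_sym, wm2)), K_v,
                 tolerance = 1e-12)
  }
  expect_error(ks_kv_correlation(0.01, 0, wm), "area")
})

test_that("SAM polarity lookup carries the bundled reference constants", {
  tab <- sam_polarity_table()
  expect_identical(tab$charge_scaling, c(0, 0.4, 0.6, 0.7, 0.8))
  expect_identical(tab$theta_deg, c(135, 120, 97, 76, 45))
  expect_true(all(diff(tab$cos_theta) > 0))
})
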