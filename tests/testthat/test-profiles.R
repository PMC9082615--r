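test_that("find_bulk recovers plateaus and rejects ramps", {
  # uniform profile: window is the full grid, c_bulk the constant
  flat <- profile_from(function(z) rep(5, length(z)))
  bk <- find_bulk(flat)
  expect_equal(bk$window, range(flat$z))
  expect_equal(bk$c_bulk, 5)
  # synthetic slab: c_bulk within 0.5% of the generator's c0,
  # window clear of the interfacial peak
  pf <- make_slab_profiles(std_slab(), std_truth(c0_mol_l = 0.2))
  bk2 <- find_bulk(pf$surfactant)
  expect_equal(bk2$c_bulk, conc_to_nm3(0.2), tolerance = 5e-3)
  expect_gt(bk2$window[1], attr(pf, "z0_true") + 0.5)
  # monotonic ramp: no window of 1 nm satisfies the flatness tolerance
  ramp <- profile_from(function(z) 1 + z, zmax = 5)
  expect_error(find_bulk(ramp), "no bulk plateau")
  expect_error(find_bulk(profile_from(function(z) rep(0, length(z)))),
               "no bulk plateau")
})

test_that("gibbs_dividing_surface solves the equal-area condition exactly", {
  c0 <- 33
  # step profile: z0 at the step
  stp <- step_profile(c0, zstar = 4)
  expect_equal(as.numeric(gibbs_dividing_surface(stp, c_bulk = c0)), 4,
               tolerance = 1e-10)
  # linear ramp from c0 at z1 to 0 at z2: z0 = midpoint
  z1 <- 3; z2 <- 5
  rampdown <- profile_from(function(z)
    c0 * pmin(1, pmax(0, (z2 - z) / (z2 - z1))), species = "water")
  expect_equal(as.numeric(gibbs_dividing_surface(rampdown, c_bulk = c0)),
               (z1 + z2) / 2, tolerance = 1e-10)
  # tanh edge centred at z_c: z0 = z_c by odd symmetry, either orientation
  for (side in c(1, -1)) {
    tanhp <- profile_from(function(z)
      c0 * 0.5 * (1 + side * tanh((z - 4.2) / 0.3)), species = "water")
    expect_equal(as.numeric(gibbs_dividing_surface(tanhp, c_bulk = c0)),
                 4.2, tolerance = 1e-9)
  }
  # non-decaying tail is rejected
  expect_error(gibbs_dividing_surface(
    profile_from(function(z) c0 * (0.6 + 0.4 * tanh(z - 5)),
                 species = "water"), c_bulk = c0),
    "decay")
})

test_that("solid_boundary finds the water-side half-height crossing", {
  # Gaussian head-group peak at 1.0, sd 0.1, water at larger z
  gp <- profile_from(function(z) exp(-(z - 1)^2 / (2 * 0.1^2)),
                     zmax = 3, dz = 0.002, species = "oh",
                     geometry = "solid_water")
  expect_equal(solid_boundary(gp, "high_z"), 1 + 0.1 * sqrt(2 * log(2)),
               tolerance = 1e-3)
  expect_equal(solid_boundary(gp, "low_z"), 1 - 0.1 * sqrt(2 * log(2)),
               tolerance = 1e-3)
  # rectangular peak on [0.9, 1.1] (half-value convention at the edges)
  dz <- 0.002
  rect <- profile_from(function(z)
    ifelse(abs(z - 1) < 0.1 - dz / 4, 1,
           ifelse(abs(z - 1) > 0.1 + dz / 4, 0, 0.5)),
    zmax = 3, dz = dz, species = "oh", geometry = "solid_water")
  expect_equal(solid_boundary(rect, "high_z"), 1.1, tolerance = 1e-9)
  # degenerate and ambiguous inputs
  expect_error(solid_boundary(profile_from(function(z) rep(0, length(z)))),
               "zero")
  bimodal <- profile_from(function(z)
    exp(-(z - 1)^2 / 0.02) + 0.9 * exp(-(z - 2)^2 / 0.02),
    zmax = 3, dz = 0.002, species = "oh", geometry = "solid_water")
  expect_error(solid_boundary(bimodal, "high_z"), "ambiguous")
})

test_that("excess_adsorption implements the trapezoid surface-excess integral", {
  # pure step at z0: zero excess
  c0 <- 0.06
  stp <- profile_from(function(z) c0 * (z >= 5), species = "surfactant")
  expect_lt(abs(excess_adsorption(stp, 5, c0, liquid_side = "high_z")), 0.01)
  # Gaussian peak of area 1 on top of the step: excess 1 within 0.01
  pk <- profile_from(function(z)
    c0 * (z >= 5) + 1 / (0.3 * sqrt(2 * pi)) * exp(-(z - 5)^2 / (2 * 0.3^2)),
    species = "surfactant")
  g1 <- excess_adsorption(pk, 5, c0, liquid_side = "high_z")
  expect_equal(g1, 1, tolerance = 0.01)
  # quadrature convergence: halving dz moves Gamma by < 0.5%
  g2 <- excess_adsorption(pk, 5, c0, dz = 0.05, liquid_side = "high_z")
  expect_lt(abs(g2 - g1) / g1, 5e-3)
  # endpoints inside the interfacial region are rejected
  expect_error(excess_adsorption(pk, 5, c0, z_from = 4.5, z_to = 7),
               "interfacial")
})

test_that("surface excess is invariant under rigid translation", {
  sp <- std_slab()
  tr <- std_truth(gamma_true = 1.4)
  pf <- make_slab_profiles(sp, tr)
  z0 <- attr(pf, "z0_true")
  g_ref <- excess_adsorption(pf$surfactant, z0, conc_to_nm3(0.1))
  for (shift in c(-0.73, 1.31)) {
    moved <- density_profile(pf$surfactant$z + shift, pf$surfactant$density,
                             species = "surfactant")
    g_sh <- excess_adsorption(moved, z0 + shift, conc_to_nm3(0.1))
    expect_equal(g_sh, g_ref, tolerance = 1e-10)
  }
})

test_that("two mirrored faces of a symmetric slab give the same excess", {
  pf <- make_slab_profiles(std_slab(), std_truth(gamma_true = 0.8),
                           two_sided = TRUE)
  z0s <- attr(pf, "z0_true")
  c_b <- conc_to_nm3(0.1)
  g_lo <- excess_adsorption(pf$surfactant, z0s[1], c_b,
                            liquid_side = "high_z")
  g_hi <- excess_adsorption(pf$surfactant, z0s[2], c_b,
                            liquid_side = "low_z")
  expect_equal(g_lo, g_hi, tolerance = 1e-9)
  expect_equal(g_lo, 0.8, tolerance = 0.01)
})

test_that("dividing surface and water-excess integral are self-consistent", {
  pf <- make_slab_profiles(std_slab(), std_truth())
  z0 <- gibbs_dividing_surface(pf$water, c_bulk = 33.3)
  # native-grid integration over the full profile: exactly zero by
  # construction of z0
  gw <- excess_adsorption(pf$water, z0, 33.3, dz = NULL,
                          z_from = min(pf$water$z), z_to = max(pf$water$z))
  expect_lt(abs(gw), 1e-10)
})
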