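# Shared fixture builders. All profiles follow the package's internal units
# (nm, nm^-3); step-like fixtures use the half-value convention at the
# discontinuity node so that trapezoid integrals of the step are exact.

std_slab <- function(...) slab_spec(...)

std_truth <- function(c0_mol_l = 0.1, gamma_true = 1.0, peak_width = 0.3,
                      seed = 1L) {
  surfactant_truth(c0_mol_l, gamma_true, peak_width, seed)
}

# profile from a function of z
profile_from <- function(f, zmin = 0, zmax = 10, dz = 0.01,
                         species = "test",
                         geometry = "water_vapor") {
  z <- seq(zmin, zmax, by = dz)
  density_profile(z, f(z), species = species, geometry = geometry)
}

# step profile: c0 for z < zstar, 0 beyond, half-value at the node
step_profile <- function(c0, zstar, zmin = 0, zmax = 10, dz = 0.01) {
  profile_from(function(z) {
    d <- ifelse(z < zstar - dz / 4, c0, ifelse(z > zstar + dz / 4, 0, c0 / 2))
    d
  }, zmin, zmax, dz, species = "water")
}

fake_fit <- function(k_c, gamma_inf) {
  list(k_c = k_c, gamma_inf = gamma_inf, K = k_c * gamma_inf)
}

# droplet state with Langmuir/tension pairs built from (K, gamma_inf, xi)
make_droplet <- function(theta_deg, gamma0, c0_mol_l,
                         K_v, gi_v = 5, xi_v = 1,
                         K_s, gi_s = 5, xi_s = 1, T = 300) {
  droplet_state(
    theta_deg = theta_deg, gamma0 = gamma0, c0_mol_l = c0_mol_l,
    fit_v = fake_fit(K_v / gi_v, gi_v),
    model_v = tension_model(gi_v, xi = xi_v, T = T, gamma0 = gamma0),
    fit_s = fake_fit(K_s / gi_s, gi_s),
    model_s = tension_model(gi_s, xi = xi_s, T = T))
}
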