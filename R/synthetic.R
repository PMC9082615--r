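#' Slab geometry specification for synthetic density profiles
#'
#' Describes a water slab in a simulation-like box: a liquid region of
#' `slab_thickness` centred at `slab_center`, with sigmoidal (tanh) edges of
#' width `interface_width`. The tanh edge is symmetric, so the Gibbs dividing
#' surface of the water phase coincides exactly with the sigmoid midpoint --
#' this anchors all generator ground truths analytically.
#'
#' @param box_height box extent along z in nm.
#' @param slab_center centre of the liquid slab in nm.
#' @param slab_thickness slab thickness in nm (must be < `box_height`).
#' @param interface_width tanh width parameter in nm (> 0).
#' @param bulk_water_density bulk water number density in nm^-3 (> 0).
#' @param geometry `"water_vapor"` or `"solid_water"`.
#' @return object of class `slab_spec`.
#' @export
slab_spec <- function(box_height = 10, slab_center = 5, slab_thickness = 5,
                      interface_width = 0.25, bulk_water_density = 33.3,
                      geometry = c("water_vapor", "solid_water")) {
  geometry <- match.arg(geometry)
  stopifnot(slab_thickness > 0, slab_thickness < box_height,
            interface_width > 0, bulk_water_density > 0,
            slab_center > 0, slab_center < box_height)
  structure(list(box_height = box_height, slab_center = slab_center,
                 slab_thickness = slab_thickness,
                 interface_width = interface_width,
                 bulk_water_density = bulk_water_density,
                 geometry = geometry),
            class = "slab_spec")
}

#' Ground-truth surfactant loading for a synthetic slab
#'
#' @param c0_mol_l bulk surfactant concentration in mol/l (>= 0).
#' @param gamma_true target interfacial surface excess in nm^-2 (>= 0).
#' @param peak_width Gaussian standard deviation of the adsorption peak in nm.
#' @param seed integer RNG seed for the optional noise; recorded in output.
#' @return object of class `surfactant_truth`.
#' @export
surfactant_truth <- function(c0_mol_l = 0.1, gamma_true = 1.0,
                             peak_width = 0.3, seed = 1L) {
  stopifnot(c0_mol_l >= 0, gamma_true >= 0, peak_width > 0)
  structure(list(c0_mol_l = c0_mol_l, gamma_true = gamma_true,
                 peak_width = peak_width, seed = as.integer(seed)),
            class = "surfactant_truth")
}

#' Generate matched water and surfactant density profiles for a slab
#'
#' Emulates the 1-D density profiles an MD analysis would produce near a
#' water-vapor (or solid-water) interface. The water profile is a tanh-edged
#' slab; the surfactant profile is the bulk concentration modulated by the
#' same edge shape, plus a Gaussian adsorption peak at the interface whose
#' area is normalized analytically so that the surface excess over the Gibbs
#' dividing surface equals `truth$gamma_true` by construction.
#'
#' By default only one interface is produced (`two_sided = FALSE`): the
#' liquid occupies the high-z side of the single edge at
#' `slab_center - slab_thickness/2`. With `two_sided = TRUE` the profile is
#' mirrored about the slab centre, giving both faces.
#'
#' @param spec [slab_spec()] geometry.
#' @param truth [surfactant_truth()] ground truth.
#' @param dz grid spacing in nm (default 0.02).
#' @param noise relative (multiplicative Gaussian) noise level; 0 disables.
#' @param two_sided mirror the profile to produce both slab faces.
#' @return list with `water` and `surfactant` [density_profile()] objects;
#'   attribute `z0_true` carries the analytic dividing-surface position(s).
#' @export
make_slab_profiles <- function(spec, truth, dz = 0.02, noise = 0,
                               two_sided = FALSE) {
  stopifnot(inherits(spec, "slab_spec"), inherits(truth, "surfactant_truth"),
            dz > 0, noise >= 0)
  if (truth$peak_width >= spec$slab_thickness / 2) {
    stop("peak_width >= slab_thickness/2: adsorption peak would not be ",
         "interfacial", call. = FALSE)
  }
  z <- seq(0, spec$box_height, by = dz)
  z_lo <- spec$slab_center - spec$slab_thickness / 2
  z_hi <- spec$slab_center + spec$slab_thickness / 2
  edge <- function(z0) 0.5 * (1 + tanh((z - z0) / spec$interface_width))
  gauss <- function(z0, area, sd) {
    area / (sd * sqrt(2 * pi)) * exp(-(z - z0)^2 / (2 * sd^2))
  }
  c0_nm3 <- conc_to_nm3(truth$c0_mol_l)
  if (two_sided) {
    shape <- edge(z_lo) * (1 - edge(z_hi))
    peak <- gauss(z_lo, truth$gamma_true, truth$peak_width) +
            gauss(z_hi, truth$gamma_true, truth$peak_width)
    z0_true <- c(z_lo, z_hi)
  } else {
    shape <- edge(z_lo)
    peak <- gauss(z_lo, truth$gamma_true, truth$peak_width)
    z0_true <- z_lo
  }
  water <- spec$bulk_water_density * shape
  surf <- c0_nm3 * shape + peak
  if (noise > 0) {
    rng <- .seeded_rng(truth$seed)
    water <- pmax(0, water * (1 + rng(length(z)) * noise))
    surf <- pmax(0, surf * (1 + rng(length(z)) * noise))
  }
  out <- list(
    water = density_profile(z, water, species = "water",
                            geometry = spec$geometry),
    surfactant = density_profile(z, surf, species = "surfactant",
                                 geometry = spec$geometry)
  )
  attr(out, "z0_true") <- z0_true
  attr(out, "c0_nm3") <- c0_nm3
  attr(out, "seed") <- truth$seed
  out
}

## local RNG stream that does not disturb the session RNG state
.seeded_rng <- function(seed) {
  state <- NULL
  withr_like <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    x <- stats::rnorm(n)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
  withr_like
}

#' Radial distribution function specification with closed-form KB integral
#'
#' Three analytic families whose Kirkwood-Buff integrals
#' \eqn{G = \int_0^\infty 4\pi r^2 (g(r)-1)\,dr} are known exactly:
#' `ideal` (g = 1, G = 0), `hard_sphere` (g = 0 below sigma,
#' G = -(4/3)\eqn{\pi\sigma^3}), and `exp_decay`
#' (g = 1 + a exp(-r/lambda), G = 8\eqn{\pi a \lambda^3}).
#'
#' @param form one of `"ideal"`, `"hard_sphere"`, `"exp_decay"`.
#' @param sigma hard-sphere contact distance in nm.
#' @param amplitude dimensionless amplitude `a` of the exponential form
#'   (may be negative but must keep g >= 0).
#' @param decay_length decay length lambda in nm.
#' @param r_max grid extent in nm; for `exp_decay` must be >= 5 lambda.
#' @return object of class `rdf_spec`.
#' @export
rdf_spec <- function(form = c("ideal", "hard_sphere", "exp_decay"),
                     sigma = 0.4, amplitude = 0.5, decay_length = 0.3,
                     r_max = 3) {
  form <- match.arg(form)
  stopifnot(r_max > 0)
  if (form == "hard_sphere") stopifnot(sigma > 0, r_max > sigma)
  if (form == "exp_decay") {
    stopifnot(decay_length > 0)
    if (r_max < 5 * decay_length) {
      stop("r_max must be at least 5 decay lengths for exp_decay",
           call. = FALSE)
    }
    if (amplitude < -1) stop("amplitude < -1 would give g < 0", call. = FALSE)
  }
  structure(list(form = form, sigma = sigma, amplitude = amplitude,
                 decay_length = decay_length, r_max = r_max),
            class = "rdf_spec")
}

#' Generate a gridded radial distribution function
#'
#' The hard-sphere step is represented by its cell average at the contact
#' node (linear ramp over one grid cell centred on sigma), which keeps the
#' trapezoid KB integral at second-order accuracy across the discontinuity.
#'
#' @param spec [rdf_spec()].
#' @param dr grid spacing in nm (default 0.005).
#' @param pair pair label, `"mm"` (molecule-molecule) or `"mw"`
#'   (molecule-water).
#' @return object of class `radial_distribution` with fields `r`, `g`,
#'   `pair`; attributes `kb_exact` (closed-form integral to infinity) and
#'   `kb_tail` (analytic remainder beyond `r_max`, nonzero only for
#'   `exp_decay`).
#' @export
make_rdf <- function(spec, dr = 0.005, pair = c("mm", "mw")) {
  stopifnot(inherits(spec, "rdf_spec"), dr > 0)
  pair <- match.arg(pair)
  r <- seq(0, spec$r_max, by = dr)
  g <- switch(spec$form,
    ideal = rep(1, length(r)),
    hard_sphere = pmin(1, pmax(0, (r - spec$sigma) / dr + 0.5)),
    exp_decay = 1 + spec$amplitude * exp(-r / spec$decay_length)
  )
  kb_exact <- switch(spec$form,
    ideal = 0,
    hard_sphere = -(4 / 3) * pi * spec$sigma^3,
    exp_decay = 8 * pi * spec$amplitude * spec$decay_length^3
  )
  kb_tail <- 0
  if (spec$form == "exp_decay") {
    R <- spec$r_max; lam <- spec$decay_length
    kb_tail <- 4 * pi * spec$amplitude * exp(-R / lam) *
      (R^2 * lam + 2 * R * lam^2 + 2 * lam^3)
  }
  structure(list(r = r, g = g, pair = pair),
            class = "radial_distribution",
            kb_exact = kb_exact, kb_tail = kb_tail, form = spec$form)
}

#' Generate a synthetic Langmuir adsorption series with biaxial noise
#'
#' Samples (c0, Gamma) pairs on the Langmuir curve
#' \eqn{\Gamma = \Gamma_\infty k_c c / (1 + k_c c)} and perturbs both
#' coordinates with independent multiplicative Gaussian noise, emulating the
#' situation that motivates orthogonal distance regression: measured bulk
#' concentrations and measured adsorptions both carry uncertainty.
#'
#' @param k_c Langmuir volume constant in nm^3 (> 0).
#' @param gamma_inf saturation adsorption in nm^-2 (> 0).
#' @param concentrations bulk concentrations in mol/l.
#' @param noise_x,noise_y relative noise levels on c0 and Gamma (>= 0).
#' @param seed integer RNG seed.
#' @param interface interface label.
#' @return an [isotherm_series()]; attribute `truth` stores the generating
#'   parameters (including K = k_c * gamma_inf in nm).
#' @export
make_isotherm_series <- function(k_c, gamma_inf, concentrations,
                                 noise_x = 0, noise_y = 0, seed = 1L,
                                 interface = c("water_vapor", "solid_water")) {
  interface <- match.arg(interface)
  stopifnot(k_c > 0, gamma_inf > 0, all(concentrations >= 0))
  if (noise_x < 0 || noise_y < 0) stop("noise levels must be >= 0", call. = FALSE)
  c_nm3 <- conc_to_nm3(concentrations)
  gam <- langmuir_gamma(c_nm3, k_c, gamma_inf)
  rng <- .seeded_rng(seed)
  c_obs <- concentrations
  g_obs <- gam
  if (noise_x > 0) c_obs <- pmax(0, concentrations * (1 + noise_x * rng(length(gam))))
  if (noise_y > 0) g_obs <- pmax(0, gam * (1 + noise_y * rng(length(gam))))
  ser <- isotherm_series(
    c0_mol_l = c_obs, gamma_nm2 = g_obs,
    sd_c0 = if (noise_x > 0) noise_x * pmax(c_obs, 1e-12) else rep(0, length(gam)),
    sd_gamma = if (noise_y > 0) noise_y * pmax(g_obs, 1e-12) else rep(0, length(gam)),
    interface = interface
  )
  attr(ser, "truth") <- list(k_c = k_c, gamma_inf = gamma_inf,
                             K = k_c * gamma_inf, seed = as.integer(seed),
                             noise_x = noise_x, noise_y = noise_y)
  ser
}

#' Write / read two-column profile files (XVG-compatible dialect)
#'
#' Whitespace-delimited z (nm) and density (nm^-3) columns with `#` comment
#' headers; `@` metadata lines are tolerated (skipped) on read.
#'
#' @param profile a [density_profile()].
#' @param path file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a [density_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# species: %s", profile$species), con)
  writeLines(sprintf("# geometry: %s", profile$geometry), con)
  writeLines("# columns: z_nm density_nm3", con)
  utils::write.table(data.frame(profile$z, profile$density), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param species,geometry labels used when the header does not carry them.
#' @export
read_profile <- function(path, species = "unknown",
                         geometry = c("water_vapor", "solid_water")) {
  geometry <- match.arg(geometry)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  sp <- sub("^# species: *", "", hdr[startsWith(hdr, "# species:")])
  ge <- sub("^# geometry: *", "", hdr[startsWith(hdr, "# geometry:")])
  if (length(sp) == 1L) species <- sp
  if (length(ge) == 1L && ge %in% c("water_vapor", "solid_water")) geometry <- ge
  dat <- lines[!startsWith(lines, "#") & !startsWith(lines, "@") &
                 nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"), function(x)
    as.numeric(x[1:2])))
  density_profile(m[, 1], m[, 2], species = species, geometry = geometry)
}

#' Write / read isotherm series as CSV
#'
#' Columns `c0_mol_l, gamma_nm2, sd_c0, sd_gamma`.
#'
#' @param series an [isotherm_series()].
#' @param path file path.
#' @export
write_isotherm <- function(series, path) {
  stopifnot(inherits(series, "isotherm_series"))
  utils::write.csv(as.data.frame(unclass(series)[c("c0_mol_l", "gamma_nm2",
                                                   "sd_c0", "sd_gamma")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isotherm
#' @param interface interface label for the loaded series.
#' @export
read_isotherm <- function(path, interface = c("water_vapor", "solid_water")) {
  interface <- match.arg(interface)
  df <- utils::read.csv(path)
  isotherm_series(df$c0_mol_l, df$gamma_nm2,
                  sd_c0 = df$sd_c0, sd_gamma = df$sd_gamma,
                  interface = interface)
}
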