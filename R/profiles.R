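#' One-dimensional species density profile near an interface
#'
#' @param z strictly increasing, uniformly spaced grid in nm.
#' @param density number densities in nm^-3 (>= 0), one per grid point.
#' @param species species label (e.g. "water", "surfactant", "oh").
#' @param geometry `"water_vapor"` or `"solid_water"`.
#' @return object of class `density_profile`: list with `z`, `density`,
#'   `species`, `geometry`, `dz` (grid spacing).
#' @export
density_profile <- function(z, density, species = "unknown",
                            geometry = c("water_vapor", "solid_water")) {
  geometry <- match.arg(geometry)
  z <- as.numeric(z); density <- as.numeric(density)
  stopifnot(length(z) == length(density), length(z) >= 4L)
  dzs <- diff(z)
  if (any(dzs <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (diff(range(dzs)) > 1e-8 * mean(dzs)) {
    stop("grid must be uniformly spaced", call. = FALSE)
  }
  if (any(density < -1e-12)) stop("density must be >= 0", call. = FALSE)
  structure(list(z = z, density = pmax(density, 0), species = species,
                 geometry = geometry, dz = mean(dzs)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %s (%s): %d points, z in [%.3g, %.3g] nm\n",
              x$species, x$geometry, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

## which end of the grid is the liquid interior: compare outer-10% tail means
.liquid_side <- function(profile) {
  n <- length(profile$z)
  k <- max(2L, floor(0.1 * n))
  lo <- mean(profile$density[seq_len(k)])
  hi <- mean(profile$density[seq(n - k + 1L, n)])
  if (hi >= lo) "high_z" else "low_z"
}

#' Locate the bulk plateau of a density profile
#'
#' Finds the maximal contiguous window around the slab interior in which the
#' density deviates from its window mean by less than `flatness_tol`
#' (relative). The window is grown greedily outward from `center` (default:
#' the density-weighted centroid of the profile), re-checking the flatness
#' condition against the updated mean after every extension.
#'
#' @param profile a [density_profile()].
#' @param flatness_tol maximum relative deviation from the window mean.
#' @param min_width minimum acceptable window width in nm; a narrower result
#'   raises a "no bulk plateau" error.
#' @param center z position to grow from (nm); defaults to the
#'   density-weighted centroid.
#' @return list with `window` (c(z_lo, z_hi) in nm), `c_bulk` (window mean,
#'   nm^-3) and `idx` (grid index range).
#' @export
find_bulk <- function(profile, flatness_tol = 0.02, min_width = 1,
                      center = NULL) {
  stopifnot(inherits(profile, "density_profile"), flatness_tol > 0)
  z <- profile$z; d <- profile$density
  if (sum(d) <= 0) stop("no bulk plateau: profile is identically zero",
                        call. = FALSE)
  if (is.null(center)) center <- sum(z * d) / sum(d)
  i0 <- which.min(abs(z - center))
  ok <- function(lo, hi) {
    w <- d[lo:hi]; m <- mean(w)
    m > 0 && max(abs(w - m)) <= flatness_tol * m
  }
  lo <- hi <- i0
  repeat {
    ext_hi <- hi < length(z) && ok(lo, hi + 1L)
    ext_lo <- lo > 1L && ok(lo - 1L, hi)
    if (ext_hi && ext_lo) {
      ## extend the side whose next point sits closer to the current mean
      m <- mean(d[lo:hi])
      if (abs(d[hi + 1L] - m) <= abs(d[lo - 1L] - m)) hi <- hi + 1L
      else lo <- lo - 1L
    } else if (ext_hi) hi <- hi + 1L
    else if (ext_lo) lo <- lo - 1L
    else break
  }
  if (z[hi] - z[lo] < min_width) {
    stop(sprintf("no bulk plateau: widest flat window is %.3g nm (< %g nm)",
                 z[hi] - z[lo], min_width), call. = FALSE)
  }
  list(window = c(z[lo], z[hi]), c_bulk = mean(d[lo:hi]), idx = c(lo, hi))
}

#' Gibbs dividing surface of the water phase
#'
#' Finds the effective interface position z0 at which the excess water
#' adsorption vanishes: the integral of c_w(z) on the vapor (or solid) side
#' of z0 exactly balances the deficit of c_w(z) below its bulk value on the
#' liquid side. On the cumulative trapezoid of the profile this equal-area
#' condition is linear in z0 and is solved in closed form,
#' z0 = z_liq - N / c_bulk with N the total trapezoid integral of the
#' profile (liquid interior at high z; mirrored otherwise).
#'
#' @param water a water [density_profile()].
#' @param c_bulk bulk water density in nm^-3; located with [find_bulk()]
#'   when omitted.
#' @param liquid_side `"high_z"` or `"low_z"`; inferred from the tail
#'   densities when omitted.
#' @param tail_tol maximum vapor-side tail density, relative to `c_bulk`,
#'   before the profile is rejected as non-decaying.
#' @return z0 in nm, with attribute `c_bulk`.
#' @export
gibbs_dividing_surface <- function(water, c_bulk = NULL, liquid_side = NULL,
                                   tail_tol = 0.02) {
  stopifnot(inherits(water, "density_profile"))
  if (is.null(liquid_side)) liquid_side <- .liquid_side(water)
  liquid_side <- match.arg(liquid_side, c("high_z", "low_z"))
  if (is.null(c_bulk)) c_bulk <- find_bulk(water)$c_bulk
  stopifnot(c_bulk > 0)
  n <- length(water$z)
  k <- max(2L, floor(0.05 * n))
  vap_idx <- if (liquid_side == "high_z") seq_len(k) else seq(n - k + 1L, n)
  if (mean(water$density[vap_idx]) > tail_tol * c_bulk) {
    stop("water density does not decay on the vapor/solid side",
         call. = FALSE)
  }
  N <- .trapz(water$z, water$density)
  z0 <- if (liquid_side == "high_z") max(water$z) - N / c_bulk
        else min(water$z) + N / c_bulk
  if (z0 < min(water$z) || z0 > max(water$z)) {
    stop("dividing surface falls outside the profile range", call. = FALSE)
  }
  structure(z0, c_bulk = c_bulk, liquid_side = liquid_side)
}

#' Effective solid boundary from the OH head-group density peak
#'
#' Locates the solid boundary as the position at half-height on the water
#' side of the head-group density peak, linearly interpolated between grid
#' points.
#'
#' @param oh_profile head-group [density_profile()] with a single dominant
#'   peak.
#' @param water_side `"high_z"` or `"low_z"`: side on which the water phase
#'   lies.
#' @return z_s in nm.
#' @export
solid_boundary <- function(oh_profile, water_side = c("high_z", "low_z")) {
  water_side <- match.arg(water_side)
  stopifnot(inherits(oh_profile, "density_profile"))
  z <- oh_profile$z; d <- oh_profile$density
  pk <- max(d)
  if (pk <= 0) stop("head-group profile is identically zero", call. = FALSE)
  half <- pk / 2
  ## candidate peaks: contiguous runs of density >= half
  above <- d >= half
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- which(runs$values)
  if (length(peaks) > 1L) {
    cand <- vapply(peaks, function(i) z[which.max(replace(d, -seq(starts[i], ends[i]), -Inf))],
                   numeric(1))
    stop("ambiguous water-side flank: multiple peaks above half height near z = ",
         paste(sprintf("%.3g", cand), collapse = ", "), " nm", call. = FALSE)
  }
  i_pk <- which.max(d)
  idx <- if (water_side == "high_z") seq(i_pk, length(z)) else seq(i_pk, 1L)
  below <- which(d[idx] < half)
  if (length(below) == 0L) {
    stop("density never falls below half height on the water side",
         call. = FALSE)
  }
  j <- below[1L]                       # first point below half on water flank
  i2 <- idx[j]; i1 <- idx[j - 1L]      # bracketing grid points
  z[i1] + (z[i2] - z[i1]) * (half - d[i1]) / (d[i2] - d[i1])
}

#' Surface-excess adsorption from a density profile
#'
#' Computes the Gibbs surface excess
#' \deqn{\Gamma = \int_{z_a}^{z_0} c(z)\,dz +
#'       \int_{z_0}^{z_b} [c(z) - c_0]\,dz}
#' with z_a well inside the vapor (or solid) phase and z_b well inside the
#' water phase, by the trapezoidal rule with subinterval length `dz`
#' (default 0.1 nm), resampling the input grid by linear interpolation when
#' needed. The bulk step is handled analytically (the c_0 term contributes
#' exactly -c_0 (z_b - z_0)), so no discretization of the Heaviside factor
#' enters. `dz = NULL` integrates on the native grid without resampling.
#'
#' @param surfactant a [density_profile()].
#' @param z0 dividing-surface position in nm (from
#'   [gibbs_dividing_surface()] or [solid_boundary()]).
#' @param c_bulk bulk surfactant density in nm^-3 (from [find_bulk()]).
#' @param dz trapezoid subinterval in nm, or NULL for the native grid.
#' @param z_from,z_to integration endpoints in nm; default `extent` nm on
#'   either side of z0 (clipped to the grid is an error, not a fallback).
#' @param extent default endpoint distance from z0 in nm.
#' @param min_margin endpoints closer than this to z0 are rejected as
#'   lying inside the interfacial region.
#' @param liquid_side `"high_z"` or `"low_z"`; inferred from tail densities
#'   when omitted (ties broken toward `"high_z"`).
#' @return Gamma in nm^-2.
#' @export
excess_adsorption <- function(surfactant, z0, c_bulk, dz = 0.1,
                              z_from = NULL, z_to = NULL, extent = 1.5,
                              min_margin = 1.0, liquid_side = NULL) {
  stopifnot(inherits(surfactant, "density_profile"), c_bulk >= 0)
  z0 <- as.numeric(z0)
  if (is.null(liquid_side)) liquid_side <- .liquid_side(surfactant)
  liquid_side <- match.arg(liquid_side, c("high_z", "low_z"))
  sgn <- if (liquid_side == "high_z") 1 else -1
  if (is.null(z_from)) z_from <- z0 - sgn * extent   # vapor/solid side
  if (is.null(z_to)) z_to <- z0 + sgn * extent       # liquid side
  if (abs(z_from - z0) < min_margin || abs(z_to - z0) < min_margin) {
    stop("integration endpoints lie inside the interfacial region (< ",
         min_margin, " nm from z0)", call. = FALSE)
  }
  lo <- min(z_from, z_to); hi <- max(z_from, z_to)
  if (lo < min(surfactant$z) - 1e-9 || hi > max(surfactant$z) + 1e-9) {
    stop("integration range exceeds the profile grid", call. = FALSE)
  }
  if (is.null(dz)) {
    keep <- surfactant$z >= lo - 1e-12 & surfactant$z <= hi + 1e-12
    zg <- surfactant$z[keep]; cg <- surfactant$density[keep]
  } else {
    n <- max(2L, round((hi - lo) / dz))
    zg <- seq(lo, hi, length.out = n + 1L)
    cg <- stats::approx(surfactant$z, surfactant$density, xout = zg)$y
  }
  z_liq <- if (liquid_side == "high_z") hi else lo
  .trapz(zg, cg) - c_bulk * abs(z_liq - z0)
}
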