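#' Cross-section to surface-area ratio of an adsorbing molecule
#'
#' The continuum adsorption model needs the ratio of the molecule's bare
#' cross-sectional area \eqn{A_c^*} to its total surface area \eqn{A_m}.
#' For a sphere (\eqn{A_m = 4\pi R^2}, \eqn{A_c^* = \pi R^2}) the ratio is
#' exactly 1/4; for an infinitely long cylinder (\eqn{A_m = 2\pi R L},
#' \eqn{A_c^* = 2 R L}) it is \eqn{1/\pi \approx 0.32}. Finite rod-like
#' molecules fall in the narrow interval between the two; a `custom_ratio`
#' outside [0.25, 0.32] triggers a warning but is passed through.
#'
#' @param shape `"sphere"`, `"cylinder"`, or `"custom_ratio"`.
#' @param ratio the ratio to pass through when `shape = "custom_ratio"`.
#' @return dimensionless ratio \eqn{A_c^*/A_m} (independent of the
#'   molecule's absolute dimensions).
#' @export
#' @examples
#' cross_section_ratio("sphere")   # 0.25
#' cross_section_ratio("cylinder") # 0.3183099
cross_section_ratio <- function(shape = c("sphere", "cylinder",
                                          "custom_ratio"),
                                ratio = NULL) {
  shape <- match.arg(shape)
  switch(shape,
    sphere = 1 / 4,
    cylinder = 1 / pi,
    custom_ratio = {
      stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0)
      if (ratio < 0.25 || ratio > 0.32) {
        warning("custom cross-section ratio outside the rod-like interval ",
                "[0.25, 0.32]", call. = FALSE)
      }
      ratio
    })
}

#' Continuum adsorption free energy of a surfactant at a soft surface
#'
#' \deqn{\Delta G_s = A_c^* (\gamma_{sm} - \gamma_{sw}) - A_c \gamma_{mw}}
#' The first term pays for replacing solid-water by solid-molecule contact
#' over the molecule's cross-section; the second rewards dewetting the
#' molecule's surface-contact area from water. Substituting the Young
#' relation \eqn{\gamma_{sw} = \gamma_{sv} - \gamma\cos\theta} gives the
#' wetting-coefficient form
#' \eqn{\Delta G_s = \Delta G_s^{(0)} + A_c^* \gamma \cos\theta} with
#' \eqn{\Delta G_s^{(0)} = A_c^*(\gamma_{sm} - \gamma_{sv}) -
#' A_c \gamma_{mw}}.
#'
#' @param gamma_mw molecule-water surface tension in mN/m.
#' @param gamma_sm solid-molecule surface tension in mN/m.
#' @param gamma_sw solid-water surface tension in mN/m.
#' @param A_c surface-accessible contact area of the molecule in nm^2.
#' @param A_c_star bare cross-sectional area in nm^2.
#' @param T temperature in kelvin.
#' @return \eqn{\Delta G_s} in units of \eqn{k_B T}, with attribute
#'   `mN_m_nm2` carrying the value in (mN/m) nm^2.
#' @export
adsorption_free_energy <- function(gamma_mw, gamma_sm, gamma_sw,
                                   A_c, A_c_star, T = 300) {
  stopifnot(A_c > 0, A_c_star > 0)
  dG <- A_c_star * (gamma_sm - gamma_sw) - A_c * gamma_mw
  structure(dG / kBT(T), mN_m_nm2 = dG)
}

#' Wetting-dependent adsorption model
#'
#' Collects the parameters of the exponential adsorption laws: reference
#' coefficient \eqn{K_s^{(0)}} at \eqn{\cos\theta = 0}, prefactors
#' \eqn{b_s, b_v}, effective molecular surface tensions
#' \eqn{\tilde\gamma_s, \tilde\gamma_v}, the water surface tension
#' \eqn{\gamma}, and the molecular geometry.
#'
#' @param Ks0 reference solid-water adsorption coefficient in nm.
#' @param b_s,b_v prefactors in nm.
#' @param gt_s,gt_v effective molecular surface tensions in mN/m.
#' @param gamma water surface tension in mN/m.
#' @param T temperature in kelvin.
#' @param shape,ratio molecular geometry, see [cross_section_ratio()].
#' @return object of class `wetting_model`.
#' @export
wetting_model <- function(Ks0 = NA_real_, b_s = NA_real_, b_v = NA_real_,
                          gt_s = NA_real_, gt_v = NA_real_, gamma,
                          T = 300, shape = "sphere", ratio = NULL) {
  stopifnot(gamma > 0, T > 0)
  structure(list(Ks0 = Ks0, b_s = b_s, b_v = b_v, gt_s = gt_s, gt_v = gt_v,
                 gamma = gamma, T = T, kBT = kBT(T),
                 ratio = cross_section_ratio(shape, ratio), shape = shape),
            class = "wetting_model")
}

#' Adsorption coefficient versus wetting coefficient
#'
#' \deqn{K_s(\cos\theta) = K_s^{(0)}
#'       \exp(-\beta \gamma A_c^* \cos\theta)}
#' with \eqn{A_c^* = (A_c^*/A_m) A_m}. \eqn{\ln K_s} is affine in
#' \eqn{\cos\theta}: adsorption weakens exponentially as the surface becomes
#' more hydrophilic.
#'
#' @param cos_theta wetting coefficient(s), in [-1, 1].
#' @param model a [wetting_model()] with `Ks0` set.
#' @param A_m molecular surface area in nm^2.
#' @return K_s in nm.
#' @export
ks_of_costheta <- function(cos_theta, model, A_m) {
  stopifnot(inherits(model, "wetting_model"), is.finite(model$Ks0),
            model$Ks0 > 0, A_m > 0)
  if (any(abs(cos_theta) > 1)) stop("|cos theta| must be <= 1", call. = FALSE)
  A_c_star <- model$ratio * A_m
  model$Ks0 * exp(-model$gamma * A_c_star * cos_theta / model$kBT)
}

#' Fit the molecular-area scaling of adsorption coefficients
#'
#' Fits \eqn{K = b \exp(\beta \tilde\gamma A_m)} by linear regression of
#' \eqn{\ln K} on \eqn{A_m}: the effective molecular surface tension
#' \eqn{\tilde\gamma} is the slope times \eqn{k_B T}, and b the
#' exponentiated intercept. Standard errors are returned for n >= 3.
#'
#' @param A_m molecular surface areas in nm^2 (>= 2 values).
#' @param K adsorption coefficients in nm (> 0).
#' @param T temperature in kelvin.
#' @return list with `b` (nm), `gt` (mN/m), `se` (named, NA for n = 2),
#'   and the underlying `lm` fit.
#' @export
fit_area_scaling <- function(A_m, K, T = 300) {
  stopifnot(length(A_m) == length(K), length(A_m) >= 2L)
  if (any(K <= 0)) stop("adsorption coefficients must be > 0", call. = FALSE)
  fit <- stats::lm(log(K) ~ A_m)
  co <- stats::coef(fit)
  b <- exp(co[[1L]])
  gt <- co[[2L]] * kBT(T)
  se <- c(b = NA_real_, gt = NA_real_)
  if (length(A_m) >= 3L) {
    # SEs computed directly: vcov() warns on exact (zero-residual) data
    X <- cbind(1, A_m)
    s2 <- sum(stats::resid(fit)^2) / (length(A_m) - 2L)
    s <- sqrt(diag(s2 * solve(crossprod(X))))
    se <- c(b = b * s[[1L]], gt = s[[2L]] * kBT(T))
  }
  list(b = b, gt = gt, se = se, lm = fit)
}

#' Correlation between solid-water and water-vapor adsorption coefficients
#'
#' Eliminating the molecular surface area from the exponential area-scaling
#' laws and the wetting-coefficient law gives
#' \deqn{K_s = b_s \left(\frac{K_v}{b_v}\right)^{
#'   (\tilde\gamma_s - \gamma \rho \cos\theta)/\tilde\gamma_v}}
#' with \eqn{\rho = A_c^*/A_m}: the logarithms of the two adsorption
#' coefficients are linearly related, with a prefactor that decreases
#' linearly with \eqn{\cos\theta}.
#'
#' @param K_v water-vapor adsorption coefficient(s) in nm; must exceed
#'   `model$b_v` (otherwise the implied molecular area is non-positive).
#' @param cos_theta wetting coefficient in [-1, 1].
#' @param model a [wetting_model()] with `b_s`, `b_v`, `gt_s`, `gt_v` set.
#' @return K_s in nm, with attribute `prefactor` = the log-log slope.
#' @export
ks_kv_correlation <- function(K_v, cos_theta, model) {
  stopifnot(inherits(model, "wetting_model"),
            is.finite(model$b_s), is.finite(model$b_v),
            is.finite(model$gt_s), is.finite(model$gt_v))
  if (any(abs(cos_theta) > 1)) stop("|cos theta| must be <= 1", call. = FALSE)
  if (any(K_v <= model$b_v)) {
    stop("K_v <= b_v implies a non-positive molecular area", call. = FALSE)
  }
  pref <- (model$gt_s - model$gamma * model$ratio * cos_theta) / model$gt_v
  structure(model$b_s * (K_v / model$b_v)^pref, prefactor = pref)
}

#' Surface polarity vs contact angle lookup for the reference SAM
#'
#' Bundled reference constants for a hydroxyl-terminated self-assembled
#' monolayer whose head-group partial charges are scaled to tune its
#' polarity: charge-scaling factors {0, 0.4, 0.6, 0.7, 0.8} correspond to
#' water contact angles {135, 120, 97, 76, 45} degrees. These are carried as
#' metadata for convenience (e.g. to label isotherm series); the package
#' does not predict contact angles from surface chemistry.
#'
#' @return data.frame with `charge_scaling`, `theta_deg`, `cos_theta`.
#' @export
sam_polarity_table <- function() {
  theta <- c(135, 120, 97, 76, 45)
  data.frame(charge_scaling = c(0, 0.4, 0.6, 0.7, 0.8),
             theta_deg = theta,
             cos_theta = cos(deg2rad(theta)))
}
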