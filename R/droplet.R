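#' Surfactant-laden sessile droplet state
#'
#' Bundles everything needed to predict the contact-angle change of a
#' sessile droplet upon adding surfactant: the neat contact angle, the neat
#' water-vapor surface tension, the bulk concentration(s), and one
#' (Langmuir fit, tension model) pair per interface. The solid-vapor
#' surface tension is treated as constant: well-soluble surfactants do not
#' populate the dry solid-vapor interface, and no hook for such adsorption
#' is provided.
#'
#' @param theta_deg neat water contact angle in degrees (0 < theta < 180).
#' @param gamma0 neat water-vapor surface tension in mN/m.
#' @param c0_mol_l bulk surfactant concentration(s) in mol/l.
#' @param fit_v,fit_s [langmuir_fit()] for the water-vapor and solid-water
#'   interface.
#' @param model_v,model_s matching [tension_model()]s.
#' @return object of class `droplet_state`.
#' @export
droplet_state <- function(theta_deg, gamma0, c0_mol_l,
                          fit_v, model_v, fit_s, model_s) {
  stopifnot(theta_deg > 0, theta_deg < 180, gamma0 > 0,
            all(c0_mol_l >= 0),
            inherits(model_v, "tension_model"),
            inherits(model_s, "tension_model"))
  structure(list(theta_deg = theta_deg, gamma0 = gamma0,
                 c0_mol_l = c0_mol_l,
                 fit_v = fit_v, model_v = model_v,
                 fit_s = fit_s, model_s = model_s),
            class = "droplet_state")
}

## tension reductions at the two interfaces, mN/m
.droplet_dgammas <- function(state) {
  dv <- dgamma_of_gamma(
    langmuir_gamma(conc_to_nm3(state$c0_mol_l),
                   state$fit_v$k_c, state$fit_v$gamma_inf),
    state$model_v)$dgamma_mN_m
  ds <- dgamma_of_gamma(
    langmuir_gamma(conc_to_nm3(state$c0_mol_l),
                   state$fit_s$k_c, state$fit_s$gamma_inf),
    state$model_s)$dgamma_mN_m
  list(dgamma_v = dv, dgamma_s = ds)
}

#' Contact-angle change from the surfactant-laden Young equation
#'
#' Solves
#' \deqn{\gamma(c_0)\cos(\theta + \Delta\theta) =
#'       \gamma_{sv} - \gamma_{sw}(c_0)}
#' for \eqn{\Delta\theta}, with \eqn{\gamma(c_0) = \gamma_0 +
#' \Delta\gamma_v} and \eqn{\gamma_{sw}(c_0) = \gamma_{sw,0} +
#' \Delta\gamma_s} (both reductions from the nonlinear tension law), and
#' \eqn{\gamma_{sv}} constant. Since neither side depends on
#' \eqn{\Delta\theta} except through the cosine, the equation isolates to
#' \eqn{\cos(\theta + \Delta\theta) = (\gamma_0\cos\theta -
#' \Delta\gamma_s)/(\gamma_0 + \Delta\gamma_v)} and is inverted directly.
#' An implied cosine above 1 is flagged `complete_wetting`, below -1
#' `dewetting` (no clamping); \eqn{\gamma(c_0) \le 0} raises a
#' beyond-model error.
#'
#' @param state a [droplet_state()].
#' @return data.frame with `c0_mol_l`, `dtheta_deg`, `theta_new_deg`,
#'   `cos_new`, and `flag` in {"ok", "complete_wetting", "dewetting"};
#'   `dtheta_deg` is NA where the cosine leaves [-1, 1].
#' @export
delta_theta_full <- function(state) {
  stopifnot(inherits(state, "droplet_state"))
  dg <- .droplet_dgammas(state)
  gamma_c <- state$gamma0 + dg$dgamma_v
  if (any(gamma_c <= 0)) {
    stop("beyond-model: predicted water-vapor tension <= 0 at the ",
         "requested concentration", call. = FALSE)
  }
  th <- deg2rad(state$theta_deg)
  cos_new <- (state$gamma0 * cos(th) - dg$dgamma_s) / gamma_c
  flag <- ifelse(cos_new > 1, "complete_wetting",
                 ifelse(cos_new < -1, "dewetting", "ok"))
  theta_new <- ifelse(flag == "ok", rad2deg(acos(pmin(1, pmax(-1, cos_new)))),
                      NA_real_)
  data.frame(c0_mol_l = state$c0_mol_l,
             dtheta_deg = theta_new - state$theta_deg,
             theta_new_deg = theta_new, cos_new = cos_new, flag = flag)
}

#' Linearized contact-angle change
#'
#' In the Henry regime, with the linear tension law at both interfaces,
#' \deqn{\Delta\theta = -\frac{k_B T\, c_0\,
#'       (\xi_s K_s + \xi_v K_v \cos\theta)}{\gamma_0 \sin\theta}.}
#' The competition between the two interfaces is carried entirely by the
#' numerator \eqn{\xi_s K_s + \xi_v K_v\cos\theta} (for ideal solutions,
#' \eqn{\xi = 1}, the familiar Lucassen-Reynders combination
#' \eqn{K_s + K_v\cos\theta}); it is returned in the diagnostics. The
#' \eqn{\sin\theta} denominator makes the linearization invalid within 1
#' degree of 0 or 180.
#'
#' @param state a [droplet_state()].
#' @return data.frame with `c0_mol_l`, `dtheta_deg`, `numerator_nm`
#'   (\eqn{\xi_s K_s + \xi_v K_v \cos\theta}).
#' @export
delta_theta_linear <- function(state) {
  stopifnot(inherits(state, "droplet_state"))
  if (state$theta_deg < 1 || state$theta_deg > 179) {
    stop("linearization invalid: theta within 1 degree of 0 or 180",
         call. = FALSE)
  }
  th <- deg2rad(state$theta_deg)
  num <- state$model_s$xi * state$fit_s$K +
         state$model_v$xi * state$fit_v$K * cos(th)
  kT <- state$model_v$kBT
  dth <- -kT * conc_to_nm3(state$c0_mol_l) * num /
    (state$gamma0 * sin(th))
  data.frame(c0_mol_l = state$c0_mol_l, dtheta_deg = rad2deg(dth),
             numerator_nm = num)
}

#' Contact-angle change across surface hydrophilicities
#'
#' Evaluates the linearized contact-angle change at fixed concentration on
#' a grid of neat contact angles, with the solid-water adsorption
#' coefficient supplied by the wetting-coefficient law
#' \eqn{K_s(\cos\theta)} (or overridden by `Ks`). On very hydrophilic
#' surfaces (\eqn{K_s \ll K_v}) the change scales as
#' \eqn{\Delta\theta \propto -\cot\theta}, diverging toward complete
#' wetting as \eqn{\theta \to 0}; the least-sensitive surfaces sit near
#' \eqn{\theta = 90^\circ}.
#'
#' @param c0_mol_l bulk concentration in mol/l (scalar).
#' @param theta_deg grid of neat contact angles in degrees, within
#'   (1, 179).
#' @param K_v water-vapor adsorption coefficient in nm.
#' @param gamma0 neat water-vapor surface tension in mN/m.
#' @param wmodel a [wetting_model()] with `Ks0` set (used unless `Ks` is
#'   given).
#' @param A_m molecular surface area in nm^2 (with `wmodel`).
#' @param Ks optional explicit solid-water adsorption coefficient(s) in nm
#'   (recycled over the grid); `Ks = 0` isolates the water-vapor term.
#' @param xi_s,xi_v correction factors for the two interfaces.
#' @param T temperature in kelvin.
#' @return data.frame with `theta_deg`, `cos_theta`, `K_s_nm`,
#'   `dtheta_deg`, `numerator_nm`; attribute `theta_min_deg` marks the grid
#'   angle of minimum |dtheta|.
#' @export
delta_theta_landscape <- function(c0_mol_l, theta_deg = seq(10, 170, by = 1),
                                  K_v, gamma0, wmodel = NULL, A_m = NULL,
                                  Ks = NULL, xi_s = 1, xi_v = 1, T = 300) {
  stopifnot(length(c0_mol_l) == 1L, c0_mol_l >= 0, K_v >= 0, gamma0 > 0,
            all(theta_deg > 1), all(theta_deg < 179))
  th <- deg2rad(theta_deg)
  if (is.null(Ks)) {
    stopifnot(inherits(wmodel, "wetting_model"), !is.null(A_m))
    Ks <- ks_of_costheta(cos(th), wmodel, A_m)
  } else {
    Ks <- rep_len(Ks, length(th))
  }
  num <- xi_s * Ks + xi_v * K_v * cos(th)
  dth <- -kBT(T) * conc_to_nm3(c0_mol_l) * num / (gamma0 * sin(th))
  out <- data.frame(theta_deg = theta_deg, cos_theta = cos(th),
                    K_s_nm = Ks, dtheta_deg = rad2deg(dth),
                    numerator_nm = num)
  attr(out, "theta_min_deg") <- theta_deg[which.min(abs(out$dtheta_deg))]
  out
}
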