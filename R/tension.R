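#' Surface-tension reduction model for an adsorbing interface
#'
#' Parameterizes the Szyszkowski-type relation between adsorption and
#' surface-tension reduction,
#' \deqn{\Delta\gamma(\Gamma) = \xi\, k_B T\, \Gamma_\infty
#'       \ln(1 - \Gamma/\Gamma_\infty),}
#' obtained by integrating the Gibbs adsorption equation
#' \eqn{d\gamma = -\Gamma\, d\mu} along the Langmuir isotherm with the
#' Kirkwood-Buff correction factor \eqn{\xi} applied to the logarithmic
#' slope of the chemical potential.
#'
#' @param gamma_inf saturation adsorption in nm^-2 (> 0).
#' @param xi correction factor (dimensionless, > 0).
#' @param T temperature in kelvin.
#' @param gamma0 neat-interface surface tension in mN/m, required for
#'   absolute tensions; no default is supplied on purpose (the value is
#'   model/system specific).
#' @return object of class `tension_model`.
#' @export
tension_model <- function(gamma_inf, xi = 1, T = 300, gamma0 = NA_real_) {
  stopifnot(gamma_inf > 0, xi > 0, T > 0)
  structure(list(gamma_inf = gamma_inf, xi = xi, T = T, gamma0 = gamma0,
                 kBT = kBT(T)),
            class = "tension_model")
}

#' Surface-tension reduction from adsorption (nonlinear closed form)
#'
#' Evaluates \eqn{\Delta\gamma = \xi k_B T \Gamma_\infty
#' \ln(1 - \Gamma/\Gamma_\infty)} (mN/m, always <= 0) and the surface
#' pressure \eqn{\pi = -\Delta\gamma}. Diverges logarithmically as
#' \eqn{\Gamma \to \Gamma_\infty}; values at or beyond saturation are
#' rejected.
#'
#' @param Gamma adsorption(s) in nm^-2, 0 <= Gamma < gamma_inf.
#' @param model a [tension_model()].
#' @return data.frame with `Gamma_nm2`, `dgamma_mN_m`, `pi_mN_m`.
#' @export
dgamma_of_gamma <- function(Gamma, model) {
  stopifnot(inherits(model, "tension_model"))
  if (any(Gamma < 0)) stop("Gamma must be >= 0", call. = FALSE)
  if (any(Gamma >= model$gamma_inf)) {
    stop("beyond saturation: Gamma >= gamma_inf", call. = FALSE)
  }
  dg <- model$xi * model$kBT * model$gamma_inf *
    log(1 - Gamma / model$gamma_inf)
  data.frame(Gamma_nm2 = Gamma, dgamma_mN_m = dg, pi_mN_m = -dg)
}

#' Surface-tension reduction from adsorption (linear law)
#'
#' The low-adsorption limit \eqn{\Delta\gamma = -\xi k_B T \Gamma}. The
#' next term of the expansion is
#' \eqn{-(\xi k_B T / 2\Gamma_\infty)\Gamma^2}, so the linear law holds for
#' \eqn{\Gamma \ll \xi^{-1}\Gamma_\infty}; a validity flag is raised for
#' \eqn{\Gamma > 0.1\, \xi^{-1}\Gamma_\infty}.
#'
#' @inheritParams dgamma_of_gamma
#' @return data.frame with `Gamma_nm2`, `dgamma_mN_m`, `pi_mN_m` and
#'   logical `linear_ok`.
#' @export
dgamma_linear <- function(Gamma, model) {
  stopifnot(inherits(model, "tension_model"))
  dg <- -model$xi * model$kBT * Gamma
  data.frame(Gamma_nm2 = Gamma, dgamma_mN_m = dg, pi_mN_m = -dg,
             linear_ok = Gamma <= 0.1 * model$gamma_inf / model$xi)
}

#' Surface-tension reduction as a function of bulk concentration
#'
#' Composes the Langmuir isotherm with the nonlinear tension law:
#' \eqn{c_0 \to \Gamma \to \Delta\gamma}. The initial slope is
#' \eqn{d\Delta\gamma/dc_0 = -\xi k_B T K} (per unit number density). As
#' \eqn{c_0 \to \infty}, \eqn{\Gamma \to \Gamma_\infty^-} and the predicted
#' reduction diverges logarithmically; where the absolute tension
#' \eqn{\gamma_0 + \Delta\gamma} falls to zero or below, the row is flagged
#' `beyond_model` rather than clamped.
#'
#' @param c0_mol_l concentration(s) in mol/l.
#' @param fit a [langmuir_fit()] (or list with `k_c`, `gamma_inf`).
#' @param model a [tension_model()]; must share `gamma_inf` with `fit`.
#' @return data.frame with `c0_mol_l`, `Gamma_nm2`, `dgamma_mN_m`,
#'   `pi_mN_m`, and, when `model$gamma0` is set, `gamma_mN_m` and
#'   `beyond_model`.
#' @export
dgamma_of_c <- function(c0_mol_l, fit, model) {
  stopifnot(inherits(model, "tension_model"))
  if (abs(fit$gamma_inf - model$gamma_inf) >
        1e-8 * max(fit$gamma_inf, model$gamma_inf)) {
    stop("fit and tension model carry inconsistent gamma_inf",
         call. = FALSE)
  }
  if (any(c0_mol_l < 0)) stop("c0 must be >= 0", call. = FALSE)
  Gamma <- langmuir_gamma(conc_to_nm3(c0_mol_l), fit$k_c, fit$gamma_inf)
  out <- dgamma_of_gamma(Gamma, model)
  out <- cbind(c0_mol_l = c0_mol_l, out)
  if (is.finite(model$gamma0)) {
    out$gamma_mN_m <- model$gamma0 + out$dgamma_mN_m
    out$beyond_model <- out$gamma_mN_m <= 0
  }
  out
}
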