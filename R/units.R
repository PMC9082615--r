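#' surfwet: surfactant adsorption and droplet wetting analysis
#'
#' Tools for extracting surface-excess adsorption from 1-D density profiles,
#' fitting Langmuir isotherms with uncertainties in both coordinates,
#' computing Kirkwood-Buff solution corrections, propagating adsorption into
#' surface-tension reduction, and predicting contact-angle changes of
#' surfactant-laden sessile droplets.
#'
#' Internal unit system: lengths in nm, number densities in nm^-3, areal
#' densities in nm^-2, surface tensions in mN/m, angles in radians.
#' Concentrations in mol/l and angles in degrees are accepted at the user
#' interface and converted at the boundary.
#'
#' @keywords internal
"_PACKAGE"

## Avogadro's number folded into the mol/l -> nm^-3 conversion:
## 6.02214076e23 / 1e24 nm^3 per litre.
.MOL_L_TO_NM3 <- 0.602214076

## Boltzmann constant in (mN/m) nm^2 per kelvin: 1 (mN/m) nm^2 = 1e-21 J.
.KB_MN_NM2 <- 1.380649e-2

#' Thermal energy in surface-tension units
#'
#' Returns \eqn{k_B T} expressed in (mN/m) nm^2, the natural unit when
#' multiplying areal densities (nm^-2) or areas (nm^2) into tensions (mN/m).
#' At the default 300 K this is 4.1419 (mN/m) nm^2.
#'
#' @param T temperature in kelvin.
#' @return numeric scalar, \eqn{k_B T} in (mN/m) nm^2.
#' @export
#' @examples
#' kBT() # 4.141947
kBT <- function(T = 300) {
  stopifnot(is.numeric(T), T > 0)
  .KB_MN_NM2 * T
}

#' Concentration unit conversions
#'
#' `conc_to_nm3()` converts molar concentration (mol/l) to number density
#' (nm^-3); `conc_to_mol_l()` is the inverse. 1 mol/l = 0.602214076 nm^-3.
#'
#' @param c_mol_l concentration in mol/l.
#' @param c_nm3 number density in nm^-3.
#' @return numeric vector in the target unit.
#' @export
conc_to_nm3 <- function(c_mol_l) c_mol_l * .MOL_L_TO_NM3

#' @rdname conc_to_nm3
#' @export
conc_to_mol_l <- function(c_nm3) c_nm3 / .MOL_L_TO_NM3

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize a table's units by its column-name suffixes
#'
#' Column names must declare their unit with a suffix from the supported set:
#' `_nm` (length), `_nm3` (number density, nm^-3), `_nm2` (areal density,
#' nm^-2), `_mol_l` (molar concentration), `_mN_m` (surface tension),
#' `_deg` (angle). Values are converted to the internal units (nm, nm^-3,
#' nm^-2, mN/m, rad) and the suffix rewritten accordingly (`_mol_l` becomes
#' `_nm3`, `_deg` becomes `_rad`). Unitless columns may use the suffix
#' `_1` or carry no recognized suffix only if `strict = FALSE`.
#'
#' @param df data.frame whose column names end in unit suffixes.
#' @param strict error on columns without a supported suffix (default TRUE).
#' @return data.frame in internal units, with rewritten column names.
#' @export
#' @examples
#' validate_units(data.frame(c0_mol_l = 1))$c0_nm3 # 0.602214076
validate_units <- function(df, strict = TRUE) {
  stopifnot(is.data.frame(df))
  passthrough <- c("nm", "nm3", "nm2", "mN_m", "1")
  out <- df
  for (j in seq_along(df)) {
    nm <- names(df)[j]
    if (grepl("_mol_l$", nm)) {
      out[[j]] <- conc_to_nm3(df[[j]])
      names(out)[j] <- sub("_mol_l$", "_nm3", nm)
    } else if (grepl("_deg$", nm)) {
      out[[j]] <- deg2rad(df[[j]])
      names(out)[j] <- sub("_deg$", "_rad", nm)
    } else if (!any(vapply(passthrough, function(s)
                grepl(paste0("_", s, "$"), nm), logical(1L)))) {
      if (strict) {
        stop("column '", nm, "' does not declare a supported unit suffix ",
             "(nm, nm3, nm2, mol_l, mN_m, deg, 1)", call. = FALSE)
      }
    }
  }
  out
}

## trapezoid rule on an arbitrary (sorted) grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## cumulative trapezoid, same length as x, starting at 0
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}
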