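#' Fluid properties
#'
#' @param density kg/m^3, > 0.
#' @param viscosity dynamic viscosity, Pa s, > 0.
#' @return object of class `"fluid_spec"`.
#' @examples
#' blood <- fluid_spec(1060, 0.0035)
#' water_glycerol <- fluid_spec(1147, 0.008113)
#' @export
fluid_spec <- function(density, viscosity) {
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(viscosity) || viscosity <= 0) stop("viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_spec")
}

#' Dynamic-similarity ratio bundle
#'
#' Houses the three dimensionless ratios that convert in-vitro (scaled
#' phantom, blood-analogue fluid) vorticity and wall shear stress back to
#' in-vivo levels: `mu_ratio` = mu_vivo/mu_vitro, `u_ratio` =
#' u_vivo/u_vitro, `d_ratio` = d_vitro/d_vivo (geometric scale-up factor).
#'
#' @param mu_ratio,u_ratio,d_ratio strictly positive dimensionless ratios.
#' @return object of class `"similarity_spec"`.
#' @export
similarity_spec <- function(mu_ratio = 1, u_ratio = 1, d_ratio = 1) {
  vals <- c(mu_ratio, u_ratio, d_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("similarity ratios must be strictly positive")
  structure(list(mu_ratio = mu_ratio, u_ratio = u_ratio, d_ratio = d_ratio),
            class = "similarity_spec")
}

#' Invert a similarity bundle
#'
#' @param sim a [similarity_spec].
#' @return the [similarity_spec] with every ratio reciprocated, so that
#'   scaling with `sim` then `invert_similarity(sim)` is the identity.
#' @export
invert_similarity <- function(sim) {
  similarity_spec(1 / sim$mu_ratio, 1 / sim$u_ratio, 1 / sim$d_ratio)
}

#' Reynolds number
#'
#' \eqn{Re = \rho V D / \mu} with the inlet diameter as characteristic
#' length and (by the package's convention) the inlet mean velocity as
#' characteristic velocity.
#'
#' @param fluid a [fluid_spec].
#' @param mean_velocity characteristic velocity, m/s, > 0.
#' @param diameter characteristic length, m, > 0.
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(fluid, mean_velocity, diameter) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (!is.finite(mean_velocity) || mean_velocity <= 0)
    stop("mean_velocity must be > 0")
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be > 0")
  fluid$density * mean_velocity * diameter / fluid$viscosity
}

#' Percent deviation from a reference value
#'
#' @param measured measured value.
#' @param reference nonzero reference value.
#' @return `100 * |measured - reference| / reference`, in percent.
#' @export
percent_deviation <- function(measured, reference) {
  if (!is.finite(reference) || reference == 0)
    stop("reference must be finite and nonzero")
  100 * abs(measured - reference) / reference
}

#' Build the similarity bundle from fluids and geometry scale
#'
#' With `re_match = TRUE` the in-vitro velocity scale is the one that makes
#' the phantom Reynolds number equal the in-vivo one: equating
#' \eqn{\rho V D / \mu} across systems gives
#' `u_ratio = (mu_vivo / mu_vitro) * (rho_vitro / rho_vivo) * d_ratio`.
#' Otherwise `u_ratio_override` is used verbatim.
#'
#' @param fluid_vivo,fluid_vitro [fluid_spec] objects for the in-vivo
#'   (blood) and in-vitro (blood-analogue) fluids.
#' @param d_ratio geometric scale-up factor d_vitro/d_vivo, > 0.
#' @param re_match derive the velocity ratio from Reynolds matching?
#' @param u_ratio_override velocity ratio to use when `re_match = FALSE`.
#' @return a [similarity_spec].
#' @export
build_similarity <- function(fluid_vivo, fluid_vitro, d_ratio,
                             re_match = TRUE, u_ratio_override = NULL) {
  stopifnot(inherits(fluid_vivo, "fluid_spec"),
            inherits(fluid_vitro, "fluid_spec"))
  if (!is.finite(d_ratio) || d_ratio <= 0) stop("d_ratio must be > 0")
  mu_ratio <- fluid_vivo$viscosity / fluid_vitro$viscosity
  u_ratio <- if (re_match) {
    mu_ratio * (fluid_vitro$density / fluid_vivo$density) * d_ratio
  } else {
    if (is.null(u_ratio_override))
      stop("supply u_ratio_override when re_match is FALSE")
    u_ratio_override
  }
  similarity_spec(mu_ratio = mu_ratio, u_ratio = u_ratio, d_ratio = d_ratio)
}
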