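#' Compensator beam model
#'
#' The surrogate treatment-planning-system model of photon transmission
#' through a brass compensator. It has two commissionable parameters —
#' the brass density `rho` and a modified scatter factor `msf` — plus a
#' fixed mass attenuation coefficient `kappa`. Central-axis transmission
#' through thickness \eqn{t} (cm) is
#' \deqn{T(t) = (1 + \mathrm{MSF}\, t)\, e^{-\kappa \rho t},}
#' i.e. exponential attenuation with an effective linear attenuation
#' coefficient \eqn{\kappa\rho} (cm\eqn{^{-1}}), multiplied by a fluence
#' boost \eqn{1 + \mathrm{MSF}\, t} accounting for extra scatter off the
#' compensator relative to tissue.
#'
#' @param rho Brass density in g/cm^3; must be positive. Nominal brass is
#'   about 8.5 g/cm^3; commissioned effective values are typically lower.
#' @param msf Modified scatter factor in cm^-1, in `[0, 1]`.
#' @param kappa Mass attenuation coefficient in cm^2/g; default 0.037, a
#'   plausible value for brass at the effective energy of a 10 MV beam.
#' @return An object of class `beam_model`.
#' @examples
#' m <- beam_model(rho = 8.498, msf = 0.2)
#' transmission(c(1, 3, 5), m)
#' @export
beam_model <- function(rho, msf, kappa = 0.037) {
  check_number(rho, "rho", lower = 0, strict_lower = TRUE)
  check_number(msf, "msf", lower = 0, upper = 1)
  check_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  structure(
    list(rho = as.numeric(rho), msf = as.numeric(msf),
         kappa = as.numeric(kappa)),
    class = "beam_model"
  )
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(
    "<beam_model> rho = %g g/cm^3, MSF = %g cm^-1, kappa = %g cm^2/g\n",
    x$rho, x$msf, x$kappa
  ))
  invisible(x)
}

is_beam_model <- function(x) inherits(x, "beam_model")

#' Central-axis transmission through a brass thickness
#'
#' Evaluates the compensator model \eqn{T(t) = (1 + \mathrm{MSF}\,t)
#' e^{-\kappa\rho t}}: the modeled ratio of attenuated to open-field
#' reading at central axis.
#'
#' @param thickness Brass thickness in cm; vectorized, all values >= 0.
#' @param model A [beam_model()].
#' @return Transmission fraction(s) in `(0, Inf)`; 1 at zero thickness.
#' @export
transmission <- function(thickness, model) {
  if (!is_beam_model(model)) stop_usage("`model` must be a beam_model")
  if (!is.numeric(thickness) || anyNA(thickness)) {
    stop_usage("`thickness` must be numeric with no missing values")
  }
  if (any(thickness < 0)) stop_usage("`thickness` must be >= 0 (cm)")
  (1 + model$msf * thickness) * exp(-model$kappa * model$rho * thickness)
}

#' Log attenuation ratio
#'
#' Natural logarithm of a transmission fraction, the quantity plotted
#' against slab thickness in attenuation measurements: negative whenever
#' the beam is attenuated.
#'
#' @param transmission Transmission fraction(s), strictly positive.
#' @return `log(transmission)`.
#' @export
log_attenuation <- function(transmission) {
  if (!is.numeric(transmission) || anyNA(transmission)) {
    stop_usage("`transmission` must be numeric with no missing values")
  }
  if (any(transmission <= 0)) {
    stop_usage("`transmission` must be strictly positive")
  }
  log(transmission)
}

#' Slab measurement specifications
#'
#' A table of slab measurement geometries: brass thickness, depth in water
#' of the ion chamber, and (square) field size. Depth and field size do not
#' enter the transmission model; they label the measurement conditions the
#' commissioning stratifies over.
#'
#' @param thickness_cm Slab thickness(es), cm, >= 0.
#' @param depth_cm Measurement depth(s) in water, cm, > 0.
#' @param field_size_cm Square field side(s), cm, > 0.
#' @return A data frame with columns `thickness_cm`, `depth_cm`,
#'   `field_size_cm` (recycled to a common length).
#' @export
slab_specs <- function(thickness_cm, depth_cm = 10, field_size_cm = 10) {
  df <- data.frame(
    thickness_cm = as.numeric(thickness_cm),
    depth_cm = as.numeric(depth_cm),
    field_size_cm = as.numeric(field_size_cm)
  )
  if (any(df$thickness_cm < 0)) stop_usage("thickness_cm must be >= 0")
  if (any(df$depth_cm <= 0)) stop_usage("depth_cm must be > 0")
  if (any(df$field_size_cm <= 0)) stop_usage("field_size_cm must be > 0")
  df
}

#' Model-predicted log attenuation for a set of slabs
#'
#' Vectorizes the compensator model over a slab table, producing the
#' predicted log ratios that are compared against measured log ratios in
#' the chi-squared objective.
#'
#' @param slabs A data frame with a `thickness_cm` column (e.g. from
#'   [slab_specs()]), or a bare numeric vector of thicknesses in cm.
#' @param model A [beam_model()].
#' @return Numeric vector, one predicted log ratio per slab, in input order.
#' @export
predicted_log_ratios <- function(slabs, model) {
  t_cm <- if (is.data.frame(slabs)) {
    if (is.null(slabs$thickness_cm)) {
      stop_usage("`slabs` must have a `thickness_cm` column")
    }
    slabs$thickness_cm
  } else {
    slabs
  }
  if (length(t_cm) == 0L) stop_usage("`slabs` must contain at least one slab")
  log_attenuation(transmission(t_cm, model))
}
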