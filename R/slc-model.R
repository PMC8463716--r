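# Single-loop-of-current (SLC) source model: closed-form on-axis field of a
# circular current loop with a relative-permeability core prefactor. The loop
# sits at depth T/2 below the screen plane, so the on-axis distance from a
# point at height z above the screen is (z + T/2).
#
# Unit policy: user-facing lengths in mm, currents in mA, fields in µT
# (gradients in µT/mm unless a function says mT/mm); SI only internally.

.MU0 <- 4e-7 * pi # vacuum permeability, T m / A

#' On-axis field of the single-loop-of-current source model
#'
#' Closed-form magnitude of the static magnetic field on the axis of a
#' circular current loop buried at depth `T_mm/2` below the screen plane:
#' \deqn{B(z) = \frac{\mu_r \mu_0 I r^2}{2\,[(z + T/2)^2 + r^2]^{3/2}}}
#' The relative permeability `mu_r` models the magnet core as a uniform
#' multiplier of the free-space loop field.
#'
#' @param z_mm Height(s) above the screen surface, mm. Must satisfy
#'   `z_mm >= -T_mm/2` (the loop plane).
#' @param r_mm Loop radius, mm (`> 0`).
#' @param I_mA Loop current, mA.
#' @param T_mm Phone thickness, mm; the loop is centred at `-T_mm/2`.
#' @param mu_r Relative permeability of the core (dimensionless, default 5000).
#' @return Field magnitude(s) in µT, same length as `z_mm`.
#' @export
#' @examples
#' slc_field(0, r_mm = 8, I_mA = 17.2, T_mm = 8.4) / 1000 # ~4.69 mT
slc_field <- function(z_mm, r_mm, I_mA, T_mm, mu_r = 5000) {
  stopifnot(is.numeric(z_mm), length(r_mm) == 1L, r_mm > 0, T_mm > 0)
  if (any(z_mm < -T_mm / 2)) {
    stop("z_mm below the loop plane (z < -T/2): the model covers the half-space above the loop")
  }
  z <- z_mm * 1e-3
  r <- r_mm * 1e-3
  i <- I_mA * 1e-3
  th <- T_mm * 1e-3
  b_tesla <- mu_r * .MU0 * i * r^2 / (2 * ((z + th / 2)^2 + r^2)^1.5)
  b_tesla * 1e6
}

#' Analytic z-derivative of the SLC on-axis field
#'
#' \deqn{dB/dz = \frac{-3 \mu_r \mu_0 I r^2 (z + T/2)}{2\,[(z + T/2)^2 + r^2]^{5/2}}}
#' Signed: negative for `z > -T/2` when `I > 0` (field decays away from the
#' loop). Use `abs()` for gradient-threshold work.
#'
#' @inheritParams slc_field
#' @return Gradient(s) dB/dz in µT/mm (numerically equal to mT/mm when divided
#'   by 1000).
#' @export
slc_gradient <- function(z_mm, r_mm, I_mA, T_mm, mu_r = 5000) {
  stopifnot(is.numeric(z_mm), length(r_mm) == 1L, r_mm > 0, T_mm > 0)
  if (any(z_mm < -T_mm / 2)) {
    stop("z_mm below the loop plane (z < -T/2)")
  }
  z <- z_mm * 1e-3
  r <- r_mm * 1e-3
  i <- I_mA * 1e-3
  th <- T_mm * 1e-3
  u <- z + th / 2
  g_T_per_m <- -3 * mu_r * .MU0 * i * r^2 * u / (2 * (u^2 + r^2)^2.5)
  g_T_per_m * 1e3 # T/m -> µT/mm
}

#' Construct a fitted-SLC parameter object
#'
#' Container for SLC source parameters, either fitted from a decay curve
#' (see [fit_slc()]) or taken from a published parameter table. `B_at_0_mT`
#' is always recomputed from the closed form, never stored independently.
#'
#' @param r_mm Loop radius, mm.
#' @param I_mA Loop current, mA.
#' @param T_mm Phone thickness, mm.
#' @param mu_r Core relative permeability.
#' @param r_squared Coefficient of determination of the fit (or `NA`).
#' @return An object of class `slc_fit`.
#' @export
slc_fit <- function(r_mm, I_mA, T_mm, mu_r = 5000, r_squared = NA_real_) {
  stopifnot(r_mm > 0, I_mA > 0, T_mm > 0, mu_r > 0)
  if (!is.na(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1)
  structure(
    list(
      r_mm = r_mm, I_mA = I_mA, T_mm = T_mm, mu_r = mu_r,
      r_squared = r_squared,
      B_at_0_mT = slc_field(0, r_mm, I_mA, T_mm, mu_r) / 1000
    ),
    class = "slc_fit"
  )
}

#' @export
print.slc_fit <- function(x, ...) {
  cat(sprintf(
    "SLC fit: r = %.2f mm, I = %.3f mA (mu_r = %g, T = %.1f mm)\n",
    x$r_mm, x$I_mA, x$mu_r, x$T_mm
  ))
  cat(sprintf(
    "  B@0 = %.3g mT, |dB/dz|@0 = %.2g mT/mm, R^2 = %s\n",
    x$B_at_0_mT, abs(slc_gradient(0, x$r_mm, x$I_mA, x$T_mm, x$mu_r)) / 1000,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))
  ))
  invisible(x)
}

#' @export
predict.slc_fit <- function(object, z_mm, ...) {
  slc_field(z_mm, object$r_mm, object$I_mA, object$T_mm, object$mu_r)
}

#' Distance at which the field gradient falls to a threshold
#'
#' Solves `|dB/dz|(z*) = g_threshold` for the unique root `z* > 0`, by
#' bracketed bisection on `[0, z_max]` to 1e-3 mm. The gradient magnitude of
#' the SLC model is strictly decreasing for z above `max(0, r/2 - T/2)`, which
#' the solver verifies by checking the bracket signs. If the screen-surface
#' gradient is already below the threshold the function returns 0 with
#' attribute `below_threshold = TRUE`.
#'
#' @param fit An [slc_fit()] object.
#' @param g_threshold_mT_mm Gradient threshold in mT/mm (default 0.02, the
#'   literature value above which inhomogeneous SMF blocked neuronal firing).
#' @param z_max_mm Upper solver bound, mm.
#' @return `z*` in mm (attribute `below_threshold` when applicable).
#' @export
threshold_distance <- function(fit, g_threshold_mT_mm = 0.02, z_max_mm = 200) {
  stopifnot(inherits(fit, "slc_fit"))
  if (!is.numeric(g_threshold_mT_mm) || g_threshold_mT_mm <= 0) {
    stop("g_threshold_mT_mm must be positive")
  }
  g <- function(z) abs(slc_gradient(z, fit$r_mm, fit$I_mA, fit$T_mm, fit$mu_r)) / 1000
  if (g(0) <= g_threshold_mT_mm) {
    return(structure(0, below_threshold = TRUE))
  }
  if (g(z_max_mm) >= g_threshold_mT_mm) {
    stop(sprintf(
      "gradient still above threshold at z_max = %g mm; increase z_max_mm",
      z_max_mm
    ))
  }
  root <- stats::uniroot(
    function(z) g(z) - g_threshold_mT_mm,
    lower = 0, upper = z_max_mm, tol = 1e-3
  )
  as.numeric(root$root)
}

#' Order-of-magnitude rate of field change when a phone is brought to the head
#'
#' The induced electric field during the motion is a transient whose driving
#' term is roughly the peak field divided by the motion duration.
#'
#' @param B_peak_mT Peak static field at the head, mT.
#' @param motion_duration_s Duration of the motion, s.
#' @return Rate of change in mT/s.
#' @export
induced_rate_estimate <- function(B_peak_mT, motion_duration_s) {
  stopifnot(is.numeric(B_peak_mT), is.numeric(motion_duration_s))
  if (B_peak_mT <= 0) stop("B_peak_mT must be positive")
  if (motion_duration_s <= 0) stop("motion_duration_s must be positive")
  B_peak_mT / motion_duration_s
}
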