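# Four-component measurement uncertainty budget, combined in quadrature:
# (1) repeatability SD of the replicate magnitudes,
# (2) sensor zeroing error (default bound 2 µT),
# (3) calibration error (default 0.5% of the reading),
# (4) field gradient along z times the z-position uncertainty (default 1.6 mm,
#     the midpoint of the stated 1.5-1.7 mm range).

#' Gradient contribution to the uncertainty budget
#'
#' `U_grad = |dB/dz| * delta_z`: the error induced by the z-position
#' uncertainty in the presence of a field gradient.
#'
#' @param dBdz_uT_mm Field gradient along z, µT/mm (sign ignored).
#' @param delta_z_mm z-position uncertainty, mm; must lie in `[0, 5]`.
#' @return U_grad in µT.
#' @export
gradient_uncertainty <- function(dBdz_uT_mm, delta_z_mm = 1.6) {
  if (delta_z_mm < 0) stop("delta_z_mm must be non-negative")
  if (delta_z_mm > 5) stop("delta_z_mm outside the supported [0, 5] mm range")
  abs(dBdz_uT_mm) * delta_z_mm
}

#' Combine the four uncertainty components in quadrature
#'
#' `u_c = sqrt(sd^2 + u_zero^2 + (u_cal_fraction * B)^2 + u_grad^2)`.
#' The calibration term applies to the measured reading `B`.
#'
#' @param B_uT Measured field magnitude, µT (>= 0).
#' @param sd_uT Repeatability SD, µT.
#' @param u_zero_uT Zeroing error, µT (default 2).
#' @param u_cal_fraction Calibration error fraction (default 0.005).
#' @param u_grad_uT Gradient x z-position error, µT.
#' @return An `uncertainty_budget`: list with the four components and `u_c`.
#' @export
combine_uncertainty <- function(B_uT, sd_uT, u_zero_uT = 2,
                                u_cal_fraction = 0.005, u_grad_uT = 0) {
  comps <- c(B_uT, sd_uT, u_zero_uT, u_cal_fraction, u_grad_uT)
  if (!all(is.finite(comps))) stop("all inputs must be finite")
  if (any(comps < 0)) stop("all inputs must be non-negative")
  u_cal <- u_cal_fraction * B_uT
  u_c <- sqrt(sd_uT^2 + u_zero_uT^2 + u_cal^2 + u_grad_uT^2)
  structure(
    list(
      B_uT = B_uT, sd = sd_uT, u_zero = u_zero_uT,
      u_cal = u_cal, u_cal_fraction = u_cal_fraction,
      u_grad = u_grad_uT, u_c = u_c
    ),
    class = "uncertainty_budget"
  )
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf(
    "Uc = %.3g uT  (sd %.3g, zero %.3g, cal %.3g, grad %.3g) at B = %.4g uT\n",
    x$u_c, x$sd, x$u_zero, x$u_cal, x$u_grad, x$B_uT
  ))
  invisible(x)
}

#' Finite-difference gradient of a measured decay curve
#'
#' Model-free slope estimates used for the U_grad term before any regression
#' exists. `at = "midpoints"` returns the slope of each successive pair at
#' the interval midpoint; `at = "nodes"` returns a slope per measurement
#' height (central differences inside, one-sided at the ends).
#'
#' @param curve A `decay_curve` (or data.frame with `z_mm`, `B_uT`).
#' @param at `"midpoints"` or `"nodes"`.
#' @return Data frame `z_mm`, `dBdz_uT_mm`.
#' @export
finite_difference_gradient <- function(curve, at = c("midpoints", "nodes")) {
  at <- match.arg(at)
  z <- curve$z_mm
  b <- curve$B_uT
  if (length(z) < 2L) stop("need at least two points")
  if (anyDuplicated(z)) stop("duplicate z values in curve")
  ord <- order(z)
  z <- z[ord]
  b <- b[ord]
  slope <- diff(b) / diff(z)
  if (at == "midpoints") {
    return(data.frame(z_mm = (z[-1] + z[-length(z)]) / 2, dBdz_uT_mm = slope))
  }
  n <- length(z)
  g <- numeric(n)
  g[1] <- slope[1]
  g[n] <- slope[n - 1]
  if (n > 2L) {
    for (i in 2:(n - 1)) {
      g[i] <- (b[i + 1] - b[i - 1]) / (z[i + 1] - z[i - 1])
    }
  }
  data.frame(z_mm = z, dBdz_uT_mm = g)
}

#' Per-height uncertainty budgets for a decay curve
#'
#' Builds one budget per measurement height from the curve's repeatability
#' SDs and a model-free finite-difference gradient.
#'
#' @param curve Data frame `z_mm`, `B_uT`.
#' @param sd_uT Per-height repeatability SD, µT (recycled if length 1).
#' @param u_zero_uT,u_cal_fraction,delta_z_mm Budget constants.
#' @return List of `uncertainty_budget`, one per height (sorted by z).
#' @export
curve_budgets <- function(curve, sd_uT, u_zero_uT = 2, u_cal_fraction = 0.005,
                          delta_z_mm = 1.6) {
  ord <- order(curve$z_mm)
  z <- curve$z_mm[ord]
  b <- curve$B_uT[ord]
  sd_uT <- rep_len(sd_uT, length(z))[ord]
  grad <- finite_difference_gradient(
    data.frame(z_mm = z, B_uT = b),
    at = "nodes"
  )$dBdz_uT_mm
  lapply(seq_along(z), function(i) {
    combine_uncertainty(
      B_uT = b[i], sd_uT = sd_uT[i], u_zero_uT = u_zero_uT,
      u_cal_fraction = u_cal_fraction,
      u_grad_uT = gradient_uncertainty(grad[i], delta_z_mm)
    )
  })
}
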