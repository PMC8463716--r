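# Bundled reference dataset: five mobile-phone models (2013-2018 vintage)
# characterized by triplicate tri-axial SMF grid mapping at z = 15-55 mm.
# These tables carry the phone dimensions, hot-spot locations, peak fields
# with combined uncertainty, and the fitted source / regression parameters.
# They serve as ground truth for the synthetic generator and as the input to
# the screen-extrapolation and head-dosimetry stages.

#' Reference phone geometries and hot-spot measurements
#'
#' One row per hot spot of the five reference phone models: phone dimensions
#' (L, W, T in mm), hot-spot location on the screen (x across the width, y
#' along the length, mm; origin at screen centre), and the measured peak
#' field magnitude with combined uncertainty at z = 15 and z = 55 mm (µT).
#' Model 3 has no lower hot spot.
#'
#' @return A data.frame with columns `model`, `L_mm`, `W_mm`, `T_mm`, `spot`,
#'   `x_mm`, `y_mm`, `B15_uT`, `Uc15_uT`, `B55_uT`, `Uc55_uT`.
#' @export
reference_hotspots <- function() {
  data.frame(
    model = c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L),
    L_mm  = c(146.9, 146.9, 143.6, 143.6, 142.3, 133.9, 133.9, 139.6, 139.6),
    W_mm  = c(70.9, 70.9, 70.9, 70.9, 71.0, 68.7, 68.7, 69.7, 69.7),
    T_mm  = c(8.4, 8.4, 7.7, 7.7, 7.8, 7.5, 7.5, 9.1, 9.1),
    spot  = c(
      "UPPER", "LOWER", "UPPER", "LOWER", "UPPER",
      "UPPER", "LOWER", "UPPER", "LOWER"
    ),
    x_mm  = c(0, 0, -10, 30, -20, 0, 30, 0, -20),
    y_mm  = c(70, -60, 60, -60, 50, 60, -50, 60, -50),
    B15_uT  = c(381.9, 705.3, 584.7, 59.8, 820.2, 242.3, 404.8, 222.0, 361.0),
    Uc15_uT = c(81.4, 123.9, 111.5, 12.8, 139.2, 50.0, 72.8, 43.9, 63.9),
    B55_uT  = c(17.5, 30.9, 32.4, 3.5, 40.2, 11.1, 29.6, 9.2, 16.4),
    Uc55_uT = c(2.6, 3.4, 3.1, 2.2, 3.4, 2.3, 2.7, 2.5, 2.6),
    stringsAsFactors = FALSE
  )
}

#' Reference fitted source and regression parameters
#'
#' One row per hot spot: the fitted SLC source parameters (loop radius `r_mm`,
#' current `I_mA`, with `mu_r` fixed at 5000) together with the exponential
#' (`a exp(-b z)`, a in mT, b in 1/mm) and power-law (`a z^-b`, a in µT)
#' comparison regressions and their coefficients of determination.
#'
#' @return A data.frame keyed by (`model`, `spot`).
#' @export
reference_fits <- function() {
  data.frame(
    model = c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L),
    spot  = c(
      "UPPER", "LOWER", "UPPER", "LOWER", "UPPER",
      "UPPER", "LOWER", "UPPER", "LOWER"
    ),
    exp_a_mT = c(0.93, 1.77, 1.32, 0.13, 2.10, 0.77, 1.12, 0.58, 0.92),
    exp_b_per_mm = c(0.074, 0.075, 0.069, 0.068, 0.073, 0.082, 0.070, 0.077, 0.075),
    exp_r2 = c(0.982, 0.981, 0.974, 0.962, 0.985, 0.948, 0.948, 0.983, 0.985),
    pow_a_uT = c(250029, 537816, 262720, 23115, 537666, 109264, 77710, 203089, 266219),
    pow_b = c(2.369, 2.419, 2.236, 2.196, 2.350, 2.228, 1.949, 2.478, 2.399),
    pow_r2 = c(0.995, 0.995, 0.998, 0.999, 0.993, 0.996, 0.997, 0.995, 0.994),
    slc_r_mm = c(8.0, 10.0, 9.5, 8.0, 10.0, 6.0, 11.0, 7.0, 8.0),
    slc_I_mA = c(17.2, 22.6, 19.8, 2.59, 26.0, 16.0, 11.6, 13.2, 17.0),
    slc_r2 = c(0.998, 0.998, 0.998, 0.998, 0.996, 0.997, 0.998, 0.997, 0.997),
    B_at_0_mT = c(4.69, 5.56, 5.21, 0.74, 6.60, 5.11, 2.81, 3.49, 4.38),
    stringsAsFactors = FALSE
  )
}

#' Reference dataset joined into SLC fit objects
#'
#' Convenience accessor joining [reference_hotspots()] and [reference_fits()]
#' into a list of [slc_fit()] objects (with each model's thickness attached),
#' named `"<model>_<spot>"`.
#'
#' @param mu_r Core relative permeability applied to every fit.
#' @return Named list of `slc_fit` objects, length 9.
#' @export
reference_slc_fits <- function(mu_r = 5000) {
  hs <- reference_hotspots()
  ft <- reference_fits()
  stopifnot(identical(hs$model, ft$model), identical(hs$spot, ft$spot))
  fits <- lapply(seq_len(nrow(ft)), function(i) {
    slc_fit(
      r_mm = ft$slc_r_mm[i], I_mA = ft$slc_I_mA[i],
      T_mm = hs$T_mm[i], mu_r = mu_r, r_squared = ft$slc_r2[i]
    )
  })
  names(fits) <- paste0(ft$model, "_", ft$spot)
  fits
}

#' Ground truth for a reference phone model
#'
#' Builds the [ground_truth_phone()] object for one of the five reference
#' models, using the fitted loop parameters as the generating truth for the
#' synthetic mapper.
#'
#' @param model Integer 1-5.
#' @param mu_r Core relative permeability.
#' @return A `ground_truth_phone` object.
#' @export
reference_truth <- function(model = 1, mu_r = 5000) {
  hs <- reference_hotspots()
  ft <- reference_fits()
  sel <- hs$model == model
  if (!any(sel)) stop("model must be one of 1:5")
  geom <- phone_geometry(
    L_mm = hs$L_mm[sel][1], W_mm = hs$W_mm[sel][1], T_mm = hs$T_mm[sel][1],
    model_label = paste0("MODEL ", model)
  )
  loops <- data.frame(
    label = hs$spot[sel],
    x_mm = hs$x_mm[sel], y_mm = hs$y_mm[sel],
    r_mm = ft$slc_r_mm[ft$model == model],
    I_mA = ft$slc_I_mA[ft$model == model],
    stringsAsFactors = FALSE
  )
  ground_truth_phone(geom, loops, mu_r = mu_r)
}
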