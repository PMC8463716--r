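# End-to-end orchestration: simulate (or load) -> average -> background
# subtract -> magnitudes -> hot spots -> uncertainty budgets -> decay fits ->
# screen extrapolation and gradients -> optional head map. All physical
# constants live in the config, never in stage logic.

#' Study configuration
#'
#' Bundles every pipeline constant with its protocol default: mapping grid
#' (120 x 200 mm at 10 mm pitch), heights 15-55 mm, triplicates, mu_r = 5000,
#' gradient threshold 0.02 mT/mm, zeroing error 2 µT, calibration error
#' 0.5%, z-position uncertainty 1.6 mm, skull depth 4 mm. Round-trips
#' through YAML unchanged.
#'
#' @param model Reference phone model (1-5) used as simulation ground truth.
#' @param z_list_mm Mapping heights, mm.
#' @param n_replicates Replicates per height.
#' @param background_uT Uniform background (geomagnetic) field, µT.
#' @param noise A [noise_model()].
#' @param grid A [grid_spec()].
#' @param mu_r Core permeability for fits and truth.
#' @param g_threshold_mT_mm Gradient threshold, mT/mm.
#' @param u_zero_uT,u_cal_fraction,delta_z_mm Uncertainty-budget constants.
#' @param skull_depth_mm Depth inside the head checked against the threshold.
#' @param n_segments Loop discretization.
#' @param head_map Compute the head-surface field stage.
#' @param outdir Optional output directory for report CSVs.
#' @param seed Seed recorded into the noise model.
#' @return A `study_config` object.
#' @export
study_config <- function(model = 1, z_list_mm = c(15, 20, 25, 30, 55),
                         n_replicates = 3L, background_uT = c(20, 0, -45),
                         noise = noise_model(), grid = grid_spec(),
                         mu_r = 5000, g_threshold_mT_mm = 0.02,
                         u_zero_uT = 2, u_cal_fraction = 0.005,
                         delta_z_mm = 1.6, skull_depth_mm = 4,
                         n_segments = 360, head_map = FALSE, outdir = NULL,
                         seed = NULL) {
  stopifnot(
    mu_r > 0, g_threshold_mT_mm > 0, u_zero_uT >= 0, u_cal_fraction >= 0,
    delta_z_mm > 0, skull_depth_mm > 0
  )
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  structure(
    list(
      model = model, z_list_mm = z_list_mm, n_replicates = n_replicates,
      background_uT = background_uT, noise = noise, grid = grid,
      mu_r = mu_r, g_threshold_mT_mm = g_threshold_mT_mm,
      u_zero_uT = u_zero_uT, u_cal_fraction = u_cal_fraction,
      delta_z_mm = delta_z_mm, skull_depth_mm = skull_depth_mm,
      n_segments = n_segments, head_map = head_map, outdir = outdir
    ),
    class = "study_config"
  )
}

#' Write / read a study configuration as YAML
#' @param config A [study_config()].
#' @param path File path.
#' @return `read_study_config` returns a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$noise <- unclass(x$noise)
  x$grid <- list(
    x_extent_mm = config$grid$x_extent_mm,
    y_extent_mm = config$grid$y_extent_mm,
    pitch_mm = config$grid$pitch_mm
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$noise <- do.call(noise_model, x$noise)
  x$grid <- do.call(grid_spec, x$grid)
  x$z_list_mm <- as.numeric(x$z_list_mm)
  x$background_uT <- as.numeric(x$background_uT)
  do.call(study_config, x[setdiff(names(x), "seed")])
}

.process_study <- function(study, config) {
  bg <- average_replicates(study$background_maps)$mean
  mags <- list()
  sds <- list()
  for (z in study$z_list_mm) {
    reps <- Filter(function(m) isTRUE(all.equal(m$z_nominal_mm, z)), study$maps)
    avg <- average_replicates(reps)
    clean <- subtract_background(avg$mean, bg)
    mags[[as.character(z)]] <- magnitude(clean, sd = avg$sd)
    sds[[as.character(z)]] <- avg$sd
  }
  list(magnitudes = mags, sds = sds, background_mean = bg)
}

#' Run the full analysis pipeline
#'
#' Simulates (or takes) a mapping study, processes it, and emits the three
#' reports: per-hot-spot peak fields with combined uncertainty at every
#' height (`hotspot_report`), all three decay regressions with R^2 and the
#' screen-extrapolated field (`fit_report`), and the screen gradient with
#' its threshold distance and skull-depth flag (`gradient_report`); plus an
#' optional head-surface field map. With `outdir` set, each report is also
#' written as CSV.
#'
#' @param config A [study_config()].
#' @param study Optional pre-built `study_dataset` (e.g. from [read_study()]);
#'   `NULL` simulates one from the config's reference model.
#' @return A `report_bundle` list: `hotspot_report`, `fit_report`,
#'   `gradient_report`, `curves`, `fits`, `head_field` (or `NULL`), `config`.
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(study)) {
    truth <- reference_truth(config$model, mu_r = config$mu_r)
    study <- simulate_study(
      truth, config$z_list_mm, config$n_replicates,
      config$background_uT, config$noise, config$grid,
      n_segments = config$n_segments
    )
  }
  proc <- .process_study(study, config)
  zs <- study$z_list_mm
  z0 <- as.character(min(zs))
  spots <- detect_hotspots(proc$magnitudes[[z0]],
    phone = study$truth$geometry
  )
  if (!length(spots)) stop("no hot spots detected on the lowest-height map")

  hotspot_rows <- list()
  curves <- list()
  fits <- list()
  fit_rows <- list()
  grad_rows <- list()
  for (sp in spots) {
    raw <- extract_decay_curve(proc$magnitudes, sp, expected_z_mm = zs)
    sd_at_spot <- vapply(names(proc$magnitudes), function(z) {
      mg <- proc$magnitudes[[z]]
      ix <- which(abs(mg$grid$x - sp$x_mm) < 1e-9)
      iy <- which(abs(mg$grid$y - sp$y_mm) < 1e-9)
      mg$sd[(iy - 1L) * length(mg$grid$x) + ix]
    }, numeric(1))
    budgets <- curve_budgets(
      raw, sd_at_spot[order(as.numeric(names(proc$magnitudes)))],
      u_zero_uT = config$u_zero_uT, u_cal_fraction = config$u_cal_fraction,
      delta_z_mm = config$delta_z_mm
    )
    curve <- extract_decay_curve(proc$magnitudes, sp,
      budgets = budgets,
      expected_z_mm = zs
    )
    curves[[sp$label]] <- curve
    hotspot_rows[[sp$label]] <- data.frame(
      spot = sp$label, x_mm = sp$x_mm, y_mm = sp$y_mm,
      z_mm = curve$z_mm, B_uT = curve$B_uT, Uc_uT = curve$Uc_uT
    )
    cmp <- compare_fits(curve, study$truth$geometry$T_mm, mu_r = config$mu_r)
    slc <- attr(cmp, "fits")$slc
    fits[[sp$label]] <- slc
    fit_rows[[sp$label]] <- cbind(spot = sp$label, cmp)
    zstar <- threshold_distance(slc, config$g_threshold_mT_mm)
    g0 <- abs(slc_gradient(0, slc$r_mm, slc$I_mA, slc$T_mm, slc$mu_r)) / 1000
    gskull <- abs(slc_gradient(
      config$skull_depth_mm, slc$r_mm, slc$I_mA,
      slc$T_mm, slc$mu_r
    )) / 1000
    grad_rows[[sp$label]] <- data.frame(
      spot = sp$label,
      B_at_0_mT = slc$B_at_0_mT,
      grad_at_0_mT_mm = g0,
      grad_at_skull_mT_mm = gskull,
      threshold_mT_mm = config$g_threshold_mT_mm,
      threshold_distance_mm = as.numeric(zstar),
      above_threshold_at_skull = gskull > config$g_threshold_mT_mm
    )
  }
  head_field <- NULL
  if (isTRUE(config$head_map)) {
    head_field <- head_map_at_ear(
      fits, spots, study$truth$geometry,
      background = config$background_uT, n_segments = config$n_segments
    )
  }
  bundle <- structure(
    list(
      hotspot_report = do.call(rbind, c(hotspot_rows, make.row.names = FALSE)),
      fit_report = do.call(rbind, c(fit_rows, make.row.names = FALSE)),
      gradient_report = do.call(rbind, c(grad_rows, make.row.names = FALSE)),
      curves = curves, fits = fits, head_field = head_field, config = config
    ),
    class = "report_bundle"
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bundle$hotspot_report,
      file.path(config$outdir, "hotspot_report.csv"),
      row.names = FALSE
    )
    utils::write.csv(bundle$fit_report,
      file.path(config$outdir, "fit_report.csv"),
      row.names = FALSE
    )
    utils::write.csv(bundle$gradient_report,
      file.path(config$outdir, "gradient_report.csv"),
      row.names = FALSE
    )
    if (!is.null(head_field)) {
      write_headfield_csv(
        head_field,
        file.path(config$outdir, "head_field.csv")
      )
    }
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n-- fits --\n")
  print(x$fit_report)
  cat("-- gradients --\n")
  print(x$gradient_report)
  invisible(x)
}

#' Head-surface field with the phone held to the ear of an ellipsoid head
#'
#' Places the screen plane parallel to the head fixture's tangent plane at
#' its maximum-x "ear" vertex, shifted along that plane so the UPPER hot
#' spot (the speaker, which a caller presses to the ear) sits directly
#' opposite the ear vertex, with the phone's long axis toward the top of the
#' head; then superposes the fitted loop fields with the background on every
#' vertex.
#'
#' @param fits Named/ordered list of [slc_fit()], parallel to `hotspots`.
#' @param hotspots Hot spots giving each loop's screen (x, y).
#' @param geometry The [phone_geometry()].
#' @param mesh Head mesh (default [make_head_mesh()] ellipsoid).
#' @param background Uniform background, µT.
#' @param standoff_mm Gap between screen plane and the ear vertex.
#' @param n_segments Loop discretization.
#' @return A `head_field_result`.
#' @export
head_map_at_ear <- function(fits, hotspots, geometry,
                            mesh = make_head_mesh(),
                            background = c(0, 0, 0), standoff_mm = 5,
                            n_segments = 360) {
  ear <- mesh$vertices[which.max(mesh$vertices[, 1]), ]
  # phone frame (x_p, y_p, z_p) -> head frame: screen normal z_p -> -x (the
  # screen faces the ear), y_p (toward the speaker) -> +z (top of head),
  # x_p -> -y to keep the transform proper (det +1)
  rot <- cbind(c(0, -1, 0), c(0, 0, 1), c(-1, 0, 0))
  labels <- vapply(hotspots, `[[`, character(1), "label")
  anchor_i <- if (any(labels == "UPPER")) which(labels == "UPPER")[1] else 1L
  anchor <- c(hotspots[[anchor_i]]$x_mm, hotspots[[anchor_i]]$y_mm, 0)
  pose <- rigid_transform(
    rot,
    ear + c(standoff_mm, 0, 0) - as.numeric(rot %*% anchor)
  )
  loops <- place_loops_from_fits(pose, geometry, hotspots, fits)
  field_on_mesh(loops, mesh, background = background, n_segments = n_segments)
}
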