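# Synthetic measurement generator. Emulates the mapping protocol: triplicate
# tri-axial grid maps at several heights plus background-only maps, with the
# documented error structure: per-reading sensor noise, a per-session
# zero-offset bias and calibration scale factor, and a per-map jitter of the
# true mapping height (the physical origin of the U_grad term — the recorded
# nominal height stays unjittered).

#' Measurement noise model
#'
#' @param sensor_noise_rms_uT RMS per-axis per-reading noise, µT (default
#'   0.1, matching the 100 nT_rms ambient AC figure).
#' @param zero_offset_bound_uT Per-axis zeroing bias bound, µT; one uniform
#'   draw in ±bound per axis per session (default 2).
#' @param cal_scale_error Calibration scale-error bound (fraction in
#'   `[0, 0.05]`, default 0.005); one uniform draw per session applied as a
#'   constant multiplicative factor.
#' @param z_jitter_sd_mm SD of the per-map perturbation of the true mapping
#'   height, mm (default 0.3, the repositioning repeatability of a spacer
#'   stack; the larger 1.5-1.7 mm figure is the systematic z-position
#'   uncertainty bound and enters the budget via `delta_z_mm`, not here).
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical dataset.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sensor_noise_rms_uT = 0.1, zero_offset_bound_uT = 2,
                        cal_scale_error = 0.005, z_jitter_sd_mm = 0.3,
                        seed = 1L) {
  stopifnot(
    sensor_noise_rms_uT >= 0, zero_offset_bound_uT >= 0, z_jitter_sd_mm >= 0,
    cal_scale_error >= 0, cal_scale_error <= 0.05
  )
  structure(
    list(
      sensor_noise_rms_uT = sensor_noise_rms_uT,
      zero_offset_bound_uT = zero_offset_bound_uT,
      cal_scale_error = cal_scale_error,
      z_jitter_sd_mm = z_jitter_sd_mm,
      seed = as.integer(seed)
    ),
    class = "noise_model"
  )
}

#' All-zero noise model (noiseless forward simulation)
#' @param seed Integer seed (kept for interface symmetry).
#' @return A `noise_model` with every magnitude zero.
#' @export
noise_free <- function(seed = 1L) {
  noise_model(0, 0, 0, 0, seed = seed)
}

#' Ground-truth phone: geometry plus generating source loops
#'
#' @param geometry A [phone_geometry()].
#' @param loops Data frame with columns `label`, `x_mm`, `y_mm`, `r_mm`,
#'   `I_mA`: one source loop per hot spot, located on the screen (within the
#'   phone footprint), buried at depth T/2.
#' @param mu_r Core relative permeability of every loop.
#' @return A `ground_truth_phone` object.
#' @export
ground_truth_phone <- function(geometry, loops, mu_r = 5000) {
  stopifnot(inherits(geometry, "phone_geometry"), is.data.frame(loops))
  req <- c("label", "x_mm", "y_mm", "r_mm", "I_mA")
  if (!all(req %in% names(loops))) {
    stop("loops needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(loops)) {
    stopifnot(all(loops$r_mm > 0), all(loops$I_mA != 0))
    inside <- abs(loops$x_mm) <= geometry$W_mm / 2 &
      abs(loops$y_mm) <= geometry$L_mm / 2
    if (!all(inside)) stop("loop positions must lie within the phone footprint")
  }
  structure(
    list(geometry = geometry, loops = loops, mu_r = mu_r),
    class = "ground_truth_phone"
  )
}

.truth_loops3d <- function(truth) {
  lapply(seq_len(nrow(truth$loops)), function(i) {
    loop3d(
      center = c(
        truth$loops$x_mm[i], truth$loops$y_mm[i],
        -truth$geometry$T_mm / 2
      ),
      axis = c(0, 0, 1),
      radius_mm = truth$loops$r_mm[i],
      current_mA = truth$loops$I_mA[i],
      mu_r = truth$mu_r
    )
  })
}

# deterministic sub-seed, kept within 32-bit integer range
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + as.double(k) * 10007) %% 2147483647)
}

# per-session systematic errors: zero-offset bias per axis and one scale factor
.draw_session <- function(noise) {
  set.seed(.derive_seed(noise$seed, 0L))
  list(
    offset_uT = stats::runif(3, -noise$zero_offset_bound_uT, noise$zero_offset_bound_uT),
    scale = stats::runif(1, -noise$cal_scale_error, noise$cal_scale_error)
  )
}

#' Simulate one tri-axial grid map
#'
#' Forward model: uniform background plus the Biot-Savart field of every
#' ground-truth loop (centred at depth T/2 below the screen), evaluated at
#' the true (jittered) height; then corrupted by the session calibration
#' scale, the session zero-offset bias, and per-reading sensor noise. The
#' stored nominal height is the unjittered one.
#'
#' @param truth A [ground_truth_phone()] (zero loop rows give a
#'   background-only map).
#' @param z_mm Nominal mapping height, mm (>= 0).
#' @param grid A [grid_spec()].
#' @param background Uniform background field 3-vector, µT.
#' @param noise A [noise_model()].
#' @param replicate_index Integer; distinguishes the seed stream per map.
#' @param session Internal: precomputed per-session systematic errors (a
#'   study draws them once for all its maps); `NULL` derives them from the
#'   noise seed.
#' @param n_segments Loop discretization for the forward field.
#' @return A [field_map()] (phone metadata attached when the truth has loops).
#' @export
simulate_map <- function(truth, z_mm, grid = grid_spec(),
                         background = c(0, 0, 0), noise = noise_model(),
                         replicate_index = 1L, session = NULL,
                         n_segments = 360) {
  stopifnot(
    inherits(truth, "ground_truth_phone"), inherits(grid, "grid_spec"),
    inherits(noise, "noise_model")
  )
  if (z_mm < 0) stop("z_mm must be non-negative")
  if (length(grid$x) < 1L || length(grid$y) < 1L) stop("grid has zero extent")
  if (is.null(session)) session <- .draw_session(noise)

  set.seed(.derive_seed(noise$seed, 7L + replicate_index * 131L + round(z_mm * 17)))
  z_true <- z_mm + stats::rnorm(1, 0, noise$z_jitter_sd_mm)
  z_true <- max(z_true, 0)

  nodes <- grid_nodes(grid)
  pts <- cbind(nodes$x_mm, nodes$y_mm, z_true)
  truef <- .superpose_loops(.truth_loops3d(truth), pts, background, n_segments)
  measured <- truef * (1 + session$scale) +
    matrix(session$offset_uT, nrow = nrow(truef), ncol = 3L, byrow = TRUE) +
    matrix(stats::rnorm(3L * nrow(truef), 0, noise$sensor_noise_rms_uT), ncol = 3L)
  field_map(grid, z_mm, measured,
    phone = if (nrow(truth$loops)) truth$geometry else NULL,
    replicate_id = as.integer(replicate_index)
  )
}

#' Simulate a full mapping study
#'
#' Replicate maps of the phone at each height plus replicate background-only
#' maps (no phone), all under one seed stream with deterministically derived
#' per-map sub-seeds and shared per-session systematic errors.
#'
#' @param truth A [ground_truth_phone()].
#' @param z_list_mm Mapping heights, mm (default the protocol's
#'   15, 20, 25, 30, 55).
#' @param n_replicates Replicates per height (default 3).
#' @param background Uniform background field 3-vector, µT.
#' @param noise A [noise_model()].
#' @param grid A [grid_spec()].
#' @param n_segments Loop discretization.
#' @return A `study_dataset`: list with `maps` (phone maps; attributes give
#'   z and replicate), `background_maps`, and the generating configuration.
#' @export
simulate_study <- function(truth, z_list_mm = c(15, 20, 25, 30, 55),
                           n_replicates = 3L, background = c(0, 0, 0),
                           noise = noise_model(), grid = grid_spec(),
                           n_segments = 360) {
  if (!length(z_list_mm)) stop("z_list_mm must not be empty")
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  session <- .draw_session(noise)
  counter <- 0L
  maps <- list()
  for (z in z_list_mm) {
    for (rep_i in seq_len(n_replicates)) {
      counter <- counter + 1L
      maps[[counter]] <- simulate_map(
        truth, z, grid, background, noise,
        replicate_index = counter, session = session, n_segments = n_segments
      )
    }
  }
  bg_truth <- ground_truth_phone(truth$geometry, truth$loops[0, , drop = FALSE],
    mu_r = truth$mu_r
  )
  background_maps <- lapply(seq_len(n_replicates), function(k) {
    simulate_map(bg_truth, z_list_mm[1], grid, background, noise,
      replicate_index = 100000L + k, session = session, n_segments = n_segments
    )
  })
  structure(
    list(
      maps = maps, background_maps = background_maps,
      truth = truth, z_list_mm = z_list_mm, n_replicates = n_replicates,
      background = as.numeric(background), noise = noise, grid = grid
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "study_dataset: %d phone maps (%d heights x %d replicates) + %d background maps\n",
    length(x$maps), length(x$z_list_mm), x$n_replicates,
    length(x$background_maps)
  ))
  invisible(x)
}
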