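# Grid-map containers and processing: replicate averaging, background
# subtraction, magnitude maps, hot-spot detection, decay-curve assembly.
#
# Coordinate frame: origin at the screen centre, x across the width, y along
# the length (positive toward the speaker end), z the outward screen normal.
# Node order everywhere is canonical y-major ascending (y slow, x fast).

#' Mapping grid specification
#'
#' Regular rectangular grid centred on the screen. Defaults reproduce the
#' 120 x 200 mm mapping area at 10 mm pitch (13 x 21 = 273 nodes).
#'
#' @param x_extent_mm,y_extent_mm Grid extents, mm; positive multiples of
#'   `pitch_mm`.
#' @param pitch_mm Node spacing, mm.
#' @return A `grid_spec` object with node coordinate vectors `x`, `y`.
#' @export
grid_spec <- function(x_extent_mm = 120, y_extent_mm = 200, pitch_mm = 10) {
  stopifnot(pitch_mm > 0, x_extent_mm > 0, y_extent_mm > 0)
  if (abs(x_extent_mm / pitch_mm - round(x_extent_mm / pitch_mm)) > 1e-9 ||
    abs(y_extent_mm / pitch_mm - round(y_extent_mm / pitch_mm)) > 1e-9) {
    stop("extents must be positive multiples of the pitch")
  }
  structure(
    list(
      x = seq(-x_extent_mm / 2, x_extent_mm / 2, by = pitch_mm),
      y = seq(-y_extent_mm / 2, y_extent_mm / 2, by = pitch_mm),
      pitch_mm = pitch_mm,
      x_extent_mm = x_extent_mm, y_extent_mm = y_extent_mm
    ),
    class = "grid_spec"
  )
}

#' Grid nodes in canonical order
#'
#' @param grid A [grid_spec()].
#' @return Data frame `x_mm`, `y_mm`, y-major ascending (x fastest).
#' @export
grid_nodes <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  expand.grid(x_mm = grid$x, y_mm = grid$y, KEEP.OUT.ATTRS = FALSE)
}

#' Phone geometry
#'
#' @param L_mm,W_mm,T_mm Length, width, thickness in mm (`T < W < L`).
#' @param model_label Free-text label.
#' @return A `phone_geometry` object.
#' @export
phone_geometry <- function(L_mm, W_mm, T_mm, model_label = "") {
  stopifnot(L_mm > 0, W_mm > 0, T_mm > 0)
  if (!(T_mm < W_mm && W_mm < L_mm)) stop("expected T < W < L")
  structure(
    list(L_mm = L_mm, W_mm = W_mm, T_mm = T_mm, model_label = model_label),
    class = "phone_geometry"
  )
}

#' Tri-axial field map at one height
#'
#' @param grid A [grid_spec()].
#' @param z_nominal_mm Nominal mapping height above the screen, mm.
#' @param values Numeric matrix, one row per grid node in canonical order,
#'   columns `Bx_uT`, `By_uT`, `Bz_uT`.
#' @param phone Optional [phone_geometry()] (absent for background maps).
#' @param replicate_id Optional replicate identifier.
#' @return A `field_map` object.
#' @export
field_map <- function(grid, z_nominal_mm, values, phone = NULL,
                      replicate_id = NA_integer_) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- length(grid$x) * length(grid$y)
  values <- as.matrix(values)
  if (nrow(values) != n || ncol(values) != 3L) {
    stop(sprintf("values must be a %d x 3 matrix for this grid", n))
  }
  if (!all(is.finite(values))) stop("field values must be finite")
  colnames(values) <- c("Bx_uT", "By_uT", "Bz_uT")
  structure(
    list(
      grid = grid, z_nominal_mm = z_nominal_mm, values = values,
      phone = phone, replicate_id = replicate_id
    ),
    class = "field_map"
  )
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf(
    "field_map: %d x %d nodes (%g mm pitch) at z = %g mm%s\n",
    length(x$grid$x), length(x$grid$y), x$grid$pitch_mm, x$z_nominal_mm,
    if (is.null(x$phone)) " [background]" else paste0(" [", x$phone$model_label, "]")
  ))
  invisible(x)
}

#' Average replicate field maps
#'
#' Per-node, per-component arithmetic mean of the replicate maps, plus the
#' per-node sample standard deviation (n-1 denominator) of the replicate
#' field *magnitudes* — the repeatability term of the uncertainty budget.
#'
#' @param maps List of `field_map` objects on the same grid and height.
#' @return List with `mean` (a `field_map`) and `sd` (numeric vector of
#'   per-node magnitude SD, µT, canonical node order).
#' @export
average_replicates <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 2L)
  g <- maps[[1]]$grid
  z <- maps[[1]]$z_nominal_mm
  for (m in maps) {
    stopifnot(inherits(m, "field_map"))
    if (!isTRUE(all.equal(m$grid$x, g$x)) || !isTRUE(all.equal(m$grid$y, g$y))) {
      stop("replicate maps must share the same grid")
    }
    if (!isTRUE(all.equal(m$z_nominal_mm, z))) {
      stop("replicate maps must share the same nominal z")
    }
  }
  vals <- lapply(maps, `[[`, "values")
  mean_vals <- Reduce(`+`, vals) / length(vals)
  mags <- vapply(vals, function(v) sqrt(rowSums(v^2)), numeric(nrow(mean_vals)))
  sd_mag <- apply(mags, 1L, stats::sd)
  list(
    mean = field_map(g, z, mean_vals, phone = maps[[1]]$phone),
    sd = sd_mag
  )
}

#' Subtract a background map (vector-wise)
#'
#' Per-node, per-component vector difference; phone metadata of `map` is
#' preserved. Always subtract vectors before taking magnitudes: the magnitude
#' of a difference is not the difference of magnitudes.
#'
#' @param map,background `field_map` objects on the same grid.
#' @return A `field_map`.
#' @export
subtract_background <- function(map, background) {
  stopifnot(inherits(map, "field_map"), inherits(background, "field_map"))
  if (!isTRUE(all.equal(map$grid$x, background$grid$x)) ||
    !isTRUE(all.equal(map$grid$y, background$grid$y))) {
    stop("map and background grids differ")
  }
  if (!all(is.finite(background$values))) stop("background contains non-finite values")
  field_map(map$grid, map$z_nominal_mm, map$values - background$values,
    phone = map$phone, replicate_id = map$replicate_id
  )
}

#' Magnitude map
#'
#' Per-node Euclidean norm of the field 3-vectors.
#'
#' @param map A `field_map`.
#' @param sd Optional per-node scalar SD (µT) to carry along.
#' @return A `magnitude_map` object with fields `grid`, `z_nominal_mm`,
#'   `values` (µT, >= 0), `sd`.
#' @export
magnitude <- function(map, sd = NULL) {
  stopifnot(inherits(map, "field_map"))
  vals <- sqrt(rowSums(map$values^2))
  if (!is.null(sd)) stopifnot(length(sd) == length(vals))
  structure(
    list(
      grid = map$grid, z_nominal_mm = map$z_nominal_mm,
      values = vals, sd = sd, phone = map$phone
    ),
    class = "magnitude_map"
  )
}

#' Detect field hot spots on a background-subtracted magnitude map
#'
#' A hot spot is a local maximum over the 8-neighbourhood whose value exceeds
#' the map median by at least `min_prominence_uT`. At most one UPPER spot
#' (maximum over the y > 0 half-grid) and one LOWER spot (y < 0) are
#' returned; ties break toward larger magnitude, then smaller |y|.
#'
#' @param mag A `magnitude_map` (background already subtracted).
#' @param phone Optional [phone_geometry()] recorded on the result.
#' @param min_prominence_uT Prominence above the map median, µT. Default:
#'   `3 * median(mag$sd)` when per-node SDs are present, else 1 µT.
#' @return List of hot spots (possibly empty), each with `label`, `x_mm`,
#'   `y_mm`, `B_uT`.
#' @export
detect_hotspots <- function(mag, phone = NULL, min_prominence_uT = NULL) {
  stopifnot(inherits(mag, "magnitude_map"))
  if (is.null(min_prominence_uT)) {
    min_prominence_uT <- if (!is.null(mag$sd)) 3 * stats::median(mag$sd) else 1
  }
  nx <- length(mag$grid$x)
  ny <- length(mag$grid$y)
  m <- matrix(mag$values, nrow = nx, ncol = ny) # x fastest -> rows are x
  cutoff <- stats::median(mag$values) + min_prominence_uT

  is_local_max <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      v <- m[i, j]
      if (v < cutoff) next
      nb <- m[
        max(1, i - 1):min(nx, i + 1),
        max(1, j - 1):min(ny, j + 1)
      ]
      if (v >= max(nb)) is_local_max[i, j] <- TRUE
    }
  }
  idx <- which(is_local_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list())
  }
  cand <- data.frame(
    x_mm = mag$grid$x[idx[, 1]],
    y_mm = mag$grid$y[idx[, 2]],
    B_uT = m[idx]
  )
  pick <- function(half) {
    cc <- cand[half, , drop = FALSE]
    if (nrow(cc) == 0L) {
      return(NULL)
    }
    cc <- cc[order(-cc$B_uT, abs(cc$y_mm)), , drop = FALSE]
    cc[1L, ]
  }
  out <- list()
  up <- pick(cand$y_mm > 0)
  lo <- pick(cand$y_mm < 0)
  if (!is.null(up)) {
    out[[length(out) + 1L]] <- structure(
      list(label = "UPPER", x_mm = up$x_mm, y_mm = up$y_mm, B_uT = up$B_uT, phone = phone),
      class = "hotspot"
    )
  }
  if (!is.null(lo)) {
    out[[length(out) + 1L]] <- structure(
      list(label = "LOWER", x_mm = lo$x_mm, y_mm = lo$y_mm, B_uT = lo$B_uT, phone = phone),
      class = "hotspot"
    )
  }
  out
}

#' Assemble the decay curve of a hot spot across mapping heights
#'
#' Reads |B| at the hot spot's fixed (x, y) node on each magnitude map and
#' attaches the per-height combined uncertainty when budgets are supplied.
#' The hot-spot position is held fixed across z (taken from the lowest-z map
#' at detection time).
#'
#' @param mags List of `magnitude_map`s at distinct heights.
#' @param spot A hot spot from [detect_hotspots()].
#' @param budgets Optional list of `uncertainty_budget`s, parallel to `mags`
#'   after sorting by z.
#' @param expected_z_mm Optional vector of heights that must all be present;
#'   missing levels raise an error naming them.
#' @return A `decay_curve`: data.frame `z_mm`, `B_uT`, `Uc_uT` sorted by z.
#' @export
extract_decay_curve <- function(mags, spot, budgets = NULL, expected_z_mm = NULL) {
  stopifnot(length(mags) >= 1L, inherits(spot, "hotspot"))
  zs <- vapply(mags, `[[`, numeric(1), "z_nominal_mm")
  if (anyDuplicated(zs)) stop("duplicate z levels in magnitude maps")
  if (!is.null(expected_z_mm)) {
    miss <- setdiff(expected_z_mm, zs)
    if (length(miss)) {
      stop("missing z levels: ", paste(miss, collapse = ", "), " mm")
    }
  }
  ord <- order(zs)
  mags <- mags[ord]
  zs <- zs[ord]
  if (!is.null(budgets)) {
    stopifnot(length(budgets) == length(mags))
    budgets <- budgets[ord]
  }
  b <- vapply(mags, function(mg) {
    ix <- which(abs(mg$grid$x - spot$x_mm) < 1e-9)
    iy <- which(abs(mg$grid$y - spot$y_mm) < 1e-9)
    if (length(ix) != 1L || length(iy) != 1L) {
      stop(sprintf(
        "hot spot (%g, %g) mm is not a grid node of the map at z = %g mm",
        spot$x_mm, spot$y_mm, mg$z_nominal_mm
      ))
    }
    mg$values[(iy - 1L) * length(mg$grid$x) + ix]
  }, numeric(1))
  uc <- if (is.null(budgets)) {
    rep(NA_real_, length(b))
  } else {
    vapply(budgets, `[[`, numeric(1), "u_c")
  }
  structure(
    data.frame(z_mm = zs, B_uT = b, Uc_uT = uc),
    class = c("decay_curve", "data.frame"),
    spot = spot
  )
}
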