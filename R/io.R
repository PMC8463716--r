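# Plain-text dataset interchange: one grid CSV per map (x_mm, y_mm, Bx_uT,
# By_uT, Bz_uT; canonical y-major ascending row order) plus a YAML manifest
# per study.

.GRID_COLUMNS <- c("x_mm", "y_mm", "Bx_uT", "By_uT", "Bz_uT")

#' Write a field map as a grid CSV
#'
#' Columns `x_mm, y_mm, Bx_uT, By_uT, Bz_uT`, canonical row order (y-major
#' ascending, x fastest), full-precision numbers so a read round trip is
#' lossless to well below 1e-6 µT.
#'
#' @param map A [field_map()].
#' @param path Output path.
#' @export
write_grid_csv <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  nodes <- grid_nodes(map$grid)
  df <- data.frame(
    x_mm = nodes$x_mm, y_mm = nodes$y_mm,
    Bx_uT = map$values[, 1], By_uT = map$values[, 2], Bz_uT = map$values[, 3]
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.GRID_COLUMNS, collapse = ","), con)
  writeLines(sprintf(
    "%.10g,%.10g,%.10g,%.10g,%.10g",
    df$x_mm, df$y_mm, df$Bx_uT, df$By_uT, df$Bz_uT
  ), con)
  invisible(path)
}

#' Read a grid CSV into a field map
#'
#' Validates the exact header, grid rectangularity and node uniqueness;
#' missing and duplicate nodes are reported with their (x, y) coordinates.
#'
#' @param path CSV path.
#' @param z_nominal_mm Nominal height recorded on the map (grid CSVs do not
#'   carry z; the study manifest does).
#' @param phone Optional [phone_geometry()].
#' @param replicate_id Optional replicate identifier.
#' @return A [field_map()].
#' @export
read_grid_csv <- function(path, z_nominal_mm = NA_real_, phone = NULL,
                          replicate_id = NA_integer_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), .GRID_COLUMNS)) {
    stop(
      "grid CSV must have exactly the columns ",
      paste(.GRID_COLUMNS, collapse = ", ")
    )
  }
  key <- paste(df$x_mm, df$y_mm)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate grid node at (x, y) = (", gsub(" ", ", ", d), ") mm")
  }
  xs <- sort(unique(df$x_mm))
  ys <- sort(unique(df$y_mm))
  if (nrow(df) != length(xs) * length(ys)) {
    full <- paste(
      rep(xs, times = length(ys)),
      rep(ys, each = length(xs))
    )
    gap <- setdiff(full, key)[1]
    stop(
      "non-rectangular grid: missing node at (x, y) = (",
      gsub(" ", ", ", gap), ") mm"
    )
  }
  pitch <- if (length(xs) > 1L) diff(xs)[1] else if (length(ys) > 1L) diff(ys)[1] else 1
  if (any(abs(diff(xs) - pitch) > 1e-9) || any(abs(diff(ys) - pitch) > 1e-9)) {
    stop("grid nodes are not evenly spaced")
  }
  g <- grid_spec(
    x_extent_mm = max(xs) - min(xs) + ifelse(length(xs) > 1, 0, pitch),
    y_extent_mm = max(ys) - min(ys) + ifelse(length(ys) > 1, 0, pitch),
    pitch_mm = pitch
  )
  # honour the file's absolute coordinates (grids need not be centred)
  g$x <- xs
  g$y <- ys
  # reorder to canonical y-major ascending
  df <- df[order(df$y_mm, df$x_mm), , drop = FALSE]
  field_map(g, z_nominal_mm, as.matrix(df[, 3:5]),
    phone = phone, replicate_id = replicate_id
  )
}

#' Write a magnitude map as CSV (`x_mm, y_mm, Bmag_uT, sd_uT`)
#'
#' @param mag A `magnitude_map`.
#' @param path Output path.
#' @export
write_magnitude_csv <- function(mag, path) {
  stopifnot(inherits(mag, "magnitude_map"))
  nodes <- grid_nodes(mag$grid)
  sd <- if (is.null(mag$sd)) rep(NA_real_, length(mag$values)) else mag$sd
  utils::write.csv(
    data.frame(
      x_mm = nodes$x_mm, y_mm = nodes$y_mm,
      Bmag_uT = mag$values, sd_uT = sd
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Write a simulated study to disk (grid CSVs + YAML manifest)
#'
#' One CSV per map (`map_z<z>_r<rep>.csv`, `background_r<rep>.csv`) and a
#' `manifest.yaml` recording geometry, heights, seed and noise parameters.
#'
#' @param study A `study_dataset` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in study$maps) {
    write_grid_csv(m, file.path(
      dir,
      sprintf("map_z%g_r%d.csv", m$z_nominal_mm, m$replicate_id)
    ))
  }
  for (k in seq_along(study$background_maps)) {
    write_grid_csv(
      study$background_maps[[k]],
      file.path(dir, sprintf("background_r%d.csv", k))
    )
  }
  manifest <- list(
    phone = study$truth$geometry[c("L_mm", "W_mm", "T_mm", "model_label")],
    mu_r = study$truth$mu_r,
    loops = if (nrow(study$truth$loops)) {
      lapply(seq_len(nrow(study$truth$loops)), function(i) as.list(study$truth$loops[i, ]))
    } else {
      list()
    },
    z_list_mm = study$z_list_mm,
    n_replicates = study$n_replicates,
    background_uT = study$background,
    grid = list(
      x_extent_mm = study$grid$x_extent_mm,
      y_extent_mm = study$grid$y_extent_mm,
      pitch_mm = study$grid$pitch_mm
    ),
    noise = unclass(study$noise)
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a study back from disk
#'
#' @param dir Directory written by [write_study()].
#' @return A `study_dataset` (maps carry their nominal z from the manifest).
#' @export
read_study <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  geom <- phone_geometry(
    manifest$phone$L_mm, manifest$phone$W_mm, manifest$phone$T_mm,
    manifest$phone$model_label %||% ""
  )
  loops <- if (length(manifest$loops)) {
    do.call(rbind, lapply(manifest$loops, as.data.frame))
  } else {
    data.frame(
      label = character(0), x_mm = numeric(0), y_mm = numeric(0),
      r_mm = numeric(0), I_mA = numeric(0)
    )
  }
  truth <- ground_truth_phone(geom, loops, mu_r = manifest$mu_r)
  nrep <- manifest$n_replicates
  counter <- 0L
  maps <- list()
  for (z in manifest$z_list_mm) {
    for (rep_i in seq_len(nrep)) {
      counter <- counter + 1L
      maps[[counter]] <- read_grid_csv(
        file.path(dir, sprintf("map_z%g_r%d.csv", z, counter)),
        z_nominal_mm = z, phone = geom, replicate_id = counter
      )
    }
  }
  background_maps <- lapply(seq_len(nrep), function(k) {
    read_grid_csv(
      file.path(dir, sprintf("background_r%d.csv", k)),
      z_nominal_mm = manifest$z_list_mm[1], replicate_id = k
    )
  })
  noise <- do.call(noise_model, manifest$noise)
  structure(
    list(
      maps = maps, background_maps = background_maps, truth = truth,
      z_list_mm = as.numeric(manifest$z_list_mm), n_replicates = nrep,
      background = as.numeric(manifest$background_uT), noise = noise,
      grid = grid_spec(
        manifest$grid$x_extent_mm, manifest$grid$y_extent_mm,
        manifest$grid$pitch_mm
      )
    ),
    class = "study_dataset"
  )
}

#' Per-vertex head-field CSV export
#'
#' Columns `vertex_id, x_mm, y_mm, z_mm, Bx_uT, By_uT, Bz_uT, Bmag_uT`.
#'
#' @param result A `head_field_result`.
#' @param path Output path.
#' @export
write_headfield_csv <- function(result, path) {
  stopifnot(inherits(result, "head_field_result"))
  v <- result$mesh$vertices
  utils::write.csv(
    data.frame(
      vertex_id = seq_len(nrow(v)),
      x_mm = v[, 1], y_mm = v[, 2], z_mm = v[, 3],
      Bx_uT = result$field[, 1], By_uT = result$field[, 2],
      Bz_uT = result$field[, 3], Bmag_uT = result$magnitude
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
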