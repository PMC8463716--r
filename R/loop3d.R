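# 3D source engine: Biot-Savart field of circular current loops discretized
# into straight segments. The permeability multiplier is applied as a uniform
# scalar prefactor to the free-space field, exactly as in the on-axis closed
# form — an idealization of the magnet core, not a boundary-value solution.

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

# orthonormal pair spanning the plane perpendicular to unit vector a
.plane_basis <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .normalize(ref - sum(ref * a) * a)
  e2 <- c(
    a[2] * e1[3] - a[3] * e1[2],
    a[3] * e1[1] - a[1] * e1[3],
    a[1] * e1[2] - a[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

#' Positioned, oriented circular current loop
#'
#' The 3D source primitive: a circular loop of current with a core
#' permeability multiplier. Axis is normalized on construction.
#'
#' @param center 3-vector, mm.
#' @param axis 3-vector, loop axis (normal of the loop plane); normalized.
#' @param radius_mm Loop radius, mm (> 0).
#' @param current_mA Loop current, mA (sign sets the field direction).
#' @param mu_r Core relative permeability multiplier.
#' @return A `loop3d` object.
#' @export
loop3d <- function(center, axis = c(0, 0, 1), radius_mm, current_mA, mu_r = 5000) {
  stopifnot(length(center) == 3L, length(axis) == 3L, radius_mm > 0)
  structure(
    list(
      center = as.numeric(center), axis = .normalize(as.numeric(axis)),
      radius_mm = radius_mm, current_mA = current_mA, mu_r = mu_r
    ),
    class = "loop3d"
  )
}

# shortest distance (mm) from each point (rows) to the loop wire
.wire_distance <- function(loop, points) {
  rel <- sweep(points, 2L, loop$center)
  h <- as.numeric(rel %*% loop$axis)
  radial <- rel - outer(h, loop$axis)
  rho <- sqrt(rowSums(radial^2))
  sqrt((rho - loop$radius_mm)^2 + h^2)
}

#' Biot-Savart field of a loop at arbitrary points
#'
#' Discretizes the loop into `n_segments` straight current elements and sums
#' `mu_r mu_0 I / (4 pi) * dl x r / |r|^3` over elements, vectorized over
#' evaluation points. Converges to the circular-loop field as `n_segments`
#' grows (error ~ n^-2); on the axis it converges to the closed form of
#' [slc_field()].
#'
#' @param loop A [loop3d()].
#' @param points Numeric matrix, one evaluation point per row (x, y, z mm),
#'   or a single 3-vector.
#' @param n_segments Number of straight elements (>= 8, default 360).
#' @return Matrix of field 3-vectors in µT, one row per point.
#' @export
loop_field_at_points <- function(loop, points, n_segments = 360) {
  stopifnot(inherits(loop, "loop3d"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (n_segments < 8L) stop("n_segments must be at least 8")
  d <- .wire_distance(loop, points)
  if (any(d < 1e-6)) {
    stop(sprintf(
      "evaluation point %d lies on the loop wire (distance %.2e mm)",
      which.min(d), min(d)
    ))
  }
  basis <- .plane_basis(loop$axis)
  dtheta <- 2 * pi / n_segments
  theta <- (seq_len(n_segments) - 0.5) * dtheta
  r <- loop$radius_mm
  # segment midpoints (S x 3) and tangential dl vectors (S x 3), mm
  mid <- sweep(
    r * (outer(cos(theta), basis$e1) + outer(sin(theta), basis$e2)),
    2L, loop$center, `+`
  )
  dl <- r * dtheta * (outer(-sin(theta), basis$e1) + outer(cos(theta), basis$e2))
  # R_ij = point_i - mid_j per component (N x S)
  rx <- outer(points[, 1], mid[, 1], `-`)
  ry <- outer(points[, 2], mid[, 2], `-`)
  rz <- outer(points[, 3], mid[, 3], `-`)
  inv_r3 <- (rx^2 + ry^2 + rz^2)^-1.5
  cx <- sweep(rz, 2L, dl[, 2], `*`) - sweep(ry, 2L, dl[, 3], `*`)
  cy <- sweep(rx, 2L, dl[, 3], `*`) - sweep(rz, 2L, dl[, 1], `*`)
  cz <- sweep(ry, 2L, dl[, 1], `*`) - sweep(rx, 2L, dl[, 2], `*`)
  # dl x R / |R|^3 in mm gives 1/mm; x 1e3 -> 1/m
  s <- cbind(
    rowSums(cx * inv_r3),
    rowSums(cy * inv_r3),
    rowSums(cz * inv_r3)
  ) * 1e3
  pref <- loop$mu_r * .MU0 * (loop$current_mA * 1e-3) / (4 * pi) # T m
  b <- pref * s * 1e6 # µT
  colnames(b) <- c("Bx_uT", "By_uT", "Bz_uT")
  b
}

#' @rdname loop_field_at_points
#' @param point A single 3-vector, mm.
#' @export
loop_field_at_point <- function(loop, point, n_segments = 360) {
  as.numeric(loop_field_at_points(loop, matrix(point, nrow = 1L), n_segments))
}

# total field of several loops plus a uniform background, at points (N x 3)
.superpose_loops <- function(loops, points, background = c(0, 0, 0),
                             n_segments = 360) {
  total <- matrix(rep(as.numeric(background), each = nrow(points)), ncol = 3L)
  for (lp in loops) {
    total <- total + loop_field_at_points(lp, points, n_segments)
  }
  colnames(total) <- c("Bx_uT", "By_uT", "Bz_uT")
  total
}

#' Rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation 3-vector, mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
    abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be a proper orthonormal matrix (rigid transform)")
  }
  structure(
    list(rotation = rotation, translation = as.numeric(translation)),
    class = "rigid_transform"
  )
}

.apply_transform <- function(pose, points) {
  t(pose$rotation %*% t(points)) +
    matrix(pose$translation, nrow = nrow(points), ncol = 3L, byrow = TRUE)
}

#' Place source loops in head coordinates from fitted parameters
#'
#' Each hot spot's fitted loop is centred at its screen location (x, y) at
#' depth T/2 below the screen plane with axis along the screen normal, then
#' carried into head coordinates by the phone pose.
#'
#' @param pose A [rigid_transform()] from phone frame to head frame.
#' @param geometry The [phone_geometry()] (supplies T).
#' @param hotspots List of hot spots (each with `x_mm`, `y_mm`).
#' @param fits List of [slc_fit()] objects, one per hot spot.
#' @return List of [loop3d()] in head coordinates.
#' @export
place_loops_from_fits <- function(pose, geometry, hotspots, fits) {
  stopifnot(
    inherits(pose, "rigid_transform"), inherits(geometry, "phone_geometry"),
    length(hotspots) == length(fits)
  )
  lapply(seq_along(hotspots), function(k) {
    hs <- hotspots[[k]]
    ft <- fits[[k]]
    center <- c(hs$x_mm, hs$y_mm, -geometry$T_mm / 2)
    loop3d(
      center = .apply_transform(pose, matrix(center, nrow = 1L))[1L, ],
      axis = as.numeric(pose$rotation %*% c(0, 0, 1)),
      radius_mm = ft$r_mm, current_mA = ft$I_mA, mu_r = ft$mu_r
    )
  })
}

#' Field of loop sources on a mesh surface
#'
#' Per-vertex superposition of all loop fields plus a uniform background
#' (e.g. the geomagnetic field, 25-65 µT).
#'
#' @param loops List of [loop3d()].
#' @param mesh A mesh from [make_head_mesh()] or [read_obj()].
#' @param background Uniform background field 3-vector, µT.
#' @param n_segments Loop discretization.
#' @return A `head_field_result`: list with `mesh`, `field` (N x 3 µT),
#'   `magnitude` (N µT), `background`, `loops`.
#' @export
field_on_mesh <- function(loops, mesh, background = c(0, 0, 0),
                          n_segments = 360) {
  stopifnot(inherits(mesh, "smf_mesh"))
  for (lp in loops) {
    d <- .wire_distance(lp, mesh$vertices)
    if (any(d < 1e-3)) {
      stop(sprintf(
        "mesh vertex %d lies within 1e-3 mm of a loop wire",
        which.min(d)
      ))
    }
  }
  fld <- .superpose_loops(loops, mesh$vertices, background, n_segments)
  structure(
    list(
      mesh = mesh, field = fld, magnitude = sqrt(rowSums(fld^2)),
      background = as.numeric(background), loops = loops
    ),
    class = "head_field_result"
  )
}

#' @export
print.head_field_result <- function(x, ...) {
  cat(sprintf(
    "head_field_result: %d vertices, |B| in [%.3g, %.3g] uT (background |%.3g| uT)\n",
    nrow(x$field), min(x$magnitude), max(x$magnitude),
    sqrt(sum(x$background^2))
  ))
  invisible(x)
}

#' Search for hypomagnetic (near-zero total field) zones
#'
#' With a uniform background opposing a loop's field there are points where
#' the two nearly cancel, leaving |B_total| close to zero. The search scans
#' a coarse grid over an axis-aligned box, then refines the best candidates
#' by coordinate descent with step halving down to 0.01 mm, and returns the
#' refined points whose total field magnitude is below `epsilon_uT`.
#'
#' @param loops List of [loop3d()].
#' @param background Background field 3-vector, µT; must be nonzero.
#' @param region List with `lower` and `upper` 3-vectors, mm.
#' @param resolution_mm Coarse scan spacing (default 2 mm).
#' @param epsilon_uT Acceptance magnitude (default 1 µT).
#' @param n_segments Loop discretization.
#' @param max_candidates Coarse minima refined at most.
#' @return Data frame `x_mm`, `y_mm`, `z_mm`, `Bmag_uT` (possibly 0 rows).
#' @export
find_hypomagnetic_zones <- function(loops, background, region,
                                    resolution_mm = 2, epsilon_uT = 1,
                                    n_segments = 360, max_candidates = 8L) {
  stopifnot(epsilon_uT > 0, sqrt(sum(background^2)) > 0)
  lo <- as.numeric(region$lower)
  hi <- as.numeric(region$upper)
  stopifnot(length(lo) == 3L, length(hi) == 3L)
  if (any(hi <= lo)) stop("empty region: upper must exceed lower on every axis")
  axes <- lapply(1:3, function(k) seq(lo[k], hi[k], by = resolution_mm))
  grid <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  total <- .superpose_loops(loops, grid, background, n_segments)
  mag <- sqrt(rowSums(total^2))

  magnitude_at <- function(p) {
    b <- .superpose_loops(loops, matrix(p, nrow = 1L), background, n_segments)
    sqrt(sum(b^2))
  }
  refine <- function(p) {
    step <- resolution_mm
    f <- magnitude_at(p)
    while (step > 0.01) {
      improved <- FALSE
      for (k in 1:3) {
        for (s in c(-1, 1)) {
          q <- p
          q[k] <- min(max(q[k] + s * step, lo[k]), hi[k])
          fq <- magnitude_at(q)
          if (fq < f) {
            p <- q
            f <- fq
            improved <- TRUE
          }
        }
      }
      if (!improved) step <- step / 2
    }
    list(p = p, f = f)
  }

  # pick well-separated low-magnitude candidates
  ord <- order(mag)
  cand <- list()
  for (i in ord) {
    if (length(cand) >= max_candidates) break
    if (mag[i] > 10 * epsilon_uT + min(mag)) break
    p <- grid[i, ]
    sep <- all(vapply(
      cand,
      function(c0) sqrt(sum((c0 - p)^2)) > 2 * resolution_mm, logical(1)
    ))
    if (sep) cand[[length(cand) + 1L]] <- p
  }
  out <- do.call(rbind, lapply(cand, function(p) {
    r <- refine(p)
    c(r$p, r$f)
  }))
  if (is.null(out)) {
    return(data.frame(
      x_mm = numeric(0), y_mm = numeric(0),
      z_mm = numeric(0), Bmag_uT = numeric(0)
    ))
  }
  out <- as.data.frame(out)
  names(out) <- c("x_mm", "y_mm", "z_mm", "Bmag_uT")
  out <- out[out$Bmag_uT < epsilon_uT, , drop = FALSE]
  # collapse refined candidates that converged to the same zone
  if (nrow(out) > 1L) {
    out <- out[order(out$Bmag_uT), , drop = FALSE]
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      p <- as.numeric(out[i, 1:3])
      dup <- FALSE
      for (j in which(keep)) {
        if (sqrt(sum((p - as.numeric(out[j, 1:3]))^2)) < resolution_mm) {
          dup <- TRUE
          break
        }
      }
      keep[i] <- !dup
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
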