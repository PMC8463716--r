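# Triangulated surface meshes: icosphere-based ellipsoid head fixture and a
# minimal OBJ (v/f records) reader/writer. The ellipsoid stands in for a
# scanned head model; it is watertight with outward-oriented faces and
# analytic outward vertex normals.

#' Triangle mesh container
#'
#' @param vertices N x 3 numeric matrix, mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param normals Optional N x 3 outward unit vertex normals.
#' @return An `smf_mesh` object.
#' @export
smf_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(all(dim(normals) == dim(vertices)))
  }
  structure(
    list(vertices = vertices, faces = faces, normals = normals),
    class = "smf_mesh"
  )
}

#' @export
print.smf_mesh <- function(x, ...) {
  cat(sprintf(
    "smf_mesh: %d vertices, %d faces\n",
    nrow(x$vertices), nrow(x$faces)
  ))
  invisible(x)
}

# unit icosahedron with outward-wound faces
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(v = v, f = f)
}

# one midpoint-subdivision step on the unit sphere, deduplicating edge midpoints
.subdivide_sphere <- function(v, f) {
  cache <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j), sep = "_")
    idx <- cache[[key]]
    if (!is.null(idx)) {
      return(idx)
    }
    m <- (verts[[i]] + verts[[j]]) / 2
    m <- m / sqrt(sum(m^2))
    verts[[length(verts) + 1L]] <<- m
    idx <- length(verts)
    cache[[key]] <- idx
    idx
  }
  new_f <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]
    b <- f[k, 2]
    c3 <- f[k, 3]
    ab <- midpoint(a, b)
    bc <- midpoint(b, c3)
    ca <- midpoint(c3, a)
    new_f[4L * k - 3L, ] <- c(a, ab, ca)
    new_f[4L * k - 2L, ] <- c(b, bc, ab)
    new_f[4L * k - 1L, ] <- c(c3, ca, bc)
    new_f[4L * k, ] <- c(ab, bc, ca)
  }
  list(v = do.call(rbind, verts), f = new_f)
}

#' Ellipsoidal head-surface fixture mesh
#'
#' Icosphere (20 * 4^k faces) scaled to semi-axes (a, b, c): a watertight
#' triangulated ellipsoid with outward analytic normals. Used as a stand-in
#' head surface for the 3D dosimetry stage.
#'
#' @param a_mm,b_mm,c_mm Semi-axes, mm (x, y, z).
#' @param n_subdivisions Subdivision depth k (>= 0, default 3: 1280 faces,
#'   642 vertices).
#' @return An [smf_mesh()].
#' @export
make_head_mesh <- function(a_mm = 100, b_mm = 120, c_mm = 90, n_subdivisions = 3) {
  stopifnot(a_mm > 0, b_mm > 0, c_mm > 0)
  if (n_subdivisions < 0) stop("n_subdivisions must be non-negative")
  ico <- .icosahedron()
  for (k in seq_len(n_subdivisions)) {
    ico <- .subdivide_sphere(ico$v, ico$f)
  }
  v <- sweep(ico$v, 2L, c(a_mm, b_mm, c_mm), `*`)
  # outward ellipsoid normal: grad of (x/a)^2 + (y/b)^2 + (z/c)^2
  n <- sweep(ico$v, 2L, c(1 / a_mm, 1 / b_mm, 1 / c_mm), `*`)
  n <- n / sqrt(rowSums(n^2))
  smf_mesh(v, ico$f, normals = n)
}

#' Write a mesh as OBJ (v/f records only)
#'
#' @param mesh An [smf_mesh()].
#' @param path Output path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "smf_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "v %.9g %.9g %.9g",
    mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]
  ), con)
  writeLines(sprintf(
    "f %d %d %d",
    mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]
  ), con)
  invisible(path)
}

#' Read an OBJ polygon file (v/f records; triangles only)
#'
#' @param path OBJ file path.
#' @return An [smf_mesh()] (no normals).
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl)) stop("no vertex records in OBJ file")
  v <- do.call(rbind, lapply(strsplit(sub("^v +", "", vl), "[[:space:]]+"), function(p) {
    as.numeric(p[1:3])
  }))
  f <- do.call(rbind, lapply(strsplit(sub("^f +", "", fl), "[[:space:]]+"), function(p) {
    if (length(p) != 3L) stop("only triangular faces are supported")
    as.integer(sub("/.*$", "", p))
  }))
  smf_mesh(v, f)
}
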