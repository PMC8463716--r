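# Biot-Savart loop engine: oracle equivalence with the closed form,
# symmetries, superposition, loop placement.

test_that("numeric on-axis field matches the closed form", {
  lp <- loop3d(c(0, 0, 0), c(0, 0, 1), 8, 17.2, 5000)
  for (h in c(5, 19.2, 40, 100)) {
    closed <- slc_field(h - 4.2, 8, 17.2, 8.4) # z + T/2 = h with T = 8.4
    b360 <- loop_field_at_point(lp, c(0, 0, h), 360)
    b3600 <- loop_field_at_point(lp, c(0, 0, h), 3600)
    expect_equal(b360[3], closed, tolerance = 1e-3)
    expect_equal(b3600[3], closed, tolerance = 1e-5)
    expect_equal(b360[1:2], c(0, 0), tolerance = 1e-12)
  }
})

test_that("off-axis evaluations converge as segments increase", {
  lp <- loop3d(c(0, 0, 0), c(0, 0, 1), 8, 17.2, 5000)
  p <- c(6, -3, 10)
  ref <- loop_field_at_point(lp, p, 5760)
  err <- function(ns) sqrt(sum((loop_field_at_point(lp, p, ns) - ref)^2)) /
    sqrt(sum(ref^2))
  expect_true(err(360) < 1e-3)
  expect_true(err(720) <= err(360) + 1e-15)
})

test_that("mirror symmetry across the loop plane", {
  lp <- loop3d(c(0, 0, 0), c(0, 0, 1), 8, 17.2, 5000)
  up <- loop_field_at_point(lp, c(5, 2, 12))
  dn <- loop_field_at_point(lp, c(5, 2, -12))
  expect_equal(up[3], dn[3], tolerance = 1e-12) # axial component even
  expect_equal(up[1:2], -dn[1:2], tolerance = 1e-10) # transverse odd
})

test_that("field is linear in current and superposes over loops", {
  lp1 <- loop3d(c(0, 70, -4.2), c(0, 0, 1), 8, 17.2, 5000)
  lp2 <- loop3d(c(0, -60, -4.2), c(0, 0, 1), 10, 22.6, 5000)
  lp1x2 <- loop3d(c(0, 70, -4.2), c(0, 0, 1), 8, 34.4, 5000)
  pts <- rbind(c(0, 70, 15), c(0, -60, 15), c(30, 0, 25))
  expect_equal(
    loop_field_at_points(lp1x2, pts),
    2 * loop_field_at_points(lp1, pts)
  )
  both <- loop_field_at_points(lp1, pts) + loop_field_at_points(lp2, pts)
  mesh <- smf_mesh(pts, matrix(c(1L, 2L, 3L), 1))
  res <- field_on_mesh(list(lp1, lp2), mesh)
  expect_equal(unname(res$field), unname(both), tolerance = 1e-12)
})

test_that("far field matches a point dipole of moment mu_r I pi r^2", {
  r <- 8
  lp <- loop3d(c(0, 0, 0), c(0, 0, 1), r, 17.2, 5000)
  d <- 100 * r # mm
  m <- 5000 * 0.0172 * pi * (r * 1e-3)^2 # A m^2
  mu0 <- 4e-7 * pi
  on_axis <- mu0 * 2 * m / (4 * pi * (d * 1e-3)^3) * 1e6
  equator <- mu0 * m / (4 * pi * (d * 1e-3)^3) * 1e6
  expect_equal(loop_field_at_point(lp, c(0, 0, d))[3], on_axis, tolerance = 1e-3)
  expect_equal(loop_field_at_point(lp, c(d, 0, 0))[3], -equator, tolerance = 1e-3)
})

test_that("points on the wire raise a singularity error", {
  lp <- loop3d(c(0, 0, 0), c(0, 0, 1), 8, 17.2, 5000)
  expect_error(loop_field_at_point(lp, c(8, 0, 0)), "wire")
  expect_error(loop3d(c(0, 0, 0), c(0, 0, 0), 8, 1), "zero-length")
})

test_that("frame invariance: rigid rotation leaves magnitudes unchanged", {
  lp <- loop3d(c(3, -2, 5), c(0, 0, 1), 8, 17.2, 5000)
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- rot %*% matrix(c(1, 0, 0, 0, cos(0.4), sin(0.4), 0, -sin(0.4), cos(0.4)), 3, 3)
  pts <- rbind(c(10, 5, 20), c(-15, 8, 3), c(0, 0, 30))
  lp_r <- loop3d(as.numeric(rot %*% lp$center), as.numeric(rot %*% lp$axis), 8, 17.2, 5000)
  b <- loop_field_at_points(lp, pts)
  b_r <- loop_field_at_points(lp_r, t(rot %*% t(pts)))
  expect_equal(sqrt(rowSums(b^2)), sqrt(rowSums(b_r^2)), tolerance = 1e-9)
  # and the field vector itself co-rotates
  expect_equal(unname(b_r), unname(t(rot %*% t(b))), tolerance = 1e-9)
})

test_that("loops are placed at hot spots, depth T/2, carried by the pose", {
  geom <- phone_geometry(146.9, 70.9, 8.4, "M1")
  hs <- list(
    structure(list(label = "UPPER", x_mm = 0, y_mm = 70), class = "hotspot"),
    structure(list(label = "LOWER", x_mm = 0, y_mm = -60), class = "hotspot")
  )
  fits <- reference_slc_fits()[c("1_UPPER", "1_LOWER")]
  ident <- rigid_transform()
  loops <- place_loops_from_fits(ident, geom, hs, fits)
  expect_equal(loops[[1]]$center, c(0, 70, -4.2))
  expect_equal(loops[[2]]$center, c(0, -60, -4.2))
  expect_equal(loops[[1]]$axis, c(0, 0, 1))
  # pure translation moves centres, not axes
  tr <- rigid_transform(translation = c(10, -5, 30))
  lt <- place_loops_from_fits(tr, geom, hs, fits)
  expect_equal(lt[[1]]$center, c(10, 65, 25.8))
  expect_equal(lt[[1]]$axis, c(0, 0, 1))
  # 90 degree rotation about y sends the axis +z -> +x
  ry <- rigid_transform(matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3))
  lr <- place_loops_from_fits(ry, geom, hs, fits)
  expect_equal(lr[[1]]$axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(lr[[1]]$radius_mm, 8)
  expect_equal(lr[[1]]$current_mA, 17.2)
  # improper transforms are rejected
  expect_error(rigid_transform(diag(c(1, 1, -1))), "rigid")
})

test_that("uniform background passes through field_on_mesh untouched", {
  mesh <- make_head_mesh(100, 100, 100, 1)
  res <- field_on_mesh(list(), mesh, background = c(0, 0, 50))
  expect_true(all(abs(res$field[, 3] - 50) < 1e-12))
  expect_equal(res$magnitude, rep(50, nrow(mesh$vertices)))
})

test_that("antiparallel background creates an on-axis hypomagnetic zone", {
  # Model 1 UPPER loop buried at T/2; 50 µT background opposing its axis
  lp <- loop3d(c(0, 0, -4.2), c(0, 0, 1), 8, 17.2, 5000)
  zones <- find_hypomagnetic_zones(
    list(lp), c(0, 0, -50),
    region = list(lower = c(-10, -10, 20), upper = c(10, 10, 50))
  )
  expect_gte(nrow(zones), 1L)
  # independent oracle: invert the closed form for B = 50 µT
  z_star <- uniroot(function(z) slc_field(z, 8, 17.2, 8.4) - 50, c(20, 60))$root
  expect_equal(zones$z_mm[1], z_star, tolerance = 0.02)
  expect_equal(zones$x_mm[1], 0, tolerance = 0.1)
  expect_equal(zones$y_mm[1], 0, tolerance = 0.1)
  expect_lt(zones$Bmag_uT[1], 1)
})

test_that("dominating or parallel backgrounds yield no on-axis zone", {
  lp <- loop3d(c(0, 0, -4.2), c(0, 0, 1), 8, 17.2, 5000)
  none <- find_hypomagnetic_zones(
    list(lp), c(0, 0, -5000),
    region = list(lower = c(-10, -10, 20), upper = c(10, 10, 50))
  )
  expect_equal(nrow(none), 0L)
  par <- find_hypomagnetic_zones(
    list(lp), c(0, 0, 50),
    region = list(lower = c(-10, -10, 20), upper = c(10, 10, 50))
  )
  if (nrow(par) > 0) {
    expect_true(all(sqrt(par$x_mm^2 + par$y_mm^2) > 1))
  }
  expect_error(
    find_hypomagnetic_zones(list(lp), c(0, 0, 50),
      region = list(lower = c(0, 0, 0), upper = c(0, 0, 0))
    ),
    "empty region"
  )
})
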