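# Map processing: averaging, background subtraction, magnitudes, hot spots,
# decay-curve assembly.

make_map <- function(vals, z = 15, grid = grid_spec(20, 20, 10)) {
  field_map(grid, z, vals)
}

test_that("replicate averaging is component-wise, SD is on magnitudes", {
  g <- grid_spec(20, 20, 10) # 3 x 3 nodes
  n <- 9
  m1 <- make_map(matrix(rep(c(1, 0, 0), each = n), ncol = 3))
  m2 <- make_map(matrix(rep(c(0, 1, 0), each = n), ncol = 3))
  m3 <- make_map(matrix(rep(c(0, 0, 1), each = n), ncol = 3))
  avg <- average_replicates(list(m1, m2, m3))
  expect_equal(unname(avg$mean$values[1, ]), c(1, 1, 1) / 3)
  # every replicate has |B| = 1, so magnitude SD is zero despite vector spread
  expect_equal(avg$sd, rep(0, n))

  # hand-computed SD: magnitudes 10, 12, 14 -> sample SD 2
  ms <- lapply(c(10, 12, 14), function(b) {
    make_map(matrix(c(rep(b, n), rep(0, 2 * n)), ncol = 3))
  })
  expect_equal(average_replicates(ms)$sd, rep(2, n))

  # identical replicates: mean equals input, SD zero
  same <- average_replicates(list(m1, m1, m1))
  expect_equal(same$mean$values, m1$values)
  expect_equal(same$sd, rep(0, n))
})

test_that("averaging rejects mismatched grids or heights", {
  a <- make_map(matrix(0, 9, 3), z = 15)
  b <- make_map(matrix(0, 9, 3), z = 20)
  expect_error(average_replicates(list(a, b)), "nominal z")
  d <- field_map(grid_spec(40, 20, 10), 15, matrix(0, 15, 3))
  expect_error(average_replicates(list(a, d)), "grid")
  expect_error(average_replicates(list(a)), "length")
})

test_that("background subtraction is a vector difference preserving metadata", {
  geom <- phone_geometry(146.9, 70.9, 8.4, "M1")
  g <- grid_spec(20, 20, 10)
  map <- field_map(g, 15, matrix(rep(c(50, 0, 0), each = 9), ncol = 3), phone = geom)
  bg <- make_map(matrix(rep(c(20, 0, -45), each = 9), ncol = 3))
  out <- subtract_background(map, bg)
  expect_equal(unname(out$values[5, ]), c(30, 0, 45))
  expect_identical(out$phone$model_label, "M1")
  expect_equal(subtract_background(map, map)$values, matrix(0, 9, 3,
    dimnames = list(NULL, c("Bx_uT", "By_uT", "Bz_uT"))
  ))
})

test_that("magnitude is the Euclidean norm and rotation invariant", {
  m <- make_map(matrix(rep(c(3, 4, 0), each = 9), ncol = 3))
  expect_equal(magnitude(m)$values, rep(5, 9))
  expect_equal(magnitude(make_map(matrix(0, 9, 3)))$values, rep(0, 9))
  # fixed rotation of every vector leaves the magnitude map unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  set.seed(11)
  vals <- matrix(rnorm(27), ncol = 3)
  expect_equal(
    magnitude(make_map(vals %*% t(rot)))$values,
    magnitude(make_map(vals))$values
  )
})

test_that("vector-then-magnitude differs from magnitude-then-subtract", {
  # counter-example: |(50,0,0) - (20,0,-45)| != |(50,0,0)| - |(20,0,-45)|
  v <- c(50, 0, 0)
  b <- c(20, 0, -45)
  vec_first <- sqrt(sum((v - b)^2))
  mag_first <- sqrt(sum(v^2)) - sqrt(sum(b^2))
  expect_false(isTRUE(all.equal(vec_first, mag_first)))
  map <- make_map(matrix(rep(v, each = 9), ncol = 3))
  bg <- make_map(matrix(rep(b, each = 9), ncol = 3))
  expect_equal(magnitude(subtract_background(map, bg))$values[1], vec_first)
})

test_that("hot spots are found at the generating loop positions", {
  truth <- reference_truth(1) # loops at (0, 70) and (0, -60)
  st <- simulate_study(truth, z_list_mm = 15, n_replicates = 1, noise = noise_free())
  mg <- magnitude(st$maps[[1]])
  spots <- detect_hotspots(mg, min_prominence_uT = 1)
  expect_length(spots, 2L)
  labels <- vapply(spots, `[[`, character(1), "label")
  up <- spots[[which(labels == "UPPER")]]
  lo <- spots[[which(labels == "LOWER")]]
  expect_equal(c(up$x_mm, up$y_mm), c(0, 70))
  expect_equal(c(lo$x_mm, lo$y_mm), c(0, -60))
})

test_that("off-node loops are detected at the nearest grid node", {
  truth <- single_loop_truth(x_mm = 4, y_mm = 66) # between nodes
  st <- simulate_study(truth, z_list_mm = 15, n_replicates = 1, noise = noise_free())
  spots <- detect_hotspots(magnitude(st$maps[[1]]), min_prominence_uT = 1)
  expect_length(spots, 1L)
  expect_identical(spots[[1]]$label, "UPPER")
  expect_true(abs(spots[[1]]$x_mm - 4) <= 10 && abs(spots[[1]]$y_mm - 66) <= 10)
})

test_that("single-loop truths yield exactly one hot spot; uniform maps none", {
  st <- simulate_study(single_loop_truth(),
    z_list_mm = 15, n_replicates = 1,
    noise = noise_free()
  )
  spots <- detect_hotspots(magnitude(st$maps[[1]]), min_prominence_uT = 1)
  expect_length(spots, 1L)
  expect_identical(spots[[1]]$label, "UPPER")
  flat <- magnitude(field_map(grid_spec(), 15, matrix(5, 273, 3)))
  expect_length(detect_hotspots(flat, min_prominence_uT = 1), 0L)
})

test_that("decay curves read the fixed hot-spot node across heights", {
  truth <- single_loop_truth()
  st <- simulate_study(truth, noise = noise_free())
  mags <- study_magnitudes(st)
  spot <- detect_hotspots(mags[[1]], min_prominence_uT = 1)[[1]]
  curve <- extract_decay_curve(mags, spot, expected_z_mm = protocol_heights)
  expect_equal(nrow(curve), 5L)
  expect_true(all(diff(curve$z_mm) > 0))
  # endpoints match the closed form (the generator is the Biot-Savart loop)
  expect_equal(curve$B_uT[1], slc_field(15, 8, 17.2, 8.4), tolerance = 1e-6)
  expect_equal(curve$B_uT[5], slc_field(55, 8, 17.2, 8.4), tolerance = 1e-6)
  expect_error(
    extract_decay_curve(mags[1:3], spot, expected_z_mm = protocol_heights),
    "missing z levels.*30.*55"
  )
})
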