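# Synthetic measurement generator: forward-model fidelity, determinism,
# noise statistics, round-trip parameter recovery.

test_that("noiseless single-loop map reproduces the closed form on axis", {
  truth <- single_loop_truth() # r = 8 mm, I = 17.2 mA, T = 8.4 mm at (0, 70)
  m <- simulate_map(truth, 15, noise = noise_free())
  nodes <- grid_nodes(m$grid)
  i <- which(nodes$x_mm == 0 & nodes$y_mm == 70)
  onaxis <- unname(m$values[i, 3])
  expect_equal(onaxis, slc_field(15, 8, 17.2, 8.4), tolerance = 1e-9)
  expect_equal(unname(m$values[i, 1:2]), c(0, 0), tolerance = 1e-9)
})

test_that("zero-loop truths return exactly the background field", {
  geom <- phone_geometry(146.9, 70.9, 8.4, "M1")
  empty <- ground_truth_phone(geom, data.frame(
    label = character(0), x_mm = numeric(0), y_mm = numeric(0),
    r_mm = numeric(0), I_mA = numeric(0)
  ))
  m <- simulate_map(empty, 15, background = c(20, 0, -45), noise = noise_free())
  expect_true(all(abs(sweep(m$values, 2, c(20, 0, -45))) < 1e-12))
  expect_null(m$phone)
})

test_that("identical seeds and inputs give bit-identical datasets", {
  truth <- reference_truth(2)
  nm <- noise_model(seed = 99)
  s1 <- simulate_study(truth, noise = nm, background = c(20, 0, -45))
  s2 <- simulate_study(truth, noise = nm, background = c(20, 0, -45))
  expect_identical(
    lapply(s1$maps, `[[`, "values"),
    lapply(s2$maps, `[[`, "values")
  )
  expect_identical(
    lapply(s1$background_maps, `[[`, "values"),
    lapply(s2$background_maps, `[[`, "values")
  )
  s3 <- simulate_study(truth, noise = noise_model(seed = 100), background = c(20, 0, -45))
  expect_false(identical(s1$maps[[1]]$values, s3$maps[[1]]$values))
})

test_that("study layout matches the protocol", {
  st <- simulate_study(reference_truth(1), noise = noise_free())
  expect_length(st$maps, 15L) # 5 heights x 3 replicates
  expect_length(st$background_maps, 3L)
  expect_error(simulate_study(reference_truth(1), z_list_mm = numeric(0)), "empty")
  expect_error(simulate_study(reference_truth(1), n_replicates = 0), "at least 1")
  expect_error(
    simulate_map(reference_truth(1), -1, noise = noise_free()),
    "non-negative"
  )
})

test_that("replicate scatter converges to the sensor noise level", {
  # background-only maps isolate the per-reading noise (session biases are
  # constant, z jitter has no effect on a uniform field)
  geom <- phone_geometry(146.9, 70.9, 8.4, "M1")
  empty <- ground_truth_phone(geom, data.frame(
    label = character(0), x_mm = numeric(0), y_mm = numeric(0),
    r_mm = numeric(0), I_mA = numeric(0)
  ))
  nm <- noise_model(seed = 5)
  grid <- grid_spec(40, 40, 10) # 25 nodes are plenty for pooling
  maps <- lapply(1:1000, function(k) {
    simulate_map(empty, 15, grid,
      background = c(20, 0, -45), noise = nm,
      replicate_index = k
    )
  })
  comp <- sapply(maps, function(m) m$values[, 1])
  pooled_sd <- sqrt(mean(apply(comp, 1, var)))
  expect_equal(pooled_sd, nm$sensor_noise_rms_uT, tolerance = 0.1)
})

test_that("the full study round-trips single-loop parameters through the fit", {
  truth <- single_loop_truth()
  st <- simulate_study(truth, noise = noise_free())
  mags <- study_magnitudes(st)
  spot <- detect_hotspots(mags[[1]], min_prominence_uT = 1)[[1]]
  curve <- extract_decay_curve(mags, spot)
  fit <- fit_slc(curve, 8.4)
  expect_equal(fit$r_mm, 8, tolerance = 1e-4)
  expect_equal(fit$I_mA, 17.2, tolerance = 1e-4)
})

test_that("noise-model validation enforces stated ranges", {
  expect_error(noise_model(cal_scale_error = 0.06), "cal_scale_error")
  expect_error(noise_model(sensor_noise_rms_uT = -1), "sensor_noise")
  expect_error(
    ground_truth_phone(
      phone_geometry(146.9, 70.9, 8.4),
      data.frame(label = "UPPER", x_mm = 0, y_mm = 120, r_mm = 8, I_mA = 17)
    ),
    "footprint"
  )
})
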