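# Closed-form SLC model: field, gradient, threshold distances.

test_that("on-axis field matches independent hand evaluation and units", {
  # mu_r*mu0*I*r^2 / (2*((z+T/2)^2+r^2)^1.5) computed digit-by-digit in SI
  mu0 <- 4e-7 * pi
  num <- 5000 * mu0 * 0.0172 * 0.008^2
  den <- 2 * ((0.015 + 0.0042)^2 + 0.008^2)^1.5
  expect_equal(slc_field(15, 8, 17.2, 8.4), num / den * 1e6, tolerance = 1e-12)
  # scales linearly with current
  expect_equal(slc_field(10, 8, 34.4, 8.4), 2 * slc_field(10, 8, 17.2, 8.4))
  # mu_r and I enter only as a product
  expect_equal(
    slc_field(c(0, 15, 40), 8, 17.2, 8.4, mu_r = 5000),
    slc_field(c(0, 15, 40), 8, 17.2 * 5000, 8.4, mu_r = 1)
  )
})

test_that("far field approaches the on-axis dipole 1/z^3 law", {
  r <- 8
  z <- 100 * r
  dipole <- 5000 * (4e-7 * pi) * 0.0172 * (r * 1e-3)^2 / (2 * (z * 1e-3)^3) * 1e6
  expect_equal(slc_field(z - 8.4 / 2, r, 17.2, 8.4) / dipole, 1, tolerance = 1e-3)
})

test_that("analytic gradient equals central finite differences of the field", {
  h <- 1e-3
  for (i in seq_len(nrow(reference_fits()))) {
    ft <- reference_fits()[i, ]
    T_mm <- reference_hotspots()$T_mm[i]
    for (z in c(0, 5, 15, 40)) {
      fd <- (slc_field(z + h, ft$slc_r_mm, ft$slc_I_mA, T_mm) -
        slc_field(z - h, ft$slc_r_mm, ft$slc_I_mA, T_mm)) / (2 * h)
      expect_equal(slc_gradient(z, ft$slc_r_mm, ft$slc_I_mA, T_mm), fd,
        tolerance = 1e-6
      )
    }
  }
})

test_that("gradient vanishes at the loop plane and field decays monotonically", {
  expect_equal(slc_gradient(-8.4 / 2, 8, 17.2, 8.4), 0)
  z <- seq(0, 100, by = 0.5)
  for (f in reference_slc_fits()[c("1_UPPER", "4_LOWER")]) {
    b <- slc_field(z, f$r_mm, f$I_mA, f$T_mm)
    expect_true(all(b > 0))
    expect_true(all(diff(b) < 0))
    # |dB/dz| strictly decreasing where T/2 covers the r/2 inflection
    zg <- seq(max(0, f$r_mm / 2 - f$T_mm / 2), 100, by = 0.5)
    g <- abs(slc_gradient(zg, f$r_mm, f$I_mA, f$T_mm))
    expect_true(all(diff(g) < 0))
  }
})

test_that("screen field B@0 decreases with thickness, increases with current", {
  b0 <- function(T_mm, I_mA = 17.2) slc_field(0, 8, I_mA, T_mm)
  expect_true(all(diff(sapply(c(6, 8, 10, 12), b0)) < 0))
  expect_equal(b0(8.4, 34.4), 2 * b0(8.4, 17.2))
})

test_that("field evaluation is rejected below the loop plane", {
  expect_error(slc_field(-5, 8, 17.2, 8.4), "loop plane")
  expect_error(slc_gradient(-5, 8, 17.2, 8.4), "loop plane")
})

test_that("threshold distance is the bisection root of the gradient magnitude", {
  f <- reference_slc_fits()[["3_UPPER"]]
  zstar <- threshold_distance(f, 0.02)
  expect_equal(abs(slc_gradient(zstar, f$r_mm, f$I_mA, f$T_mm)) / 1000, 0.02,
    tolerance = 1e-3
  )
  # uniqueness: gradient above threshold below the root, below it above
  expect_true(abs(slc_gradient(zstar - 1, f$r_mm, f$I_mA, f$T_mm)) / 1000 > 0.02)
  expect_true(abs(slc_gradient(zstar + 1, f$r_mm, f$I_mA, f$T_mm)) / 1000 < 0.02)
})

test_that("threshold distance handles degenerate thresholds", {
  f <- reference_slc_fits()[["1_UPPER"]]
  high <- threshold_distance(f, 10) # above the screen gradient
  expect_equal(as.numeric(high), 0)
  expect_true(attr(high, "below_threshold"))
  expect_error(threshold_distance(f, 0), "positive")
  expect_error(threshold_distance(f, 1e-9), "z_max")
})

test_that("induced-field rate estimate is peak field over motion duration", {
  expect_equal(induced_rate_estimate(1, 1), 1)
  expect_equal(induced_rate_estimate(1, 0.1), 10)
  b_max <- max(reference_fits()$B_at_0_mT)
  expect_true(induced_rate_estimate(b_max, 1) >= 1 &&
    induced_rate_estimate(b_max, 1) <= 10)
  expect_error(induced_rate_estimate(1, 0), "positive")
})
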