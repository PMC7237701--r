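test_that("polar conversion reproduces hand geometry and flags degeneracy", {
  dw <- dwell_point(c(0, 0, 0), c(0, 0, 1))
  cases <- list(
    list(p = c(10, 0, 0), r = 1, th = 90),
    list(p = c(0, 0, 10), r = 1, th = 0),
    list(p = c(0, 0, -10), r = 1, th = 180),
    list(p = c(10, 0, 10), r = sqrt(2), th = 45))
  for (cs in cases) {
    pc <- to_polar(dw, cs$p)
    expect_equal(pc$r_cm, cs$r, tolerance = 1e-12)
    expect_equal(pc$theta_deg, cs$th, tolerance = 1e-9)
  }
  expect_error(to_polar(dw, c(0, 0, 0)), "degenerate")

  # translation/orientation covariance of the polar map
  R <- rotation_matrix(c(1, 2, 3), 33)
  t <- c(4, -7, 2)
  dw2 <- dwell_point(as.vector(R %*% c(0, 0, 0)) + t,
                     as.vector(R %*% c(0, 0, 1)))
  pc2 <- to_polar(dw2, as.vector(R %*% c(10, 0, 10)) + t)
  expect_equal(pc2$r_cm, sqrt(2), tolerance = 1e-12)
  expect_equal(pc2$theta_deg, 45, tolerance = 1e-9)
})

test_that("line-source geometry factor matches closed forms and the
           line-integral oracle", {
  L <- 0.36
  expect_equal(geometry_factor_line(1, 90, L), 2 * atan(0.18) / 0.36,
               tolerance = 1e-12)
  expect_equal(geometry_factor_line(1, 0, L), 1 / (1 - 0.0324),
               tolerance = 1e-12)
  # point-source limit
  expect_equal(geometry_factor_line(2, 37, 1e-6), 0.25, tolerance = 1e-6)

  # brute-force inverse-square line integral, assorted geometries
  n <- 2e5
  s <- (seq_len(n) - 0.5) / n * L - L / 2
  for (r in c(0.36, 0.7, 1.5, 4)) for (th in c(3, 30, 90, 150, 178)) {
    z <- r * cos(th * pi / 180); y <- r * sin(th * pi / 180)
    G_num <- mean(1 / ((z - s)^2 + y^2))
    expect_equal(geometry_factor_line(r, th, L), G_num,
                 tolerance = 1e-4, label = paste("G at", r, th))
  }
  expect_error(geometry_factor_line(0.1, 0, L), "inside the active source")
})

test_that("point-source limit holds within 0.5% for r >= 10 L", {
  L <- 0.36
  for (r in seq(10 * L, 12, length.out = 7))
    for (th in seq(5, 175, by = 10))
      expect_lt(abs(geometry_factor_line(r, th, L) * r^2 - 1), 5e-3)
})

test_that("table interpolation: knot identity, midpoints, clamping", {
  src <- source_model("t", 0.36, 1.1,
                      data.frame(r_cm = c(1, 2), g = c(1, 0.9)),
                      list(r_cm = c(1, 2), theta_deg = c(80, 90),
                           F = matrix(c(0.96, 0.98, 1, 1), 2, 2)))
  expect_equal(radial_dose(src, 1), 1)
  expect_equal(radial_dose(src, 2), 0.9)
  expect_equal(radial_dose(src, 1.5), 0.95)                 # linear midpoint
  expect_warning(out <- radial_dose(src, 5), "clamped")
  expect_equal(out, 0.9)

  expect_equal(anisotropy(src, 1, 80), 0.96)                # knot identity
  expect_equal(anisotropy(src, 2, 90), 1)
  expect_equal(anisotropy(src, 1.5, 85), (0.96 + 0.98 + 1 + 1) / 4)
  expect_warning(anisotropy(src, 1, 10), "clamped")

  # constructor rejects broken tables
  expect_error(source_model("b", 0.36, 1.1,
                            data.frame(r_cm = c(2, 1), g = c(1, 1)),
                            src$anisotropy_table), "increasing")
  expect_error(source_model("b", 0.36, 1.1,
                            data.frame(r_cm = c(0.5, 2), g = c(2, 0.1)),
                            src$anisotropy_table), "g_L")
})

test_that("dose rate: reference identity, inverse square, rigid invariance", {
  toy <- toy_source()
  dw <- dwell_point(c(0, 0, 0), c(0, 0, 1), sk = 40700)
  expect_equal(dose_rate(toy, dw, c(10, 0, 0)),
               40700 * toy$dose_rate_constant, tolerance = 1e-13)

  tiny <- toy_source(active_length_cm = 1e-4)
  dw1 <- dwell_point(c(0, 0, 0), c(0, 0, 1), sk = 1)
  expect_equal(dose_rate(tiny, dw1, c(20, 0, 0)),
               tiny$dose_rate_constant / 4, tolerance = 1e-3)

  # joint rotation + translation leaves the dose rate unchanged
  real <- hdr_source_ir192()
  R <- rotation_matrix(c(2, -1, 1), 61)
  t <- c(11, -3, 8)
  p <- c(13, 4, -6)
  dwr <- dwell_point(as.vector(R %*% c(0, 0, 0)) + t,
                     as.vector(R %*% c(0, 0, 1)), sk = 40700)
  expect_equal(dose_rate(real, dwr, as.vector(R %*% p) + t),
               dose_rate(real, dw, p), tolerance = 1e-12)
})

test_that("realistic kernel agrees with the line-integral oracle", {
  src <- hdr_source_ir192()
  set.seed(42)
  for (i in 1:10) {
    r <- runif(1, 0.5, 8)
    th <- runif(1, 5, 175)
    p <- c(r * 10 * sin(th * pi / 180), 0, r * 10 * cos(th * pi / 180))
    dw <- dwell_point(c(0, 0, 0), c(0, 0, 1), sk = 40700)
    expect_equal(dose_rate(src, dw, p),
                 oracle_dose_rate(src, 40700, c(0, 0, 0), c(0, 0, 1), p),
                 tolerance = 1e-3)
  }
})

test_that("dose accumulation is linear and additive over dwells", {
  toy <- toy_source()
  dw <- function(t) dwell_point(c(0, 0, 0), c(0, 0, 1), time_s = t, sk = 40700)
  p <- c(10, 0, 0)
  expect_equal(accumulate_dose(toy, dw(3600), p),
               40700 * toy$dose_rate_constant, tolerance = 1e-13)
  expect_equal(accumulate_dose(toy, list(dw(100), dw(100)), p),
               2 * accumulate_dose(toy, dw(100), p), tolerance = 1e-13)
  expect_equal(accumulate_dose(toy, list(dw(200), dw(500)), p),
               2 * accumulate_dose(toy, list(dw(100), dw(250)), p),
               tolerance = 1e-13)
  expect_warning(z <- accumulate_dose(toy, list(), p), "empty")
  expect_identical(z, 0)
})
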