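one_dwell_plan <- function(time_s = 3600, sk = 40700) {
  dwells <- data.frame(channel = "ch1", applicator = "generic",
                       x = 0, y = 0, z = 0, time_s = time_s,
                       ux = 0, uy = 0, uz = 1, stringsAsFactors = FALSE)
  plan <- brachy_plan(dwells, air_kerma_strength = sk)
  plan$direction_method <- "manual"
  plan
}

test_that("grid voxel value at reference geometry equals S_K * Lambda", {
  toy <- toy_source()
  plan <- one_dwell_plan()
  g <- grid_spec(c(10, 0, 0), c(1, 1, 1), c(1, 1, 1))
  dv <- compute_dose_volume(plan, toy, g)
  expect_equal(as.vector(dv$values), 40700 * toy$dose_rate_constant,
               tolerance = 1e-13)
})

test_that("refining the grid never changes shared voxel-center values", {
  src <- hdr_source_ir192()
  plan <- one_dwell_plan()
  g1 <- grid_spec(c(10, -5, -5), c(1, 1, 1), c(5, 5, 5))
  g05 <- grid_spec(c(10, -5, -5), c(0.5, 0.5, 0.5), c(9, 9, 9))
  d1 <- suppressWarnings(compute_dose_volume(plan, src, g1))
  d05 <- suppressWarnings(compute_dose_volume(plan, src, g05))
  # voxel centers of g1 coincide with every other center of g05
  expect_equal(d05$values[seq(1, 9, 2), seq(1, 9, 2), seq(1, 9, 2)],
               d1$values, tolerance = 1e-12)
})

test_that("mirror-symmetric plan gives a mirror-symmetric dose volume", {
  toy <- toy_source()
  dwells <- data.frame(channel = "ch1", applicator = "generic",
                       x = c(-5, 5), y = 0, z = 0, time_s = 60,
                       ux = 1, uy = 0, uz = 0, stringsAsFactors = FALSE)
  plan <- brachy_plan(dwells, air_kerma_strength = 100)
  g <- grid_spec(c(-10, 2, -4), c(1, 1, 1), c(21, 9, 9))
  dv <- compute_dose_volume(plan, toy, g)
  expect_equal(dv$values, dv$values[21:1, , ], tolerance = 1e-12)
})

test_that("dose volume is linear in dwell times and in S_K", {
  src <- hdr_source_ir192()
  g <- grid_spec(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4))
  p1 <- one_dwell_plan(time_s = 100, sk = 1000)
  p2 <- one_dwell_plan(time_s = 200, sk = 1000)
  p3 <- one_dwell_plan(time_s = 100, sk = 3000)
  d1 <- suppressWarnings(compute_dose_volume(p1, src, g))
  d2 <- suppressWarnings(compute_dose_volume(p2, src, g))
  d3 <- suppressWarnings(compute_dose_volume(p3, src, g))
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  expect_equal(d3$values, 3 * d1$values, tolerance = 1e-12)
})

test_that("point doses equal an independently coded per-dwell summation", {
  src <- hdr_source_ir192()
  spec <- fixture_spec(seed = 11)
  plan <- assign_plan_directions(make_ring_plan(spec)$plan)
  pts <- data.frame(name = c("p1", "p2", "p3"),
                    x_mm = c(30, -20, 0), y_mm = c(10, 25, -40),
                    z_mm = c(20, 5, 15))
  got <- suppressWarnings(dose_at_points(plan, src, pts))
  dw <- plan$dwells
  for (j in 1:3) {
    want <- 0
    for (i in seq_len(nrow(dw)))
      want <- want + suppressWarnings(oracle_dose_rate(
        src, plan$air_kerma_strength,
        c(dw$x[i], dw$y[i], dw$z[i]), c(dw$ux[i], dw$uy[i], dw$uz[i]),
        c(pts$x_mm[j], pts$y_mm[j], pts$z_mm[j]), n = 2e4)) *
        dw$time_s[i] / 3600
    expect_equal(got$dose_cgy[j], want, tolerance = 1e-3)
  }
  # a one-voxel grid and the point evaluator agree exactly
  g <- grid_spec(c(30, 10, 20), c(1, 1, 1), c(1, 1, 1))
  dv <- suppressWarnings(compute_dose_volume(plan, src, g))
  expect_equal(as.vector(dv$values), got$dose_cgy[1], tolerance = 1e-12)
  # results come back in input order
  expect_identical(got$name, pts$name)
})

test_that("points inside a source capsule are rejected by name", {
  src <- hdr_source_ir192()
  plan <- one_dwell_plan()
  pts <- data.frame(name = "bad", x_mm = 0.5, y_mm = 0, z_mm = 0)
  expect_error(dose_at_points(plan, src, pts), "bad")
})

test_that("points A/B construction and its covariance", {
  cp_pos <- t(sapply(2 * pi * (0:7) / 8, function(p)
    c(15 * cos(p), 15 * sin(p), 0)))
  fit <- fit_ring(cp_pos)
  pts <- construct_points_ab(fit, tandem_axis = c(0, 0, 1),
                             lateral_axis = c(1, 0, 0))
  expect_equal(unlist(pts[pts$name == "A_right", c("x_mm", "y_mm", "z_mm")],
                      use.names = FALSE), c(20, 0, 20), tolerance = 1e-9)
  expect_equal(unlist(pts[pts$name == "A_left", c("x_mm", "y_mm", "z_mm")],
                      use.names = FALSE), c(-20, 0, 20), tolerance = 1e-9)
  expect_equal(unlist(pts[pts$name == "B_right", c("x_mm", "y_mm", "z_mm")],
                      use.names = FALSE), c(50, 0, 20), tolerance = 1e-9)

  R <- rotation_matrix(c(0, 1, 0), 25)
  fit_r <- fit_ring(t(apply(cp_pos, 1, function(p) as.vector(R %*% p))))
  pts_r <- construct_points_ab(fit_r, as.vector(R %*% c(0, 0, 1)),
                               as.vector(R %*% c(1, 0, 0)))
  for (nm in pts$name) {
    a <- unlist(pts[pts$name == nm, c("x_mm", "y_mm", "z_mm")],
                use.names = FALSE)
    b <- unlist(pts_r[pts_r$name == nm, c("x_mm", "y_mm", "z_mm")],
                use.names = FALSE)
    expect_equal(b, as.vector(R %*% a), tolerance = 1e-8)
  }
  expect_error(construct_points_ab(fit, tandem_axis = c(1, 0, 0)),
               "ring plane")
})

test_that("percentage difference follows the second-check convention", {
  expect_equal(percent_difference(4.67, 4.69), 100 * (4.67 - 4.69) / 4.69)
  expect_lt(percent_difference(4.67, 4.69), 0)   # lower second check -> negative
  expect_identical(percent_difference(3, 3), 0)
  expect_identical(percent_difference(6, 3), 100)
  expect_error(percent_difference(1, 0), "zero")
})
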