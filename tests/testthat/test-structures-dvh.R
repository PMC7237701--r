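square_roi <- function(side = 10, z = 0, name = "sq") {
  xy <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  list(name = name, role = "other", polygons = list(list(z = z, xy = xy)))
}

test_that("square phantom rasterization matches the exhaustive oracle", {
  roi <- square_roi(10)
  # 1 mm grid with centers at 0.5 .. 9.5 inside the square
  g1 <- grid_spec(c(-4.5, -4.5, 0), c(1, 1, 1), c(20, 20, 1))
  m1 <- rasterize(roi, g1)
  expect_equal(sum(m1), 100L)
  # 2.5 mm grid with centers at 1.25, 3.75, 6.25, 8.75
  g25 <- grid_spec(c(-8.75, -8.75, 0), c(2.5, 2.5, 2.5), c(8, 8, 1))
  m25 <- rasterize(roi, g25)
  expect_equal(sum(m25), 16L)
  # voxel-by-voxel agreement with an independent point-in-polygon oracle
  ctr <- expand.grid(x = -4.5 + 0:19, y = -4.5 + 0:19)
  xy <- roi$polygons[[1]]$xy
  want <- pracma::inpolygon(ctr$x, ctr$y,
                            c(xy[, 1], xy[1, 1]), c(xy[, 2], xy[1, 2]))
  expect_equal(as.vector(m1[, , 1]), as.vector(matrix(want, 20, 20)))
})

test_that("contours off the grid slices are skipped with a warning", {
  roi <- square_roi(10, z = 1.4)     # 1.4 mm from the only slice (dz = 1)
  g <- grid_spec(c(0, 0, 0), c(1, 1, 1), c(12, 12, 1))
  ws <- capture_warnings(m <- rasterize(roi, g))
  expect_match(ws, "skipped", all = FALSE)
  expect_match(ws, "empty mask", all = FALSE)
  expect_equal(sum(m), 0L)
})

test_that("applicator exclusion is plain set arithmetic", {
  dims <- c(5, 5, 4)
  target <- array(FALSE, dims); target[1:5, 1:4, 1] <- TRUE   # 20 voxels
  app <- array(FALSE, dims); app[1:5, 1, 1] <- TRUE           # 5 overlap
  out <- exclude_applicator(target, app)
  expect_equal(sum(out), 15L)
  none <- array(FALSE, dims)
  expect_equal(exclude_applicator(target, none), target)
  expect_equal(sum(exclude_applicator(target, target)), 0L)
  expect_error(exclude_applicator(target, array(FALSE, c(2, 2, 2))),
               "grids")
})

test_that("DVH metrics reproduce hand cases and scale equivariantly", {
  # 27 voxels of 1 cc each, doses 1..27 -> D2cc = 26
  g <- grid_spec(c(0, 0, 0), c(10, 10, 10), c(3, 3, 3))
  dv <- dose_volume(array(1:27, c(3, 3, 3)), g)
  mask <- array(TRUE, c(3, 3, 3))
  d <- cumulative_dvh(dv, mask, "cube")
  expect_equal(d$volume_cc, 27)
  expect_equal(dvh_metric(d, "D2cc"), 26)
  expect_equal(dvh_metric(d, "D100%"), 1)

  # uniform dose: D100% = D90% = D0.1cc = dose
  du <- cumulative_dvh(uniform_dose(150, c(4, 4, 4), c(5, 5, 5)),
                       array(TRUE, c(4, 4, 4)), "unif")
  expect_equal(dvh_metric(du, "D100%"), 150)
  expect_equal(dvh_metric(du, "D90%"), 150)
  expect_equal(dvh_metric(du, "D0.1cc"), 150)

  # D90% on 10 equal-volume voxels of doses 1..10: hottest 9 -> 2
  g10 <- grid_spec(c(0, 0, 0), c(10, 10, 10), c(10, 1, 1))
  d10 <- cumulative_dvh(dose_volume(array(1:10, c(10, 1, 1)), g10),
                        array(TRUE, c(10, 1, 1)), "ten")
  expect_equal(dvh_metric(d10, "D90%"), 2)

  # doubling the dose doubles every metric
  d2 <- cumulative_dvh(dose_volume(array(2 * (1:27), c(3, 3, 3)), g),
                       mask, "cube2")
  for (m in c("D100%", "D90%", "D2cc", "D0.1cc"))
    expect_equal(dvh_metric(d2, m), 2 * dvh_metric(d, m))

  expect_error(dvh_metric(d, "D50cc"), "insufficient volume")
  expect_error(cumulative_dvh(dv, array(FALSE, c(3, 3, 3)), "empty"),
               "empty")
})

test_that("DVH metrics equal the sort-based oracle on random fixtures", {
  set.seed(7)
  for (i in 1:12) {
    dims <- c(sample(3:6, 1), sample(3:6, 1), sample(2:4, 1))
    sp <- runif(3, 1, 6)
    vals <- array(runif(prod(dims), 0, 900), dims)
    mask <- array(runif(prod(dims)) < 0.7, dims)
    if (!any(mask)) mask[1] <- TRUE
    dv <- dose_volume(vals, grid_spec(c(0, 0, 0), sp, dims))
    d <- cumulative_dvh(dv, mask, "rand")
    vox <- prod(sp) / 1000
    for (m in c("D100%", "D90%", "D37.5%")) {
      expect_equal(dvh_metric(d, m),
                   oracle_dvh_metric(vals[mask], vox, m), tolerance = 1e-9)
    }
    x <- 0.8 * d$volume_cc
    sp_cc <- sprintf("D%.4gcc", x)
    expect_equal(dvh_metric(d, sp_cc),
                 oracle_dvh_metric(vals[mask], vox, sp_cc),
                 tolerance = 1e-9)
  }
})

test_that("DVH curve is monotone and exclusion obeys its inequalities", {
  set.seed(9)
  dims <- c(6, 6, 4)
  vals <- array(runif(prod(dims), 0, 700), dims)
  dv <- dose_volume(vals, grid_spec(c(0, 0, 0), c(2, 2, 2), dims))
  mask <- array(runif(prod(dims)) < 0.8, dims)
  app <- array(runif(prod(dims)) < 0.3, dims)
  mask[1] <- TRUE; app[1] <- FALSE
  d <- cumulative_dvh(dv, mask, "s")
  expect_true(all(diff(d$curve$volume_cc) <= 0))
  expect_equal(d$curve$volume_cc[1], d$volume_cc)
  expect_lte(dvh_metric(d, "D100%"), dvh_metric(d, "D90%"))

  excl <- exclude_applicator(mask, app)
  if (any(excl)) {
    de <- cumulative_dvh(dv, excl, "s_wo")
    expect_lte(de$volume_cc, d$volume_cc)
    expect_gte(dvh_metric(de, "D100%"), dvh_metric(d, "D100%"))
  }
})

test_that("plan criteria: limits, strictness, unevaluable structures", {
  metrics <- data.frame(structure = c("HR-CTV", "bladder", "rectum"),
                        metric = c("D90%", "D2cc", "D2cc"),
                        value_cgy = c(551, 324, 420))
  res <- check_plan_criteria(metrics)
  df <- as.data.frame(res)
  expect_true(df$pass[df$structure == "bladder"])
  expect_equal(df$margin_cgy[df$structure == "bladder"], 136)
  expect_false(df$pass[df$structure == "rectum"])     # 420 < 420 is FALSE
  expect_true(is.na(df$pass[df$structure == "sigmoid"]))
  expect_false(attr(res, "overall_pass"))

  metrics2 <- rbind(metrics,
                    data.frame(structure = "sigmoid", metric = "D2cc",
                               value_cgy = 300))
  metrics2$value_cgy[metrics2$structure == "rectum"] <- 419
  expect_true(attr(check_plan_criteria(metrics2), "overall_pass"))
})
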