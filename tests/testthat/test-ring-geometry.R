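circle_points <- function(n, radius = 15, center = c(0, 0, 10),
                          normal = c(0, 0, 1), phase = 0) {
  # right-handed basis, dwells counter-clockwise around the normal
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  phi <- phase + 2 * pi * (seq_len(n) - 1) / n
  pos <- t(sapply(phi, function(p) center + radius * (cos(p) * u + sin(p) * v)))
  tang <- t(sapply(phi, function(p) -sin(p) * u + cos(p) * v))
  list(pos = pos, tangent = tang, u = u, v = v)
}

test_that("candidate planes: coordinate triples, coplanarity, degeneracy", {
  tri <- candidate_planes(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)))
  expect_equal(nrow(tri), 1L)
  expect_equal(abs(tri[1, ]), c(0, 0, 1), tolerance = 1e-12)

  cp <- circle_points(8)
  cand <- candidate_planes(cp$pos)
  expect_equal(nrow(cand), choose(8, 3))
  expect_true(all(abs(abs(cand[, 3]) - 1) < 1e-9))

  # a collinear triple among valid points is skipped, the rest survive
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  cand2 <- candidate_planes(pts)
  expect_equal(nrow(cand2), choose(4, 3) - 1L)
  expect_error(candidate_planes(rbind(c(0, 0, 0), c(1, 0, 0))),
               "insufficient")
  expect_error(candidate_planes(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("ring fit recovers a noiseless circle exactly", {
  cp <- circle_points(8, radius = 15, center = c(0, 0, 10))
  fit <- fit_ring(cp$pos)
  expect_s3_class(fit, "ring_fit")
  expect_equal(abs(fit$plane_normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fit$center, c(0, 0, 10), tolerance = 1e-9)
  expect_equal(fit$radius, 15, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
})

test_that("RMSE selection prefers the true plane over a perturbed one", {
  cp <- circle_points(8, center = c(0, 0, 10))
  true_n <- c(0, 0, 1)
  tilted <- rotation_matrix(c(1, 0, 0), 5) %*% true_n
  fit <- fit_ring(cp$pos, candidates = rbind(true_n, as.vector(tilted)))
  expect_equal(abs(fit$plane_normal), c(0, 0, 1), tolerance = 1e-12)
})

test_that("noisy ring recovery stays within tight angular bounds", {
  errs_n <- c(); errs_t <- c()
  for (i in 1:30) {
    set.seed(100 + i)
    sigma <- c(0.05, 0.1, 0.2)[(i %% 3) + 1]
    cp <- circle_points(8, center = c(2, -1, 10))
    noisy <- cp$pos + matrix(rnorm(24, sd = sigma), ncol = 3)
    fit <- fit_ring(noisy)
    errs_n <- c(errs_n, min(angle_between_deg(fit$plane_normal, c(0, 0, 1)),
                            angle_between_deg(-fit$plane_normal, c(0, 0, 1))))
    dirs <- tangent_directions(fit, noisy)
    errs_t <- c(errs_t, mean(sapply(1:8, function(k)
      angle_between_deg(dirs[k, ], cp$tangent[k, ]))))
  }
  expect_lt(mean(errs_n), 1)
  expect_lt(mean(errs_t), 1)
})

test_that("tangent directions: cardinal cases, orthogonality, center error", {
  cp <- circle_points(8, radius = 15, center = c(0, 0, 10), phase = 0)
  fit <- fit_ring(cp$pos)
  dirs <- tangent_directions(fit, cp$pos)
  # dwell order is counter-clockwise; position (15,0,10) -> tangent (0,1,0)
  i_px <- which.min(rowSums(sweep(cp$pos, 2, c(15, 0, 10))^2))
  expect_equal(dirs[i_px, ], c(0, 1, 0), tolerance = 1e-9)
  i_py <- which.min(rowSums(sweep(cp$pos, 2, c(0, 15, 10))^2))
  expect_equal(dirs[i_py, ], c(-1, 0, 0), tolerance = 1e-9)
  for (k in 1:8) {
    expect_lt(abs(sum(dirs[k, ] * (cp$pos[k, ] - fit$center))), 1e-9)
    expect_lt(abs(sum(dirs[k, ] * fit$plane_normal)), 1e-9)
  }
  expect_error(tangent_directions(fit, matrix(fit$center, 1, 3)),
               "undefined tangent")
})

test_that("chained directions: straight channel, chord lag, minimal input", {
  line <- cbind(0, 0, seq(0, 35, by = 5))
  dirs <- chained_directions(line)
  expect_true(all(abs(sweep(dirs, 2, c(0, 0, 1))) < 1e-12))

  for (n in c(4, 8, 16, 36)) {
    cp <- circle_points(n)
    ch <- chained_directions(cp$pos)
    gaps <- sapply(seq_len(n), function(k)
      angle_between_deg(ch[k, ], cp$tangent[k, ]))
    expect_equal(gaps, rep(360 / n / 2, n), tolerance = 1e-9,
                 label = paste("chord-tangent gap, n =", n))
  }

  two <- rbind(c(0, 0, 0), c(3, 4, 0))
  d2 <- chained_directions(two)
  expect_equal(d2[1, ], c(0.6, 0.8, 0))
  expect_equal(d2[2, ], d2[1, ])
  expect_error(chained_directions(rbind(c(0, 0, 0), c(0, 0, 0))),
               "duplicate")
})

test_that("direction assignment dispatches on applicator type", {
  cp <- circle_points(8)
  ring <- assign_directions(cp$pos, "ring")
  expect_equal(ring$method, "tangent")
  expect_s3_class(ring$ring_fit, "ring_fit")
  expect_equal(ring$directions, cp$tangent, tolerance = 1e-9)

  line <- cbind(0, 0, seq(0, 30, by = 10))
  tan_ch <- assign_directions(line, "tandem")
  expect_equal(tan_ch$method, "chained")
  expect_true(all(abs(sweep(tan_ch$directions, 2, c(0, 0, 1))) < 1e-12))

  gen <- assign_directions(rbind(c(0, 0, 0), c(0, 10, 0)), "generic")
  expect_equal(gen$directions[1, ], c(0, 1, 0))
  expect_error(assign_directions(cp$pos, "helix"))
})

test_that("ring fit transforms covariantly under rigid motion", {
  cp <- circle_points(9, radius = 12, center = c(1, 2, 3))
  R <- rotation_matrix(c(1, 1, 0), 40)
  t <- c(-4, 6, 2)
  moved <- t(apply(cp$pos, 1, function(p) as.vector(R %*% p) + t))
  f1 <- fit_ring(cp$pos)
  f2 <- fit_ring(moved)
  expect_equal(f2$center, as.vector(R %*% f1$center) + t, tolerance = 1e-8)
  expect_equal(f2$radius, f1$radius, tolerance = 1e-9)
  n_moved <- as.vector(R %*% f1$plane_normal)
  expect_lt(min(angle_between_deg(f2$plane_normal, n_moved),
                angle_between_deg(-f2$plane_normal, n_moved)), 1e-6)
})
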