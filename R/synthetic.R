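#' Specification of the synthetic tandem-and-ring fixture
#'
#' Describes the deterministic virtual plan and phantom the generator
#' emulates: a ring channel of equally spaced dwells on a circle, a tandem
#' channel of collinear dwells along the ring axis, and ellipsoidal
#' HR-CTV / organ-at-risk contours around them in a water-equivalent
#' geometry. Defaults describe one fixed study condition (26/30-mm-class
#' ring, 20 s dwells, 10 Ci-class source, 5 x 5.5 Gy course) and are not
#' meant to be tuned per run.
#'
#' @param seed integer seed driving every random draw of the generator.
#' @param ring_radius_mm ring channel radius.
#' @param ring_n number of ring dwells (>= 3), equally spaced over the
#'   full circle.
#' @param ring_center length-3, mm.
#' @param ring_normal length-3, ring plane normal (phantom generation
#'   requires the axial orientation c(0,0,1)).
#' @param dwell_time_s dwell time applied to every dwell.
#' @param tandem_length_mm extent of the tandem dwell train.
#' @param tandem_n number of tandem dwells.
#' @param noise_sigma_mm Gaussian position noise applied per coordinate.
#' @param slice_spacing_mm contour slice spacing.
#' @param sk air-kerma strength, U.
#' @param fractions,dose_per_fraction_gy fractionation scheme.
#' @param source "toy" or "ir192" (the packaged synthetic Ir-192 tables).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, ring_radius_mm = 15, ring_n = 8L,
                         ring_center = c(0, 0, 0),
                         ring_normal = c(0, 0, 1),
                         dwell_time_s = 20,
                         tandem_length_mm = 40, tandem_n = 8L,
                         noise_sigma_mm = 0, slice_spacing_mm = 2.5,
                         sk = 40700, fractions = 5L,
                         dose_per_fraction_gy = 5.5,
                         source = c("ir192", "toy")) {
  source <- match.arg(source)
  if (ring_radius_mm <= 0) stop("ring radius must be positive")
  if (ring_n < 3L) stop("a ring channel needs at least 3 dwells")
  if (noise_sigma_mm < 0) stop("noise sigma must be >= 0")
  structure(list(seed = as.integer(seed), ring_radius_mm = ring_radius_mm,
                 ring_n = as.integer(ring_n),
                 ring_center = as.numeric(ring_center),
                 ring_normal = normalize3(as.numeric(ring_normal)),
                 dwell_time_s = dwell_time_s,
                 tandem_length_mm = tandem_length_mm,
                 tandem_n = as.integer(tandem_n),
                 noise_sigma_mm = noise_sigma_mm,
                 slice_spacing_mm = slice_spacing_mm, sk = sk,
                 fractions = as.integer(fractions),
                 dose_per_fraction_gy = dose_per_fraction_gy,
                 source = source),
            class = "fixture_spec")
}

# Right-handed in-plane basis (u, v) with n = u x v.
ring_basis <- function(n_hat) {
  b <- orthobasis(n_hat)
  u <- b$e1
  v <- cross3(n_hat, u)
  list(u = u, v = v)
}

#' Generate the synthetic tandem-and-ring plan
#'
#' Ring dwells are equally spaced over the full circle (counter-clockwise
#' around the ring normal); tandem dwells are collinear along the ring
#' axis starting 5 mm above the ring plane. Seeded Gaussian position
#' noise is applied per coordinate. The exact tangent directions of the
#' noiseless circle are returned as ground truth.
#'
#' @param spec a [fixture_spec()].
#' @return list with `plan` (a `brachy_plan`, directions unassigned),
#'   `truth` (list: `ring_directions`, `ring_positions_true`, `center`,
#'   `normal`, `radius`, `tandem_axis`).
#' @export
make_ring_plan <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  bas <- ring_basis(spec$ring_normal)
  phi <- 2 * pi * (seq_len(spec$ring_n) - 1L) / spec$ring_n
  ring_true <- t(vapply(phi, function(p)
    spec$ring_center + spec$ring_radius_mm *
      (cos(p) * bas$u + sin(p) * bas$v), numeric(3L)))
  ring_tangent <- t(vapply(phi, function(p)
    -sin(p) * bas$u + cos(p) * bas$v, numeric(3L)))
  ring_pos <- ring_true +
    matrix(stats::rnorm(3L * spec$ring_n, sd = spec$noise_sigma_mm),
           ncol = 3L)
  t_step <- if (spec$tandem_n > 1L)
    spec$tandem_length_mm / (spec$tandem_n - 1L) else 0
  tandem_pos <- t(vapply(seq_len(spec$tandem_n) - 1L, function(k)
    spec$ring_center + (5 + k * t_step) * spec$ring_normal, numeric(3L)))
  tandem_pos <- tandem_pos +
    matrix(stats::rnorm(3L * spec$tandem_n, sd = spec$noise_sigma_mm),
           ncol = 3L)
  dwells <- data.frame(
    channel = c(rep("ring", spec$ring_n), rep("tandem", spec$tandem_n)),
    applicator = c(rep("ring", spec$ring_n), rep("tandem", spec$tandem_n)),
    x = c(ring_pos[, 1L], tandem_pos[, 1L]),
    y = c(ring_pos[, 2L], tandem_pos[, 2L]),
    z = c(ring_pos[, 3L], tandem_pos[, 3L]),
    time_s = spec$dwell_time_s,
    stringsAsFactors = FALSE)
  plan <- brachy_plan(dwells, air_kerma_strength = spec$sk,
                      source_model_id = if (spec$source == "toy")
                        "toy_isotropic" else "ir192_hdr_synthetic",
                      fractions = spec$fractions,
                      dose_per_fraction_gy = spec$dose_per_fraction_gy,
                      frame_of_reference = "fixture")
  list(plan = plan,
       truth = list(ring_directions = ring_tangent,
                    ring_positions_true = ring_true,
                    center = spec$ring_center, normal = spec$ring_normal,
                    radius = spec$ring_radius_mm,
                    tandem_axis = spec$ring_normal))
}

# Closed polygon (m x 2) of an axis-aligned ellipse cross-section;
# vertices every `step_deg` degrees.
ellipse_polygon <- function(cx, cy, a, b, step_deg = 1) {
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  cbind(cx + a * cos(ang), cy + b * sin(ang))
}

# Slice polygons of an axis-aligned ellipsoid between its z-extent.
ellipsoid_polygons <- function(center, semi, z_grid, step_deg = 1) {
  out <- list()
  for (z in z_grid) {
    t <- (z - center[3L]) / semi[3L]
    if (abs(t) >= 1) next
    s <- sqrt(1 - t^2)
    out[[length(out) + 1L]] <-
      list(z = z, xy = ellipse_polygon(center[1L], center[2L],
                                       semi[1L] * s, semi[2L] * s,
                                       step_deg))
  }
  out
}

#' Generate the synthetic pelvis phantom
#'
#' Ellipsoidal HR-CTV enclosing the ring, offset ellipsoids for bladder,
#' rectum and sigmoid, and an applicator ROI built from a torus around the
#' ring circle plus a cylinder along the tandem. Contours are sampled at
#' 1 degree vertex spacing on slices aligned to the fixture slice spacing.
#' Requires the axial ring orientation (normal +z).
#'
#' @param spec a [fixture_spec()].
#' @return a `structure_set`.
#' @export
make_phantom <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (max(abs(spec$ring_normal - c(0, 0, 1))) > 1e-9)
    stop("make_phantom() supports the axial ring orientation ",
         "(ring_normal = c(0, 0, 1)) only")
  ctr <- spec$ring_center
  dz <- spec$slice_spacing_mm
  z_grid <- seq(ctr[3L] - 40, ctr[3L] + 75, by = dz)
  R <- spec$ring_radius_mm
  tube <- 3
  rois <- list(
    list(name = "HR-CTV", role = "HR-CTV",
         polygons = ellipsoid_polygons(ctr + c(0, 0, 10),
                                       c(25, 25, 30), z_grid)),
    list(name = "bladder", role = "bladder",
         polygons = ellipsoid_polygons(ctr + c(0, 35, 15),
                                       c(25, 20, 25), z_grid)),
    list(name = "rectum", role = "rectum",
         polygons = ellipsoid_polygons(ctr + c(0, -32, 5),
                                       c(15, 14, 30), z_grid)),
    list(name = "sigmoid", role = "sigmoid",
         polygons = ellipsoid_polygons(ctr + c(0, -25, 48),
                                       c(20, 15, 25), z_grid)))
  app <- list()
  for (z in z_grid) {
    t <- z - ctr[3L]
    if (abs(t) < tube) {                     # torus cross-section: annulus
      w <- sqrt(tube^2 - t^2)
      app[[length(app) + 1L]] <-
        list(z = z, xy = ellipse_polygon(ctr[1L], ctr[2L], R + w, R + w))
      if (R - w > 0.5)
        app[[length(app) + 1L]] <-
          list(z = z, xy = ellipse_polygon(ctr[1L], ctr[2L], R - w, R - w))
    }
    if (t >= 0 && t <= 5 + spec$tandem_length_mm + 5)  # tandem cylinder
      app[[length(app) + 1L]] <-
        list(z = z, xy = ellipse_polygon(ctr[1L], ctr[2L], tube, tube))
  }
  rois[[length(rois) + 1L]] <-
    list(name = "applicator", role = "applicator", polygons = app)
  structure_set(rois, slice_spacing_mm = dz, frame_of_reference = "fixture")
}

#' Perturbed comparison dose volumes
#'
#' Derives a comparison distribution from a computed dose volume for gamma
#' tests: `identical` copies it; `scaled` multiplies by `k`;
#' `shifted` translates the dose content by `shift_mm` (trilinear
#' resampling on the same grid, edge values clamped); `noisy` applies
#' seeded multiplicative Gaussian noise of `noise_pct` percent.
#'
#' @param dose a `dose_volume`.
#' @param mode one of "identical", "scaled", "shifted", "noisy".
#' @param k scale factor for `scaled`.
#' @param shift_mm length-3 translation for `shifted`.
#' @param noise_pct,seed noise level (%) and seed for `noisy`.
#' @return a `dose_volume` with the perturbation recorded in metadata.
#' @export
make_comparison_dose <- function(dose, mode = c("identical", "scaled",
                                                "shifted", "noisy"),
                                 k = 1.03, shift_mm = c(3, 0, 0),
                                 noise_pct = 1, seed = 1L) {
  stopifnot(inherits(dose, "dose_volume"))
  mode <- match.arg(mode)
  g <- dose$grid
  vals <- switch(mode,
    identical = dose$values,
    scaled = dose$values * k,
    shifted = {
      ctr <- grid_centers(g)
      rel <- sweep(ctr, 2L, as.numeric(shift_mm), `-`)
      rel <- sweep(rel, 2L, g$origin, `-`)
      for (a in 1:3)
        rel[, a] <- pmin(pmax(rel[, a], 0), (g$dims[a] - 1L) * g$spacing[a])
      array(interp_nd(dose$values, g$spacing, rel), g$dims)
    },
    noisy = {
      set.seed(seed)
      pmax(dose$values *
             (1 + noise_pct / 100 * stats::rnorm(length(dose$values))), 0)
    })
  md <- dose$metadata
  md$perturbation <- switch(mode,
    identical = "identical",
    scaled = paste0("scaled k=", k),
    shifted = paste0("shifted (", paste(shift_mm, collapse = ", "), ") mm"),
    noisy = paste0("noisy ", noise_pct, "% seed=", seed))
  dose_volume(array(vals, g$dims), g, md)
}
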