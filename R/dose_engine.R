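#' Dose-grid specification
#'
#' Describes a rectilinear calculation grid. The in-plane spacing is
#' selectable (the standard choices are 0.5, 1.0 and 2.5 mm, with 1.0 mm
#' the default workflow grid); the slice spacing normally follows the
#' structure set.
#'
#' @param origin length-3, mm: center of the first voxel.
#' @param spacing length-3, mm: (dx, dy, dz), all > 0.
#' @param dims length-3 integer: (nx, ny, nz), all >= 1.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(spacing <= 0)) stop("grid spacings must be positive")
  if (any(dims < 1L)) stop("grid must have at least one voxel per axis")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$dims, collapse = " x "), " voxels, spacing ",
      paste(x$spacing, collapse = " x "), " mm, origin (",
      paste(format(x$origin), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

# Voxel-center coordinate vectors along each axis.
grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$dims[a]) - 1L) * grid$spacing[a])
}

# All voxel centers as an N x 3 matrix, x fastest (matches array order).
grid_centers <- function(grid) {
  ax <- grid_axes(grid)
  nx <- grid$dims[1L]; ny <- grid$dims[2L]; nz <- grid$dims[3L]
  cbind(rep(ax[[1L]], times = ny * nz),
        rep(rep(ax[[2L]], each = nx), times = nz),
        rep(ax[[3L]], each = nx * ny))
}

#' 3D dose volume container
#'
#' @param values nx x ny x nz array, cGy per fraction, all finite >= 0.
#' @param grid a `grid_spec` with matching dims.
#' @param metadata named list (source model id, direction method, ...).
#' @return an object of class `dose_volume`.
#' @export
dose_volume <- function(values, grid, metadata = list()) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (!all(dim(values) == grid$dims))
    stop("values dims must match the grid dims")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  structure(list(values = values, grid = grid, metadata = metadata),
            class = "dose_volume")
}

#' @export
print.dose_volume <- function(x, ...) {
  units <- x$metadata$units %||% "cGy"
  cat("<dose_volume> ", paste(x$grid$dims, collapse = " x "),
      " voxels (", units, "), max ", format(max(x$values), digits = 5),
      ", spacing ", paste(x$grid$spacing, collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute the 3D dose volume for a plan
#'
#' Evaluates the TG-43 dwell-time superposition at every voxel center
#' (pure point sampling, no volume averaging). Voxels closer than half the
#' active length to a dwell center receive that dwell's transverse-axis
#' dose at r = L/2 (near-source cap); the number of capped voxels is
#' recorded in the metadata.
#'
#' @param plan a `brachy_plan` with directions assigned (see
#'   [assign_plan_directions()]).
#' @param source a `source_model`.
#' @param grid a `grid_spec`.
#' @return a `dose_volume`, cGy per fraction.
#' @export
compute_dose_volume <- function(plan, source, grid) {
  stopifnot(inherits(plan, "brachy_plan"), inherits(source, "source_model"),
            inherits(grid, "grid_spec"))
  dw <- plan$dwells
  if (nrow(dw) == 0L || all(dw$time_s <= 0))
    stop("plan has no dwell with positive time")
  if (any(is.na(dw$ux)))
    stop("dwell directions not assigned; run assign_plan_directions() first")
  pts <- grid_centers(grid)
  total <- numeric(nrow(pts))
  cap_r_cm <- source$active_length_cm / 2
  n_capped <- 0L
  for (i in seq_len(nrow(dw))) {
    if (dw$time_s[i] == 0) next
    d <- cbind(pts[, 1L] - dw$x[i], pts[, 2L] - dw$y[i], pts[, 3L] - dw$z[i])
    dist_cm <- sqrt(rowSums(d^2)) / 10
    capped <- dist_cm < cap_r_cm
    n_capped <- n_capped + sum(capped)
    dist_cm[capped] <- cap_r_cm
    ct <- (d[, 1L] * dw$ux[i] + d[, 2L] * dw$uy[i] + d[, 3L] * dw$uz[i]) /
      (dist_cm * 10)
    ct <- pmin(pmax(ct, -1), 1)
    theta <- acos(ct) * 180 / pi
    theta[capped] <- 90
    rate <- dose_rate_polar(source, plan$air_kerma_strength, dist_cm, theta)
    total <- total + rate * dw$time_s[i] / 3600
  }
  dose_volume(array(total, grid$dims), grid,
              metadata = list(source_model = source$name,
                              direction_method = plan$direction_method,
                              n_capped_voxel_contributions = n_capped,
                              units = "cGy"))
}

#' Exact point doses at absolute coordinates
#'
#' Evaluates the kernel at the given absolute positions (no grid
#' interpolation), as used for reference points A, B and the rectal point.
#'
#' @param plan a `brachy_plan` with directions assigned.
#' @param source a `source_model`.
#' @param points data.frame with columns `name`, `x_mm`, `y_mm`, `z_mm`.
#' @return the input data.frame with a `dose_cgy` column appended, in
#'   input order.
#' @export
dose_at_points <- function(plan, source, points) {
  stopifnot(inherits(plan, "brachy_plan"), is.data.frame(points),
            all(c("name", "x_mm", "y_mm", "z_mm") %in% names(points)))
  dw <- plan$dwells
  if (any(is.na(dw$ux)))
    stop("dwell directions not assigned; run assign_plan_directions() first")
  pts <- cbind(points$x_mm, points$y_mm, points$z_mm)
  cap_mm <- source$active_length_cm / 2 * 10
  total <- numeric(nrow(pts))
  for (i in seq_len(nrow(dw))) {
    d <- cbind(pts[, 1L] - dw$x[i], pts[, 2L] - dw$y[i], pts[, 3L] - dw$z[i])
    dist_mm <- sqrt(rowSums(d^2))
    if (any(dist_mm < cap_mm))
      stop("degenerate geometry: point '",
           points$name[which(dist_mm < cap_mm)[1L]],
           "' lies inside the source capsule of a dwell in channel '",
           dw$channel[i], "'")
    if (dw$time_s[i] == 0) next
    ct <- (d[, 1L] * dw$ux[i] + d[, 2L] * dw$uy[i] + d[, 3L] * dw$uz[i]) /
      dist_mm
    ct <- pmin(pmax(ct, -1), 1)
    rate <- dose_rate_polar(source, plan$air_kerma_strength, dist_mm / 10,
                            acos(ct) * 180 / pi)
    total <- total + rate * dw$time_s[i] / 3600
  }
  out <- points
  out$dose_cgy <- total
  out
}

#' Construct reference points A and B from the ring geometry
#'
#' Geometric convention for the classical cervix reference points: points
#' A lie 20 mm along the tandem axis from the ring center and +/- 20 mm
#' along the lateral in-plane axis; points B use +/- 50 mm laterally. The
#' lateral axis is the supplied reference direction orthogonalized against
#' the tandem axis. Verification against a planning system should use the
#' plan's own absolute coordinates; this construction is a convenience for
#' synthetic geometries.
#'
#' @param fit a `ring_fit`.
#' @param tandem_axis length-3 unit vector (source travel direction of the
#'   tandem); must not lie in the ring plane.
#' @param lateral_axis length-3 vector fixing the patient left-right
#'   direction; orthogonalized against `tandem_axis`.
#' @return data.frame with columns name, x_mm, y_mm, z_mm.
#' @export
construct_points_ab <- function(fit, tandem_axis, lateral_axis = c(1, 0, 0)) {
  stopifnot(inherits(fit, "ring_fit"))
  t_hat <- normalize3(as.numeric(tandem_axis))
  if (abs(sum(t_hat * fit$plane_normal)) < 1e-6)
    stop("geometry error: tandem axis lies in the ring plane; ",
         "the superior direction is undefined")
  lat <- as.numeric(lateral_axis)
  lat <- lat - sum(lat * t_hat) * t_hat
  if (sqrt(sum(lat^2)) < 1e-9)
    stop("geometry error: lateral axis is parallel to the tandem axis")
  lat <- normalize3(lat)
  ctr <- fit$center
  mk <- function(name, along, lateral) {
    p <- ctr + along * t_hat + lateral * lat
    data.frame(name = name, x_mm = p[1L], y_mm = p[2L], z_mm = p[3L],
               stringsAsFactors = FALSE)
  }
  rbind(mk("A_right", 20, 20), mk("A_left", 20, -20),
        mk("B_right", 20, 50), mk("B_left", 20, -50))
}

#' Percentage difference of a test dose against a reference
#'
#' 100 * (test - reference) / reference; negative when the second check
#' reads lower than the planning system.
#'
#' @param test test value(s) (the independent calculation).
#' @param reference reference value(s) (the planning system), nonzero.
#' @return percentage difference(s).
#' @export
percent_difference <- function(test, reference) {
  if (any(reference == 0))
    stop("undefined percentage difference: reference dose is zero")
  100 * (test - reference) / reference
}
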