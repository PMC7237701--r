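#' Configuration of a verification run
#'
#' Collects every physical choice of the second-check workflow so nothing
#' is silently defaulted: the chosen values are echoed in the report.
#'
#' @param source a `source_model` used for the recalculation.
#' @param grid_size_mm in-plane dose-grid size, mm; 0.5, 1.0 and 2.5 are
#'   the standard options (1.0 is the conventional default) but any
#'   positive value is accepted.
#' @param slice_spacing_mm grid slice spacing; NULL follows the structure
#'   set.
#' @param alpha_beta_map named vector of alpha/beta (Gy) per structure
#'   role.
#' @param criteria plan criteria table for [check_plan_criteria()].
#' @param gamma a [gamma_criteria()] used when a comparison dose is given.
#' @param reference_points optional data.frame (name, x_mm, y_mm, z_mm,
#'   optional tps_dose_cgy); when NULL, points A/B are constructed from
#'   the ring geometry.
#' @param grid_margin_mm margin added around the structure bounding box.
#' @return an object of class `verify_config`.
#' @export
verify_config <- function(source, grid_size_mm = 1.0,
                          slice_spacing_mm = NULL,
                          alpha_beta_map = c("HR-CTV" = 10, bladder = 3,
                                             rectum = 3, sigmoid = 3),
                          criteria = igabt_criteria(),
                          gamma = gamma_criteria(),
                          reference_points = NULL,
                          grid_margin_mm = 10) {
  stopifnot(inherits(source, "source_model"))
  if (grid_size_mm <= 0) stop("grid size must be positive")
  structure(list(source = source, grid_size_mm = grid_size_mm,
                 slice_spacing_mm = slice_spacing_mm,
                 alpha_beta_map = alpha_beta_map, criteria = criteria,
                 gamma = gamma, reference_points = reference_points,
                 grid_margin_mm = grid_margin_mm),
            class = "verify_config")
}

structures_bbox <- function(structures) {
  lo <- c(Inf, Inf, Inf); hi <- -lo
  for (roi in structures$rois) for (pg in roi$polygons) {
    lo <- pmin(lo, c(min(pg$xy[, 1L]), min(pg$xy[, 2L]), pg$z))
    hi <- pmax(hi, c(max(pg$xy[, 1L]), max(pg$xy[, 2L]), pg$z))
  }
  list(lo = lo, hi = hi)
}

#' Run the full second-check verification workflow
#'
#' Stages: frame-of-reference check, source-direction assignment (ring
#' tangent / chained), 3D dose grid, reference-point doses (with
#' percentage differences when planning-system values are supplied), DVH
#' metrics for every ROI -- the HR-CTV in both variants, with and without
#' the applicator volume -- EQD2 conversion, plan-criteria check, and
#' optionally a gamma comparison of the ring-axis plane against a
#' supplied planning-system dose volume. Stage progress and timings go to
#' standard error; the returned report is deterministic for fixed inputs.
#'
#' @param plan a `brachy_plan`.
#' @param structures a `structure_set` in the same frame of reference.
#' @param config a [verify_config()].
#' @param tps_dose optional `dose_volume` from the planning system, on the
#'   same grid the engine uses (or any grid for plane comparison).
#' @return an object of class `verification_report`.
#' @export
run_verification <- function(plan, structures, config, tps_dose = NULL) {
  stopifnot(inherits(plan, "brachy_plan"),
            inherits(structures, "structure_set"),
            inherits(config, "verify_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) message(sprintf("[verify %7.2fs] %s",
                                         proc.time()[["elapsed"]] - t0, msg))
  if (!identical(plan$frame_of_reference, structures$frame_of_reference))
    stop("frame-of-reference mismatch: plan '", plan$frame_of_reference,
         "' vs structures '", structures$frame_of_reference, "'")

  stage("assigning source directions")
  plan <- assign_plan_directions(plan)
  ring_fit <- if (length(plan$ring_fits)) plan$ring_fits[[1L]] else NULL

  stage("building dose grid")
  dz <- config$slice_spacing_mm %||% structures$slice_spacing_mm
  bb <- structures_bbox(structures)
  m <- config$grid_margin_mm
  gs <- config$grid_size_mm
  # Align grid slices to the contour slices so each contour maps exactly.
  zs <- sort(unique(unlist(lapply(structures$rois, function(r)
    vapply(r$polygons, `[[`, 0, "z")))))
  z0 <- min(zs)
  dims <- c(ceiling((bb$hi[1L] - bb$lo[1L] + 2 * m) / gs) + 1L,
            ceiling((bb$hi[2L] - bb$lo[2L] + 2 * m) / gs) + 1L,
            length(seq(z0, bb$hi[3L], by = dz)))
  grid <- grid_spec(c(bb$lo[1L] - m, bb$lo[2L] - m, z0),
                    c(gs, gs, dz), dims)

  stage(sprintf("computing dose volume (%d voxels, %d dwells)",
                prod(dims), nrow(plan$dwells)))
  dose <- compute_dose_volume(plan, config$source, grid)

  stage("reference-point doses")
  pts <- config$reference_points
  if (is.null(pts) && !is.null(ring_fit)) {
    tandem <- plan$dwells[plan$dwells$applicator == "tandem", ]
    tandem_axis <- if (nrow(tandem) >= 2L)
      normalize3(c(tandem$x[nrow(tandem)] - tandem$x[1L],
                   tandem$y[nrow(tandem)] - tandem$y[1L],
                   tandem$z[nrow(tandem)] - tandem$z[1L]))
      else ring_fit$plane_normal
    pts <- construct_points_ab(ring_fit, tandem_axis)
  }
  point_doses <- NULL
  if (!is.null(pts)) {
    point_doses <- dose_at_points(plan, config$source, pts)
    if (!is.null(pts$tps_dose_cgy))
      point_doses$pct_diff <- percent_difference(point_doses$dose_cgy,
                                                 pts$tps_dose_cgy)
  }

  stage("rasterizing structures and computing DVHs")
  app_mask <- NULL
  if (!is.null(structures$rois[["applicator"]]))
    app_mask <- rasterize(structures$rois[["applicator"]], grid)
  dvhs <- list()
  metrics <- data.frame(structure = character(0), metric = character(0),
                        value_cgy = numeric(0), stringsAsFactors = FALSE)
  for (roi in structures$rois) {
    if (roi$role == "applicator") next
    mask <- rasterize(roi, grid)
    if (!any(mask)) next
    if (roi$role == "HR-CTV" && !is.null(app_mask)) {
      dvhs[[paste0(roi$name, "_W")]] <-
        cumulative_dvh(dose, mask, roi$name, applicator_excluded = FALSE)
      dvhs[[paste0(roi$name, "_WO")]] <-
        cumulative_dvh(dose, exclude_applicator(mask, app_mask), roi$name,
                       applicator_excluded = TRUE)
      use <- dvhs[[paste0(roi$name, "_WO")]]
    } else {
      dvhs[[roi$name]] <- cumulative_dvh(dose, mask, roi$name)
      use <- dvhs[[roi$name]]
    }
    for (mm in names(use$metrics))
      if (!is.na(use$metrics[[mm]]))
        metrics <- rbind(metrics,
                         data.frame(structure = roi$name, metric = mm,
                                    value_cgy = use$metrics[[mm]],
                                    stringsAsFactors = FALSE))
  }

  stage("EQD2 conversion")
  n_frac <- plan$fractions
  eqd2_tab <- NULL
  if (nrow(metrics)) {
    ab <- config$alpha_beta_map[metrics$structure]
    ab[is.na(ab)] <- config$alpha_beta_map[["HR-CTV"]]
    per <- eqd2(metrics$value_cgy / 100, ab, n = 1)
    eqd2_tab <- data.frame(structure = metrics$structure,
                           metric = metrics$metric,
                           alpha_beta = as.numeric(ab),
                           per_fraction_gy = per,
                           total_gy = vapply(seq_along(per), function(i)
                             eqd2_total(rep(metrics$value_cgy[i] / 100,
                                            n_frac),
                                        ab[i])$total_gy, 0),
                           stringsAsFactors = FALSE)
  }

  stage("plan criteria check")
  crit <- check_plan_criteria(metrics, config$criteria)

  gamma_res <- NULL
  if (!is.null(tps_dose)) {
    stage("gamma comparison against supplied dose")
    if (!is.null(ring_fit)) {
      ref_plane <- extract_plane(tps_dose, ring_fit)
      ev_plane <- extract_plane(dose, ring_fit)
      gamma_res <- gamma_map(ref_plane, ev_plane, config$gamma)
    } else {
      gamma_res <- gamma_map(tps_dose, dose, config$gamma)
    }
  }
  stage("done")

  structure(list(
    config_echo = list(source_model = config$source$name,
                       grid_size_mm = config$grid_size_mm,
                       slice_spacing_mm = dz,
                       alpha_beta_map = config$alpha_beta_map,
                       gamma_criteria = unclass(config$gamma)),
    direction_method = plan$direction_method,
    ring_fit = ring_fit,
    grid = grid,
    dose = dose,
    point_doses = point_doses,
    dvhs = dvhs,
    metrics = metrics,
    eqd2 = eqd2_tab,
    criteria = crit,
    gamma = gamma_res),
    class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("== HDR second-check verification report ==\n")
  cat("source model: ", x$config_echo$source_model,
      "; grid ", x$config_echo$grid_size_mm, " x ",
      x$config_echo$grid_size_mm, " mm (slices ",
      x$config_echo$slice_spacing_mm, " mm)\n", sep = "")
  cat("direction methods: ", x$direction_method, "\n", sep = "")
  if (!is.null(x$ring_fit)) {
    cat("ring fit: radius ", format(x$ring_fit$radius, digits = 5),
        " mm, RMSE ", format(x$ring_fit$rmse, digits = 3), " mm\n",
        sep = "")
  }
  if (!is.null(x$point_doses)) {
    cat("\nreference-point doses (cGy):\n")
    print(x$point_doses, row.names = FALSE, digits = 5)
  }
  if (nrow(x$metrics)) {
    cat("\ndosimetric parameters (cGy):\n")
    print(x$metrics, row.names = FALSE, digits = 5)
  }
  if (!is.null(x$eqd2)) {
    cat("\nEQD2 (Gy):\n")
    print(x$eqd2, row.names = FALSE, digits = 4)
  }
  cat("\nplan criteria:\n")
  print(x$criteria)
  if (!is.null(x$gamma)) {
    cat("\ngamma comparison (ring-axis plane):\n")
    print(x$gamma)
  }
  invisible(x)
}

#' Write a verification report as structured text
#'
#' The body is deterministic for fixed inputs (no timestamps).
#'
#' @param report a `verification_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "verification_report"))
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(path)
}
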