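#' Structure set of planar contours
#'
#' Named regions of interest, each a stack of closed planar polygons
#' grouped by slice z. Vertices are in mm, patient coordinates; polygons
#' are stored open (the closing edge back to the first vertex is implied).
#' A slice may carry several polygons (e.g. the annular cross-section of a
#' ring applicator); membership uses the even-odd rule across all polygons
#' of the slice.
#'
#' @param rois list of ROI entries, each a list with `name`, `role` (one
#'   of HR-CTV, bladder, rectum, sigmoid, applicator, other) and
#'   `polygons`, a list of lists with `z` (mm) and `xy` (m x 2 vertex
#'   matrix, m >= 3).
#' @param slice_spacing_mm nominal contour slice spacing, mm.
#' @param frame_of_reference identifier shared with the plan.
#' @param validate check polygons are simple (no self-intersection).
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(rois, slice_spacing_mm = 2.5,
                          frame_of_reference = "default", validate = TRUE) {
  roles <- c("HR-CTV", "bladder", "rectum", "sigmoid", "applicator", "other")
  for (roi in rois) {
    if (!all(c("name", "role", "polygons") %in% names(roi)))
      stop("each ROI needs name, role and polygons")
    if (!roi$role %in% roles)
      stop("ROI '", roi$name, "': unknown role '", roi$role, "'")
    for (pg in roi$polygons) {
      if (!is.finite(pg$z)) stop("ROI '", roi$name, "': non-finite slice z")
      if (nrow(pg$xy) < 3L)
        stop("ROI '", roi$name, "', slice z=", pg$z,
             ": polygon needs at least 3 vertices")
      if (validate && !polygon_is_simple(pg$xy))
        stop("ROI '", roi$name, "', slice z=", pg$z,
             ": polygon is self-intersecting")
    }
  }
  names(rois) <- vapply(rois, `[[`, "", "name")
  structure(list(rois = rois, slice_spacing_mm = slice_spacing_mm,
                 frame_of_reference = frame_of_reference),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> ", length(x$rois), " ROI(s), slice spacing ",
      x$slice_spacing_mm, " mm\n", sep = "")
  for (roi in x$rois)
    cat("  ", roi$name, " [", roi$role, "]: ", length(roi$polygons),
        " polygon(s) over z in [",
        format(min(vapply(roi$polygons, `[[`, 0, "z"))), ", ",
        format(max(vapply(roi$polygons, `[[`, 0, "z"))), "] mm\n", sep = "")
  invisible(x)
}

# Simple-polygon test: no two non-adjacent edges intersect.
polygon_is_simple <- function(xy) {
  m <- nrow(xy)
  if (m < 4L) return(TRUE)
  x1 <- xy[, 1L]; y1 <- xy[, 2L]
  nx <- c(2:m, 1L)
  x2 <- x1[nx]; y2 <- y1[nx]
  idx <- which(outer(seq_len(m), seq_len(m),
                     function(i, j) j > i + 1L & !(i == 1L & j == m)),
               arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  d1 <- orient2(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
  d2 <- orient2(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- orient2(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
  d4 <- orient2(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

orient2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Even-odd point-in-polygon, vectorized over query points.
point_in_polygon_eo <- function(px, py, vx, vy) {
  m <- length(vx)
  inside <- logical(length(px))
  j <- m
  for (i in seq_len(m)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize an ROI onto a dose grid
#'
#' A voxel belongs to the structure iff its center lies inside the ROI's
#' polygon(s) on its slice (even-odd rule, no partial-volume weighting).
#' Each contour slice is matched to the nearest grid slice; contours whose
#' z mismatch exceeds half the grid slice spacing are skipped with a
#' warning.
#'
#' @param roi one ROI entry of a [structure_set()] (or its name plus the
#'   set via `structures`).
#' @param grid a `grid_spec`.
#' @param structures optional `structure_set` when `roi` is a name.
#' @return logical array with the grid's dims.
#' @export
rasterize <- function(roi, grid, structures = NULL) {
  if (is.character(roi)) {
    stopifnot(inherits(structures, "structure_set"))
    if (is.null(structures$rois[[roi]]))
      stop("no ROI named '", roi, "' in the structure set")
    roi <- structures$rois[[roi]]
  }
  stopifnot(inherits(grid, "grid_spec"))
  ax <- grid_axes(grid)
  nx <- grid$dims[1L]; ny <- grid$dims[2L]; nz <- grid$dims[3L]
  mask <- array(FALSE, grid$dims)
  px <- rep(ax[[1L]], times = ny)
  py <- rep(ax[[2L]], each = nx)
  dz <- grid$spacing[3L]
  n_used <- 0L
  for (pg in roi$polygons) {
    k <- which.min(abs(ax[[3L]] - pg$z))
    if (abs(ax[[3L]][k] - pg$z) > dz / 2 + 1e-9) {
      warning("ROI '", roi$name, "': contour at z=", pg$z,
              " mm is more than half a slice spacing from any grid ",
              "slice; skipped", call. = FALSE)
      next
    }
    n_used <- n_used + 1L
    inside <- point_in_polygon_eo(px, py, pg$xy[, 1L], pg$xy[, 2L])
    mask[, , k] <- xor(mask[, , k], matrix(inside, nx, ny))
  }
  if (n_used == 0L)
    warning("ROI '", roi$name,
            "' does not overlap the grid: empty mask", call. = FALSE)
  mask
}

#' Remove the applicator volume from a target mask
#'
#' Set difference target AND NOT applicator, as used to compute the
#' HR-CTV with and without the applicator volume.
#'
#' @param target_mask,applicator_mask logical arrays on the same grid.
#' @return logical array.
#' @export
exclude_applicator <- function(target_mask, applicator_mask) {
  if (!all(dim(target_mask) == dim(applicator_mask)))
    stop("masks are on different grids (dims differ)")
  target_mask & !applicator_mask
}
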