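#' Candidate ring-plane normals from dwell-position triples
#'
#' Every non-degenerate triple of dwell positions defines a plane; its unit
#' normal is a candidate orientation for the ring plane. All C(n,3) triples
#' are enumerated for n <= 12 positions; for larger n a deterministic
#' stride subsample of at most 220 triples is used. Normals are oriented
#' into a canonical hemisphere (first nonzero component positive).
#'
#' @param positions n x 3 matrix of dwell positions, mm.
#' @param area_tol triples whose triangle area (mm^2) falls below this are
#'   rejected as collinear.
#' @return matrix of unit normals (one row per accepted triple).
#' @export
candidate_planes <- function(positions, area_tol = 1e-6) {
  positions <- as_point_matrix(positions)
  n <- nrow(positions)
  if (n < 3L) stop("insufficient geometry: need at least 3 dwell positions")
  triples <- triple_index(n)
  normals <- matrix(NA_real_, nrow(triples), 3L)
  keep <- logical(nrow(triples))
  for (k in seq_len(nrow(triples))) {
    p1 <- positions[triples[k, 1L], ]
    p2 <- positions[triples[k, 2L], ]
    p3 <- positions[triples[k, 3L], ]
    cr <- cross3(p2 - p1, p3 - p1)
    area <- sqrt(sum(cr^2)) / 2
    if (area < area_tol) next
    keep[k] <- TRUE
    normals[k, ] <- canonical_hemisphere(cr / sqrt(sum(cr^2)))
  }
  if (!any(keep))
    stop("insufficient geometry: all dwell-position triples are collinear")
  normals[keep, , drop = FALSE]
}

# All index triples for n <= 12; else a deterministic stride subsample of
# about 220 triples (bounds cost on long channels).
triple_index <- function(n, max_triples = 220L) {
  all_triples <- t(utils::combn(n, 3L))
  if (n <= 12L || nrow(all_triples) <= max_triples) return(all_triples)
  stride <- ceiling(nrow(all_triples) / max_triples)
  all_triples[seq(1L, nrow(all_triples), by = stride), , drop = FALSE]
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

canonical_hemisphere <- function(v) {
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1L]] < 0) -v else v
}

normalize3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalize a zero vector")
  v / nv
}

#' Fit the ring plane and circle to dwell positions
#'
#' Step 1 of the tangent orientation method: among the candidate plane
#' normals, select the one minimizing the RMSE of point-to-plane distances
#' (plane offset chosen optimally for each candidate), then fit the circle
#' (center, radius) to the positions projected into that plane by linear
#' least squares.
#'
#' @param positions n x 3 matrix of dwell positions, mm.
#' @param candidates optional matrix of candidate unit normals; computed
#'   with [candidate_planes()] when omitted.
#' @return an object of class `ring_fit` with fields `plane_normal`,
#'   `center` (mm), `radius` (mm) and `rmse` (mm).
#' @export
fit_ring <- function(positions, candidates = NULL) {
  positions <- as_point_matrix(positions)
  if (is.null(candidates)) candidates <- candidate_planes(positions)
  candidates <- as_point_matrix(candidates)
  if (nrow(candidates) < 1L) stop("need at least one candidate plane")
  best <- NULL
  best_rmse <- Inf
  for (k in seq_len(nrow(candidates))) {
    nrm <- normalize3(candidates[k, ])
    proj <- as.vector(positions %*% nrm)
    res <- proj - mean(proj)
    rmse <- sqrt(mean(res^2))
    if (rmse < best_rmse) {
      best_rmse <- rmse
      best <- nrm
    }
  }
  # In-plane orthonormal basis for the winning plane.
  u <- orthobasis(best)
  offset <- mean(as.vector(positions %*% best))
  xy <- positions %*% cbind(u$e1, u$e2)
  circ <- fit_circle_2d(xy[, 1L], xy[, 2L])
  center <- circ$cx * u$e1 + circ$cy * u$e2 + offset * best
  structure(list(plane_normal = best, center = as.numeric(center),
                 radius = circ$radius, rmse = best_rmse,
                 n_positions = nrow(positions)),
            class = "ring_fit")
}

# Deterministic orthonormal basis of the plane orthogonal to unit n.
orthobasis <- function(n) {
  ref <- if (abs(n[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- normalize3(cross3(n, ref))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

# Kasa algebraic circle fit: x^2 + y^2 = 2 a x + 2 b y + c, linear LS.
fit_circle_2d <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  radius <- sqrt(sol[3L] + sol[1L]^2 + sol[2L]^2)
  list(cx = sol[1L], cy = sol[2L], radius = radius)
}

#' @export
print.ring_fit <- function(x, ...) {
  cat("<ring_fit> on", x$n_positions, "dwell positions\n")
  cat("  plane normal:", paste(format(x$plane_normal, digits = 6),
                               collapse = " "), "\n")
  cat("  center (mm): ", paste(format(x$center, digits = 6),
                               collapse = " "), "\n")
  cat("  radius (mm): ", format(x$radius, digits = 6), "\n")
  cat("  plane RMSE (mm):", format(x$rmse, digits = 4), "\n")
  invisible(x)
}

#' Tangent source directions on a fitted ring
#'
#' Step 2 of the tangent orientation method: each dwell's source direction
#' is the tangent of the fitted circle at that dwell,
#' normalize(plane_normal x (p - center)), with the sign chosen so that
#' the direction advances along the channel's dwell ordering (positive dot
#' product with the chord to the next dwell; to the previous dwell for the
#' last position).
#'
#' @param fit a `ring_fit`.
#' @param positions n x 3 matrix of dwell positions in delivery order, mm.
#' @return n x 3 matrix of unit direction vectors.
#' @export
tangent_directions <- function(fit, positions) {
  stopifnot(inherits(fit, "ring_fit"))
  positions <- as_point_matrix(positions)
  n <- nrow(positions)
  dirs <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    radial <- positions[i, ] - fit$center
    tang <- cross3(fit$plane_normal, radial)
    nt <- sqrt(sum(tang^2))
    if (nt < 1e-12)
      stop("undefined tangent: dwell ", i, " lies at the ring center")
    tang <- tang / nt
    chord <- if (i < n) positions[i + 1L, ] - positions[i, ]
             else positions[i, ] - positions[i - 1L, ]
    if (n > 1L && sum(tang * chord) < 0) tang <- -tang
    dirs[i, ] <- tang
  }
  dirs
}

#' Chained-chord source directions (baseline method)
#'
#' The baseline orientation used by earlier second-check systems: each
#' source direction is the chord from the dwell to the next dwell; the last
#' dwell reuses the previous direction. For dwells on a circle this chord
#' lags the true tangent by half the angular step.
#'
#' @param positions n x 3 matrix of ordered dwell positions, mm.
#' @return n x 3 matrix of unit direction vectors.
#' @export
chained_directions <- function(positions) {
  positions <- as_point_matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 positions for chained directions")
  dirs <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n - 1L)) {
    chord <- positions[i + 1L, ] - positions[i, ]
    len <- sqrt(sum(chord^2))
    if (len < 1e-12)
      stop("duplicate consecutive dwell positions at index ", i)
    dirs[i, ] <- chord / len
  }
  dirs[n, ] <- dirs[n - 1L, ]
  dirs
}

#' Assign source directions to a channel by applicator type
#'
#' Dispatches between the orientation methods: ring channels use the
#' circle-tangent method; tandem and generic channels use the chained
#' chords.
#'
#' @param positions n x 3 matrix of ordered dwell positions, mm.
#' @param applicator_type one of "ring", "tandem", "generic".
#' @return list with `directions` (n x 3 unit vectors), `method`, and
#'   `ring_fit` (NULL unless the tangent method ran).
#' @export
assign_directions <- function(positions,
                              applicator_type = c("ring", "tandem",
                                                  "generic")) {
  applicator_type <- match.arg(applicator_type)
  positions <- as_point_matrix(positions)
  if (applicator_type == "ring") {
    fit <- fit_ring(positions)
    list(directions = tangent_directions(fit, positions),
         method = "tangent", ring_fit = fit)
  } else {
    list(directions = chained_directions(positions),
         method = "chained", ring_fit = NULL)
  }
}
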