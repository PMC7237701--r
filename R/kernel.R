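#' A single dwell position of the stepping source
#'
#' Positions are in mm (DICOM patient coordinates), the direction is the
#' unit vector of the source long axis, dwell time is in seconds, and the
#' air-kerma strength S_K is in U (1 U = 1 cGy cm^2 h^-1).
#'
#' @param position numeric length-3, mm.
#' @param direction numeric length-3, unit norm (within 1e-9).
#' @param time_s dwell time, seconds, >= 0.
#' @param channel_id channel identifier.
#' @param sk air-kerma strength in U, > 0.
#' @return an object of class `dwell_point`.
#' @export
dwell_point <- function(position, direction, time_s = 0,
                        channel_id = "ch1", sk = 1) {
  position <- as.numeric(position); direction <- as.numeric(direction)
  stopifnot(length(position) == 3L, length(direction) == 3L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be a unit vector (||direction|| = 1 within 1e-9)")
  if (!is.numeric(time_s) || time_s < 0) stop("dwell time must be >= 0 s")
  if (!is.numeric(sk) || sk <= 0) stop("air-kerma strength S_K must be > 0")
  structure(list(position = position, direction = direction,
                 time_s = time_s, channel_id = channel_id, sk = sk),
            class = "dwell_point")
}

#' Polar coordinates of a point relative to a dwell
#'
#' Returns the TG-43 kernel coordinates: r, the distance from the active
#' source center to the point of interest (converted mm to cm), and theta,
#' the polar angle in degrees between the source long axis and the line to
#' the point.
#'
#' @param dwell a `dwell_point`.
#' @param point numeric length-3 (mm) or an n x 3 matrix of points.
#' @return list with numeric `r_cm` and `theta_deg` (each length n).
#' @export
to_polar <- function(dwell, point) {
  stopifnot(inherits(dwell, "dwell_point"))
  pts <- as_point_matrix(point)
  d <- sweep(pts, 2L, dwell$position)
  dist_mm <- sqrt(rowSums(d^2))
  if (any(dist_mm == 0))
    stop("degenerate geometry: point coincides with dwell '",
         dwell$channel_id, "' at (",
         paste(format(dwell$position), collapse = ", "), ") mm")
  ct <- as.vector(d %*% dwell$direction) / dist_mm
  ct <- pmin(pmax(ct, -1), 1)
  list(r_cm = dist_mm / 10, theta_deg = acos(ct) * 180 / pi)
}

as_point_matrix <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3L)
    point
  } else {
    stopifnot(length(point) == 3L)
    matrix(as.numeric(point), 1L, 3L)
  }
}

#' TG-43U1 line-source geometry factor G_L(r, theta)
#'
#' Off the source axis G_L = beta / (L r sin theta), where beta is the
#' angle (radians) subtended by the active line at the point. On axis
#' (sin theta below a small threshold) the closed form
#' G_L = (r^2 - L^2/4)^-1 is used; that branch requires r > L/2.
#'
#' @param r_cm distance(s) from source center, cm.
#' @param theta_deg polar angle(s), degrees in 0..180.
#' @param L_cm active length, cm.
#' @param axis_sin_tol sin(theta) threshold below which the on-axis closed
#'   form is used.
#' @return geometry factor(s), cm^-2.
#' @export
geometry_factor_line <- function(r_cm, theta_deg, L_cm,
                                 axis_sin_tol = 1e-6) {
  n <- max(length(r_cm), length(theta_deg))
  r <- rep_len(r_cm, n)
  th <- rep_len(theta_deg, n) * pi / 180
  if (any(r <= 0)) stop("r must be positive")
  s <- sin(th)
  z <- r * cos(th)
  y <- r * s
  on_axis <- s < axis_sin_tol
  out <- numeric(n)
  if (any(on_axis)) {
    ra <- r[on_axis]
    if (any(ra <= L_cm / 2))
      stop("point inside the active source: on-axis evaluation requires ",
           "r > L/2 = ", L_cm / 2, " cm")
    out[on_axis] <- 1 / (ra^2 - L_cm^2 / 4)
  }
  if (any(!on_axis)) {
    beta <- atan2(y[!on_axis], z[!on_axis] - L_cm / 2) -
      atan2(y[!on_axis], z[!on_axis] + L_cm / 2)
    out[!on_axis] <- beta / (L_cm * y[!on_axis])
  }
  out
}

#' TG-43U1 line-source dose rate at a point
#'
#' Evaluates S_K * Lambda * G_L(r,theta)/G_L(r0,theta0) * g_L(r) *
#' F(r,theta) with r0 = 1 cm, theta0 = 90 degrees.
#'
#' @param source a `source_model`.
#' @param dwell a `dwell_point` (its `sk` supplies S_K).
#' @param point length-3 mm vector or n x 3 matrix.
#' @return dose rate(s) in cGy/h.
#' @export
dose_rate <- function(source, dwell, point) {
  stopifnot(inherits(source, "source_model"))
  pc <- tryCatch(to_polar(dwell, point), error = function(e)
    stop("dwell '", dwell$channel_id, "': ", conditionMessage(e),
         call. = FALSE))
  dose_rate_polar(source, dwell$sk, pc$r_cm, pc$theta_deg)
}

# Kernel on precomputed polar coordinates (vectorized workhorse).
dose_rate_polar <- function(source, sk, r_cm, theta_deg) {
  L <- source$active_length_cm
  g_ref <- geometry_factor_line(source$reference_distance_cm,
                                source$reference_angle_deg, L)
  gl <- geometry_factor_line(r_cm, theta_deg, L)
  sk * source$dose_rate_constant * (gl / g_ref) *
    radial_dose(source, r_cm) * anisotropy(source, r_cm, theta_deg)
}

#' Accumulated dose from a set of dwells
#'
#' Superposes the dose-rate kernel over all dwells, weighting each by its
#' dwell time: dose = sum_i rate_i * time_i / 3600, in cGy.
#'
#' @param source a `source_model`.
#' @param dwells a list of `dwell_point`s (or a single one).
#' @param point length-3 mm vector or n x 3 matrix.
#' @return absorbed dose(s), cGy.
#' @export
accumulate_dose <- function(source, dwells, point) {
  if (inherits(dwells, "dwell_point")) dwells <- list(dwells)
  pts <- as_point_matrix(point)
  if (length(dwells) == 0L) {
    warning("empty dwell list: accumulated dose is 0 cGy", call. = FALSE)
    return(numeric(nrow(pts)))
  }
  total <- numeric(nrow(pts))
  for (dw in dwells) {
    if (dw$time_s == 0) next
    total <- total + dose_rate(source, dw, pts) * dw$time_s / 3600
  }
  total
}
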