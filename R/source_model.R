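#' Physical HDR source description
#'
#' A `source_model` bundles everything the TG-43U1 line-source formalism
#' needs about a sealed source: the active length L (cm), the dose-rate
#' constant Lambda (cGy h^-1 U^-1), the radial dose function g_L(r) on a
#' monotone radial grid, and the 2D anisotropy function F(r, theta) on an
#' r x theta grid. Both tables are normalized at the TG-43 reference
#' geometry: r0 = 1 cm on the transverse axis (theta0 = 90 degrees).
#'
#' @param name identifier for the model (echoed in reports).
#' @param active_length_cm active source length L in cm, > 0.
#' @param dose_rate_constant Lambda in cGy h^-1 U^-1, > 0.
#' @param radial_table data.frame with columns `r_cm` (strictly increasing)
#'   and `g` (dimensionless, > 0).
#' @param anisotropy_table list with elements `r_cm` (increasing vector),
#'   `theta_deg` (increasing vector covering 90 degrees within 0..180) and
#'   `F` (matrix, rows = radii, cols = angles, all > 0).
#' @return an object of class `source_model`.
#' @export
source_model <- function(name, active_length_cm, dose_rate_constant,
                         radial_table, anisotropy_table) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(active_length_cm) || length(active_length_cm) != 1L ||
      active_length_cm <= 0)
    stop("active_length_cm must be a single positive number")
  if (!is.numeric(dose_rate_constant) || dose_rate_constant <= 0)
    stop("dose_rate_constant must be positive")
  if (!all(c("r_cm", "g") %in% names(radial_table)))
    stop("radial_table needs columns r_cm and g")
  r <- radial_table$r_cm
  g <- radial_table$g
  if (any(diff(r) <= 0)) stop("radial grid must be strictly increasing")
  if (any(g <= 0)) stop("g_L values must be positive")
  if (r[1] <= 1 && r[length(r)] >= 1) {
    g1 <- stats::approx(r, g, xout = 1)$y
    if (abs(g1 - 1) > 0.01)
      stop("g_L(r0 = 1 cm) must equal 1 within table round-off (got ",
           format(g1), ")")
  }
  at <- anisotropy_table
  if (!all(c("r_cm", "theta_deg", "F") %in% names(at)))
    stop("anisotropy_table needs r_cm, theta_deg and F")
  if (any(diff(at$r_cm) <= 0) || any(diff(at$theta_deg) <= 0))
    stop("anisotropy grids must be strictly increasing")
  if (min(at$theta_deg) > 90 || max(at$theta_deg) < 90)
    stop("anisotropy theta grid must cover the 90 degree reference angle")
  if (!is.matrix(at$F) ||
      nrow(at$F) != length(at$r_cm) || ncol(at$F) != length(at$theta_deg))
    stop("F must be a length(r_cm) x length(theta_deg) matrix")
  if (any(at$F <= 0)) stop("F values must be positive")
  F90 <- apply(at$F, 1L, function(row)
    stats::approx(at$theta_deg, row, xout = 90)$y)
  if (any(abs(F90 - 1) > 0.01))
    stop("F(r, theta0 = 90) must equal 1 within table round-off")

  structure(
    list(name = name,
         active_length_cm = active_length_cm,
         dose_rate_constant = dose_rate_constant,
         radial_table = data.frame(r_cm = r, g = g),
         anisotropy_table = list(r_cm = at$r_cm, theta_deg = at$theta_deg,
                                 F = at$F),
         reference_distance_cm = 1,
         reference_angle_deg = 90),
    class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat("<source_model> ", x$name, "\n", sep = "")
  cat("  active length L: ", x$active_length_cm, " cm\n", sep = "")
  cat("  dose-rate constant: ", x$dose_rate_constant, " cGy/h/U\n", sep = "")
  cat("  g_L(r) knots: ", nrow(x$radial_table), " over [",
      min(x$radial_table$r_cm), ", ", max(x$radial_table$r_cm), "] cm\n",
      sep = "")
  cat("  F(r,theta) grid: ", length(x$anisotropy_table$r_cm), " x ",
      length(x$anisotropy_table$theta_deg), "\n", sep = "")
  invisible(x)
}

#' Idealized isotropic test source
#'
#' A source with g_L identically 1 and F identically 1, used for analytic
#' identities (at the reference geometry its dose rate is exactly
#' S_K * Lambda).
#'
#' @param active_length_cm active length, default 0.36 cm.
#' @param dose_rate_constant default 1.108 cGy h^-1 U^-1.
#' @return a `source_model`.
#' @export
toy_source <- function(active_length_cm = 0.36, dose_rate_constant = 1.108) {
  source_model(
    name = "toy_isotropic",
    active_length_cm = active_length_cm,
    dose_rate_constant = dose_rate_constant,
    radial_table = data.frame(r_cm = c(0.1, 20), g = c(1, 1)),
    anisotropy_table = list(r_cm = c(0.1, 20), theta_deg = c(0, 90, 180),
                            F = matrix(1, 2, 3)))
}

#' Packaged HDR Ir-192 stepping-source model (synthetic tables)
#'
#' Loads the packaged Ir-192 source description. The g_L(r) and F(r,theta)
#' tables are a synthetic stand-in representative of published HDR Ir-192
#' (mHDR-v2 class) consensus data; they are a fixture for exercising the
#' interpolating kernel, not vendor or consensus data, and must not be used
#' clinically.
#'
#' @return a `source_model`.
#' @export
hdr_source_ir192 <- function() {
  path <- system.file("extdata", "ir192_hdr_synthetic.src",
                      package = "hdrcheck", mustWork = TRUE)
  read_source_model(path)
}

#' Radial dose function g_L(r)
#'
#' Linear interpolation of the tabulated radial dose function. Radii
#' outside the table range are clamped to the nearest edge value and a
#' single warning is emitted for the call.
#'
#' @param source a `source_model`.
#' @param r_cm radial distance(s) in cm, > 0.
#' @return dimensionless g_L value(s).
#' @export
radial_dose <- function(source, r_cm) {
  stopifnot(inherits(source, "source_model"))
  if (any(r_cm <= 0)) stop("r_cm must be positive")
  tab <- source$radial_table
  out_of_range <- r_cm < tab$r_cm[1] | r_cm > tab$r_cm[nrow(tab)]
  if (any(out_of_range))
    warning(sum(out_of_range), " radius value(s) outside the g_L table [",
            tab$r_cm[1], ", ", tab$r_cm[nrow(tab)],
            "] cm; clamped to the table edge", call. = FALSE)
  stats::approx(tab$r_cm, tab$g, xout = r_cm, rule = 2)$y
}

#' Anisotropy function F(r, theta)
#'
#' Bilinear interpolation of the tabulated 2D anisotropy function.
#' Coordinates outside the table are clamped to the nearest edge (one
#' warning per call).
#'
#' @param source a `source_model`.
#' @param r_cm radial distance(s), cm.
#' @param theta_deg polar angle(s) in degrees, within 0..180.
#' @return dimensionless F value(s).
#' @export
anisotropy <- function(source, r_cm, theta_deg) {
  stopifnot(inherits(source, "source_model"))
  if (any(theta_deg < 0 | theta_deg > 180))
    stop("theta_deg must lie in [0, 180]")
  at <- source$anisotropy_table
  n <- max(length(r_cm), length(theta_deg))
  r <- rep_len(r_cm, n)
  th <- rep_len(theta_deg, n)
  out_of_range <- r < at$r_cm[1] | r > at$r_cm[length(at$r_cm)] |
    th < at$theta_deg[1] | th > at$theta_deg[length(at$theta_deg)]
  if (any(out_of_range))
    warning(sum(out_of_range),
            " point(s) outside the F(r,theta) table; clamped to the edge",
            call. = FALSE)
  bilinear_interp(at$r_cm, at$theta_deg, at$F, r, th)
}

# Clamped bilinear interpolation on a rectilinear grid; x/y are the grid
# vectors, z the nrow(x) x ncol(y) value matrix, xi/yi query vectors.
bilinear_interp <- function(x, y, z, xi, yi) {
  xi <- pmin(pmax(xi, x[1]), x[length(x)])
  yi <- pmin(pmax(yi, y[1]), y[length(y)])
  ix <- findInterval(xi, x, rightmost.closed = TRUE)
  iy <- findInterval(yi, y, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(x) - 1L)
  iy <- pmin(pmax(iy, 1L), length(y) - 1L)
  tx <- (xi - x[ix]) / (x[ix + 1L] - x[ix])
  ty <- (yi - y[iy]) / (y[iy + 1L] - y[iy])
  z00 <- z[cbind(ix, iy)]
  z10 <- z[cbind(ix + 1L, iy)]
  z01 <- z[cbind(ix, iy + 1L)]
  z11 <- z[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}
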