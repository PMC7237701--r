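#' Gamma-analysis acceptance criteria
#'
#' @param dose_tol_pct dose-difference tolerance as a percentage of the
#'   normalization dose (3 for the common 3%/3-mm criteria).
#' @param dta_mm distance-to-agreement, mm.
#' @param normalization "global-max" (maximum of the reference
#'   distribution) or an explicit dose value.
#' @param low_dose_threshold_pct reference points below this percentage of
#'   the normalization dose are not evaluated; 0 evaluates all points.
#' @return an object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol_pct = 3, dta_mm = 3,
                           normalization = "global-max",
                           low_dose_threshold_pct = 0) {
  if (dose_tol_pct <= 0 || dta_mm <= 0)
    stop("dose tolerance and DTA must be positive")
  if (low_dose_threshold_pct < 0 || low_dose_threshold_pct >= 100)
    stop("low-dose threshold must lie in [0, 100)")
  if (!(identical(normalization, "global-max") ||
        (is.numeric(normalization) && normalization > 0)))
    stop("normalization must be \"global-max\" or a positive dose")
  structure(list(dose_tol_pct = dose_tol_pct, dta_mm = dta_mm,
                 normalization = normalization,
                 low_dose_threshold_pct = low_dose_threshold_pct),
            class = "gamma_criteria")
}

# Pull (values, spacing) out of the supported dose containers.
gamma_input <- function(x, spacing = NULL) {
  if (inherits(x, "dose_volume"))
    list(values = x$values, spacing = x$grid$spacing, origin = x$grid$origin)
  else if (inherits(x, "dose_plane"))
    list(values = x$values, spacing = x$spacing, origin = c(x$u[1L], x$v[1L]))
  else if (is.array(x) || is.matrix(x)) {
    if (is.null(spacing))
      stop("plain arrays need an explicit `spacing` (mm per axis)")
    list(values = x, spacing = rep_len(spacing, length(dim(x))),
         origin = rep(0, length(dim(x))))
  } else stop("unsupported dose container for gamma analysis")
}

#' Gamma index map between two dose distributions
#'
#' For each evaluated reference point r the gamma index is the minimum
#' over nearby points e of the evaluated distribution of
#' sqrt(dist(e, r)^2 / dta^2 + (D_eval(e) - D_ref(r))^2 / (tol * Dnorm)^2).
#' The search is exhaustive over evaluated grid points within a radius of
#' 3 x DTA, followed (when `refine = TRUE`) by one level of 10x sub-grid
#' refinement with multilinear interpolation around the best coarse point.
#' Points with gamma <= 1 pass (the boundary passes).
#'
#' @param reference,evaluated `dose_volume`s, `dose_plane`s, or plain
#'   matrices/arrays on the same grid.
#' @param criteria a [gamma_criteria()].
#' @param spacing spacing (mm) when plain arrays are supplied.
#' @param refine logical; apply sub-grid refinement.
#' @param refine_basins number of best coarse candidates around which the
#'   sub-grid refinement is run for each reference point.
#' @return an object of class `gamma_result`: `gamma` (array, NA at
#'   unevaluated points), `pass_rate` (%), `n_evaluated`, `dnorm`,
#'   `criteria`.
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      spacing = NULL, refine = TRUE, refine_basins = 4L) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  ref <- gamma_input(reference, spacing)
  ev <- gamma_input(evaluated, spacing)
  if (!identical(dim(ref$values), dim(ev$values)) ||
      max(abs(ref$spacing - ev$spacing)) > 1e-9 ||
      max(abs(ref$origin - ev$origin)) > 1e-9)
    stop("geometry error: reference and evaluated grids differ")
  vals_r <- ref$values
  vals_e <- ev$values
  sp <- ref$spacing
  nd <- length(dim(vals_r))
  dta <- criteria$dta_mm
  dnorm <- if (identical(criteria$normalization, "global-max"))
    max(vals_r, na.rm = TRUE) else criteria$normalization
  tol_dose <- criteria$dose_tol_pct / 100 * dnorm

  eval_pt <- !is.na(vals_r) &
    vals_r >= criteria$low_dose_threshold_pct / 100 * dnorm
  if (!any(eval_pt))
    stop("empty evaluation: no reference point reaches the low-dose ",
         "threshold")
  ridx <- which(eval_pt)                      # linear indices
  rsub <- arrayInd(ridx, dim(vals_r))         # n x nd integer subscripts
  dref <- vals_r[ridx]
  n_ref <- length(ridx)

  # Coarse exhaustive search: loop over integer offsets within 3 * DTA.
  off <- offset_table(sp, 3 * dta)
  n_off <- nrow(off$idx)
  dims <- dim(vals_r)
  best_g2 <- rep(Inf, n_ref)
  best_off <- matrix(0L, n_ref, nd)
  # Keep the full candidate table when affordable so the refinement can
  # descend into the few best coarse basins, not just the single best.
  keep_all <- refine && (as.double(n_ref) * n_off <= 6e7)
  if (keep_all) cand_g2 <- matrix(Inf, n_ref, n_off)
  for (k in seq_len(n_off)) {
    sub <- sweep(rsub, 2L, off$idx[k, ], `+`)
    ok <- rep(TRUE, nrow(sub))
    for (a in seq_len(nd))
      ok <- ok & sub[, a] >= 1L & sub[, a] <= dims[a]
    if (!any(ok)) next
    lin <- linear_index(sub[ok, , drop = FALSE], dims)
    de <- vals_e[lin]
    g2 <- off$dist2[k] / dta^2 + (de - dref[ok])^2 / tol_dose^2
    g2[is.na(g2)] <- Inf
    if (keep_all) cand_g2[which(ok), k] <- g2
    upd <- which(ok)[g2 < best_g2[ok]]
    if (length(upd)) {
      best_g2[upd] <- g2[g2 < best_g2[ok]]
      best_off[upd, ] <- matrix(off$idx[k, ], length(upd), nd, byrow = TRUE)
    }
  }

  if (refine) {
    # 10x sub-grid multilinear refinement, descending into the best
    # `refine_basins` coarse candidates per point (basin choice from the
    # coarse ranking is criteria-dependent; refining several basins keeps
    # the gamma map monotone under criteria tightening).
    steps <- lapply(seq_len(nd), function(a)
      seq(-sp[a], sp[a], by = sp[a] / 10))
    delta <- as.matrix(expand.grid(steps))
    ref_pos <- sweep(rsub - 1, 2L, sp, `*`)
    n_basins <- if (keep_all) min(refine_basins, n_off) else 1L
    for (kk in seq_len(n_basins)) {
      if (keep_all) {
        j <- max.col(-cand_g2, ties.method = "first")
        valid <- is.finite(cand_g2[cbind(seq_len(n_ref), j)])
        cand_g2[cbind(seq_len(n_ref), j)] <- Inf
        boff <- off$idx[j, , drop = FALSE]
      } else {
        valid <- rep(TRUE, n_ref)
        boff <- best_off
      }
      if (!any(valid)) break
      base_pos <- sweep((rsub - 1) + boff, 2L, sp, `*`)
      for (k in seq_len(nrow(delta))) {
        pos <- sweep(base_pos, 2L, delta[k, ], `+`)
        de <- interp_nd(vals_e, sp, pos)
        d2 <- rowSums((pos - ref_pos)^2)
        g2 <- d2 / dta^2 + (de - dref)^2 / tol_dose^2
        g2[is.na(g2) | !valid] <- Inf
        best_g2 <- pmin(best_g2, g2)
      }
    }
  }

  gmap <- array(NA_real_, dims)
  gmap[ridx] <- sqrt(best_g2)
  res <- structure(list(gamma = gmap,
                        n_evaluated = length(ridx),
                        dnorm = dnorm, criteria = criteria),
                   class = "gamma_result")
  res$pass_rate <- pass_rate(res)
  res
}

# Integer index offsets (and squared physical distances) within radius_mm.
offset_table <- function(sp, radius_mm) {
  rng <- lapply(sp, function(s) seq(-floor(radius_mm / s), floor(radius_mm / s)))
  idx <- as.matrix(expand.grid(rng))
  dist2 <- as.vector((idx^2) %*% sp^2)
  keep <- dist2 <= radius_mm^2 + 1e-12
  list(idx = idx[keep, , drop = FALSE], dist2 = dist2[keep])
}

linear_index <- function(sub, dims) {
  stride <- cumprod(c(1L, dims[-length(dims)]))
  as.vector((sub - 1L) %*% stride) + 1L
}

# Multilinear interpolation of an nd array at physical positions (mm,
# relative to the first grid node); NA outside the grid or when any
# corner value is NA.
interp_nd <- function(values, sp, pos) {
  dims <- dim(values)
  nd <- length(dims)
  n <- nrow(pos)
  fi <- sweep(pos, 2L, sp, `/`)          # fractional 0-based index
  lo <- floor(fi)
  frac <- fi - lo
  out <- numeric(n)
  inb <- rep(TRUE, n)
  for (a in seq_len(nd)) {
    at_top <- lo[, a] == dims[a] - 1 & frac[, a] < 1e-12
    lo[at_top, a] <- dims[a] - 2
    frac[at_top, a] <- 1
    inb <- inb & lo[, a] >= 0 & lo[, a] <= dims[a] - 2
  }
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  acc <- numeric(n)
  for (k in seq_len(nrow(corners))) {
    w <- rep(1, n)
    sub <- matrix(0L, n, nd)
    for (a in seq_len(nd)) {
      c_a <- corners[k, a]
      w <- w * if (c_a == 1) frac[, a] else 1 - frac[, a]
      sub[, a] <- as.integer(lo[, a]) + c_a + 1L
    }
    sub[!inb, ] <- 1L
    acc <- acc + w * values[linear_index(sub, dims)]
  }
  acc[!inb] <- NA_real_
  acc
}

#' Gamma pass rate
#'
#' Percentage of evaluated points with gamma <= 1 (the boundary counts as
#' passing; a tie tolerance of 1e-9 absorbs floating-point round-off on
#' the boundary).
#'
#' @param result a `gamma_result`.
#' @return pass rate in percent.
#' @export
pass_rate <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  g <- result$gamma[!is.na(result$gamma)]
  if (length(g) == 0L) stop("empty evaluation: no gamma values")
  100 * mean(g <= 1 + 1e-9)
}

#' @export
print.gamma_result <- function(x, ...) {
  cr <- x$criteria
  cat("<gamma_result> ", cr$dose_tol_pct, "%/", cr$dta_mm, "-mm, ",
      "normalization ", format(x$dnorm, digits = 5), "\n", sep = "")
  g <- x$gamma[!is.na(x$gamma)]
  cat("  evaluated points: ", x$n_evaluated, "\n", sep = "")
  cat("  pass rate: ", format(x$pass_rate, digits = 4), "% (gamma <= 1)\n",
      sep = "")
  cat("  gamma mean/max: ", format(mean(g), digits = 4), " / ",
      format(max(g), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Extract the ring-axis plane from a dose volume
#'
#' Resamples the volume onto the 2D plane through the ring center that
#' contains the ring axis (plane normal x radial reference). Values are
#' interpolated trilinearly; sample points outside the volume are NA.
#'
#' @param volume a `dose_volume`.
#' @param fit a `ring_fit` providing center and plane normal.
#' @param radial length-3 vector fixing the in-plane radial direction
#'   (orthogonalized against the ring axis).
#' @param spacing sample spacing in mm; defaults to the volume's in-plane
#'   spacing.
#' @return an object of class `dose_plane`: `values` (radial x axis
#'   matrix), `u`/`v` plane coordinates (mm, 0 at the ring center),
#'   `spacing`, `center`, `basis`.
#' @export
extract_plane <- function(volume, fit, radial = c(1, 0, 0),
                          spacing = NULL) {
  stopifnot(inherits(volume, "dose_volume"), inherits(fit, "ring_fit"))
  if (is.null(spacing)) spacing <- volume$grid$spacing[1L]
  e_axis <- normalize3(fit$plane_normal)
  rad <- as.numeric(radial)
  rad <- rad - sum(rad * e_axis) * e_axis
  if (sqrt(sum(rad^2)) < 1e-9)
    stop("radial reference is parallel to the ring axis")
  e_rad <- normalize3(rad)
  g <- volume$grid
  lo <- g$origin
  hi <- g$origin + (g$dims - 1L) * g$spacing
  half <- sqrt(sum((hi - lo)^2)) / 2
  n_half <- ceiling(half / spacing)
  u <- seq(-n_half, n_half) * spacing
  v <- seq(-n_half, n_half) * spacing
  uu <- rep(u, times = length(v))
  vv <- rep(v, each = length(u))
  pts <- cbind(fit$center[1L] + uu * e_rad[1L] + vv * e_axis[1L],
               fit$center[2L] + uu * e_rad[2L] + vv * e_axis[2L],
               fit$center[3L] + uu * e_rad[3L] + vv * e_axis[3L])
  rel <- sweep(pts, 2L, lo)
  vals <- interp_nd(volume$values, g$spacing, rel)
  if (all(is.na(vals)))
    stop("geometry error: the ring-axis plane does not intersect the volume")
  structure(list(values = matrix(vals, length(u), length(v)),
                 u = u, v = v, spacing = c(spacing, spacing),
                 center = fit$center,
                 basis = list(radial = e_rad, axis = e_axis)),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat("<dose_plane> ", nrow(x$values), " x ", ncol(x$values),
      " samples, spacing ", x$spacing[1L], " mm, ",
      sum(!is.na(x$values)), " inside the volume\n", sep = "")
  invisible(x)
}
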