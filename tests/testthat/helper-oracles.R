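# Independent oracles used across the suite. Each reimplements the
# quantity under test by a different route (numerical integration,
# exhaustive search, sort-based bookkeeping) and shares no code with the
# package internals.

# Brute-force line-integral dose rate: the active length is discretized
# into n point sources, the inverse-square sum replaces the analytic
# geometry factor, and g_L / F are interpolated with approx()/pracma.
oracle_dose_rate <- function(source, sk, pos_mm, dir, point_mm, n = 1e5) {
  L_mm <- source$active_length_cm * 10
  s <- (seq_len(n) - 0.5) / n * L_mm - L_mm / 2     # segment midpoints
  seg <- outer(s, dir)                              # n x 3 offsets
  d2_cm2 <- ((point_mm[1] - (pos_mm[1] + seg[, 1]))^2 +
             (point_mm[2] - (pos_mm[2] + seg[, 2]))^2 +
             (point_mm[3] - (pos_mm[3] + seg[, 3]))^2) / 100
  G <- mean(1 / d2_cm2)
  # reference geometry: 1 cm from center, transverse
  perp <- if (abs(dir[3]) < 0.9) c(-dir[2], dir[1], 0) else c(0, -dir[3], dir[2])
  perp <- perp / sqrt(sum(perp^2))
  ref_pt <- pos_mm + 10 * perp
  d2_ref <- ((ref_pt[1] - (pos_mm[1] + seg[, 1]))^2 +
             (ref_pt[2] - (pos_mm[2] + seg[, 2]))^2 +
             (ref_pt[3] - (pos_mm[3] + seg[, 3]))^2) / 100
  G_ref <- mean(1 / d2_ref)
  v <- point_mm - pos_mm
  r_cm <- sqrt(sum(v^2)) / 10
  theta <- acos(max(-1, min(1, sum(v * dir) / sqrt(sum(v^2))))) * 180 / pi
  tab <- source$radial_table
  g <- approx(tab$r_cm, tab$g, xout = min(max(r_cm, tab$r_cm[1]),
                                          max(tab$r_cm)), rule = 2)$y
  at <- source$anisotropy_table
  Fv <- pracma::interp2(at$theta_deg, at$r_cm, at$F,
                        min(max(theta, at$theta_deg[1]), max(at$theta_deg)),
                        min(max(r_cm, at$r_cm[1]), max(at$r_cm)))
  sk * source$dose_rate_constant * (G / G_ref) * g * Fv
}

# Sort-based DVH metric oracle: descending sort + approx() at the
# fractional rank.
oracle_dvh_metric <- function(doses, voxel_cc, spec) {
  sorted <- sort(doses, decreasing = TRUE)
  n <- length(sorted)
  m <- regmatches(spec, regexec("^D([0-9.]+)(%|cc)$", spec))[[1]]
  x <- as.numeric(m[2])
  k <- if (m[3] == "%") x / 100 * n else x / voxel_cc
  k <- min(max(k, 1), n)
  if (n == 1) return(sorted[1])
  approx(seq_len(n), sorted, xout = k, rule = 2)$y
}

# Exhaustive gamma oracle: every evaluated grid point is a candidate, no
# search radius, no sub-grid refinement.
oracle_gamma <- function(ref, ev, spacing, tol_pct, dta_mm,
                         dnorm = max(ref)) {
  dims <- dim(ref)
  nd <- length(dims)
  sub <- arrayInd(seq_along(ref), dims)
  pos <- sweep(sub - 1, 2, rep_len(spacing, nd), `*`)
  tol <- tol_pct / 100 * dnorm
  out <- array(NA_real_, dims)
  for (i in seq_along(ref)) {
    d2 <- rowSums(sweep(pos, 2, pos[i, ])^2)
    g2 <- d2 / dta_mm^2 + (ev - ref[i])^2 / tol^2
    out[i] <- sqrt(min(g2))
  }
  out
}

# Rotation matrix about a unit axis (Rodrigues).
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

angle_between_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cu))) * 180 / pi
}

# Small uniform-cube dose volume helper.
uniform_dose <- function(value, dims = c(5, 5, 5), spacing = c(1, 1, 1)) {
  dose_volume(array(value, dims), grid_spec(c(0, 0, 0), spacing, dims))
}

# A tiny two-dwell toy plan used by engine tests.
toy_plan <- function(times = c(3600, 3600), sk = 1) {
  dwells <- data.frame(
    channel = "ch1", applicator = "generic",
    x = c(0, 0), y = c(0, 0), z = c(-5, 5), time_s = times,
    stringsAsFactors = FALSE)
  assign_plan_directions(brachy_plan(dwells, air_kerma_strength = sk))
}
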