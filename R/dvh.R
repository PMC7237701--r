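#' Cumulative dose-volume histogram of a structure
#'
#' Builds the cumulative DVH of the in-mask voxel doses. Metrics are
#' computed from the exact sorted voxel doses (no histogram binning); the
#' exported curve is binned at 1 cGy for plotting only.
#'
#' @param dose a `dose_volume` (cGy per fraction).
#' @param mask logical array on the same grid.
#' @param structure structure name for reporting.
#' @param applicator_excluded flag recorded in the result.
#' @return an object of class `dvh` with fields `structure`, `volume_cc`,
#'   `metrics` (named vector: D100%, D90%, D10cc, D2cc, D0.1cc, cGy; NA
#'   where the requested volume exceeds the structure), `curve`
#'   (data.frame dose_cgy, volume_cc, volume_pct), and the sorted doses.
#' @export
cumulative_dvh <- function(dose, mask, structure = "structure",
                           applicator_excluded = FALSE) {
  stopifnot(inherits(dose, "dose_volume"), is.logical(mask))
  if (!all(dim(mask) == dose$grid$dims))
    stop("mask dims do not match the dose grid")
  doses <- dose$values[mask]
  if (length(doses) == 0L)
    stop("empty structure '", structure, "': mask selects no voxel")
  voxel_cc <- prod(dose$grid$spacing) / 1000
  sorted <- sort(doses, decreasing = TRUE)
  volume_cc <- length(sorted) * voxel_cc

  bins <- seq(0, ceiling(max(sorted)) + 1, by = 1)
  vol_at <- vapply(bins, function(b) sum(sorted >= b) * voxel_cc, 0)
  curve <- data.frame(dose_cgy = bins, volume_cc = vol_at,
                      volume_pct = 100 * vol_at / volume_cc)

  res <- structure(list(structure = structure, volume_cc = volume_cc,
                        voxel_cc = voxel_cc, sorted_doses = sorted,
                        curve = curve,
                        applicator_excluded = applicator_excluded),
                   class = "dvh")
  want <- c("D100%", "D90%", "D10cc", "D2cc", "D0.1cc")
  res$metrics <- vapply(want, function(m)
    tryCatch(dvh_metric(res, m), error = function(e) NA_real_), 0)
  res
}

#' @export
print.dvh <- function(x, ...) {
  cat("<dvh> ", x$structure,
      if (x$applicator_excluded) " (applicator excluded)", "\n", sep = "")
  cat("  volume: ", format(x$volume_cc, digits = 5), " cc (",
      length(x$sorted_doses), " voxels of ", format(x$voxel_cc),
      " cc)\n", sep = "")
  m <- x$metrics[!is.na(x$metrics)]
  if (length(m))
    cat("  ", paste(names(m), "=", format(m, digits = 5), "cGy",
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Dose-volume metric Dx% or Dxcc
#'
#' Dx% is the minimum dose received by the hottest x percent of the
#' structure volume; Dxcc the minimum dose received by the hottest x cm3.
#' Fractional voxel counts are resolved by linear interpolation between
#' adjacent sorted voxel doses.
#'
#' @param dvh a `dvh` object.
#' @param spec metric name such as "D90%", "D100%", "D2cc", "D0.1cc".
#' @return dose in cGy.
#' @export
dvh_metric <- function(dvh, spec) {
  stopifnot(inherits(dvh, "dvh"), is.character(spec), length(spec) == 1L)
  m <- regmatches(spec, regexec("^D([0-9.]+)(%|cc)$", spec))[[1L]]
  if (length(m) != 3L)
    stop("metric spec must look like 'D90%' or 'D2cc' (got '", spec, "')")
  x <- as.numeric(m[2L])
  sorted <- dvh$sorted_doses
  n <- length(sorted)
  if (m[3L] == "%") {
    if (x <= 0 || x > 100) stop("Dx% requires 0 < x <= 100")
    k <- x / 100 * n
  } else {
    if (x <= 0) stop("Dxcc requires x > 0")
    if (x > dvh$volume_cc * (1 + 1e-9))
      stop("insufficient volume: ", spec, " requested but '",
           dvh$structure, "' has only ",
           format(dvh$volume_cc, digits = 5), " cc")
    k <- x / dvh$voxel_cc
  }
  sorted_at(sorted, k)
}

# Dose at fractional rank k (1-based) on the descending-sorted doses;
# clamped to [1, n], linear between adjacent ranks.
sorted_at <- function(sorted, k) {
  n <- length(sorted)
  k <- min(max(k, 1), n)
  i <- floor(k)
  frac <- k - i
  if (i >= n) return(sorted[n])
  sorted[i] + frac * (sorted[i + 1L] - sorted[i])
}

#' Check dosimetric parameters against plan criteria
#'
#' Compares computed metrics with a criteria table. Limits of type "lt"
#' are strict upper bounds (value < limit passes); type "ge" are
#' prescription targets (value >= limit passes). A criterion whose
#' structure/metric is missing from `metrics` is reported unevaluable and
#' fails the plan.
#'
#' @param metrics data.frame with columns `structure`, `metric`,
#'   `value_cgy`.
#' @param criteria data.frame with columns `structure`, `metric`,
#'   `limit_cgy`, `type` ("ge" or "lt"); defaults to [igabt_criteria()].
#' @return data.frame of class `plan_criteria` with pass/fail, margin
#'   (cGy) and an `overall_pass` attribute.
#' @export
check_plan_criteria <- function(metrics, criteria = igabt_criteria()) {
  stopifnot(all(c("structure", "metric", "value_cgy") %in% names(metrics)),
            all(c("structure", "metric", "limit_cgy", "type") %in%
                  names(criteria)))
  out <- criteria
  out$value_cgy <- NA_real_
  out$pass <- NA
  out$margin_cgy <- NA_real_
  for (i in seq_len(nrow(criteria))) {
    sel <- metrics$structure == criteria$structure[i] &
      metrics$metric == criteria$metric[i]
    if (!any(sel) || is.na(metrics$value_cgy[which(sel)[1L]])) next
    v <- metrics$value_cgy[which(sel)[1L]]
    out$value_cgy[i] <- v
    if (criteria$type[i] == "lt") {
      out$pass[i] <- v < criteria$limit_cgy[i]
      out$margin_cgy[i] <- criteria$limit_cgy[i] - v
    } else {
      out$pass[i] <- v >= criteria$limit_cgy[i]
      out$margin_cgy[i] <- v - criteria$limit_cgy[i]
    }
  }
  attr(out, "overall_pass") <- !any(is.na(out$pass)) && all(out$pass)
  class(out) <- c("plan_criteria", "data.frame")
  out
}

#' @export
print.plan_criteria <- function(x, ...) {
  df <- as.data.frame(x)
  df$status <- ifelse(is.na(df$pass), "UNEVALUABLE",
                      ifelse(df$pass, "pass", "FAIL"))
  print(df, row.names = FALSE)
  cat("overall:", if (isTRUE(attr(x, "overall_pass"))) "PASS" else "FAIL",
      "\n")
  invisible(x)
}

#' Default IGABT plan criteria
#'
#' The standard per-fraction criteria: HR-CTV D90% at the 550 cGy
#' prescription, bladder D2cc below 460 cGy, rectum and sigmoid D2cc below
#' 420 cGy (strict).
#'
#' @return criteria data.frame for [check_plan_criteria()].
#' @export
igabt_criteria <- function() {
  data.frame(
    structure = c("HR-CTV", "bladder", "rectum", "sigmoid"),
    metric = c("D90%", "D2cc", "D2cc", "D2cc"),
    limit_cgy = c(550, 460, 420, 420),
    type = c("ge", "lt", "lt", "lt"),
    stringsAsFactors = FALSE)
}
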