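#' HDR brachytherapy plan document
#'
#' Carries the delivery data of one fraction: per-channel ordered dwell
#' positions (mm) and times (s), the applicator type of each channel, the
#' air-kerma strength, the source model id and the fractionation scheme.
#'
#' @param dwells data.frame with columns `channel`, `applicator` (ring /
#'   tandem / generic), `x`, `y`, `z` (mm) and `time_s`; optional unit
#'   direction columns `ux`, `uy`, `uz` (NA until assigned).
#' @param air_kerma_strength S_K in U, > 0.
#' @param source_model_id identifier of the source model.
#' @param fractions number of fractions n >= 1.
#' @param dose_per_fraction_gy prescribed dose per fraction, Gy.
#' @param frame_of_reference identifier shared with the structure set.
#' @return an object of class `brachy_plan`.
#' @export
brachy_plan <- function(dwells, air_kerma_strength, source_model_id = "toy",
                        fractions = 1L, dose_per_fraction_gy = NA_real_,
                        frame_of_reference = "default") {
  need <- c("channel", "applicator", "x", "y", "z", "time_s")
  if (!all(need %in% names(dwells)))
    stop("dwells must have columns ", paste(need, collapse = ", "))
  if (nrow(dwells) == 0L) stop("plan must contain at least one dwell")
  if (any(dwells$time_s < 0)) stop("dwell times must be >= 0 s")
  if (!is.numeric(air_kerma_strength) || air_kerma_strength <= 0)
    stop("air-kerma strength S_K must be > 0")
  if (fractions < 1L) stop("fractions must be >= 1")
  bad <- !dwells$applicator %in% c("ring", "tandem", "generic")
  if (any(bad))
    stop("unknown applicator type(s): ",
         paste(unique(dwells$applicator[bad]), collapse = ", "))
  for (cc in c("ux", "uy", "uz"))
    if (is.null(dwells[[cc]])) dwells[[cc]] <- NA_real_
  structure(list(dwells = dwells,
                 air_kerma_strength = air_kerma_strength,
                 source_model_id = source_model_id,
                 fractions = as.integer(fractions),
                 dose_per_fraction_gy = dose_per_fraction_gy,
                 frame_of_reference = frame_of_reference,
                 direction_method = NA_character_),
            class = "brachy_plan")
}

#' @export
print.brachy_plan <- function(x, ...) {
  cat("<brachy_plan> ", nrow(x$dwells), " dwells in ",
      length(unique(x$dwells$channel)), " channel(s); S_K = ",
      x$air_kerma_strength, " U; source '", x$source_model_id, "'\n",
      sep = "")
  for (ch in unique(x$dwells$channel)) {
    sel <- x$dwells$channel == ch
    cat("  ", ch, " (", x$dwells$applicator[which(sel)[1L]], "): ",
        sum(sel), " dwells, total time ",
        format(sum(x$dwells$time_s[sel])), " s\n", sep = "")
  }
  if (!is.na(x$direction_method))
    cat("  directions:", x$direction_method, "\n")
  invisible(x)
}

#' Assign source directions to every channel of a plan
#'
#' Dispatches per channel on applicator type: ring channels get the
#' circle-tangent method, tandem and generic channels the chained-chord
#' baseline. Set `method = "chained"` to force the baseline everywhere
#' (for method comparisons).
#'
#' @param plan a `brachy_plan`.
#' @param method "auto" (dispatch on applicator type) or "chained".
#' @return the plan with `ux`, `uy`, `uz` filled, the per-channel method
#'   recorded in `direction_method`, and any ring fits in `ring_fits`.
#' @export
assign_plan_directions <- function(plan, method = c("auto", "chained")) {
  stopifnot(inherits(plan, "brachy_plan"))
  method <- match.arg(method)
  dw <- plan$dwells
  fits <- list()
  used <- character(0)
  for (ch in unique(dw$channel)) {
    sel <- which(dw$channel == ch)
    app <- dw$applicator[sel[1L]]
    if (method == "chained") app <- "generic"
    res <- assign_directions(cbind(dw$x[sel], dw$y[sel], dw$z[sel]), app)
    dw$ux[sel] <- res$directions[, 1L]
    dw$uy[sel] <- res$directions[, 2L]
    dw$uz[sel] <- res$directions[, 3L]
    used <- c(used, paste0(ch, ":", res$method))
    if (!is.null(res$ring_fit)) fits[[ch]] <- res$ring_fit
  }
  plan$dwells <- dw
  plan$direction_method <- paste(used, collapse = ", ")
  plan$ring_fits <- fits
  plan
}

# Dwells of a plan as a list of dwell_point objects (kernel interface).
plan_dwell_points <- function(plan) {
  dw <- plan$dwells
  lapply(seq_len(nrow(dw)), function(i)
    dwell_point(c(dw$x[i], dw$y[i], dw$z[i]),
                c(dw$ux[i], dw$uy[i], dw$uz[i]),
                time_s = dw$time_s[i], channel_id = dw$channel[i],
                sk = plan$air_kerma_strength))
}
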