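#' Biologically effective dose (BED)
#'
#' Linear-quadratic BED for n fractions of d Gy:
#' BED = n * d * (1 + d / (alpha/beta)).
#'
#' @param d_gy dose per fraction, Gy, >= 0 (vectorized).
#' @param alpha_beta tissue alpha/beta ratio, Gy, > 0 (10 is typical for
#'   tumor, 3 for late-responding organs at risk).
#' @param n number of fractions, >= 1.
#' @return BED in Gy.
#' @export
bed <- function(d_gy, alpha_beta, n = 1) {
  check_lq_args(d_gy, alpha_beta, n)
  n * d_gy * (1 + d_gy / alpha_beta)
}

#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' EQD2 = BED / (1 + 2 / (alpha/beta)). At d = 2 Gy the conversion is the
#' identity (EQD2 = n * d).
#'
#' @inheritParams bed
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(d_gy, alpha_beta, n = 1) {
  bed(d_gy, alpha_beta, n) / (1 + 2 / alpha_beta)
}

check_lq_args <- function(d_gy, alpha_beta, n) {
  if (any(d_gy < 0)) stop("dose per fraction must be >= 0 Gy")
  if (any(alpha_beta <= 0)) stop("alpha/beta must be > 0 Gy")
  if (any(n < 1)) stop("number of fractions must be >= 1")
  invisible(TRUE)
}

#' Total EQD2 over a course of fractions
#'
#' Each fraction is converted at its own per-fraction dose (n = 1) and the
#' EQD2 values are summed; the per-fraction breakdown is preserved for
#' reporting.
#'
#' @param per_fraction_doses_gy vector of per-fraction doses, Gy, >= 0.
#' @param alpha_beta tissue alpha/beta ratio, Gy.
#' @return list with `total_gy` and `per_fraction_gy`.
#' @export
eqd2_total <- function(per_fraction_doses_gy, alpha_beta) {
  if (any(per_fraction_doses_gy < 0))
    stop("per-fraction doses must be >= 0 Gy")
  per <- eqd2(per_fraction_doses_gy, alpha_beta, n = 1)
  list(total_gy = sum(per), per_fraction_gy = per)
}

#' Convert a physical dose volume to EQD2
#'
#' Applies the linear-quadratic conversion voxelwise, taking each voxel's
#' per-fraction dose as d. Input doses are cGy per fraction; the output
#' volume is in Gy (units tagged in the metadata).
#'
#' @param dose a `dose_volume` in cGy per fraction.
#' @param alpha_beta tissue alpha/beta ratio, Gy.
#' @param n number of identical fractions.
#' @return a `dose_volume` with EQD2 values in Gy.
#' @export
eqd2_volume <- function(dose, alpha_beta, n = 1) {
  stopifnot(inherits(dose, "dose_volume"))
  d_gy <- dose$values / 100
  vals <- eqd2(d_gy, alpha_beta, n = n)
  md <- dose$metadata
  md$units <- "Gy (EQD2)"
  md$alpha_beta <- alpha_beta
  md$fractions <- n
  dose_volume(array(vals, dose$grid$dims), dose$grid, md)
}
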