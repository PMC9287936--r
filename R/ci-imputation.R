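## Empirical population-specific constants for the 95% CI of a QTL position
## as a function of population size N and explained variance R2.
CI_CONSTANTS <- c(F2 = 530, F2_3 = 530, F3_4 = 530, BC = 530, TC = 530,
  RIL = 163, DH = 163)

#' Impute a 95% confidence interval width from N and R-squared
#'
#' When a published QTL reports no confidence interval, its expected 95% CI
#' width (in cM) is estimated from the mapping-population size N and the
#' proportion of phenotypic variance explained: `530 / (N * R2)` for
#' backcross and F2-derived populations and `163 / (N * R2)` for fully
#' inbred populations (recombinant inbred lines, doubled haploids).
#' Testcross and advanced-F populations use the F2-family constant.
#'
#' @param N mapping-population size (integer >= 2).
#' @param r_squared fraction of variance explained, in (0, 1].
#' @param population_type one of `"F2"`, `"F2_3"`, `"F3_4"`, `"BC"`,
#'   `"TC"` (constant 530) or `"RIL"`, `"DH"` (constant 163).
#' @return CI width in cM (vectorised over the inputs).
#' @examples
#' imputeCI(400, 0.09, "F2")   # 14.722 cM
#' imputeCI(258, 0.10, "RIL")  # 6.318 cM
#' @export
imputeCI <- function(N, r_squared, population_type) {
  if (any(is.na(N)) || any(N < 2))
    stop("population size N must be >= 2")
  if (any(is.na(r_squared)) || any(r_squared <= 0) || any(r_squared > 1))
    stop("r_squared must lie in (0, 1]")
  k <- CI_CONSTANTS[as.character(population_type)]
  if (anyNA(k))
    stop("no CI formula for population type ",
      paste(unique(population_type[is.na(k)]), collapse = ", "),
      "; an explicit CI or flanking markers are required")
  unname(k / (N * r_squared))
}

#' Fill in the default LOD score
#'
#' Studies that do not report a LOD take the conventional support value 2.5.
#'
#' @param qtls QTL `data.frame` with a `lod` column.
#' @param default LOD used where missing (2.5).
#' @return The table with missing `lod` replaced.
#' @export
applyLODDefault <- function(qtls, default = 2.5) {
  if (nrow(qtls)) qtls$lod[is.na(qtls$lod)] <- default
  qtls
}

#' Convert a 95% CI width to a Gaussian standard deviation
#'
#' The mixture model weighs each QTL by the precision of its position; a
#' 95% normal interval spans \eqn{\pm 1.96\sigma}, so
#' \eqn{\sigma = \mathrm{width} / 3.92}.
#'
#' @param ci_width CI width in cM (> 0).
#' @return sigma in cM.
#' @export
ciToSigma <- function(ci_width) {
  if (any(is.na(ci_width)) || any(ci_width <= 0))
    stop("CI width must be positive")
  ci_width / 3.92
}
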