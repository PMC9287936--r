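#' @import methods
#' @importFrom stats dnorm quantile runif rnorm setNames phyper p.adjust
#'   splinefun rbinom
#' @importFrom utils read.delim write.table head tail
NULL

#' GeneticMap: an ordered linkage map
#'
#' A linkage map holds marker loci grouped into linkage groups, each marker
#' with a genetic position in centimorgans (cM) and, optionally, a physical
#' position in base pairs (bp).  Markers are kept sorted by genetic position
#' within each group; marker names are unique within a map.
#'
#' @slot mapId single string identifying the map (e.g. the study it came
#'   from, or `"IBM2"` for a reference map).
#' @slot markers `data.frame` with columns `marker` (character),
#'   `group` (character linkage-group label), `cM` (numeric, >= 0) and
#'   `bp` (integer physical anchor position or `NA`).
#'
#' @seealso [readGeneticMap()], [mergeMaps()]
#' @export
setClass("GeneticMap",
  representation(mapId = "character", markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  msg <- character()
  m <- object@markers
  need <- c("marker", "group", "cM", "bp")
  if (!all(need %in% names(m)))
    return(paste("markers must have columns", paste(need, collapse = ", ")))
  if (length(object@mapId) != 1L || is.na(object@mapId))
    msg <- c(msg, "mapId must be a single non-NA string")
  if (nrow(m)) {
    if (anyNA(m$cM) || any(m$cM < 0))
      msg <- c(msg, "genetic positions must be non-negative and non-missing")
    if (anyDuplicated(m$marker))
      msg <- c(msg, sprintf("duplicate marker name(s): %s",
        paste(unique(m$marker[duplicated(m$marker)]), collapse = ", ")))
    if (!all(is.na(m$bp) | m$bp >= 1))
      msg <- c(msg, "physical positions must be >= 1 bp when present")
    ord <- unlist(lapply(split(m$cM, m$group), function(x) !is.unsorted(x)),
      use.names = FALSE)
    if (!all(ord))
      msg <- c(msg, "markers must be sorted by cM within each linkage group")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusMap: an integrated linkage map with provenance
#'
#' Extends [GeneticMap-class] with per-marker provenance (which source maps
#' contributed the marker, comma-separated), an `anchor` flag (the marker
#' carries a physical position usable for cM <-> bp interpolation) and a
#' placement `status` (`"reference"`, `"interpolated"` or `"extrapolated"`).
#'
#' @seealso [mergeMaps()]
#' @export
setClass("ConsensusMap", contains = "GeneticMap")

setValidity("ConsensusMap", function(object) {
  m <- object@markers
  need <- c("provenance", "anchor", "status")
  if (!all(need %in% names(m)))
    return(paste("consensus markers need columns",
      paste(need, collapse = ", ")))
  if (nrow(m) && any(!nzchar(m$provenance)))
    return("every consensus marker must be traceable to >= 1 source map")
  TRUE
})

#' MixtureFit: a fitted variance-weighted 1-D Gaussian mixture
#'
#' Result of [fitMixture()]: K component means on the cM axis, mixing
#' proportions, the maximised log-likelihood, the AIC
#' (\eqn{-2\log L + 2(2K-1)}; free means plus free proportions), and the
#' n x K posterior responsibility matrix in input-row order.
#'
#' @slot k integer number of components.
#' @slot means numeric, sorted ascending.
#' @slot proportions numeric, non-negative, summing to 1.
#' @slot loglik,aic numeric scalars.
#' @slot responsibilities numeric matrix, rows = observations.
#' @slot converged logical: EM met the tolerance within the iteration cap.
#' @export
setClass("MixtureFit",
  representation(k = "integer", means = "numeric", proportions = "numeric",
    loglik = "numeric", aic = "numeric", responsibilities = "matrix",
    converged = "logical"))

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@means) != object@k || length(object@proportions) != object@k)
    msg <- c(msg, "means and proportions must have length k")
  if (is.unsorted(object@means)) msg <- c(msg, "means must be sorted ascending")
  if (any(object@proportions < 0) ||
      abs(sum(object@proportions) - 1) > 1e-9)
    msg <- c(msg, "proportions must be non-negative and sum to 1")
  expected <- -2 * object@loglik + 2 * (2 * object@k - 1)
  if (is.finite(object@aic) && abs(object@aic - expected) > 1e-6)
    msg <- c(msg, "aic must equal -2*loglik + 2*(2k-1)")
  if (length(msg)) msg else TRUE
})
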