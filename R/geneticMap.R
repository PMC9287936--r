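#' Construct a GeneticMap
#'
#' Builds a validated [GeneticMap-class] from a marker table.  Markers are
#' sorted by genetic position within each linkage group; a missing `bp`
#' column is filled with `NA`.
#'
#' @param mapId single string identifying the map.
#' @param markers `data.frame` with columns `marker`, `group`, `cM` and
#'   optionally `bp`.
#' @return A `GeneticMap`.
#' @examples
#' gm <- GeneticMap("toy", data.frame(
#'   marker = c("m2", "m1"), group = "2", cM = c(10, 0)))
#' markers(gm)$marker  # sorted by cM: m1, m2
#' @export
GeneticMap <- function(mapId, markers) {
  markers <- as.data.frame(markers)
  if (!"bp" %in% names(markers)) markers$bp <- NA_integer_
  markers$marker <- as.character(markers$marker)
  markers$group <- as.character(markers$group)
  markers$cM <- as.numeric(markers$cM)
  markers$bp <- as.integer(round(as.numeric(markers$bp)))
  markers <- markers[order(orderGroups(markers$group), markers$cM,
    markers$marker), c("marker", "group", "cM", "bp"), drop = FALSE]
  rownames(markers) <- NULL
  new("GeneticMap", mapId = as.character(mapId), markers = markers)
}

# natural order for linkage-group labels: numeric where possible, then names
orderGroups <- function(g) {
  n <- suppressWarnings(as.numeric(g))
  ifelse(is.na(n), rank(g) + 1e6, n)
}

#' Accessors for GeneticMap objects
#'
#' `mapId()` returns the map identifier, `markers()` the marker table,
#' `groupNames()` the linkage-group labels in natural order, and
#' `nMarkers()` the marker count.
#'
#' @param x a [GeneticMap-class] (or [ConsensusMap-class]).
#' @name GeneticMap-accessors
NULL

#' @rdname GeneticMap-accessors
#' @export
setMethod("mapId", "GeneticMap", function(x) x@mapId)

#' @rdname GeneticMap-accessors
#' @export
setMethod("markers", "GeneticMap", function(x) x@markers)

#' @rdname GeneticMap-accessors
#' @export
setMethod("groupNames", "GeneticMap", function(x) {
  g <- unique(x@markers$group)
  g[order(orderGroups(g))]
})

#' @rdname GeneticMap-accessors
#' @export
setMethod("nMarkers", "GeneticMap", function(x) nrow(x@markers))

#' Map length and marker density
#'
#' `mapLength()` returns per-group lengths (max cM - min cM) plus an
#' `overall` sum; `mapDensity()` returns markers per cM per group plus the
#' `overall` density (total markers / total length).  Zero-length groups are
#' excluded from the density denominator with a warning.
#'
#' @param x a [GeneticMap-class].
#' @return Named numeric vector (one entry per group plus `"overall"`).
#' @export
#' @rdname mapDensity
setMethod("mapLength", "GeneticMap", function(x) {
  stopifnot(nrow(x@markers) > 0)
  len <- vapply(split(x@markers$cM, x@markers$group),
    function(p) max(p) - min(p), numeric(1))
  len <- len[groupNames(x)]
  c(len, overall = sum(len))
})

#' @rdname mapDensity
#' @export
setMethod("mapDensity", "GeneticMap", function(x) {
  len <- mapLength(x)
  len <- len[names(len) != "overall"]
  cnt <- table(x@markers$group)[names(len)]
  zero <- len <= 0
  if (any(zero))
    warning("excluding zero-length group(s) from density: ",
      paste(names(len)[zero], collapse = ", "))
  dens <- ifelse(zero, NA_real_, as.numeric(cnt) / len)
  names(dens) <- names(len)
  c(dens, overall = sum(cnt[!zero]) / sum(len[!zero]))
})

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("%s \"%s\": %d markers in %d linkage group(s)\n",
    class(object), object@mapId, nrow(object@markers),
    length(unique(object@markers$group))))
  if (nrow(object@markers)) {
    len <- mapLength(object)
    cat(sprintf("  total length %.1f cM; %d physical anchor(s)\n",
      len[["overall"]], sum(!is.na(object@markers$bp))))
  }
})

#' Read a linkage map from a tab-separated file
#'
#' Expects a header row and columns `marker`, `linkage_group`, `cM_position`
#' and optionally `bp_position`.  Rows are sorted by genetic position within
#' each group; duplicate marker names or negative positions are errors.
#'
#' @param path path to the TSV file.
#' @param map_id identifier to assign to the map.
#' @return A [GeneticMap-class].
#' @export
readGeneticMap <- function(path, map_id) {
  df <- read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE)
  need <- c("marker", "linkage_group", "cM_position")
  if (!all(need %in% names(df)))
    stop("map file ", path, " must have columns ",
      paste(need, collapse = ", "))
  cm <- suppressWarnings(as.numeric(df$cM_position))
  bad <- which(is.na(cm) & nzchar(df$cM_position))
  if (length(bad))
    stop("malformed cM_position at data line ", bad[1], " of ", path)
  if (anyNA(cm))
    stop("missing cM_position at data line ", which(is.na(cm))[1],
      " of ", path)
  if (any(cm < 0))
    stop("negative cM_position at data line ", which(cm < 0)[1], " of ", path)
  bp <- if ("bp_position" %in% names(df))
    suppressWarnings(as.integer(df$bp_position)) else NA_integer_
  GeneticMap(map_id, data.frame(marker = df$marker,
    group = df$linkage_group, cM = cm, bp = bp))
}

#' Write a linkage (or consensus) map to a tab-separated file
#'
#' The inverse of [readGeneticMap()]; a [ConsensusMap-class] additionally
#' writes its `provenance`, `anchor` and `status` columns.
#'
#' @param map a [GeneticMap-class] or [ConsensusMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneticMap <- function(map, path) {
  m <- markers(map)
  out <- data.frame(marker = m$marker, linkage_group = m$group,
    cM_position = m$cM, bp_position = m$bp, check.names = FALSE)
  extra <- intersect(c("provenance", "anchor", "status"), names(m))
  out <- cbind(out, m[extra])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "")
  invisible(path)
}
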