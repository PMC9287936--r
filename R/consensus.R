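#' Resolve marker-order conflicts between two maps
#'
#' When the display order of markers shared by two linkage maps disagrees,
#' the smallest possible set of conflicting markers is discarded: the
#' retained set is the maximal subset of shared markers whose relative order
#' agrees in both maps — the longest increasing subsequence of the study
#' positions indexed by reference rank.  When several maximal subsets exist
#' the lexicographically smallest reference-index sequence is chosen, making
#' the result deterministic.
#'
#' @param ref_order character vector: shared markers in reference-map order.
#' @param study_order character vector: the same markers in study-map order.
#' @return Retained marker names, in reference order.  An empty shared set
#'   returns `character(0)` with a warning (the group cannot be merged).
#' @examples
#' resolveMarkerConflicts(c("A", "B", "C", "D"), c("A", "C", "B", "D"))
#' # "A" "B" "D"
#' @export
resolveMarkerConflicts <- function(ref_order, study_order) {
  shared <- intersect(ref_order, study_order)
  if (!length(shared)) {
    warning("no shared markers; group cannot be merged")
    return(character(0))
  }
  ref_order <- ref_order[ref_order %in% shared]
  study_order <- study_order[study_order %in% shared]
  refRank <- match(study_order, ref_order)
  keep <- lisLexSmallest(refRank)
  ref_order[refRank[keep]]
}

#' Merge study linkage maps with a reference map into a consensus map
#'
#' The reference cM scale is authoritative: markers present in the reference
#' keep their reference positions exactly.  Each study is merged
#' independently against the reference (star topology).  Per linkage group,
#' shared markers are first conflict-resolved with
#' [resolveMarkerConflicts()]; study-only markers are then placed by
#' homothetic (piecewise-linear) interpolation of their study position
#' between the nearest flanking retained shared markers, and extrapolated
#' with the nearest interval's ratio beyond the terminal shared markers
#' (flagged `"extrapolated"`).  A study group sharing fewer than two
#' markers with the reference contributes nothing (warning).
#'
#' @param reference a [GeneticMap-class]; its `bp` anchors are carried into
#'   the consensus.
#' @param studies list of [GeneticMap-class] study maps.
#' @return A list with elements
#'   \describe{
#'     \item{consensus}{[ConsensusMap-class] on the reference scale;}
#'     \item{frameworks}{`data.frame` (map_id, group, marker, source_cM,
#'       consensus_cM) of the retained shared markers per study — the
#'       projection framework used by [projectQTL()];}
#'     \item{dropped}{`data.frame` log of markers discarded per study with
#'       reasons.}
#'   }
#' @export
mergeMaps <- function(reference, studies) {
  ref <- markers(reference)
  cons <- data.frame(ref,
    provenance = mapId(reference),
    anchor = !is.na(ref$bp),
    status = "reference",
    stringsAsFactors = FALSE)
  frameworks <- list()
  dropped <- list()
  note <- function(map, group, marker, reason)
    data.frame(map_id = map, group = group, marker = marker,
      reason = reason, stringsAsFactors = FALSE)

  for (st in studies) {
    sm <- markers(st)
    sid <- mapId(st)
    for (grp in unique(sm$group)) {
      sg <- sm[sm$group == grp, , drop = FALSE]
      rg <- cons[cons$group == grp & cons$status == "reference", ,
        drop = FALSE]
      shared <- intersect(rg$marker, sg$marker)
      if (length(shared) < 2) {
        warning(sprintf("study %s group %s shares %d marker(s) with the reference; group skipped",
          sid, grp, length(shared)))
        if (nrow(sg))
          dropped[[length(dropped) + 1L]] <- note(sid, grp, sg$marker,
            "group shares < 2 markers with reference")
        next
      }
      retained <- resolveMarkerConflicts(rg$marker, sg$marker)
      conflicted <- setdiff(shared, retained)
      if (length(conflicted))
        dropped[[length(dropped) + 1L]] <- note(sid, grp, conflicted,
          "marker order conflicts with reference")
      if (length(retained) < 2) {
        dropped[[length(dropped) + 1L]] <- note(sid, grp,
          setdiff(sg$marker, shared), "no usable shared framework")
        next
      }
      srcCM <- sg$cM[match(retained, sg$marker)]
      refCM <- rg$cM[match(retained, rg$marker)]
      # knots must be strictly increasing on the study scale; collapse ties
      keep <- !duplicated(srcCM)
      srcK <- srcCM[keep]; refK <- refCM[keep]
      # credit the study on retained shared markers
      idx <- match(retained, cons$marker)
      cons$provenance[idx] <- paste(cons$provenance[idx], sid, sep = ",")
      frameworks[[length(frameworks) + 1L]] <- data.frame(map_id = sid,
        group = grp, marker = retained, source_cM = srcCM,
        consensus_cM = refCM, stringsAsFactors = FALSE)

      only <- sg[!sg$marker %in% shared, , drop = FALSE]
      if (!nrow(only)) next
      if (length(srcK) < 2) {
        dropped[[length(dropped) + 1L]] <- note(sid, grp, only$marker,
          "shared framework degenerate on study scale")
        next
      }
      proj <- interpolatePiecewise(only$cM, srcK, refK)
      for (j in seq_len(nrow(only))) {
        mk <- only$marker[j]
        hit <- match(mk, cons$marker)
        if (!is.na(hit)) {  # placed earlier by another study
          cons$provenance[hit] <- paste(cons$provenance[hit], sid, sep = ",")
          next
        }
        cons <- rbind(cons, data.frame(marker = mk, group = grp,
          cM = max(0, proj$value[j]), bp = only$bp[j],
          provenance = sid, anchor = !is.na(only$bp[j]),
          status = if (proj$extrapolated[j]) "extrapolated" else
            "interpolated", stringsAsFactors = FALSE))
      }
    }
  }
  cons <- cons[order(orderGroups(cons$group), cons$cM, cons$marker), ,
    drop = FALSE]
  rownames(cons) <- NULL
  consensus <- new("ConsensusMap", mapId = "consensus", markers = cons)
  emptyFw <- data.frame(map_id = character(), group = character(),
    marker = character(), source_cM = numeric(), consensus_cM = numeric())
  emptyDrop <- data.frame(map_id = character(), group = character(),
    marker = character(), reason = character())
  list(consensus = consensus,
    frameworks = if (length(frameworks)) do.call(rbind, frameworks) else
      emptyFw,
    dropped = if (length(dropped)) do.call(rbind, dropped) else emptyDrop)
}
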