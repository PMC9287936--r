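#' Project a genetic position from a source map onto the consensus scale
#'
#' A position is re-expressed homothetically between its flanking shared
#' markers: with flanks at source positions M1 < M2 mapping to consensus
#' positions M1', M2', the projected position is
#' `M1' + (pos - M1) * (M2' - M1') / (M2 - M1)`.  Positions outside the
#' terminal shared markers are extended with the nearest interval's ratio
#' and flagged `extrapolated`.
#'
#' @param pos cM position(s) on the source map.
#' @param source_cM,consensus_cM coordinates of the >= 2 shared framework
#'   markers on the two maps, in matching order (strictly increasing
#'   `source_cM`).
#' @return list with `value` (consensus cM) and `extrapolated` (logical),
#'   vectorised over `pos`.
#' @examples
#' projectPosition(10, c(5, 15), c(10, 30))$value  # 20
#' @export
projectPosition <- function(pos, source_cM, consensus_cM) {
  if (length(source_cM) < 2)
    stop("need >= 2 shared markers to project")
  interpolatePiecewise(pos, source_cM, consensus_cM)
}

#' Convert a physical position to a genetic position via marker anchors
#'
#' Inverse of the cM -> bp anchoring rule: with flanking anchors at physical
#' positions p1 < p2 and genetic positions g1, g2,
#' `g = g1 + (g2 - g1) * (p - p1) / (p2 - p1)`.  Positions beyond the
#' anchored span use the nearest interval's ratio and are flagged.
#'
#' @param p physical position(s) in bp.
#' @param anchor_bp,anchor_cM coordinates of >= 2 anchor markers (strictly
#'   increasing `anchor_bp`).
#' @return list with `value` (cM) and `extrapolated`.
#' @export
physicalToGenetic <- function(p, anchor_bp, anchor_cM) {
  if (length(anchor_bp) < 2) stop("need >= 2 anchors")
  interpolatePiecewise(as.numeric(p), as.numeric(anchor_bp), anchor_cM)
}

#' Project QTLs onto the consensus map
#'
#' Every accepted QTL is re-expressed on the consensus map, covering the
#' four situations met in the literature:
#' \describe{
#'   \item{full map}{peak and CI known on a study map — all three positions
#'     are projected independently through the study's retained shared-marker
#'     framework (`both_flanks`);}
#'   \item{CI from formula}{no CI published — the width is imputed with
#'     [imputeCI()] around the projected peak (`formula_only`);}
#'   \item{flanking markers only}{the CI endpoints are the consensus
#'     positions of the two flanking markers; with only one flank locatable
#'     the missing endpoint is completed with the imputed width
#'     (`one_flank_plus_formula`), the peak at the CI midpoint;}
#'   \item{physical coordinates}{SNP-based studies report bp endpoints,
#'     converted to cM with [physicalToGenetic()] over the consensus
#'     anchors (`physical_converted`).}
#' }
#' QTLs that cannot be placed (no framework, no locatable flank, or
#' extrapolation beyond `max_extrapolation` of the group length) are
#' discarded with a reason.
#'
#' @param qtls accepted QTL `data.frame` ([readQTLTable()] schema).
#' @param experiments experiment metadata ([readExperimentTable()]).
#' @param consensus a [ConsensusMap-class].
#' @param frameworks per-study shared-marker framework from [mergeMaps()].
#' @param study_of named character: `map_id` of the study map used by each
#'   `experiment_id`; defaults to `experiment_id` itself.
#' @param max_extrapolation maximum allowed extrapolation beyond the
#'   terminal shared markers, as a fraction of the group length (0.2).
#' @return list with `projected` (`data.frame`: qtl_id, trait,
#'   experiment_id, linkage_group, peak, ci_start, ci_end, sigma,
#'   provenance, lod, r_squared) and `discarded` (qtl_id + reason).
#' @export
projectQTL <- function(qtls, experiments, consensus, frameworks,
    study_of = NULL, max_extrapolation = 0.2) {
  cons <- markers(consensus)
  out <- list(); disc <- list()
  addDisc <- function(id, reason)
    data.frame(qtl_id = id, reason = reason, stringsAsFactors = FALSE)
  expIdx <- match(qtls$experiment_id, experiments$experiment_id)
  glen <- vapply(split(cons$cM, cons$group), function(p) max(p) - min(p),
    numeric(1))

  for (i in seq_len(nrow(qtls))) {
    q <- qtls[i, ]
    N <- experiments$population_size[expIdx[i]]
    ptype <- experiments$population_type[expIdx[i]]
    grp <- q$linkage_group
    cg <- cons[cons$group == grp, , drop = FALSE]
    mapid <- if (is.null(study_of)) q$experiment_id else
      study_of[[q$experiment_id]]
    fw <- frameworks[frameworks$map_id == mapid &
      frameworks$group == grp, , drop = FALSE]
    imputedWidth <- function() {
      if (is.na(q$r_squared)) return(NA_real_)
      tryCatch(imputeCI(N, q$r_squared, ptype), error = function(e) NA_real_)
    }
    peak <- cis <- cie <- NA_real_
    prov <- NA_character_
    extra <- FALSE

    if (identical(q$coord_system, "physical")) {
      anch <- cg[cg$anchor %in% TRUE & !is.na(cg$bp), , drop = FALSE]
      if (nrow(anch) < 2) {
        disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
          "no physical anchors on linkage group")
        next
      }
      keepIdx <- lisLexSmallest(as.numeric(anch$bp))
      anch <- anch[keepIdx, , drop = FALSE]
      if (nrow(anch) < 2 || anyNA(c(q$ci_start, q$ci_end))) {
        disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
          "physical QTL lacks bp endpoints or usable anchors")
        next
      }
      g1 <- physicalToGenetic(q$ci_start, anch$bp, anch$cM)
      g2 <- physicalToGenetic(q$ci_end, anch$bp, anch$cM)
      cis <- min(g1$value, g2$value); cie <- max(g1$value, g2$value)
      extra <- g1$extrapolated || g2$extrapolated
      peak <- if (!is.na(q$peak_cM)) {
        physicalToGenetic(q$peak_cM, anch$bp, anch$cM)$value
      } else (cis + cie) / 2
      prov <- "physical_converted"
    } else if (nrow(fw) >= 2) {
      src <- fw$source_cM; dst <- fw$consensus_cM
      keep <- !duplicated(src)
      src <- src[keep]; dst <- dst[keep]
      if (length(src) < 2) {
        disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
          "degenerate projection framework")
        next
      }
      haveCI <- !is.na(q$ci_start) && !is.na(q$ci_end)
      if (is.na(q$peak_cM) && !haveCI) {
        disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
          "no genetic peak or CI on study map")
        next
      }
      if (haveCI) {
        pr <- projectPosition(c(q$ci_start, q$ci_end,
          if (is.na(q$peak_cM)) (q$ci_start + q$ci_end) / 2 else q$peak_cM),
          src, dst)
        cis <- pr$value[1]; cie <- pr$value[2]; peak <- pr$value[3]
        extra <- any(pr$extrapolated)
        prov <- "both_flanks"
      } else {
        w <- imputedWidth()
        if (is.na(w)) {
          disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
            "no CI and no imputable R2/population formula")
          next
        }
        pr <- projectPosition(q$peak_cM, src, dst)
        peak <- pr$value; extra <- pr$extrapolated
        cis <- peak - w / 2; cie <- peak + w / 2
        prov <- "formula_only"
      }
    } else {
      # no study map framework: locate flanking markers on the consensus
      lpos <- if (!is.na(q$flank_left))
        cg$cM[match(q$flank_left, cg$marker)] else NA_real_
      rpos <- if (!is.na(q$flank_right))
        cg$cM[match(q$flank_right, cg$marker)] else NA_real_
      nFound <- sum(!is.na(c(lpos, rpos)))
      if (nFound == 2) {
        cis <- min(lpos, rpos); cie <- max(lpos, rpos)
        peak <- (cis + cie) / 2
        prov <- "both_flanks"
      } else if (nFound == 1) {
        w <- imputedWidth()
        if (is.na(w)) {
          disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
            "single flank and no imputable CI width")
          next
        }
        known <- c(lpos, rpos)[!is.na(c(lpos, rpos))]
        if (!is.na(lpos)) { cis <- known; cie <- known + w }
        else { cie <- known; cis <- max(0, known - w) }
        peak <- (cis + cie) / 2
        prov <- "one_flank_plus_formula"
      } else {
        disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
          "neither flank locatable on consensus map")
        next
      }
    }

    if (is.na(peak) || is.na(cis) || is.na(cie)) {
      disc[[length(disc) + 1L]] <- addDisc(q$qtl_id, "unresolvable position")
      next
    }
    if (extra) {
      span <- glen[[grp]]
      lim <- max_extrapolation * span
      lo <- min(cg$cM); hi <- max(cg$cM)
      if (peak < lo - lim || peak > hi + lim) {
        disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
          "extrapolation beyond allowed fraction of group length")
        next
      }
    }
    if (cie <= cis) {
      disc[[length(disc) + 1L]] <- addDisc(q$qtl_id,
        "projected CI has non-positive width")
      next
    }
    peak <- min(max(peak, cis), cie)  # keep peak inside the projected CI
    out[[length(out) + 1L]] <- data.frame(qtl_id = q$qtl_id,
      trait = q$trait, experiment_id = q$experiment_id,
      linkage_group = grp, peak = peak, ci_start = cis, ci_end = cie,
      sigma = (cie - cis) / 3.92, provenance = prov, lod = q$lod,
      r_squared = q$r_squared, extrapolated = extra,
      stringsAsFactors = FALSE)
  }
  emptyP <- data.frame(qtl_id = character(), trait = character(),
    experiment_id = character(), linkage_group = character(),
    peak = numeric(), ci_start = numeric(), ci_end = numeric(),
    sigma = numeric(), provenance = character(), lod = numeric(),
    r_squared = numeric(), extrapolated = logical())
  list(projected = if (length(out)) do.call(rbind, out) else emptyP,
    discarded = if (length(disc)) do.call(rbind, disc) else
      data.frame(qtl_id = character(), reason = character()))
}
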