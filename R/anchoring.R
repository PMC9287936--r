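#' Convert a genetic position to a physical position via marker anchors
#'
#' Linear interpolation between the nearest flanking anchor markers:
#' `p = p1 + (p2 - p1) * (g - g1) / (g2 - g1)`, rounded to the nearest
#' integer bp.  Anchors whose bp order is inverted relative to their cM
#' order (assembly/legacy-map inversions) are excluded first by keeping the
#' maximal bp-monotone subset (longest increasing subsequence), with a
#' warning.
#'
#' @param g genetic position(s) in cM.
#' @param anchor_cM,anchor_bp coordinates of >= 2 anchor markers ordered by
#'   cM.
#' @return list with `value` (integer bp), `value_exact` (unrounded),
#'   `extrapolated` (logical) and `n_anchors_used`.
#' @examples
#' geneticToPhysical(12.5, c(10, 20), c(1e6, 3e6))$value  # 1500000
#' @export
geneticToPhysical <- function(g, anchor_cM, anchor_bp) {
  if (length(anchor_cM) < 2) stop("need >= 2 anchors")
  if (any(diff(anchor_cM) < 0)) {
    o <- order(anchor_cM)
    anchor_cM <- anchor_cM[o]; anchor_bp <- anchor_bp[o]
  }
  keep <- lisLexSmallest(as.numeric(anchor_bp))
  if (length(keep) < length(anchor_bp))
    warning(length(anchor_bp) - length(keep),
      " anchor(s) with inverted bp order excluded")
  anchor_cM <- anchor_cM[keep]; anchor_bp <- anchor_bp[keep]
  if (length(anchor_cM) < 2) stop("fewer than 2 bp-monotone anchors")
  # collapse cM ties so knots are strictly increasing
  dup <- duplicated(anchor_cM)
  anchor_cM <- anchor_cM[!dup]; anchor_bp <- anchor_bp[!dup]
  if (length(anchor_cM) < 2) stop("degenerate anchors (identical cM)")
  r <- interpolatePiecewise(g, anchor_cM, as.numeric(anchor_bp))
  list(value = as.numeric(round(r$value)), value_exact = r$value,
    extrapolated = r$extrapolated, n_anchors_used = length(anchor_cM))
}

#' Resolve the physical interval of each meta-QTL
#'
#' The cM endpoints of every MQTL 95% CI are interpolated to bp through the
#' physical anchor markers of its linkage group on the consensus map
#' ([geneticToPhysical()]); inverted endpoints are swapped so start <= end,
#' and the result is clamped to >= 1 bp.  Groups without at least two
#' usable anchors yield an absent interval (`NA`), flagged in the
#' `phys_status` column.
#'
#' @param mqtls MQTL `data.frame` ([extractMQTLs()]).
#' @param consensus a [ConsensusMap-class] carrying bp anchors.
#' @return `mqtls` with added columns `phys_chrom`, `phys_start`,
#'   `phys_end` (1-based inclusive bp) and `phys_status`.
#' @export
mqtlPhysicalInterval <- function(mqtls, consensus) {
  cons <- markers(consensus)
  mqtls$phys_chrom <- mqtls$linkage_group
  mqtls$phys_start <- NA_real_
  mqtls$phys_end <- NA_real_
  mqtls$phys_status <- "ok"
  for (i in seq_len(nrow(mqtls))) {
    cg <- cons[cons$group == mqtls$linkage_group[i] & !is.na(cons$bp), ,
      drop = FALSE]
    if (nrow(cg) < 2) {
      mqtls$phys_status[i] <- "no anchors on group"
      next
    }
    r <- tryCatch(
      geneticToPhysical(c(mqtls$ci_start[i], mqtls$ci_end[i]), cg$cM,
        cg$bp),
      error = function(e) NULL)
    if (is.null(r)) {
      mqtls$phys_status[i] <- "degenerate anchors"
      next
    }
    ends <- sort(pmax(1, r$value))
    mqtls$phys_start[i] <- ends[1]
    mqtls$phys_end[i] <- ends[2]
    if (any(r$extrapolated)) mqtls$phys_status[i] <- "extrapolated"
  }
  mqtls
}

intervalsToGRanges <- function(df, names = NULL) {
  keep <- !is.na(df$start) & !is.na(df$end)
  df <- df[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chromosome,
    IRanges::IRanges(start = df$start, end = df$end))
  if (!is.null(names)) names(gr) <- names[keep]
  gr
}

#' Overlap domains between two sets of physical intervals
#'
#' Computes every pairwise intersection (>= 1 bp) between the intervals of
#' two traits' MQTLs, merges intersections that themselves overlap, and
#' reports the contributing interval names on both sides.  Symmetric in its
#' arguments.
#'
#' @param set_a,set_b `data.frame`s with columns `chromosome`, `start`,
#'   `end` (1-based inclusive) and optionally `name`.
#' @return `data.frame` of merged overlap domains: chromosome, start, end,
#'   `names_a`, `names_b` (comma-separated contributors).  Zero rows when
#'   disjoint.
#' @export
overlapDomains <- function(set_a, set_b) {
  nmA <- if ("name" %in% names(set_a)) set_a$name else
    paste0("A", seq_len(nrow(set_a)))
  nmB <- if ("name" %in% names(set_b)) set_b$name else
    paste0("B", seq_len(nrow(set_b)))
  grA <- intervalsToGRanges(set_a, nmA)
  grB <- intervalsToGRanges(set_b, nmB)
  empty <- data.frame(chromosome = character(), start = numeric(),
    end = numeric(), names_a = character(), names_b = character())
  if (!length(grA) || !length(grB)) return(empty)
  lev <- union(GenomicRanges::seqnames(GenomicRanges::seqinfo(grA)),
    GenomicRanges::seqnames(GenomicRanges::seqinfo(grB)))
  GenomeInfoDb::seqlevels(grA) <- as.character(lev)
  GenomeInfoDb::seqlevels(grB) <- as.character(lev)
  hits <- GenomicRanges::findOverlaps(grA, grB, minoverlap = 1L)
  if (!length(hits)) return(empty)
  inter <- GenomicRanges::pintersect(grA[S4Vectors::queryHits(hits)],
    grB[S4Vectors::subjectHits(hits)])
  merged <- GenomicRanges::reduce(inter)
  ovA <- GenomicRanges::findOverlaps(merged, grA)
  ovB <- GenomicRanges::findOverlaps(merged, grB)
  collectNames <- function(ov, nm) {
    out <- rep("", length(merged))
    sp <- split(nm[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
    out[as.integer(names(sp))] <-
      vapply(sp, function(x) paste(unique(x), collapse = ","), character(1))
    out
  }
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    names_a = collectNames(ovA, names(grA)),
    names_b = collectNames(ovB, names(grB)),
    stringsAsFactors = FALSE)
}
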