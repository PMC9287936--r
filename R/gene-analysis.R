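#' Read gene models from a GFF3 annotation
#'
#' Thin wrapper over [rtracklayer::import()] returning one `GRanges` entry
#' per gene feature, named by gene identifier (`ID`/`gene_id`/`Name`,
#' whichever is present).
#'
#' @param path GFF3 file.
#' @param feature_type feature rows to keep (`"gene"`).
#' @return `GRanges` of genes.
#' @export
readGeneAnnotation <- function(path, feature_type = "gene") {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == feature_type]
  ids <- if (!is.null(genes$ID)) genes$ID else if (!is.null(genes$gene_id))
    genes$gene_id else genes$Name
  names(genes) <- as.character(ids)
  genes
}

#' Candidate genes inside a physical interval
#'
#' Returns the genes whose span overlaps the query interval by at least one
#' bp (inclusive rule, not full containment), sorted by start coordinate.
#' An interval on a chromosome absent from the annotation returns an empty
#' result with a warning.
#'
#' @param genes `GRanges` of gene models (see [readGeneAnnotation()]).
#' @param chromosome,start,end the query interval, 1-based inclusive bp.
#' @return `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` in coordinate order.
#' @export
genesInInterval <- function(genes, chromosome, start, end) {
  empty <- data.frame(gene_id = character(), chromosome = character(),
    start = integer(), end = integer(), strand = character())
  if (!chromosome %in% as.character(unique(GenomicRanges::seqnames(genes)))) {
    warning("chromosome ", chromosome, " absent from annotation")
    return(empty)
  }
  q <- GenomicRanges::GRanges(chromosome,
    IRanges::IRanges(start = start, end = end))
  hit <- IRanges::subsetByOverlaps(genes, q, minoverlap = 1L)
  hit <- hit[order(GenomicRanges::start(hit))]
  data.frame(gene_id = names(hit),
    chromosome = as.character(GenomicRanges::seqnames(hit)),
    start = GenomicRanges::start(hit), end = GenomicRanges::end(hit),
    strand = as.character(GenomicRanges::strand(hit)),
    stringsAsFactors = FALSE)
}

#' Intersect two candidate-gene lists
#'
#' Set intersection keeping the order of the first list (used e.g. to
#' compare MQTL candidate genes with genes reported by GWAS).
#'
#' @param a,b character vectors of gene identifiers.
#' @return Common identifiers, ordered as in `a`.
#' @export
intersectGeneLists <- function(a, b) {
  unique(a[a %in% b])
}

#' GO-term enrichment of a candidate-gene set
#'
#' For each term annotated in the population, the one-sided hypergeometric
#' upper-tail probability \eqn{P(X \ge k)} of observing `k` term-carrying
#' genes in the study set is computed (parameters: population size,
#' population term count, study size).  A term is called enriched when its
#' raw P-value is below `threshold`; no multiple-testing correction is
#' applied by default (an optional Benjamini-Hochberg adjusted call is
#' reported alongside when `bh = TRUE`).
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of background gene ids.
#' @param annotation `data.frame` with columns `gene_id`, `term`
#'   (one row per gene-term pair); genes without rows carry no terms.
#' @param threshold enrichment call threshold on the raw P-value (0.01).
#' @param bh also compute Benjamini-Hochberg adjusted P-values (`FALSE`).
#' @return `data.frame` per term: `term`, `study_count`, `study_size`,
#'   `population_count`, `population_size`, `p_value`, `enriched`
#'   (+ `p_adjusted`, `enriched_bh` when `bh`), sorted by `p_value`.
#' @export
goEnrichment <- function(study, population, annotation, threshold = 0.01,
    bh = FALSE) {
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population))
    stop("study genes must be a subset of the population")
  ann <- annotation[annotation$gene_id %in% population, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term")])
  terms <- unique(ann$term)
  N <- length(population); n <- length(study)
  res <- lapply(terms, function(tm) {
    carriers <- ann$gene_id[ann$term == tm]
    K <- length(carriers)
    k <- sum(study %in% carriers)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, study_count = k, study_size = n,
      population_count = K, population_size = N, p_value = p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(term = character(), study_count = integer(),
      study_size = integer(), population_count = integer(),
      population_size = integer(), p_value = numeric())
  out$enriched <- out$p_value < threshold
  if (bh) {
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
    out$enriched_bh <- out$p_adjusted < threshold
  }
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Max-normalise an FPKM expression profile
#'
#' Divides each gene's expression values by the gene's maximum FPKM across
#' the time course, giving values in [0, 1] with the maximum exactly 1.
#' All-zero profiles are left unnormalised and flagged.
#'
#' @param values numeric FPKM values over the time course.
#' @return list with `normalized` values and `expressed` flag
#'   (`max(values) > 0`).
#' @export
normalizeProfile <- function(values) {
  mx <- max(values)
  if (mx <= 0) return(list(normalized = values, expressed = FALSE))
  list(normalized = values / mx, expressed = TRUE)
}

#' Classify an expression profile into a developmental window
#'
#' Grain expression time courses (days after pollination, DAP) are
#' summarised into the windows before `boundaries[1]` DAP ("early"),
#' between the boundaries ("mid") and after `boundaries[2]` DAP ("late").
#' After max-normalisation, a window is called high when its mean
#' normalised value is at least `high_threshold`.  Categories: `early`,
#' `mid`, `late`, `early_and_late` (high at both ends, low in between),
#' `mid_other` (any other high-window combination), or `not_expressed`
#' when the profile maximum is below `min_fpkm`.
#'
#' @param values FPKM values.
#' @param timepoints matching DAP values (typically 0-38; values outside
#'   that range are accepted with a warning).
#' @param boundaries the two window boundaries in DAP, default `c(10, 30)`.
#' @param min_fpkm minimum peak FPKM to call a gene expressed (1).
#' @param high_threshold mean normalised expression needed to call a
#'   window high (0.5).
#' @return single string: the window category.
#' @export
classifyExpressionWindow <- function(values, timepoints,
    boundaries = c(10, 30), min_fpkm = 1, high_threshold = 0.5) {
  stopifnot(length(values) == length(timepoints), length(boundaries) == 2)
  if (any(timepoints < 0 | timepoints > 38))
    warning("timepoints outside the 0-38 DAP grain time course")
  if (max(values) < min_fpkm) return("not_expressed")
  norm <- normalizeProfile(values)$normalized
  win <- cut(timepoints, c(-Inf, boundaries[1], boundaries[2], Inf),
    labels = c("early", "mid", "late"), right = FALSE)
  means <- tapply(norm, win, mean)
  high <- names(means)[!is.na(means) & means >= high_threshold]
  if (identical(high, "early")) return("early")
  if (identical(high, "mid")) return("mid")
  if (identical(high, "late")) return("late")
  if (setequal(high, c("early", "late"))) return("early_and_late")
  "mid_other"
}

#' Classify every gene in an FPKM matrix
#'
#' @param fpkm numeric matrix, genes x timepoints; column names are DAP
#'   values.
#' @param ... passed to [classifyExpressionWindow()].
#' @return `data.frame` with `gene_id`, `category`, `max_fpkm`.
#' @export
classifyExpressionMatrix <- function(fpkm, ...) {
  dap <- as.numeric(colnames(fpkm))
  stopifnot(!anyNA(dap))
  data.frame(gene_id = rownames(fpkm),
    category = apply(fpkm, 1, classifyExpressionWindow, timepoints = dap,
      ...),
    max_fpkm = apply(fpkm, 1, max), stringsAsFactors = FALSE)
}
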