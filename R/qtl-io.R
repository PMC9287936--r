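POP_TYPES <- c("F2", "F2_3", "F3_4", "BC", "TC", "RIL", "DH", "other")
TRAITS <- c("GDR", "GWC")

#' Read the experiment metadata table
#'
#' One row per mapping experiment (the unit of the >= 2-experiment support
#' filter): identifier, parents, population type, population size N (used by
#' the confidence-interval imputation formulas), number of environments and
#' mapping method.
#'
#' @param path TSV with header columns `experiment_id`, `parents`,
#'   `population_type`, `population_size`, `n_environments`,
#'   `mapping_method`.
#' @return `data.frame` of experiment metadata.
#' @export
readExperimentTable <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character",
    check.names = FALSE)
  need <- c("experiment_id", "population_type", "population_size")
  if (!all(need %in% names(df)))
    stop("experiment table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$experiment_id))
    stop("duplicate experiment_id in ", path)
  df$population_size <- as.integer(df$population_size)
  if (any(is.na(df$population_size) | df$population_size < 2))
    stop("population_size must be an integer >= 2")
  bad <- setdiff(unique(df$population_type), POP_TYPES)
  if (length(bad))
    stop("unknown population_type: ", paste(bad, collapse = ", "))
  for (col in c("parents", "n_environments", "mapping_method"))
    if (!col %in% names(df)) df[[col]] <- NA
  if (!all(is.na(df$n_environments)))
    df$n_environments <- as.integer(df$n_environments)
  df
}

numOrNA <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
chrOrNA <- function(x) ifelse(nzchar(x), x, NA_character_)

#' Read a table of published QTLs
#'
#' Reads QTL records and validates them against the record contract: each
#' accepted QTL must carry at least one usable localisation — a CI pair,
#' a pair of flanking markers, or an R-squared together with the population
#' size of a known experiment (so the CI can be imputed).  Records failing
#' that rule are not dropped silently: they are returned in a `rejected`
#' table with a reason, mirroring the removal of under-documented QTLs
#' before meta-analysis.
#'
#' @param path TSV with header columns `qtl_id`, `trait`, `experiment_id`,
#'   `linkage_group` and any of `peak_cM`, `ci_start`, `ci_end`,
#'   `flank_left`, `flank_right`, `lod`, `r_squared`, `coord_system`.
#'   Empty cells are missing values.  `r_squared` given in percent (> 1)
#'   is rescaled to a fraction with a warning.
#' @param experiments experiment table from [readExperimentTable()]; every
#'   `experiment_id` in the QTL table must appear there.
#' @return list with elements `qtls` (accepted records) and `rejected`
#'   (records plus a `reason` column).
#' @export
readQTLTable <- function(path, experiments) {
  df <- read.delim(path, sep = "\t", colClasses = "character",
    check.names = FALSE)
  need <- c("qtl_id", "trait", "experiment_id", "linkage_group")
  if (!all(need %in% names(df)))
    stop("QTL table must have columns ", paste(need, collapse = ", "))
  opt <- c("peak_cM", "ci_start", "ci_end", "flank_left", "flank_right",
    "lod", "r_squared", "coord_system")
  for (col in opt) if (!col %in% names(df)) df[[col]] <- ""
  qtls <- data.frame(
    qtl_id = df$qtl_id, trait = df$trait, experiment_id = df$experiment_id,
    linkage_group = df$linkage_group,
    peak_cM = numOrNA(df$peak_cM),
    ci_start = numOrNA(df$ci_start), ci_end = numOrNA(df$ci_end),
    flank_left = chrOrNA(df$flank_left), flank_right = chrOrNA(df$flank_right),
    lod = numOrNA(df$lod), r_squared = numOrNA(df$r_squared),
    coord_system = ifelse(nzchar(df$coord_system), df$coord_system,
      "genetic"),
    stringsAsFactors = FALSE)
  validateQTLs(qtls, experiments)
}

#' Validate in-memory QTL records
#'
#' Core validation shared by [readQTLTable()]: enforces hard invariants
#' (errors) and splits records into accepted and rejected-with-reason.
#'
#' @param qtls QTL `data.frame` in the [readQTLTable()] schema.
#' @param experiments experiment metadata table.
#' @return list(`qtls`, `rejected`) as in [readQTLTable()].
#' @export
validateQTLs <- function(qtls, experiments) {
  if (anyDuplicated(qtls$qtl_id))
    stop("duplicate qtl_id")
  bad <- setdiff(unique(qtls$trait), TRAITS)
  if (length(bad)) stop("unknown trait: ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(qtls$experiment_id), experiments$experiment_id)
  if (length(unknown))
    stop("QTL table references unknown experiment_id: ",
      paste(unknown, collapse = ", "))
  both <- !is.na(qtls$ci_start) & !is.na(qtls$ci_end)
  if (any(both & qtls$ci_start > qtls$ci_end))
    stop("ci_start > ci_end for: ",
      paste(qtls$qtl_id[both & qtls$ci_start > qtls$ci_end], collapse = ", "))
  if (any(!is.na(qtls$r_squared) & qtls$r_squared > 1)) {
    warning("r_squared > 1 interpreted as percent and rescaled to fraction")
    idx <- !is.na(qtls$r_squared) & qtls$r_squared > 1
    qtls$r_squared[idx] <- qtls$r_squared[idx] / 100
  }
  if (any(!is.na(qtls$r_squared) & qtls$r_squared <= 0))
    stop("r_squared must lie in (0, 1]")

  hasCI <- both
  hasFlanks <- !is.na(qtls$flank_left) & !is.na(qtls$flank_right)
  hasFormula <- !is.na(qtls$r_squared)  # N guaranteed by experiment join
  ok <- hasCI | hasFlanks | hasFormula
  rejected <- qtls[!ok, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- "insufficient information (no CI, flanks or R2)"
  else rejected$reason <- character(0)
  rownames(rejected) <- rownames(qtls) <- NULL
  list(qtls = qtls[ok, , drop = FALSE], rejected = rejected)
}

#' Write a QTL table
#'
#' Inverse of [readQTLTable()]: writes accepted QTL records back to the
#' canonical TSV schema (empty cells for missing values), so that
#' read -> write -> read round-trips on all fields.
#'
#' @param qtls QTL `data.frame` in the [readQTLTable()] schema.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeQTLTable <- function(qtls, path) {
  cols <- c("qtl_id", "trait", "experiment_id", "linkage_group", "peak_cM",
    "ci_start", "ci_end", "flank_left", "flank_right", "lod", "r_squared",
    "coord_system")
  write.table(qtls[intersect(cols, names(qtls))], path, sep = "\t",
    quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the MQTL summary table
#'
#' Columns mirror the published MQTL summary: name, linkage group,
#' consensus position and 95% CI in cM, PVE in percent, physical interval
#' endpoints in bp, and the member-QTL / candidate-gene / supporting
#' experiment counts.  MQTLs without a resolved physical interval are
#' written with empty bp fields (never zeros).
#'
#' @param mqtls MQTL `data.frame` from [extractMQTLs()] /
#'   [mqtlPhysicalInterval()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeMQTLTable <- function(mqtls, path) {
  cols <- c("name", "linkage_group", "position", "pve_percent", "ci_width",
    "ci_start", "ci_end", "phys_start", "phys_end", "n_qtls", "n_genes",
    "n_experiments")
  out <- data.frame(matrix(nrow = nrow(mqtls), ncol = 0))
  for (col in cols)
    out[[col]] <- if (col %in% names(mqtls)) mqtls[[col]] else NA
  names(out) <- c("MQTL", "Chromosome", "Position_cM", "PVE_percent",
    "CI_cM", "CI_start_cM", "CI_end_cM", "Left_Physical_Position_bp",
    "Right_Physical_Position_bp", "QTL_Integrated", "N_Genes",
    "N_Experiments_Involved")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "")
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Internal intervals are 1-based inclusive; BED is 0-based half-open, so
#' `start_bed = start - 1` and `end_bed = end`.
#'
#' @param intervals `data.frame` with columns `chromosome`, `start`, `end`
#'   (1-based inclusive) and optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBED <- function(intervals, path) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(intervals)))
  keep <- !is.na(intervals$start) & !is.na(intervals$end)
  intervals <- intervals[keep, , drop = FALSE]
  if (nrow(intervals) && any(intervals$start < 1 |
      intervals$start > intervals$end))
    stop("intervals must satisfy 1 <= start <= end")
  bed <- data.frame(chrom = intervals$chromosome,
    start = format(intervals$start - 1, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(intervals)) bed$name <- intervals$name
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}
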