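#' Read an FPKM expression matrix
#'
#' @param path TSV: first column `gene_id`, remaining columns one per
#'   timepoint, named by DAP value.
#' @return numeric matrix, genes x timepoints.
#' @export
readFPKM <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a gene-to-GO-term table
#'
#' @param path TSV with columns `gene_id` and `term`.
#' @return `data.frame`.
#' @export
readGeneGO <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  stopifnot(all(c("gene_id", "term") %in% names(df)))
  df
}

#' Run the full meta-QTL pipeline from a configuration
#'
#' Orchestrates every stage for one or both traits: read inputs, impute
#' missing LODs, build the consensus map, project the QTLs, cluster each
#' linkage group with AIC-selected variance-weighted mixtures, filter by
#' experiment support, anchor the surviving MQTLs physically, extract
#' candidate genes, run GO enrichment and expression-window classification,
#' and (when both traits are run) compute the trait-pair overlap domains.
#' Every artifact is written under `out_dir`, and a run log records each
#' dropped marker and QTL with its reason, plus the stage-by-stage counts.
#'
#' @param config either a named list or the path of a YAML file with keys:
#'   `reference_map`, `experiments`, `qtls` (paths); `study_maps` (named
#'   list experiment_id -> map path, or a directory containing
#'   `map_<experiment_id>.tsv` files); optional `annotation` (GFF3),
#'   `fpkm`, `gene_go` (paths); `traits` (default both present in the QTL
#'   table); `k_max` (10), `min_experiments` (2), `max_extrapolation`
#'   (0.2), `go_threshold` (0.01), `out_dir`.
#' @return Invisibly, a named list of per-trait results (`consensus`,
#'   `projected`, `discarded`, `mqtls_all`, `mqtls`, `genes`, `enrichment`,
#'   `expression`) plus `overlap` when both traits were run.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- function(key, default = NULL)
    if (!is.null(config[[key]])) config[[key]] else default
  outDir <- cfg("out_dir", stop("config must set out_dir"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, sprintf(...))

  for (key in c("reference_map", "experiments", "qtls"))
    if (!file.exists(cfg(key, "")))
      stop("missing input file for '", key, "': ", cfg(key, "<unset>"))

  reference <- readGeneticMap(cfg("reference_map"), "reference")
  experiments <- readExperimentTable(cfg("experiments"))
  qres <- readQTLTable(cfg("qtls"), experiments)
  note("input QTLs: %d accepted, %d rejected (insufficient information)",
    nrow(qres$qtls), nrow(qres$rejected))
  qtls <- applyLODDefault(qres$qtls)

  sm <- cfg("study_maps")
  study_maps <- list()
  if (is.character(sm) && length(sm) == 1 && dir.exists(sm)) {
    for (f in list.files(sm, pattern = "^map_.*\\.tsv$", full.names = TRUE)) {
      id <- sub("^map_(.*)\\.tsv$", "\\1", basename(f))
      study_maps[[id]] <- readGeneticMap(f, id)
    }
  } else if (is.list(sm)) {
    for (id in names(sm)) study_maps[[id]] <- readGeneticMap(sm[[id]], id)
  }
  note("study maps loaded: %d", length(study_maps))

  merged <- mergeMaps(reference, study_maps)
  consensus <- merged$consensus
  note("consensus map: %d markers, %.1f cM, density %.2f markers/cM; %d marker(s) dropped in conflict resolution",
    nMarkers(consensus), mapLength(consensus)[["overall"]],
    mapDensity(consensus)[["overall"]], nrow(merged$dropped))
  writeGeneticMap(consensus, file.path(outDir, "consensus_map.tsv"))
  if (nrow(merged$dropped))
    write.table(merged$dropped, file.path(outDir, "dropped_markers.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

  traits <- cfg("traits", intersect(TRAITS, unique(qtls$trait)))
  annotation <- if (!is.null(cfg("annotation")))
    readGeneAnnotation(cfg("annotation"))
  fpkm <- if (!is.null(cfg("fpkm"))) readFPKM(cfg("fpkm"))
  geneGO <- if (!is.null(cfg("gene_go"))) readGeneGO(cfg("gene_go"))

  results <- list()
  for (tr in traits) {
    tq <- qtls[qtls$trait == tr, , drop = FALSE]
    proj <- projectQTL(tq, experiments, consensus, merged$frameworks,
      max_extrapolation = cfg("max_extrapolation", 0.2))
    note("[%s] projected %d / %d QTLs (%d discarded)", tr,
      nrow(proj$projected), nrow(tq), nrow(proj$discarded))
    for (i in seq_len(nrow(proj$discarded)))
      note("[%s] discarded %s: %s", tr, proj$discarded$qtl_id[i],
        proj$discarded$reason[i])
    meta <- metaAnalyze(proj$projected, tr, k_max = cfg("k_max", 10L))
    filt <- filterMQTLs(meta$mqtls,
      min_experiments = cfg("min_experiments", 2L))
    note("[%s] %d MQTLs before support filter, %d after (>= %d experiments)",
      tr, nrow(meta$mqtls), nrow(filt), cfg("min_experiments", 2L))
    filt <- mqtlPhysicalInterval(filt, consensus)

    genes <- NULL; enrich <- NULL; expr <- NULL
    if (!is.null(annotation)) {
      glist <- lapply(seq_len(nrow(filt)), function(i) {
        if (is.na(filt$phys_start[i])) return(NULL)
        gi <- genesInInterval(annotation, filt$phys_chrom[i],
          filt$phys_start[i], filt$phys_end[i])
        if (nrow(gi)) cbind(mqtl = filt$name[i], gi)
      })
      genes <- do.call(rbind, glist)
      filt$n_genes <- vapply(seq_len(nrow(filt)), function(i)
        if (is.null(genes)) 0L else sum(genes$mqtl == filt$name[i]),
        integer(1))
      note("[%s] candidate genes: %d (over %d MQTLs)", tr,
        if (is.null(genes)) 0L else nrow(genes), nrow(filt))
      if (!is.null(geneGO) && !is.null(genes)) {
        enrich <- goEnrichment(unique(genes$gene_id), names(annotation),
          geneGO, threshold = cfg("go_threshold", 0.01))
        note("[%s] enriched GO terms (P < %.3g): %d", tr,
          cfg("go_threshold", 0.01), sum(enrich$enriched))
      }
      if (!is.null(fpkm) && !is.null(genes)) {
        sel <- intersect(unique(genes$gene_id), rownames(fpkm))
        expr <- classifyExpressionMatrix(fpkm[sel, , drop = FALSE])
      }
    }

    pre <- file.path(outDir, tolower(tr))
    write.table(proj$projected, paste0(pre, "_projected_qtls.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(proj$discarded, paste0(pre, "_discarded_qtls.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(meta$profiles, paste0(pre, "_aic_profiles.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeMQTLTable(meta$mqtls, paste0(pre, "_mqtls_all.tsv"))
    writeMQTLTable(filt, paste0(pre, "_mqtls_filtered.tsv"))
    writeBED(data.frame(chromosome = filt$phys_chrom,
      start = filt$phys_start, end = filt$phys_end, name = filt$name),
      paste0(pre, "_mqtls.bed"))
    if (!is.null(genes))
      write.table(genes, paste0(pre, "_candidate_genes.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    if (!is.null(enrich))
      write.table(enrich, paste0(pre, "_go_enrichment.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    if (!is.null(expr))
      write.table(expr, paste0(pre, "_expression_categories.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    results[[tr]] <- list(consensus = consensus, projected = proj$projected,
      discarded = proj$discarded, mqtls_all = meta$mqtls, mqtls = filt,
      profiles = meta$profiles, genes = genes, enrichment = enrich,
      expression = expr)
  }

  if (all(c("GDR", "GWC") %in% names(results))) {
    a <- results$GDR$mqtls; b <- results$GWC$mqtls
    ov <- overlapDomains(
      data.frame(chromosome = a$phys_chrom, start = a$phys_start,
        end = a$phys_end, name = a$name),
      data.frame(chromosome = b$phys_chrom, start = b$phys_start,
        end = b$phys_end, name = b$name))
    note("overlap domains between GDR and GWC MQTLs: %d", nrow(ov))
    write.table(ov, file.path(outDir, "overlap_domains.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    writeBED(ov, file.path(outDir, "overlap_domains.bed"))
    results$overlap <- ov
  }
  writeLines(logLines, logPath)
  invisible(results)
}
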