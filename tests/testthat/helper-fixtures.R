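# Small in-code fixtures shared across test files.

toyMap <- function(id = "ref", markers = NULL) {
  if (is.null(markers))
    markers <- data.frame(
      marker = c("A", "B", "C", "D"), group = "2",
      cM = c(0, 20, 40, 60), bp = c(1e6, 5e6, 9e6, 13e6))
  GeneticMap(id, markers)
}

toyExperiments <- function() {
  data.frame(
    experiment_id = c("e1", "e2", "e3"),
    parents = "X x Y",
    population_type = c("F2", "RIL", "RIL"),
    population_size = c(400L, 258L, 265L),
    n_environments = 2L,
    mapping_method = "CIM",
    stringsAsFactors = FALSE)
}

emptyQTLRow <- function(...) {
  base <- list(qtl_id = "q1", trait = "GDR", experiment_id = "e1",
    linkage_group = "2", peak_cM = NA_real_, ci_start = NA_real_,
    ci_end = NA_real_, flank_left = NA_character_,
    flank_right = NA_character_, lod = NA_real_, r_squared = NA_real_,
    coord_system = "genetic")
  mod <- list(...)
  base[names(mod)] <- mod
  as.data.frame(base, stringsAsFactors = FALSE)
}

writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "")
  path
}

# minimal hand-written GFF3 gene annotation
writeToyGFF3 <- function(path, genes) {
  lines <- c("##gff-version 3",
    sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chromosome, genes$start, genes$end, genes$strand,
      genes$gene_id))
  writeLines(lines, path)
  path
}
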