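#' Define a synthetic meta-QTL simulation scenario
#'
#' A scenario fixes every knob of the generator and carries the planted
#' ground truth (true meta-QTL positions and member counts per trait and
#' linkage group), so that downstream accuracy — K-selection rate, position
#' error, CI coverage, gene recovery — is computable exactly.  All
#' randomness derives from `seed` through a private generator; the caller's
#' RNG state is never touched.
#'
#' True MQTL positions are drawn per group with pairwise separation at
#' least `separation_factor * max(qtl_sigma_range)` (relaxed geometrically
#' when the group is too short to hold them), each with at least
#' `members_range[1]` member QTLs.
#'
#' @param seed integer master seed.
#' @param n_chromosomes number of linkage groups (10).
#' @param ref_markers_per_group reference markers per group (100).
#' @param group_length genetic length of each group in cM (150).
#' @param chrom_size_bp physical chromosome size in bp (2e8).
#' @param n_experiments number of simulated mapping experiments (25).
#' @param traits traits simulated (`c("GDR", "GWC")`).
#' @param n_mqtl_range true MQTLs per group per trait (`c(2, 4)`).
#' @param members_range member QTLs per true MQTL (`c(4, 8)`).
#' @param total_qtls optional named total QTL counts per trait (e.g.
#'   `c(GDR = 87, GWC = 195)`); member counts are then rescaled to hit the
#'   totals exactly.
#' @param qtl_sigma_range per-QTL positional standard deviation range in cM
#'   (`c(1, 3)`; the 95% CI width is 3.92 sigma).
#' @param r2_range per-QTL explained-variance range (`c(0.05, 0.3)`).
#' @param popsize_range mapping-population sizes (`c(80, 400)`).
#' @param shared_marker_fraction fraction of reference markers present on
#'   each study map (0.5).
#' @param map_distortion multiplicative jitter amplitude on study-map
#'   inter-marker distances (0.05).
#' @param missing_ci_fraction fraction of QTLs published without a CI,
#'   which must be imputed from N and R-squared (0).
#' @param missing_lod_fraction fraction published without a LOD (0.3).
#' @param experiment_kinds unnormalised proportions of experiment kinds:
#'   `mapped` (full study linkage map), `flanks` (no map; QTLs given by
#'   flanking markers of the reference map) and `physical` (SNP studies;
#'   QTL endpoints in bp).
#' @param separation_factor minimum true-MQTL separation in units of the
#'   maximum sigma (5).
#' @param genes_per_group gene models tiled per chromosome (60).
#' @return A `list` of class `"SimulationScenario"` including the
#'   `$truth` table (trait, group, mqtl_id, position, n_members).
#' @export
simulationScenario <- function(seed, n_chromosomes = 10L,
    ref_markers_per_group = 100L, group_length = 150,
    chrom_size_bp = 2e8, n_experiments = 25L, traits = c("GDR", "GWC"),
    n_mqtl_range = c(2L, 4L), members_range = c(4L, 8L),
    total_qtls = NULL, qtl_sigma_range = c(1, 3),
    r2_range = c(0.05, 0.3), popsize_range = c(80L, 400L),
    shared_marker_fraction = 0.5, map_distortion = 0.05,
    missing_ci_fraction = 0, missing_lod_fraction = 0.3,
    experiment_kinds = c(mapped = 1, flanks = 0, physical = 0),
    separation_factor = 5, genes_per_group = 60L) {
  stopifnot(ref_markers_per_group >= 2, group_length > 0,
    n_chromosomes >= 1, diff(qtl_sigma_range) >= 0, diff(r2_range) >= 0,
    r2_range[1] > 0, r2_range[2] <= 1,
    shared_marker_fraction > 0, shared_marker_fraction <= 1,
    missing_ci_fraction >= 0, missing_ci_fraction <= 1,
    missing_lod_fraction >= 0, missing_lod_fraction <= 1)
  sc <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    ref_markers_per_group = as.integer(ref_markers_per_group),
    group_length = group_length, chrom_size_bp = chrom_size_bp,
    n_experiments = as.integer(n_experiments), traits = traits,
    n_mqtl_range = n_mqtl_range, members_range = members_range,
    qtl_sigma_range = qtl_sigma_range, r2_range = r2_range,
    popsize_range = popsize_range,
    shared_marker_fraction = shared_marker_fraction,
    map_distortion = map_distortion,
    missing_ci_fraction = missing_ci_fraction,
    missing_lod_fraction = missing_lod_fraction,
    experiment_kinds = experiment_kinds,
    separation_factor = separation_factor,
    genes_per_group = as.integer(genes_per_group))
  sc$truth <- withPrivateSeed(seedFromValues(seed, 11L),
    planTruth(sc, total_qtls))
  class(sc) <- "SimulationScenario"
  sc
}

# draw true MQTL positions and member counts for every trait x group
planTruth <- function(sc, total_qtls) {
  L <- sc$group_length
  minsep <- sc$separation_factor * max(sc$qtl_sigma_range)
  rows <- list()
  for (tr in sc$traits) {
    for (g in seq_len(sc$n_chromosomes)) {
      nm <- sampleFrom(seq(sc$n_mqtl_range[1], sc$n_mqtl_range[2]), 1)
      sep <- minsep
      repeat {
        if ((nm - 1) * sep <= 0.8 * L) break
        sep <- sep / 2
        if (sep < 1e-3) break
      }
      pos <- numeric(0)
      for (attempt in seq_len(500)) {
        cand <- runif(1, 0.05 * L, 0.95 * L)
        if (!length(pos) || min(abs(pos - cand)) >= sep)
          pos <- c(pos, cand)
        if (length(pos) == nm) break
      }
      pos <- sort(pos)
      members <- sampleFrom(seq(sc$members_range[1], sc$members_range[2]),
        length(pos), replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(trait = tr,
        group = as.character(g),
        mqtl_id = sprintf("true_%s_%d_%d", tr, g, seq_along(pos)),
        position = pos, n_members = members, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  if (!is.null(total_qtls)) {
    for (tr in names(total_qtls)) {
      idx <- which(truth$trait == tr)
      target <- total_qtls[[tr]]
      base <- pmax(2L, truth$n_members[idx])
      # proportional rescale, then fix the remainder one by one
      n <- pmax(2L, as.integer(round(base * target / sum(base))))
      diffn <- target - sum(n)
      j <- 1L
      while (diffn != 0) {
        step <- sign(diffn)
        if (n[j] + step >= 2L) { n[j] <- n[j] + step; diffn <- diffn - step }
        j <- if (j == length(n)) 1L else j + 1L
      }
      truth$n_members[idx] <- n
    }
  }
  truth
}

#' A scenario emulating the published study's scale
#'
#' Ten linkage groups of roughly reference-map length, 25 experiments of
#' mixed population types and kinds (full study maps, flank-only studies,
#' SNP studies with physical coordinates), 282 QTLs (87 GDR + 195 GWC)
#' with wide dispersion of CI widths (sigma up to 40 cM; additional width
#' from formula-imputed CIs over R-squared 1-90%) and 35% of CIs missing.
#'
#' @param seed integer master seed.
#' @return A `SimulationScenario`.
#' @export
paperScenario <- function(seed) {
  simulationScenario(seed, n_chromosomes = 10L,
    ref_markers_per_group = 120L, group_length = 800, chrom_size_bp = 2.3e8,
    n_experiments = 25L, traits = c("GDR", "GWC"),
    n_mqtl_range = c(2L, 5L), members_range = c(2L, 10L),
    total_qtls = c(GDR = 87L, GWC = 195L),
    qtl_sigma_range = c(0.5, 40), r2_range = c(0.01, 0.9),
    popsize_range = c(80L, 400L), shared_marker_fraction = 0.35,
    map_distortion = 0.08, missing_ci_fraction = 0.35,
    missing_lod_fraction = 0.4,
    experiment_kinds = c(mapped = 14, flanks = 9, physical = 2),
    separation_factor = 5, genes_per_group = 80L)
}

#' Simulate a reference linkage map with physical anchors
#'
#' Markers are uniformly spaced with jitter along each group; physical
#' positions follow a monotone cubic cM -> bp map (Hyman-filtered spline
#' through random monotone control points), guaranteeing invertibility of
#' the genetic/physical interpolation.
#'
#' @param scenario a `SimulationScenario`.
#' @return A [GeneticMap-class] with `bp` set for every marker.
#' @export
simulateReferenceMap <- function(scenario) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  if (scenario$ref_markers_per_group < 1) stop("need >= 1 marker per group")
  withPrivateSeed(seedFromValues(scenario$seed, 23L), {
    n <- scenario$ref_markers_per_group
    L <- scenario$group_length
    rows <- lapply(seq_len(scenario$n_chromosomes), function(g) {
      cm <- seq(0, L, length.out = n) +
        c(0, runif(n - 2, -0.3, 0.3) * L / n, 0)
      cm <- sort(pmin(pmax(cm, 0), L))
      # monotone cubic cM -> bp through 6 random increasing control points
      kx <- seq(0, L, length.out = 6)
      ky <- cumsum(runif(6, 0.5, 1.5))
      ky <- 1 + (ky - ky[1]) / (ky[6] - ky[1]) * (scenario$chrom_size_bp - 1)
      f <- splinefun(kx, ky, method = "hyman")
      bp <- round(f(cm))
      bp <- cummax(bp + seq_along(bp))  # strictly increasing, >= 1
      data.frame(marker = sprintf("c%d_m%04d", g, seq_len(n)),
        group = as.character(g), cM = cm, bp = bp,
        stringsAsFactors = FALSE)
    })
    GeneticMap("reference", do.call(rbind, rows))
  })
}

# piecewise ref->study warp for one group of one study map
warpPositions <- function(ref_cM, distortion) {
  gaps <- diff(c(0, ref_cM))
  cumsum(gaps * runif(length(gaps), 1 - distortion, 1 + distortion))
}

#' Simulate mapping experiments, study maps and QTL tables
#'
#' Generates, per experiment: metadata (population type, size, mapping
#' method), a study map (for "mapped" experiments: a
#' `shared_marker_fraction` subset of the reference with smoothly jittered
#' cM positions), and QTL records.  Each QTL's true peak is drawn
#' `Normal(true MQTL position, sigma_i)` on the reference scale with
#' `sigma_i` uniform over `qtl_sigma_range`, its 95% CI is
#' `peak +/- 1.96 sigma_i`, and the record is expressed in the experiment's
#' own coordinates (warped study map, flanking reference markers, or bp for
#' SNP studies).  Per the missing-data settings, CIs and LODs are blanked;
#' blanked CIs carry an R-squared consistent with the population-size
#' formula so imputation is exercised.
#'
#' @param scenario a `SimulationScenario`.
#' @param reference the map from [simulateReferenceMap()].
#' @return list: `experiments` (metadata `data.frame`), `study_maps`
#'   (named list of [GeneticMap-class], mapped experiments only), `qtls`
#'   (QTL table in the [readQTLTable()] schema), `truth` (per-QTL true
#'   MQTL id, true position and sigma), `study_of` (named map_id per
#'   experiment).
#' @export
simulateExperiments <- function(scenario, reference) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  truth <- scenario$truth
  refm <- markers(reference)
  if (any(truth$position > scenario$group_length | truth$position < 0))
    stop("true MQTL position outside group span")
  withPrivateSeed(seedFromValues(scenario$seed, 37L), {
    nE <- scenario$n_experiments
    kinds <- rep(names(scenario$experiment_kinds),
      round(scenario$experiment_kinds / sum(scenario$experiment_kinds) * nE))
    kinds <- c(kinds, rep("mapped", max(0, nE - length(kinds))))[seq_len(nE)]
    ptypes <- sample(c("F2", "F2_3", "F3_4", "BC", "TC", "RIL", "DH"), nE,
      replace = TRUE, prob = c(1, 2, 2, 1, 2, 4, 1))
    experiments <- data.frame(
      experiment_id = sprintf("exp%02d", seq_len(nE)),
      parents = sprintf("P%02da x P%02db", seq_len(nE), seq_len(nE)),
      population_type = ptypes,
      population_size = sampleFrom(seq(scenario$popsize_range[1],
        scenario$popsize_range[2]), nE, replace = TRUE),
      n_environments = sample(1:8, nE, replace = TRUE),
      mapping_method = sample(c("IM", "CIM", "SPA"), nE, replace = TRUE,
        prob = c(3, 6, 1)),
      kind = kinds, stringsAsFactors = FALSE)

    # study maps for mapped experiments
    study_maps <- list()
    for (e in which(kinds == "mapped")) {
      rows <- lapply(unique(refm$group), function(g) {
        rg <- refm[refm$group == g, , drop = FALSE]
        n <- nrow(rg)
        take <- sort(unique(c(1L, n,
          sample(seq_len(n), max(2, round(scenario$shared_marker_fraction * n))))))
        sg <- rg[take, , drop = FALSE]
        sg$cM <- warpPositions(sg$cM, scenario$map_distortion)
        sg$bp <- NA_integer_
        sg
      })
      study_maps[[experiments$experiment_id[e]]] <-
        GeneticMap(experiments$experiment_id[e], do.call(rbind, rows))
    }

    # allocate member QTLs of every true MQTL to experiments
    qtl <- list(); qtruth <- list()
    qn <- 0L
    for (i in seq_len(nrow(truth))) {
      tr <- truth$trait[i]; grp <- truth$group[i]
      for (j in seq_len(truth$n_members[i])) {
        qn <- qn + 1L
        e <- sample(nE, 1)
        eid <- experiments$experiment_id[e]
        kind <- kinds[e]
        sig <- runif(1, scenario$qtl_sigma_range[1],
          scenario$qtl_sigma_range[2])
        peak_ref <- rnorm(1, truth$position[i], sig)
        peak_ref <- min(max(peak_ref, 0), scenario$group_length)
        ciL <- peak_ref - 1.96 * sig
        ciR <- peak_ref + 1.96 * sig
        r2 <- runif(1, scenario$r2_range[1], scenario$r2_range[2])
        lod <- if (runif(1) < scenario$missing_lod_fraction) NA_real_ else
          round(runif(1, 2.5, 15), 2)
        rg <- refm[refm$group == grp, , drop = FALSE]
        rec <- data.frame(qtl_id = sprintf("q%04d", qn), trait = tr,
          experiment_id = eid, linkage_group = grp,
          peak_cM = NA_real_, ci_start = NA_real_, ci_end = NA_real_,
          flank_left = NA_character_, flank_right = NA_character_,
          lod = lod, r_squared = r2, coord_system = "genetic",
          stringsAsFactors = FALSE)
        if (kind == "mapped") {
          sm <- markers(study_maps[[eid]])
          sg <- sm[sm$group == grp, , drop = FALSE]
          src <- rg$cM[match(sg$marker, rg$marker)]
          pr <- interpolatePiecewise(c(peak_ref, ciL, ciR), src, sg$cM)
          rec$peak_cM <- pr$value[1]
          if (runif(1) < scenario$missing_ci_fraction) {
            # CI withheld; R2 made formula-consistent with the true width
            N <- experiments$population_size[e]
            k <- unname(CI_CONSTANTS[experiments$population_type[e]])
            rec$r_squared <- min(0.95, max(0.005, k / (N * 3.92 * sig)))
          } else {
            rec$ci_start <- pr$value[2]
            rec$ci_end <- pr$value[3]
          }
        } else if (kind == "flanks") {
          below <- rg$marker[rg$cM <= ciL]
          above <- rg$marker[rg$cM >= ciR]
          rec$flank_left <- if (length(below)) tail(below, 1) else rg$marker[1]
          rec$flank_right <- if (length(above)) above[1] else
            tail(rg$marker, 1)
        } else {  # physical: SNP study, endpoints in bp
          bpv <- geneticToPhysical(c(max(0, ciL),
            min(scenario$group_length, ciR)), rg$cM, rg$bp)$value
          rec$coord_system <- "physical"
          rec$ci_start <- min(bpv); rec$ci_end <- max(bpv)
        }
        qtl[[qn]] <- rec
        qtruth[[qn]] <- data.frame(qtl_id = rec$qtl_id,
          true_mqtl = truth$mqtl_id[i], true_position = truth$position[i],
          sigma = sig, stringsAsFactors = FALSE)
      }
    }
    list(experiments = experiments, study_maps = study_maps,
      qtls = do.call(rbind, qtl), truth = do.call(rbind, qtruth),
      study_of = setNames(as.list(experiments$experiment_id),
        experiments$experiment_id))
  })
}

#' Simulate a gene annotation, FPKM time course and GO table
#'
#' Genes tile each chromosome at jittered regular bp intervals; the subset
#' falling inside the physical span of a true MQTL (its position +/- 2
#' average sigmas, converted through the reference cM -> bp map) is
#' recorded as planted.  Expression profiles over 0-38 DAP follow early /
#' mid / late / bimodal / silent templates with known labels, and one GO
#' term is planted at strongly elevated frequency among in-MQTL genes.
#'
#' @param scenario a `SimulationScenario`.
#' @param reference map from [simulateReferenceMap()].
#' @return list: `genes` (`GRanges` named by gene id, with metadata column
#'   `in_mqtl`), `fpkm` (matrix genes x DAP), `expression_labels`
#'   (named character), `go` (`data.frame` gene_id, term),
#'   `enriched_term` (string).
#' @export
simulateAnnotationAndExpression <- function(scenario, reference) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  refm <- markers(reference)
  truth <- scenario$truth
  withPrivateSeed(seedFromValues(scenario$seed, 53L), {
    rows <- list()
    sigbar <- mean(scenario$qtl_sigma_range)
    for (g in unique(refm$group)) {
      rg <- refm[refm$group == g, , drop = FALSE]
      ng <- scenario$genes_per_group
      centers <- round(seq(min(rg$bp) + 1e4, max(rg$bp) - 1e4,
        length.out = ng) + runif(ng, -5e3, 5e3))
      width <- round(runif(ng, 2e3, 6e3))
      tg <- truth[truth$group == g, , drop = FALSE]
      span <- lapply(seq_len(nrow(tg)), function(i)
        sort(geneticToPhysical(
          c(max(0, tg$position[i] - 2 * sigbar),
            min(scenario$group_length, tg$position[i] + 2 * sigbar)),
          rg$cM, rg$bp)$value))
      inm <- vapply(centers, function(p)
        any(vapply(span, function(s) p >= s[1] && p <= s[2], logical(1))),
        logical(1))
      rows[[g]] <- data.frame(
        gene_id = sprintf("Zm%s_%03d", g, seq_len(ng)), chromosome = g,
        start = pmax(1, centers - width %/% 2),
        end = centers + width %/% 2,
        strand = sample(c("+", "-"), ng, replace = TRUE),
        in_mqtl = inm, stringsAsFactors = FALSE)
    }
    gdf <- do.call(rbind, rows)
    genes <- GenomicRanges::GRanges(gdf$chromosome,
      IRanges::IRanges(gdf$start, gdf$end), strand = gdf$strand,
      in_mqtl = gdf$in_mqtl)
    names(genes) <- gdf$gene_id

    dap <- seq(0, 38, by = 2)
    template <- list(
      early = dnorm(dap, 4, 4), mid = dnorm(dap, 20, 5),
      late = dnorm(dap, 34, 4),
      early_and_late = dnorm(dap, 3, 3) + dnorm(dap, 35, 3),
      not_expressed = rep(0, length(dap)))
    labels <- sample(names(template), nrow(gdf), replace = TRUE,
      prob = c(0.3, 0.2, 0.2, 0.15, 0.15))
    fpkm <- t(vapply(seq_len(nrow(gdf)), function(i) {
      base <- template[[labels[i]]]
      if (labels[i] == "not_expressed")
        return(pmax(0, rnorm(length(dap), 0, 0.05)))
      prof <- base / max(base) * runif(1, 5, 80)
      pmax(0, prof + rnorm(length(dap), 0, 0.02 * max(prof)))
    }, numeric(length(dap))))
    dimnames(fpkm) <- list(gdf$gene_id, dap)
    names(labels) <- gdf$gene_id

    terms <- sprintf("GO:%07d", 1:12)
    enriched_term <- terms[1]
    go <- list()
    for (i in seq_len(nrow(gdf))) {
      tset <- terms[-1][runif(11) < 0.08]
      if (gdf$in_mqtl[i] && runif(1) < 0.6) tset <- c(enriched_term, tset)
      else if (runif(1) < 0.03) tset <- c(enriched_term, tset)
      if (length(tset))
        go[[length(go) + 1L]] <- data.frame(gene_id = gdf$gene_id[i],
          term = tset, stringsAsFactors = FALSE)
    }
    list(genes = genes, fpkm = fpkm, expression_labels = labels,
      go = do.call(rbind, go), enriched_term = enriched_term)
  })
}

#' Write a full synthetic input bundle to disk
#'
#' Serialises every generator output through the package's canonical
#' plain-text formats (TSV maps and tables, GFF3 annotation), so the whole
#' pipeline can be exercised from files exactly as with literature data.
#'
#' @param scenario a `SimulationScenario`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeScenarioBundle <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulateReferenceMap(scenario)
  sim <- simulateExperiments(scenario, ref)
  ann <- simulateAnnotationAndExpression(scenario, ref)
  paths <- c(reference = file.path(dir, "reference_map.tsv"),
    experiments = file.path(dir, "experiments.tsv"),
    qtls = file.path(dir, "qtls.tsv"),
    truth = file.path(dir, "qtl_truth.tsv"),
    annotation = file.path(dir, "annotation.gff3"),
    fpkm = file.path(dir, "fpkm.tsv"),
    go = file.path(dir, "gene_go.tsv"))
  writeGeneticMap(ref, paths["reference"])
  exp_out <- sim$experiments[, c("experiment_id", "parents",
    "population_type", "population_size", "n_environments",
    "mapping_method")]
  write.table(exp_out, paths["experiments"], sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  writeQTLTable(sim$qtls, paths["qtls"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
    row.names = FALSE)
  rtracklayer::export(geneGRangesToGFF(ann$genes), paths["annotation"],
    format = "gff3")
  fp <- data.frame(gene_id = rownames(ann$fpkm), ann$fpkm,
    check.names = FALSE)
  write.table(fp, paths["fpkm"], sep = "\t", quote = FALSE,
    row.names = FALSE)
  write.table(ann$go, paths["go"], sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (id in names(sim$study_maps))
    writeGeneticMap(sim$study_maps[[id]],
      file.path(dir, paste0("map_", id, ".tsv")))
  invisible(paths)
}

# GRanges of genes -> GFF3-exportable GRanges with type/ID columns
geneGRangesToGFF <- function(genes) {
  g <- genes
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(source = "maizeMQTLsim",
    type = "gene", ID = names(genes), Name = names(genes))
  g
}
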