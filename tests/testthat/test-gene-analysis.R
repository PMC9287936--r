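toyGenes <- function() {
  data.frame(
    gene_id = paste0("g", 1:5), chromosome = "2",
    start = c(100, 301, 500, 800, 1200),
    end = c(200, 400, 700, 1100, 1300),
    strand = c("+", "-", "+", "+", "-"), stringsAsFactors = FALSE)
}

test_that("genes overlapping an interval by >= 1 bp are returned in order", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeToyGFF3(f, toyGenes())
  genes <- readGeneAnnotation(f)
  expect_length(genes, 5)

  got <- genesInInterval(genes, "2", 150, 300)
  expect_identical(got$gene_id, "g1")       # [301,400] excluded: no overlap
  got3 <- genesInInterval(genes, "2", 350, 900)
  expect_identical(got3$gene_id, c("g2", "g3", "g4"))
  expect_true(!is.unsorted(got3$start))

  # whole-chromosome interval returns every gene on the chromosome
  all5 <- genesInInterval(genes, "2", 1, 1e9)
  expect_identical(all5$gene_id, paste0("g", 1:5))

  expect_warning(none <- genesInInterval(genes, "9", 1, 1e9), "absent")
  expect_identical(nrow(none), 0L)
})

test_that("gene-list intersection keeps first-list order and is idempotent", {
  expect_identical(intersectGeneLists(c("g1", "g2", "g3"), c("g2", "g4")),
    "g2")
  expect_identical(intersectGeneLists(c("g3", "g1"), c("g1", "g3")),
    c("g3", "g1"))
  expect_length(intersectGeneLists(c("a"), c("b")), 0)
  a <- c("g5", "g2", "g9")
  expect_identical(intersectGeneLists(a, a), a)
})

test_that("enrichment P-values are the closed-form hypergeometric tail", {
  ann <- data.frame(gene_id = c("g1", "g2"), term = "T")
  res <- goEnrichment(c("g1", "g2"), paste0("g", 1:4), ann)
  expect_equal(res$p_value, 1 / 6)           # C(2,2)C(2,0)/C(4,2)
  expect_false(res$enriched)

  # term absent from the study set: P(X >= 0) = 1
  res0 <- goEnrichment(c("g3", "g4"), paste0("g", 1:4), ann)
  expect_equal(res0$p_value, 1)

  # degenerate: every gene in study and population carries the term
  annAll <- data.frame(gene_id = paste0("g", 1:3), term = "T")
  resAll <- goEnrichment(paste0("g", 1:3), paste0("g", 1:3), annAll)
  expect_equal(resAll$p_value, 1)

  expect_error(goEnrichment("gX", c("g1"), ann), "subset")

  # invariance to gene-id relabelling
  relab <- setNames(paste0("x", 1:4), paste0("g", 1:4))
  annR <- data.frame(gene_id = relab[ann$gene_id], term = "T")
  resR <- goEnrichment(relab[c("g1", "g2")], unname(relab), annR)
  expect_equal(resR$p_value, res$p_value)
})

test_that("hypergeometric tail matches a permutation oracle", {
  set.seed(61)
  population <- paste0("g", 1:40)
  carriers <- sample(population, 12)
  ann <- data.frame(gene_id = carriers, term = "T")
  study <- sample(population, 10)
  p <- goEnrichment(study, population, ann)$p_value
  k <- sum(study %in% carriers)
  hits <- replicate(400, {
    perm <- sample(population, length(carriers))
    sum(study %in% perm) >= k
  })
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / 400) + 0.02)
})

test_that("expression profiles are max-normalised and classified by window", {
  dap <- seq(0, 38, 2)
  early <- ifelse(dap <= 6, c(10, 9, 8, 2)[pmin(dap / 2 + 1, 4)], 0.1)
  expect_identical(classifyExpressionWindow(early, dap), "early")

  bimodal <- ifelse(dap <= 6 | dap >= 32, 8, 0.2)
  expect_identical(classifyExpressionWindow(bimodal, dap),
    "early_and_late")

  late <- ifelse(dap >= 32, 5, 0.1)
  expect_identical(classifyExpressionWindow(late, dap), "late")

  mid <- ifelse(dap >= 12 & dap < 30, 4, 0.05)
  expect_identical(classifyExpressionWindow(mid, dap), "mid")

  expect_identical(classifyExpressionWindow(rep(0, 20), dap),
    "not_expressed")
  # peak FPKM below the expression cutoff
  expect_identical(classifyExpressionWindow(rep(0.5, 20), dap),
    "not_expressed")
  # flat high profile: high everywhere -> mid_other
  expect_identical(classifyExpressionWindow(rep(7, 20), dap), "mid_other")
  expect_warning(classifyExpressionWindow(c(1, 2), c(10, 45)), "0-38")

  # normalisation is scale invariant
  v <- c(1, 3, 10, 2)
  expect_equal(normalizeProfile(v)$normalized,
    normalizeProfile(v * 37.5)$normalized)
  expect_false(normalizeProfile(c(0, 0))$expressed)

  m <- rbind(gA = early, gB = bimodal)
  colnames(m) <- dap
  cl <- classifyExpressionMatrix(m)
  expect_identical(cl$category, c("early", "early_and_late"))
})
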