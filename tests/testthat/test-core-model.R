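test_that("genetic maps parse, sort and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTSV(data.frame(marker = c("m2", "m1"), linkage_group = "2",
    cM_position = c(10, 0)), f)
  gm <- readGeneticMap(f, "toy")
  expect_s4_class(gm, "GeneticMap")
  expect_identical(markers(gm)$marker, c("m1", "m2"))
  expect_equal(markers(gm)$cM, c(0, 10))

  writeTSV(data.frame(marker = c("m1", "m1"), linkage_group = "2",
    cM_position = c(0, 5)), f)
  expect_error(readGeneticMap(f, "dup"), "duplicate")

  writeTSV(data.frame(marker = "m1", linkage_group = "2",
    cM_position = -1), f)
  expect_error(readGeneticMap(f, "neg"), "negative")

  writeTSV(data.frame(marker = "m1", linkage_group = "2",
    cM_position = "abc"), f)
  expect_error(readGeneticMap(f, "bad"), "line 1")
})

test_that("map read -> write -> read round-trips all fields", {
  gm <- toyMap()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneticMap(gm, f)
  back <- readGeneticMap(f, mapId(gm))
  expect_equal(markers(back), markers(gm))
  expect_identical(mapId(back), mapId(gm))
})

test_that("QTL tables split into accepted and rejected with reasons", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- rbind(
    emptyQTLRow(qtl_id = "ok_full", peak_cM = 10, ci_start = 6,
      ci_end = 14, lod = 4.1, r_squared = 0.09),
    emptyQTLRow(qtl_id = "ok_r2", experiment_id = "e2", r_squared = 0.10,
      peak_cM = 12),
    emptyQTLRow(qtl_id = "ok_flanks", flank_left = "A", flank_right = "B"),
    emptyQTLRow(qtl_id = "bad_nothing", peak_cM = 33))
  writeTSV(rows, f)
  res <- readQTLTable(f, toyExperiments())
  expect_setequal(res$qtls$qtl_id, c("ok_full", "ok_r2", "ok_flanks"))
  expect_identical(res$rejected$qtl_id, "bad_nothing")
  expect_match(res$rejected$reason, "insufficient information")

  writeTSV(emptyQTLRow(qtl_id = "inv", ci_start = 14, ci_end = 6), f)
  expect_error(readQTLTable(f, toyExperiments()), "ci_start > ci_end")

  writeTSV(emptyQTLRow(qtl_id = "q", experiment_id = "nope",
    ci_start = 1, ci_end = 2), f)
  expect_error(readQTLTable(f, toyExperiments()), "unknown experiment_id")
})

test_that("QTL table round-trips and percent R2 is rescaled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- rbind(
    emptyQTLRow(qtl_id = "a", peak_cM = 10.5, ci_start = 6.25,
      ci_end = 14.75, lod = 3.3, r_squared = 0.09),
    emptyQTLRow(qtl_id = "b", experiment_id = "e2", flank_left = "mA",
      flank_right = "mB"))
  writeTSV(rows, f)
  res <- readQTLTable(f, toyExperiments())
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeQTLTable(res$qtls, f2)
  back <- readQTLTable(f2, toyExperiments())
  expect_equal(back$qtls, res$qtls)

  writeTSV(emptyQTLRow(qtl_id = "pct", r_squared = 9), f)
  expect_warning(res <- readQTLTable(f, toyExperiments()), "percent")
  expect_equal(res$qtls$r_squared, 0.09)
})

test_that("BED export uses 0-based half-open coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeBED(data.frame(chromosome = "2", start = 214385071,
    end = 215364994), f)
  expect_identical(readLines(f), "2\t214385070\t215364994")

  # conversion property on random intervals
  set.seed(42)
  iv <- data.frame(chromosome = "1",
    start = sample.int(1e6, 20), end = 0)
  iv$end <- iv$start + sample.int(1e4, 20)
  writeBED(iv, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, iv$start - 1)
  expect_equal(bed$V3, iv$end)
  expect_error(writeBED(data.frame(chromosome = "1", start = 0, end = 5),
    f), "1 <= start")
})

test_that("MQTL table mirrors the published summary shape", {
  f <- withr::local_tempfile(fileext = ".tsv")
  mq <- data.frame(name = "mGdr2-3", linkage_group = "2",
    position = 502.05, pve_percent = 7.64, ci_width = 7.43,
    ci_start = 498.335, ci_end = 505.765, phys_start = 214385071,
    phys_end = 215364994, n_qtls = 6L, n_genes = 32L, n_experiments = 3L)
  writeMQTLTable(mq, f)
  back <- read.delim(f)
  expect_equal(back$QTL_Integrated, 6L)
  expect_equal(back$N_Experiments_Involved, 3L)
  expect_equal(back$Left_Physical_Position_bp, 214385071)

  # unresolved physical interval -> empty fields, not zeros
  mq$phys_start <- NA; mq$phys_end <- NA
  writeMQTLTable(mq, f)
  txt <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_identical(txt[8], "")

  # empty list -> header-only file
  writeMQTLTable(mq[0, ], f)
  expect_length(readLines(f), 1L)
})
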