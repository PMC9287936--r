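test_that("positions project homothetically between shared markers", {
  # shared A (source 5 -> consensus 10), B (source 15 -> consensus 30)
  p <- projectPosition(c(10, 5, 20), c(5, 15), c(10, 30))
  expect_equal(p$value, c(20, 10, 40))
  expect_identical(p$extrapolated, c(FALSE, FALSE, TRUE))
  expect_error(projectPosition(1, c(5), c(10)), ">= 2")
  expect_error(projectPosition(1, c(5, 5), c(10, 30)), "degenerate")
})

test_that("physical positions interpolate to genetic positions and back", {
  g <- physicalToGenetic(c(2e6, 1e6, 5e5), c(1e6, 3e6), c(10, 20))
  expect_equal(g$value, c(15, 10, 7.5))
  expect_identical(g$extrapolated, c(FALSE, FALSE, TRUE))

  # mutual inverse with geneticToPhysical at machine precision
  anchors_cM <- c(0, 8, 15, 40)
  anchors_bp <- c(1, 2e6, 2.5e6, 9e6)
  g0 <- c(3.3, 12.120000000001, 39.9)
  p <- geneticToPhysical(g0, anchors_cM, anchors_bp)
  back <- physicalToGenetic(p$value_exact, anchors_bp, anchors_cM)
  expect_equal(back$value, g0, tolerance = 1e-12)
})

test_that("QTLs with peak and CI project through their own intervals", {
  fw <- data.frame(map_id = "e1", group = "2",
    marker = c("A", "B"), source_cM = c(5, 15), consensus_cM = c(10, 30))
  cons <- new("ConsensusMap", mapId = "consensus", markers = data.frame(
    marker = c("A", "B"), group = "2", cM = c(10, 30),
    bp = c(NA_integer_, NA_integer_), provenance = "ref", anchor = FALSE,
    status = "reference"))
  q <- emptyQTLRow(peak_cM = 10, ci_start = 6, ci_end = 14, lod = 3,
    r_squared = 0.09)
  res <- projectQTL(q, toyExperiments(), cons, fw)
  expect_identical(nrow(res$projected), 1L)
  expect_equal(res$projected$peak, 20)
  expect_equal(res$projected$ci_start, 12)
  expect_equal(res$projected$ci_end, 28)
  expect_equal(res$projected$sigma, 16 / 3.92)
  expect_identical(res$projected$provenance, "both_flanks")
})

test_that("one locatable flank is completed with the imputed CI width", {
  cons <- new("ConsensusMap", mapId = "consensus", markers = data.frame(
    marker = c("L", "R"), group = "2", cM = c(50, 120),
    bp = c(NA_integer_, NA_integer_), provenance = "ref", anchor = FALSE,
    status = "reference"))
  fw <- data.frame(map_id = character(), group = character(),
    marker = character(), source_cM = numeric(), consensus_cM = numeric())
  # e3: RIL, N = 265; CI = 163 / (265 * r2); r2 chosen so CI = 8
  r2 <- 163 / (265 * 8)
  q <- emptyQTLRow(experiment_id = "e3", flank_left = "L",
    flank_right = "absent", r_squared = r2)
  res <- projectQTL(q, toyExperiments(), cons, fw)
  expect_equal(res$projected$ci_start, 50)
  expect_equal(res$projected$ci_end, 58)
  expect_equal(res$projected$peak, 54)
  expect_identical(res$projected$provenance, "one_flank_plus_formula")

  # both flanks locatable: CI spans the two markers
  q2 <- emptyQTLRow(qtl_id = "q2", flank_left = "L", flank_right = "R")
  res2 <- projectQTL(q2, toyExperiments(), cons, fw)
  expect_equal(res2$projected$ci_start, 50)
  expect_equal(res2$projected$ci_end, 120)

  # no locatable flank and no framework: discarded with reason
  q3 <- emptyQTLRow(qtl_id = "q3", flank_left = "nope",
    flank_right = "alsono", r_squared = 0.1)
  res3 <- projectQTL(q3, toyExperiments(), cons, fw)
  expect_identical(nrow(res3$projected), 0L)
  expect_match(res3$discarded$reason, "neither flank")
})

test_that("physical-coordinate QTLs convert through the anchor markers", {
  cons <- new("ConsensusMap", mapId = "consensus", markers = data.frame(
    marker = c("A", "B"), group = "2", cM = c(10, 20),
    bp = c(1000000L, 3000000L), provenance = "ref", anchor = TRUE,
    status = "reference"))
  fw <- data.frame(map_id = character(), group = character(),
    marker = character(), source_cM = numeric(), consensus_cM = numeric())
  q <- emptyQTLRow(ci_start = 1.5e6, ci_end = 2.5e6,
    coord_system = "physical")
  res <- projectQTL(q, toyExperiments(), cons, fw)
  expect_equal(res$projected$ci_start, 12.5)
  expect_equal(res$projected$ci_end, 17.5)
  expect_identical(res$projected$provenance, "physical_converted")
})

test_that("projection preserves peak order through a shared framework", {
  set.seed(33)
  for (rep in 1:20) {
    src <- sort(runif(5, 0, 100))
    dst <- sort(runif(5, 0, 300))
    peaks <- sort(runif(10, -10, 110))
    out <- projectPosition(peaks, src, dst)$value
    expect_true(all(diff(out) >= -1e-12))
  }
})

test_that("excessive extrapolation discards the QTL", {
  fw <- data.frame(map_id = "e1", group = "2",
    marker = c("A", "B"), source_cM = c(40, 50), consensus_cM = c(40, 50))
  cons <- new("ConsensusMap", mapId = "consensus", markers = data.frame(
    marker = c("A", "B"), group = "2", cM = c(40, 50),
    bp = c(NA_integer_, NA_integer_), provenance = "ref", anchor = FALSE,
    status = "reference"))
  q <- emptyQTLRow(peak_cM = 90, ci_start = 85, ci_end = 95, lod = 3)
  res <- projectQTL(q, toyExperiments(), cons, fw, max_extrapolation = 0.2)
  expect_identical(nrow(res$projected), 0L)
  expect_match(res$discarded$reason, "extrapolation")
})
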