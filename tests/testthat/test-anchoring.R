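test_that("genetic positions interpolate linearly to physical positions", {
  r <- geneticToPhysical(c(12.5, 20, 10), c(10, 20), c(1e6, 3e6))
  expect_equal(r$value, c(1.5e6, 3e6, 1e6))
  expect_false(any(r$extrapolated))
  expect_error(geneticToPhysical(5, c(10), c(1e6)), ">= 2")
})

test_that("bp-inverted anchors are excluded by the monotone-subset rule", {
  # middle anchor's bp contradicts the flanking ones (local inversion)
  expect_warning(
    r <- geneticToPhysical(15, c(10, 12, 20), c(1e6, 5e6, 3e6)),
    "inverted")
  # with the inverted anchor (5e6) removed, interpolation uses 1e6 -> 3e6
  expect_equal(r$value, 2e6)
  expect_identical(r$n_anchors_used, 2L)
  # monotone over a monotone anchor set
  g <- sort(runif(20, 0, 50))
  out <- geneticToPhysical(g, c(0, 10, 30, 50), c(1, 4e6, 5e6, 9e6))
  expect_true(all(diff(out$value) >= 0))
})

test_that("MQTL genetic CIs resolve to physical intervals", {
  cons <- new("ConsensusMap", mapId = "consensus", markers = data.frame(
    marker = c("A", "B", "C"), group = "2", cM = c(10, 20, 30),
    bp = c(1000000L, 5000000L, 3000000L), provenance = "ref",
    anchor = TRUE, status = "reference"))
  mq <- data.frame(name = "mGdr2-1", trait = "GDR", linkage_group = "2",
    position = 15, se = 1, ci_start = 10, ci_end = 20, ci_width = 10,
    n_qtls = 2L, n_experiments = 2L, pve_percent = 10)
  # the inverted middle anchor (5e6) is excluded; interpolation runs
  # through (10 cM -> 1e6 bp) and (30 cM -> 3e6 bp)
  out <- suppressWarnings(mqtlPhysicalInterval(mq, cons))
  expect_equal(out$phys_start, 1e6)
  expect_equal(out$phys_end, 2e6)

  # zero-width CI -> 1-bp interval
  mq0 <- mq; mq0$ci_start <- mq0$ci_end <- 15
  out0 <- suppressWarnings(mqtlPhysicalInterval(mq0, cons))
  expect_equal(out0$phys_start, out0$phys_end)

  # no anchors on the group -> interval absent, flagged
  consNA <- new("ConsensusMap", mapId = "consensus", markers = data.frame(
    marker = c("A", "B"), group = "2", cM = c(10, 20),
    bp = c(NA_integer_, NA_integer_), provenance = "ref", anchor = FALSE,
    status = "reference"))
  outNA <- mqtlPhysicalInterval(mq, consNA)
  expect_true(is.na(outNA$phys_start))
  expect_match(outNA$phys_status, "no anchors")
})

test_that("descending-bp spans yield a swapped, valid interval", {
  # anchors decreasing in bp across the CI: LIS keeps a monotone subset,
  # but a locally decreasing cM->bp relation can still invert the endpoints
  cons <- new("ConsensusMap", mapId = "consensus", markers = data.frame(
    marker = c("A", "B"), group = "7", cM = c(0, 50),
    bp = c(8000000L, 2000000L), provenance = "ref", anchor = TRUE,
    status = "reference"))
  mq <- data.frame(name = "m1", linkage_group = "7", ci_start = 10,
    ci_end = 20)
  out <- suppressWarnings(mqtlPhysicalInterval(mq, cons))
  # only one bp-monotone anchor survives -> flagged absent
  expect_true(is.na(out$phys_start) || out$phys_start <= out$phys_end)
})

test_that("overlap domains match a sweep-line oracle and are symmetric", {
  a <- data.frame(chromosome = "2", start = 100, end = 200, name = "a1")
  b <- data.frame(chromosome = "2", start = 150, end = 300, name = "b1")
  ov <- overlapDomains(a, b)
  expect_equal(ov$start, 150)
  expect_equal(ov$end, 200)
  expect_identical(ov$names_a, "a1")

  disjoint <- overlapDomains(a,
    data.frame(chromosome = "2", start = 500, end = 600))
  expect_identical(nrow(disjoint), 0L)

  set.seed(404)
  for (rep in 1:15) {
    nA <- sample(1:4, 1); nB <- sample(1:4, 1)
    mk <- function(n) {
      s <- sample.int(400, n)
      data.frame(chromosome = sample(c("1", "2"), n, replace = TRUE),
        start = s, end = s + sample.int(150, n))
    }
    A <- mk(nA); B <- mk(nB)
    got <- overlapDomains(A, B)
    want <- oracleOverlap(A, B)
    o <- order(got$chromosome, got$start)
    ow <- order(want$chromosome, want$start)
    expect_equal(got$start[o], want$start[ow])
    expect_equal(got$end[o], want$end[ow])
    # symmetry
    sym <- overlapDomains(B, A)
    expect_equal(sort(sym$start), sort(got$start))
    # total overlap length bounded by the smaller side
    lenTot <- function(d) if (!nrow(d)) 0 else sum(d$end - d$start + 1)
    expect_lte(lenTot(got),
      min(sum(A$end - A$start + 1), sum(B$end - B$start + 1)))
  }
})

test_that("three mutually overlapping pairs merge into labelled domains", {
  a <- data.frame(chromosome = "3", start = c(100, 400), end = c(250, 600),
    name = c("a1", "a2"))
  b <- data.frame(chromosome = "3", start = c(200, 450), end = c(500, 700),
    name = c("b1", "b2"))
  ov <- overlapDomains(a, b)
  # intersections: [200,250], [400,500], [450,600] -> merged [400,600]
  expect_equal(ov$start, c(200, 400))
  expect_equal(ov$end, c(250, 600))
  expect_identical(ov$names_b[2], "b1,b2")
  expect_identical(ov$names_a[2], "a2")
})
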