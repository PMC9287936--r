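test_that("K = 1 is the exact inverse-variance weighted mean", {
  f <- fitMixture(c(10, 20), c(2, 2), 1)
  expect_equal(f@means, 15)
  f2 <- fitMixture(c(10, 20), c(1, 2), 1)
  expect_equal(f2@means, (10 * 1 + 20 * 0.25) / 1.25)  # 12.0
  expect_equal(f2@loglik,
    sum(dnorm(c(10, 20), 12, c(1, 2), log = TRUE)))
  expect_equal(f2@aic, -2 * f2@loglik + 2)
  expect_error(fitMixture(c(10, 20), c(1, 2), 3), "k must")
  expect_error(fitMixture(c(10, NA), c(1, 1), 1), "non-finite")
  expect_error(fitMixture(c(10, 20), c(1, 0), 1), "positive")
})

test_that("two tight clusters are recovered with K = 2", {
  x <- c(10, 10.5, 50, 50.5)
  s <- rep(1, 4)
  f <- fitMixture(x, s, 2)
  expect_equal(f@means, c(10.25, 50.25), tolerance = 1e-6)
  expect_equal(f@proportions, c(0.5, 0.5), tolerance = 1e-6)
  sel <- selectModel(x, s)
  expect_identical(sel@k, 2L)
  # and the oracle agrees on both K and the likelihood
  orc <- oracleSelect(x, s)
  expect_identical(sel@k, orc$k)
  expect_equal(sel@loglik, orc$loglik, tolerance = 1e-6)
})

test_that("degenerate inputs select K = 1", {
  one <- selectModel(25, 3)
  expect_identical(one@k, 1L)
  expect_equal(one@means, 25)
  collinear <- selectModel(rep(40, 12), rep(2, 12))
  expect_identical(collinear@k, 1L)
})

test_that("model selection matches the exhaustive oracle on small instances", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    x <- runif(n, 0, 60)
    s <- runif(n, 0.5, 5)
    sel <- selectModel(x, s)
    orc <- oracleSelect(x, s)
    expect_identical(sel@k, orc$k)
    expect_equal(sel@loglik, orc$loglik, tolerance = 1e-6)
  }
})

test_that("log-likelihood is non-decreasing in K", {
  set.seed(5)
  x <- runif(12, 0, 100); s <- runif(12, 1, 6)
  ll <- vapply(1:6, function(k) fitMixture(x, s, k)@loglik, numeric(1))
  expect_true(all(diff(ll) > -1e-6))
})

test_that("fits are invariant to the input order of QTLs", {
  set.seed(9)
  x <- runif(15, 0, 80); s <- runif(15, 0.5, 4)
  perm <- sample(15)
  a <- selectModel(x, s)
  b <- selectModel(x[perm], s[perm])
  expect_identical(a@k, b@k)
  expect_equal(a@means, b@means)
  expect_equal(a@loglik, b@loglik)
  expect_equal(a@responsibilities[perm, , drop = FALSE],
    b@responsibilities)
})

mkProjected <- function(peaks, sigmas, exps = NULL, r2 = NA_real_) {
  n <- length(peaks)
  data.frame(qtl_id = paste0("q", seq_len(n)), trait = "GDR",
    experiment_id = if (is.null(exps)) paste0("e", seq_len(n)) else exps,
    linkage_group = "2", peak = peaks,
    ci_start = peaks - 1.96 * sigmas, ci_end = peaks + 1.96 * sigmas,
    sigma = sigmas, provenance = "both_flanks", lod = 3,
    r_squared = rep_len(r2, n), stringsAsFactors = FALSE)
}

test_that("MQTL extraction gives the closed-form consensus position and CI", {
  m <- mkProjected(c(10, 11, 9, 10.5), rep(4, 4))
  f <- fitMixture(m$peak, m$sigma, 1)
  mq <- extractMQTLs(f, m, "GDR", "2")
  expect_equal(mq$se, 2)                     # sqrt(1 / (4 / 16))
  expect_equal(mq$ci_width, 7.84)            # 2 * 1.96 * 2
  expect_equal(mq$position, mean(m$peak))    # equal weights
  expect_identical(mq$n_qtls, 4L)
  expect_identical(mq$n_experiments, 4L)
  expect_identical(mq$name, "mGdr2-1")

  # single member: consensus CI width equals the member's own CI width
  one <- mkProjected(30, 10 / 3.92)
  mq1 <- extractMQTLs(fitMixture(one$peak, one$sigma, 1), one, "GDR", "2")
  expect_equal(mq1$ci_width, 10)

  # PVE is the mean member R2 in percent
  two <- mkProjected(c(10, 10.4), c(2, 2), r2 = c(0.08, 0.12))
  mq2 <- extractMQTLs(fitMixture(two$peak, two$sigma, 1), two, "GDR", "2")
  expect_equal(mq2$pve_percent, 10)
})

test_that("consensus CI is never wider than the narrowest member CI", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    m <- mkProjected(runif(n, 0, 10), runif(n, 0.5, 8))
    mq <- extractMQTLs(fitMixture(m$peak, m$sigma, 1), m, "GDR", "2")
    expect_lte(mq$se, min(m$sigma) + 1e-12)
    expect_lte(mq$ci_width, min(m$ci_end - m$ci_start) + 1e-9)
  }
})

test_that("support filtering keeps MQTLs seen in >= 2 experiments, names intact", {
  m <- mkProjected(c(10, 10.5, 60, 61, 60.5), rep(1, 5),
    exps = c("e1", "e2", "e3", "e3", "e3"))
  fit <- fitMixture(m$peak, m$sigma, 2)
  mq <- extractMQTLs(fit, m, "GWC", "2")
  expect_identical(mq$name, c("mGwc2-1", "mGwc2-2"))
  expect_identical(mq$n_experiments, c(2L, 1L))
  filt <- filterMQTLs(mq, 2)
  expect_identical(filt$name, "mGwc2-1")     # numbering gap survives
  expect_identical(filterMQTLs(mq, 1), mq)   # min_experiments = 1: identity
})

test_that("metaAnalyze clusters per linkage group and reports AIC profiles", {
  m <- rbind(mkProjected(c(10, 10.5, 50, 50.6), rep(1, 4)),
    within(mkProjected(c(20, 21), c(1, 1)), linkage_group <- "5"))
  m$qtl_id <- paste0("q", seq_len(nrow(m)))
  res <- metaAnalyze(m, "GDR")
  expect_identical(res$mqtls$linkage_group, c("2", "2", "5"))
  expect_identical(res$mqtls$name, c("mGdr2-1", "mGdr2-2", "mGdr5-1"))
  for (g in unique(res$profiles$linkage_group)) {
    p <- res$profiles[res$profiles$linkage_group == g, ]
    expect_equal(p$aic[p$selected], min(p$aic))
  }
})
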