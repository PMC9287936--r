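# Independent oracles, deliberately written as plain, naive code so the
# implementation under test is checked against a different path.

# naive EM for the heteroscedastic 1-D mixture, from a given mean start
oracleEM <- function(x, s, mu0, maxit = 3000, tol = 1e-10) {
  k <- length(mu0)
  mu <- mu0
  p <- rep(1 / k, k)
  llOld <- -Inf
  for (it in seq_len(maxit)) {
    ld <- matrix(0, length(x), k)
    for (j in seq_len(k)) ld[, j] <- log(p[j]) + dnorm(x, mu[j], s,
      log = TRUE)
    mx <- apply(ld, 1, max)
    tot <- mx + log(rowSums(exp(ld - mx)))
    ll <- sum(tot)
    r <- exp(ld - tot)
    p <- colMeans(r)
    p <- pmax(p, 1e-12); p <- p / sum(p)
    for (j in seq_len(k))
      mu[j] <- sum(r[, j] * x / s^2) / sum(r[, j] / s^2)
    if (abs(ll - llOld) < tol) break
    llOld <- ll
  }
  list(mu = sort(mu), p = p[order(mu)], loglik = ll)
}

# exhaustive search: EM started from every contiguous partition of the
# sorted positions (clusters of a hard-assigned 1-D mixture are contiguous)
oracleSelect <- function(x, s, kmax = 10) {
  ord <- order(x)
  xs <- x[ord]; ss <- s[ord]
  n <- length(xs)
  bestPerK <- numeric(0)
  for (k in seq_len(min(kmax, n))) {
    cuts <- if (k == 1) matrix(nrow = 0, ncol = 1) else
      utils::combn(n - 1, k - 1)
    nPart <- if (k == 1) 1 else ncol(cuts)
    fits <- vector("list", nPart)
    for (ip in seq_len(nPart)) {
      bounds <- c(0, if (k > 1) cuts[, ip], n)
      mu0 <- vapply(seq_len(k), function(j) {
        idx <- (bounds[j] + 1):bounds[j + 1]
        sum(xs[idx] / ss[idx]^2) / sum(1 / ss[idx]^2)
      }, numeric(1))
      fits[[ip]] <- oracleEM(xs, ss, mu0, maxit = 80, tol = 1e-5)
    }
    ord <- order(vapply(fits, function(f) -f$loglik, numeric(1)))
    best <- -Inf
    for (ip in ord[seq_len(min(3, nPart))]) {
      f <- oracleEM(xs, ss, fits[[ip]]$mu)
      if (f$loglik > best) best <- f$loglik
    }
    bestPerK[k] <- best
  }
  aic <- -2 * bestPerK + 2 * (2 * seq_along(bestPerK) - 1)
  k <- which.min(aic)
  list(k = k, loglik = bestPerK[k], aic = aic, loglikPerK = bestPerK)
}

# brute force: maximum-size subset of shared markers whose order agrees in
# both lists; among ties, the lexicographically smallest reference-index set
oracleCommonOrder <- function(refOrder, studyOrder) {
  shared <- intersect(refOrder, studyOrder)
  refOrder <- refOrder[refOrder %in% shared]
  studyOrder <- studyOrder[studyOrder %in% shared]
  n <- length(refOrder)
  lexLess <- function(a, b) {
    d <- a - b
    first <- which(d != 0)[1]
    !is.na(first) && d[first] < 0
  }
  bestIdx <- NULL
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    pos <- match(refOrder[idx], studyOrder)
    if (is.unsorted(pos, strictly = TRUE)) next
    if (is.null(bestIdx) || length(idx) > length(bestIdx) ||
        (length(idx) == length(bestIdx) && lexLess(idx, bestIdx)))
      bestIdx <- idx
  }
  refOrder[bestIdx]
}

# sweep over integer coordinates: reference computation of overlap domains
oracleOverlap <- function(setA, setB) {
  out <- list()
  for (chr in union(setA$chromosome, setB$chromosome)) {
    a <- setA[setA$chromosome == chr, , drop = FALSE]
    b <- setB[setB$chromosome == chr, , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    hi <- max(a$end, b$end)
    inA <- inB <- logical(hi)
    for (i in seq_len(nrow(a))) inA[a$start[i]:a$end[i]] <- TRUE
    for (i in seq_len(nrow(b))) inB[b$start[i]:b$end[i]] <- TRUE
    both <- which(inA & inB)
    if (!length(both)) next
    runs <- split(both, cumsum(c(1, diff(both) != 1)))
    for (r in runs)
      out[[length(out) + 1L]] <- data.frame(chromosome = chr,
        start = min(r), end = max(r), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(chromosome = character(),
    start = numeric(), end = numeric()))
  do.call(rbind, out)
}
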