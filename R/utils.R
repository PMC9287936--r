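## Longest strictly-increasing subsequence of distinct values, returning the
## positions of the lexicographically smallest value sequence among all
## maximum-length solutions.  O(n^2); inputs here are shared-marker lists.
lisLexSmallest <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  lenFrom <- rep(1L, n)
  if (n >= 2L) for (i in seq(n - 1L, 1L)) {
    after <- which(seq_len(n) > i & v > v[i])
    if (length(after)) lenFrom[i] <- 1L + max(lenFrom[after])
  }
  L <- max(lenFrom)
  res <- integer(L)
  prevPos <- 0L
  prevVal <- -Inf
  for (t in seq_len(L)) {
    cand <- which(seq_len(n) > prevPos & v > prevVal & lenFrom >= L - t + 1L)
    pick <- cand[which.min(v[cand])]
    res[t] <- pick
    prevPos <- pick
    prevVal <- v[pick]
  }
  res
}

## Piecewise-linear interpolation through >= 2 strictly increasing knots xs.
## Positions beyond the terminal knots are extended with the nearest
## interval's slope (homothetic rule) and flagged extrapolated.
interpolatePiecewise <- function(x, xs, ys) {
  stopifnot(length(xs) >= 2, length(xs) == length(ys))
  if (any(diff(xs) <= 0)) stop("degenerate interpolation knots (xs not strictly increasing)")
  i <- findInterval(x, xs, all.inside = TRUE)
  val <- ys[i] + (x - xs[i]) * (ys[i + 1] - ys[i]) / (xs[i + 1] - xs[i])
  list(value = val,
    extrapolated = x < xs[1] - 1e-12 | x > xs[length(xs)] + 1e-12)
}

## sample() that never falls into the scalar-x trap
sampleFrom <- function(v, n, replace = FALSE) {
  v[sample.int(length(v), n, replace = replace)]
}

## Deterministic 31-bit seed from a numeric vector; used so that mixture
## restarts depend only on the (sorted) data, never on input order or the
## caller's RNG state.
seedFromValues <- function(x, salt = 0L) {
  u <- sum(abs(as.numeric(x)) * seq_along(x) * 1000) + salt * 7919
  as.integer(round(u) %% 2147483587L) + 1L
}

## Run expr with a private RNG stream; restores the caller's .Random.seed.
withPrivateSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
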