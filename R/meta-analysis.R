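## log-density matrix n x k for the heteroscedastic 1-D mixture:
## observation i keeps its own fixed variance sigma_i^2 in every component.
mixLogDens <- function(x, sigmas, means) {
  outer(seq_along(x), seq_along(means),
    function(i, j) dnorm(x[i], means[j], sigmas[i], log = TRUE))
}

logSumExpRows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

## One EM run from given starting means; proportions start uniform.
emRun <- function(x, sigmas, means0, tol = 1e-8, maxit = 500L,
    prop_floor = 1e-6) {
  k <- length(means0)
  mu <- sort(means0)
  pi_k <- rep(1 / k, k)
  ll <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    ld <- sweep(mixLogDens(x, sigmas, mu), 2, log(pi_k), "+")
    rowLse <- logSumExpRows(ld)
    newLL <- sum(rowLse)
    r <- exp(ld - rowLse)
    pi_k <- pmax(colMeans(r), prop_floor)
    pi_k <- pi_k / sum(pi_k)
    w <- r / sigmas^2
    mu <- colSums(w * x) / colSums(w)
    if (is.finite(ll) && abs(newLL - ll) < tol) {
      ll <- newLL
      converged <- TRUE
      break
    }
    ll <- newLL
  }
  list(means = mu, proportions = pi_k, loglik = ll, converged = converged)
}

#' Fit a variance-weighted 1-D Gaussian mixture with K components
#'
#' The meta-analysis model: projected QTL positions \eqn{x_i} on one
#' linkage group are modelled as draws from a K-component normal mixture in
#' which each observation keeps its own fixed standard deviation
#' \eqn{\sigma_i} (derived from its 95% CI width); only the component means
#' and mixing proportions are free.  The likelihood
#' \eqn{L = \sum_i \log \sum_k \pi_k \,\phi(x_i;\mu_k,\sigma_i^2)} is
#' maximised by EM.  For K = 1 the exact closed form is returned: the
#' inverse-variance weighted mean
#' \eqn{\mu = (\sum x_i/\sigma_i^2)/(\sum 1/\sigma_i^2)}.
#'
#' For K > 1 the EM is restarted from K-quantiles of the sorted positions
#' plus `n_restarts` jittered starts from a generator seeded by the sorted
#' data, so the fit is deterministic and invariant to input order.
#'
#' @param positions projected QTL peak positions (cM).
#' @param sigmas per-QTL standard deviations (cM, > 0).
#' @param k number of components, `1 <= k <= length(positions)`.
#' @param n_restarts jittered restarts added to the quantile start (8).
#' @param tol,maxit EM convergence tolerance on the log-likelihood and
#'   iteration cap.
#' @return A [MixtureFit-class].
#' @examples
#' fitMixture(c(10, 20), c(1, 2), k = 1)  # mean 12: inverse-variance weight
#' @export
fitMixture <- function(positions, sigmas, k, n_restarts = 8L,
    tol = 1e-8, maxit = 500L) {
  n <- length(positions)
  stopifnot(length(sigmas) == n)
  if (!all(is.finite(positions)) || !all(is.finite(sigmas)))
    stop("non-finite positions or sigmas")
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n")

  ord <- order(positions)
  xs <- positions[ord]; ss <- sigmas[ord]

  if (k == 1L) {
    w <- 1 / ss^2
    mu <- sum(xs * w) / sum(w)
    ll <- sum(dnorm(xs, mu, ss, log = TRUE))
    fit <- list(means = mu, proportions = 1, loglik = ll, converged = TRUE)
  } else {
    starts <- list(quantile(xs, probs = (seq_len(k) - 0.5) / k,
      names = FALSE, type = 7))
    span <- max(xs) - min(xs)
    jit <- withPrivateSeed(seedFromValues(xs, salt = k), {
      lapply(seq_len(n_restarts), function(r)
        sort(runif(k, min(xs) - 0.05 * span, max(xs) + 0.05 * span)))
    })
    # also try centers on distinct observed positions (k-points starts)
    ux <- unique(xs)
    if (length(ux) >= k)
      starts <- c(starts, list(ux[round(seq(1, length(ux), length.out = k))]))
    starts <- c(starts, jit)
    # hard clusters of a 1-D mixture are contiguous in the sorted data, so
    # for small n all contiguous-partition starts make the search exhaustive
    if (n <= 10L && k > 1L && choose(n - 1, k - 1) <= 252) {
      cuts <- utils::combn(n - 1L, k - 1L)
      w <- 1 / ss^2
      partStarts <- lapply(seq_len(ncol(cuts)), function(ip) {
        bounds <- c(0L, cuts[, ip], n)
        vapply(seq_len(k), function(j) {
          idx <- (bounds[j] + 1L):bounds[j + 1L]
          sum(xs[idx] * w[idx]) / sum(w[idx])
        }, numeric(1))
      })
      starts <- c(starts, partStarts)
    }
    # screen every start with a short EM, then polish the best few
    starts <- unique(lapply(starts, function(s) round(sort(s), 8)))
    screened <- lapply(starts, function(s)
      emRun(xs, ss, s, tol = 1e-5, maxit = 60L))
    ord <- order(vapply(screened, function(f) -f$loglik, numeric(1)))
    best <- NULL
    for (i in head(ord, 3L)) {
      f <- emRun(xs, ss, screened[[i]]$means, tol = tol, maxit = maxit)
      if (is.null(best) || f$loglik > best$loglik + 1e-12) best <- f
    }
    fit <- best
  }
  co <- order(fit$means)
  means <- fit$means[co]
  props <- fit$proportions[co]
  ld <- sweep(mixLogDens(positions, sigmas, means), 2, log(props), "+")
  resp <- exp(ld - logSumExpRows(ld))
  new("MixtureFit", k = k, means = as.numeric(means),
    proportions = as.numeric(props), loglik = fit$loglik,
    aic = -2 * fit$loglik + 2 * (2 * k - 1),
    responsibilities = resp, converged = fit$converged)
}

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: K = %d, logLik = %.4f, AIC = %.4f%s\n",
    object@k, object@loglik, object@aic,
    if (object@converged) "" else " (not converged)"))
  cat("  means (cM):", paste(sprintf("%.3f", object@means),
    collapse = ", "), "\n")
  cat("  proportions:", paste(sprintf("%.3f", object@proportions),
    collapse = ", "), "\n")
})

#' Select the number of meta-QTLs on a linkage group by AIC
#'
#' Fits the variance-weighted mixture for K = 1 to `min(k_max, n)` and
#' returns the fit minimising \eqn{AIC = -2\log L + 2(2K-1)}; exact ties go
#' to the smaller K.
#'
#' @inheritParams fitMixture
#' @param k_max largest K considered (10).
#' @param profile if `TRUE`, return `list(fit, profile)` where `profile` is
#'   the per-K AIC table (diagnostics).
#' @return A [MixtureFit-class] (or a list when `profile = TRUE`).
#' @export
selectModel <- function(positions, sigmas, k_max = 10L, profile = FALSE,
    n_restarts = 8L) {
  n <- length(positions)
  stopifnot(n >= 1)
  ks <- seq_len(min(k_max, n))
  fits <- lapply(ks, function(k) fitMixture(positions, sigmas, k,
    n_restarts = n_restarts))
  aics <- vapply(fits, function(f) f@aic, numeric(1))
  best <- fits[[which.min(aics)]]
  if (!profile) return(best)
  list(fit = best, profile = data.frame(k = ks,
    loglik = vapply(fits, function(f) f@loglik, numeric(1)), aic = aics,
    selected = ks == best@k))
}

#' Extract meta-QTLs from a fitted mixture
#'
#' Each projected QTL is assigned to the component with the highest
#' posterior responsibility (ties to the left component).  Per component:
#' the consensus position is the inverse-variance weighted mean of member
#' peaks, its standard error \eqn{se = \sqrt{1/\sum 1/\sigma_i^2}}, the 95%
#' CI is `position +/- 1.96 se`, and PVE is the arithmetic mean of member
#' R-squared values (in percent).  Components left empty after hard
#' assignment are dropped (K effectively reduced).  Names are assigned as
#' `m{Trait}{group}-{rank by position}` over all extracted components, so
#' downstream filtering leaves visible gaps in the numbering rather than
#' renumbering.
#'
#' @param fit a [MixtureFit-class] for one trait and linkage group.
#' @param members the projected QTL `data.frame` the fit was computed from
#'   (same row order as the fit's responsibility matrix).
#' @param trait `"GDR"` or `"GWC"`.
#' @param group linkage-group label.
#' @return `data.frame` with one row per MQTL: name, trait, linkage_group,
#'   position, se, ci_start, ci_end, ci_width, n_qtls, n_experiments,
#'   pve_percent, and a `members` list-column of member `qtl_id`s.
#' @export
extractMQTLs <- function(fit, members, trait, group) {
  stopifnot(nrow(members) == nrow(fit@responsibilities))
  assign <- apply(fit@responsibilities, 1, which.max)
  rows <- list()
  for (comp in seq_len(fit@k)) {
    idx <- which(assign == comp)
    if (!length(idx)) {
      message(sprintf("component %d on group %s empty after assignment; dropped",
        comp, group))
      next
    }
    m <- members[idx, , drop = FALSE]
    w <- 1 / m$sigma^2
    pos <- sum(m$peak * w) / sum(w)
    se <- sqrt(1 / sum(w))
    r2 <- m$r_squared[!is.na(m$r_squared)]
    rows[[length(rows) + 1L]] <- data.frame(
      trait = trait, linkage_group = group, position = pos, se = se,
      ci_start = pos - 1.96 * se, ci_end = pos + 1.96 * se,
      ci_width = 2 * 1.96 * se, n_qtls = length(idx),
      n_experiments = length(unique(m$experiment_id)),
      pve_percent = if (length(r2)) mean(r2) * 100 else NA_real_,
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$members <- I(list(m$qtl_id))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  pretty <- paste0("m", substr(trait, 1, 1),
    tolower(substr(trait, 2, nchar(trait))))
  out$name <- sprintf("%s%s-%d", pretty, group, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("name", setdiff(names(out), "name"))]
}

#' Filter meta-QTLs by experiment support
#'
#' Retains MQTLs whose member QTLs come from at least `min_experiments`
#' distinct experiments; singletons detected in only one experiment are
#' considered unreplicated and removed from the final candidate set.
#'
#' @param mqtls MQTL `data.frame` from [extractMQTLs()].
#' @param min_experiments minimum number of distinct supporting
#'   experiments (2).
#' @return The filtered `data.frame` (names kept as assigned).
#' @export
filterMQTLs <- function(mqtls, min_experiments = 2L) {
  mqtls[mqtls$n_experiments >= min_experiments, , drop = FALSE]
}

#' Run the per-group meta-analysis over a projected QTL set
#'
#' Convenience wrapper: splits projected QTLs of one trait by linkage
#' group, selects K by AIC on each, extracts MQTLs and binds the results.
#'
#' @param projected projected QTL `data.frame` for one trait.
#' @param trait trait label used for naming.
#' @param k_max AIC search cap per group (10).
#' @return list with `mqtls` (all extracted, unfiltered) and `profiles`
#'   (per-group AIC tables).
#' @export
metaAnalyze <- function(projected, trait, k_max = 10L) {
  groups <- unique(projected$linkage_group)
  groups <- groups[order(orderGroups(groups))]
  all <- list(); profs <- list()
  for (grp in groups) {
    sub <- projected[projected$linkage_group == grp, , drop = FALSE]
    sel <- selectModel(sub$peak, sub$sigma, k_max = k_max, profile = TRUE)
    mq <- extractMQTLs(sel$fit, sub, trait, grp)
    all[[grp]] <- mq
    profs[[grp]] <- cbind(linkage_group = grp, sel$profile)
  }
  list(mqtls = do.call(rbind, c(all, list(make.row.names = FALSE))),
    profiles = do.call(rbind, c(profs, list(make.row.names = FALSE))))
}
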