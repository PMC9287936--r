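#' Parameter-recovery benchmark on synthetic chromosomes
#'
#' Runs the full generator -> consensus -> projection -> mixture/AIC path on
#' `n_replicates` independent single-chromosome scenarios (default
#' conditions: 2-4 true MQTLs separated by at least five times the largest
#' QTL sigma, each supported by at least four member QTLs) and measures how
#' well the meta-analysis recovers the planted truth:
#' the rate at which AIC selects the true number of MQTLs, the coverage of
#' true positions by the reported 95% CIs, and the position errors.
#'
#' @param n_replicates number of simulated chromosomes (200).
#' @param seed master seed; replicate r uses scenario seed `seed + r`.
#' @param n_experiments experiments per scenario (6).
#' @param ... further arguments passed to [simulationScenario()].
#' @return list: `k_selection_rate`, `ci_coverage`, `mean_abs_error`
#'   (cM), `mean_se` (cM), and the per-replicate `details` data.frame.
#' @export
benchmarkRecovery <- function(n_replicates = 200L, seed = 1L,
    n_experiments = 6L, ...) {
  kOK <- logical(n_replicates)
  covered <- list(); abserr <- list(); ses <- list()
  for (r in seq_len(n_replicates)) {
    sc <- simulationScenario(seed + r, n_chromosomes = 1L,
      n_experiments = n_experiments, traits = "GDR", ...)
    ref <- simulateReferenceMap(sc)
    sim <- simulateExperiments(sc, ref)
    mg <- mergeMaps(ref, sim$study_maps)
    pr <- projectQTL(applyLODDefault(sim$qtls), sim$experiments,
      mg$consensus, mg$frameworks)
    fit <- selectModel(pr$projected$peak, pr$projected$sigma)
    kOK[r] <- fit@k == nrow(sc$truth)
    mq <- extractMQTLs(fit, pr$projected, "GDR", "1")
    # match each true MQTL to the extracted MQTL holding most of its members
    trueOf <- sim$truth$true_mqtl[match(pr$projected$qtl_id,
      sim$truth$qtl_id)]
    for (t in seq_len(nrow(sc$truth))) {
      tid <- sc$truth$mqtl_id[t]
      share <- vapply(mq$members, function(ids)
        sum(trueOf[match(ids, pr$projected$qtl_id)] == tid), integer(1))
      if (!any(share > 0)) next
      hit <- which.max(share)
      tp <- sc$truth$position[t]
      covered[[length(covered) + 1L]] <-
        mq$ci_start[hit] <= tp && tp <= mq$ci_end[hit]
      abserr[[length(abserr) + 1L]] <- abs(mq$position[hit] - tp)
      ses[[length(ses) + 1L]] <- mq$se[hit]
    }
  }
  list(k_selection_rate = mean(kOK),
    ci_coverage = mean(unlist(covered)),
    mean_abs_error = mean(unlist(abserr)),
    mean_se = mean(unlist(ses)),
    details = data.frame(replicate = seq_len(n_replicates), k_ok = kOK))
}
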