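#' Type-I-error calibration of the heterogeneity test
#'
#' Repeatedly generates null study collections (no association, no
#' between-study variance, no gradient), pools the variant-homozygote
#' risk ratio and records how often Cochran's Q rejects at `alpha`.
#' Under a well-calibrated test the rate sits near `alpha`.
#'
#' @param n_reps Number of replicate collections.
#' @param k Studies per collection.
#' @param n_arm Cases and controls per study arm.
#' @param alpha Nominal level of the heterogeneity test.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List: `rate`, `n_reps`.
#' @export
calibrate_heterogeneity_null <- function(n_reps = 1000, k = 10,
                                         n_arm = 200, alpha = 0.05,
                                         seed = 0) {
  rej <- 0L
  half <- floor(k / 2)
  alloc <- c(`2` = half, `3` = k - 2 * half, `4` = half)
  alloc <- alloc[alloc > 0]
  for (r in seq_len(n_reps)) {
    cfg <- synthetic_config(k = k, n_cases = c(n_arm, n_arm),
                            n_controls = c(n_arm, n_arm),
                            level_alloc = alloc, seed = seed + r)
    res <- meta_analyze(generate_null(cfg), "TT", "RR", alpha)
    if (!is.na(res$Q_p) && res$Q_p < alpha) rej <- rej + 1L
  }
  list(rate = rej / n_reps, n_reps = n_reps)
}

#' Type-I-error calibration of the Hardy-Weinberg screen
#'
#' Draws control arms from an exactly-HWE population (F = 0) and records
#' how often the 1-df chi-square screen rejects at `alpha`.
#'
#' @param n_reps Number of simulated control arms.
#' @param n_arm Controls per arm.
#' @param alpha Screening level.
#' @param seed Base seed.
#' @return List: `rate`, `n_reps`.
#' @export
calibrate_hwe_null <- function(n_reps = 500, n_arm = 200, alpha = 0.05,
                               seed = 0) {
  rej <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    p <- stats::runif(1, 0.2, 0.4)
    counts <- as.integer(stats::rmultinom(1, n_arm,
                                          control_genotype_probs(p, 0)))
    h <- hwe_test(genotype_counts(counts[1], counts[2], counts[3]), alpha)
    if (!h$monomorphic && h$p_value < alpha) rej <- rej + 1L
  }
  list(rate = rej / n_reps, n_reps = n_reps)
}

#' Parameter recovery of the pooled variant-homozygote risk ratio
#'
#' Generates collections under a known configuration, pools the TT risk
#' ratio with DerSimonian-Laird random effects and measures how often the
#' pooled estimate falls within `tol` of the configuration's true
#' marginal risk ratio (see [true_marginal_rr()]).
#'
#' @param n_seeds Number of replicate collections.
#' @param config Template [synthetic_config()]; its seed is replaced by
#'   the replicate index offset by `seed`.
#' @param tol Absolute tolerance on the risk-ratio scale.
#' @param seed Base seed.
#' @return List: `rate`, `truth`, `estimates`, `n_seeds`.
#' @export
recover_pooled_rr <- function(n_seeds = 100, config = NULL, tol = 0.15,
                              seed = 0) {
  if (is.null(config))
    config <- synthetic_config(k = 40, n_cases = c(500, 500),
                               n_controls = c(500, 500), p_variant = 0.3,
                               rr_homvar = 1.75, rr_het = 1, tau = 0.1,
                               gamma = 0)
  truth <- true_marginal_rr(config, "TT")
  est <- vapply(seq_len(n_seeds), function(r) {
    config$seed <- as.integer(seed + r)
    res <- meta_analyze(generate_studies(config), "TT", "RR")
    pool_random(res$estimates)$effect
  }, numeric(1))
  list(rate = mean(abs(est - truth) <= tol), truth = truth,
       estimates = est, n_seeds = n_seeds)
}

#' Detection of a case-arm pollution gradient
#'
#' Generates collections with the configured case-arm gradient and, for
#' the case-arm carrier percentage (`pct_TTCT_case`), records how often
#' the AICc partition isolates level 4 (`{2,3}|{4}`) and how often the
#' Tukey-Kramer 4-vs-2 comparison is significant at `alpha`. With
#' `gamma = 0` the same machinery on the control arm gives the
#' false-positive rate (`clean_rate` = share of seeds with no significant
#' pair).
#'
#' @param n_seeds Number of replicate collections.
#' @param config Template [synthetic_config()]; needs equal per-level
#'   allocation for the detection setting.
#' @param arm `"case"` or `"ctrl"`: which arm's carrier percentage.
#' @param alpha Significance level for the Tukey comparison.
#' @param seed Base seed.
#' @return List: `split_rate`, `tukey_rate`, `clean_rate`, `n_seeds`.
#' @export
gradient_detection <- function(n_seeds = 100, config = NULL,
                               arm = c("case", "ctrl"), alpha = 0.05,
                               seed = 0) {
  arm <- match.arg(arm)
  if (is.null(config))
    config <- synthetic_config(k = 36,
                               level_alloc = c(`2` = 12, `3` = 12,
                                               `4` = 12))
  variable <- paste0("pct_TTCT_", arm)
  split_hit <- tukey_hit <- clean <- 0L
  for (r in seq_len(n_seeds)) {
    config$seed <- as.integer(seed + r)
    out <- compute_outcomes(generate_studies(config))
    ov <- out[out$variable == variable, ]
    ps <- partition_split(ov)
    tk <- tukey_hsd(ov$value, ov$pollution_level)
    if (identical(ps$chosen, "{2,3}|{4}")) split_hit <- split_hit + 1L
    p42 <- tk$p_adj[(tk$level_a == "4" & tk$level_b == "2") |
                      (tk$level_a == "2" & tk$level_b == "4")]
    if (length(p42) && p42 < alpha) tukey_hit <- tukey_hit + 1L
    if (all(tk$p_adj >= alpha)) clean <- clean + 1L
  }
  list(split_rate = split_hit / n_seeds, tukey_rate = tukey_hit / n_seeds,
       clean_rate = clean / n_seeds, n_seeds = n_seeds)
}
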