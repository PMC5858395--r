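test_that("study_effect reproduces hand-derived RR values", {
  e <- study_effect(list(a = 10, n1 = 100, c = 10, n2 = 100), "RR")
  expect_equal(e$effect, 1)
  expect_equal(e$log_effect, 0)

  # crude pooled African variant-homozygote counts
  e <- study_effect(list(a = 20, n1 = 713, c = 2, n2 = 775), "RR",
                    correction = 0)
  expect_equal(e$effect, (20 / 713) / (2 / 775), tolerance = 1e-12)
  expect_equal(e$effect, 10.8696, tolerance = 1e-4)
  expect_equal(e$se, sqrt(1 / 20 - 1 / 713 + 1 / 2 - 1 / 775),
               tolerance = 1e-12)
  expect_equal(e$se, 0.7398, tolerance = 1e-4)

  # Haldane correction fires on a zero cell and adjusts the totals
  e <- study_effect(list(a = 0, n1 = 50, c = 5, n2 = 50), "RR", 0.5)
  expect_true(e$continuity_corrected)
  expect_equal(e$effect, (0.5 / 51) / (5.5 / 51), tolerance = 1e-12)
  expect_equal(e$effect, 0.0909, tolerance = 1e-3)

  # double zero carries no ratio information
  e <- study_effect(list(a = 0, n1 = 50, c = 0, n2 = 60), "RR")
  expect_true(e$excluded)
})

test_that("odds ratios use the cross-product and Woolf variance", {
  e <- study_effect(list(a = 30, n1 = 100, c = 20, n2 = 100), "OR")
  expect_equal(e$effect, (30 * 80) / (20 * 70), tolerance = 1e-12)
  expect_equal(e$se, sqrt(1 / 30 + 1 / 70 + 1 / 20 + 1 / 80),
               tolerance = 1e-12)
})

test_that("RR and OR converge for rare exposure", {
  gap <- vapply(c(0.1, 0.03, 0.01, 0.001), function(rate) {
    n <- 1e5
    a <- round(n * rate * 1.5)
    c_ <- round(n * rate)
    tab <- list(a = a, n1 = n, c = c_, n2 = n)
    abs(study_effect(tab, "OR")$log_effect -
          study_effect(tab, "RR")$log_effect)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[length(gap)], 1e-3)
})

test_that("fixed-effect pooling is inverse-variance weighting", {
  est <- random_estimates(2, seed = 1)
  est$log_effect <- c(log(2), log(2))
  est$se <- c(0.1, 0.2)
  p <- pool_fixed(est)
  expect_equal(p$log_effect, log(2), tolerance = 1e-12)
  expect_equal(p$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(p$se, 0.0894, tolerance = 1e-3)

  single <- random_estimates(1, seed = 2)
  ps <- pool_fixed(single)
  expect_equal(ps$log_effect, single$log_effect)
  expect_equal(ps$se, single$se)
  expect_equal(ps$Q, 0)
  expect_identical(ps$Q_df, 0L)
  expect_error(pool_fixed(random_estimates(3, 1)[0, ]), "no estimates")
})

test_that("heterogeneity truncates Q below its df to zero I2 and tau2", {
  est <- random_estimates(2, seed = 3)
  est$log_effect <- c(0, 1)
  est$se <- c(1, 1)
  h <- heterogeneity(est)
  expect_equal(h$Q, 0.5, tolerance = 1e-12)
  expect_identical(h$Q_df, 1L)
  expect_equal(h$I2, 0)
  expect_equal(h$tau2, 0)

  est$log_effect <- c(0.4, 0.4)
  h <- heterogeneity(est)
  expect_equal(h$Q, 0)
  expect_equal(h$I2, 0)
})

test_that("Q, tau2 and DL pooling match brute-force oracles on random sets", {
  for (seed in 1:200) {
    est <- random_estimates(sample(2:12, 1), seed = seed)
    h <- heterogeneity(est)
    expect_equal(h$Q, oracle_q(est$log_effect, est$se), tolerance = 1e-10)
    expect_equal(h$tau2, oracle_dl_tau2(est$log_effect, est$se),
                 tolerance = 1e-10)
    o <- oracle_dl_pooled(est$log_effect, est$se)
    p <- pool_random(est)
    expect_equal(p$log_effect, o$pooled, tolerance = 1e-10)
    expect_equal(p$se, o$se, tolerance = 1e-10)
  }
})

test_that("random-effects pooling reduces to fixed when tau2 is zero", {
  est <- random_estimates(4, seed = 9)
  est$log_effect <- rep(0.3, 4)       # Q = 0 forces tau2 = 0
  pf <- pool_fixed(est)
  pr <- pool_random(est)
  expect_identical(pr$log_effect, pf$log_effect)
  expect_identical(pr$se, pf$se)
  expect_identical(pr$ci_low, pf$ci_low)
  expect_equal(pr$tau2, 0)
})

test_that("pooled fixed se never exceeds the smallest study se", {
  for (seed in 1:25) {
    est <- random_estimates(sample(2:10, 1), seed = seed + 100)
    expect_lte(pool_fixed(est)$se, min(est$se))
  }
})

test_that("the model-selection rule is strict at alpha", {
  expect_identical(select_model(0.04, 0.05), "Random")
  expect_identical(select_model(0.5, 0.05), "Fixed")
  expect_identical(select_model(0.05, 0.05), "Fixed")
  expect_identical(select_model(NA_real_, 0.05), "Fixed")
})

test_that("meta_analyze composes per-study estimation, selection and pooling", {
  s1 <- make_study("S001", case = c(40, 40, 20), ctrl = c(50, 40, 10))
  one <- meta_analyze(s1, "TT", "RR")
  direct <- study_effect(contrast_table(genotype_counts(40, 40, 20),
                                        genotype_counts(50, 40, 10), "TT"),
                         "RR", study_id = "S001")
  expect_equal(one$effect, direct$effect)
  expect_identical(one$model, "Fixed")

  dup <- rbind(s1, make_study("S002", case = c(40, 40, 20),
                              ctrl = c(50, 40, 10)))
  two <- meta_analyze(dup, "TT", "RR")
  expect_equal(two$effect, direct$effect, tolerance = 1e-12)
  expect_equal(two$Q, 0, tolerance = 1e-12)

  # a double-zero study is excluded and reported
  dz <- rbind(s1, make_study("S003", case = c(60, 40, 0),
                             ctrl = c(70, 30, 0)))
  res <- meta_analyze(dz, "TT", "RR")
  expect_identical(res$excluded, "S003")
  expect_identical(res$k, 1L)
})

test_that("random-effects pooling agrees with metafor on a synthetic set", {
  skip_if_not_installed("metafor")
  est <- random_estimates(8, seed = 11)
  p <- pool_random(est)
  m <- metafor::rma(yi = est$log_effect, sei = est$se, method = "DL")
  expect_equal(p$log_effect, as.numeric(m$beta), tolerance = 1e-8)
  expect_equal(p$se, m$se, tolerance = 1e-8)
  expect_equal(p$tau2, m$tau2, tolerance = 1e-8)
})

test_that("Egger regression matches the normal-equations oracle", {
  est <- random_estimates(3, seed = 21)
  e <- egger_test(est)
  o <- oracle_egger(est$log_effect, est$se)
  expect_equal(e$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(e$intercept_se, o$intercept_se, tolerance = 1e-10)
  expect_equal(e$t, o$t, tolerance = 1e-10)
  expect_identical(e$df, 1L)

  # equal effects make y = theta * x exactly: zero intercept
  est <- random_estimates(6, seed = 22)
  est$log_effect <- rep(0.7, 6)
  e <- suppressWarnings(egger_test(est))  # exact fit: summary.lm warns
  expect_equal(e$intercept, 0, tolerance = 1e-9)
  expect_equal(e$slope, 0.7, tolerance = 1e-9)

  expect_error(egger_test(random_estimates(2, 1)), "at least 3")
})

test_that("funnel coordinates conserve the study set around the fixed center", {
  est <- random_estimates(7, seed = 31)
  f <- funnel_data(est)
  expect_identical(nrow(f$points), 7L)
  expect_equal(f$center, pool_fixed(est)$effect)

  same <- random_estimates(4, seed = 32)
  same$log_effect <- rep(0.2, 4)
  same$se <- rep(0.1, 4)
  same$effect <- exp(same$log_effect)
  f <- funnel_data(same)
  expect_true(all(f$points$effect == f$points$effect[1]))
  expect_equal(f$center, exp(0.2))
})
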