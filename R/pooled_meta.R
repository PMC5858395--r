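#' Per-study effect estimate from a 2x2 table
#'
#' Standardized ratios use the arm totals as denominators: for measure
#' `"RR"` the effect is `(a/n1)/(c/n2)` with
#' `var(log RR) = 1/a - 1/n1 + 1/c - 1/n2`; for `"OR"` it is
#' `a(n2-c) / (c(n1-a))` with the usual Woolf variance. When any of the
#' four cells `a`, `n1-a`, `c`, `n2-c` is zero, the Haldane-Anscombe
#' constant `correction` is added to all four cells (and the totals grow by
#' `2*correction` for RR) before computing. A table with `a = 0` and
#' `c = 0` carries no information about the ratio and is flagged
#' `excluded`.
#'
#' @param table List with `a`, `n1`, `c`, `n2` (see [contrast_table()]).
#' @param measure `"RR"` (default) or `"OR"`.
#' @param correction Continuity-correction constant, `>= 0`.
#' @param study_id Identifier carried into the estimate.
#' @return One-row data frame: `study_id`, `measure`, `log_effect`, `se`,
#'   `effect`, `ci_low`, `ci_high`, `continuity_corrected`, `excluded`.
#' @export
study_effect <- function(table, measure = c("RR", "OR"), correction = 0.5,
                         study_id = NA_character_) {
  measure <- match.arg(measure)
  stopifnot(correction >= 0)
  a <- table$a; n1 <- table$n1; c_ <- table$c; n2 <- table$n2
  if (n1 < 1 || n2 < 1) stop("study_effect: empty arm")
  if (a > n1 || c_ > n2) stop("study_effect: exposed count exceeds total")
  row <- data.frame(study_id = study_id, measure = measure,
                    log_effect = NA_real_, se = NA_real_, effect = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    continuity_corrected = FALSE, excluded = FALSE,
                    stringsAsFactors = FALSE)
  if (a == 0 && c_ == 0) {               # double zero: undefined ratio
    row$excluded <- TRUE
    return(row)
  }
  b <- n1 - a; d <- n2 - c_
  if (any(c(a, b, c_, d) == 0) && correction > 0) {
    a <- a + correction; b <- b + correction
    c_ <- c_ + correction; d <- d + correction
    n1 <- a + b; n2 <- c_ + d
    row$continuity_corrected <- TRUE
  }
  if (measure == "RR") {
    log_eff <- log((a / n1) / (c_ / n2))
    v <- 1 / a - 1 / n1 + 1 / c_ - 1 / n2
  } else {
    log_eff <- log((a * d) / (c_ * b))
    v <- 1 / a + 1 / b + 1 / c_ + 1 / d
  }
  if (!is.finite(log_eff) || v <= 0) {
    row$excluded <- TRUE
    return(row)
  }
  se <- sqrt(v)
  z <- stats::qnorm(0.975)
  row$log_effect <- log_eff; row$se <- se; row$effect <- exp(log_eff)
  row$ci_low <- exp(log_eff - z * se); row$ci_high <- exp(log_eff + z * se)
  row
}

.check_estimates <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  if (!nrow(estimates)) stop("no estimates to pool")
  if (length(unique(estimates$measure)) > 1)
    stop("estimates mix RR and OR")
  if (any(!is.finite(estimates$se)) || any(estimates$se <= 0))
    stop("estimates contain non-positive or missing standard errors")
  invisible(estimates)
}

.pool_with_weights <- function(theta, w, model, k, het) {
  pooled <- sum(w * theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  zq <- stats::qnorm(0.975)
  list(model = model, k = k,
       log_effect = pooled, se = se,
       effect = exp(pooled),
       ci_low = exp(pooled - zq * se), ci_high = exp(pooled + zq * se),
       z = z, p_value = 2 * stats::pnorm(-abs(z)),
       Q = het$Q, Q_df = het$Q_df, Q_p = het$Q_p,
       I2 = het$I2, tau2 = het$tau2)
}

#' Cochran heterogeneity statistics and DerSimonian-Laird tau-squared
#'
#' `Q = sum w_i (theta_i - theta_fixed)^2` with inverse-variance weights
#' `w_i = 1/se_i^2`; `I2 = max(0, 100 (Q - df) / Q)`;
#' `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))`. With a single
#' study all statistics are zero by convention and `Q_p` is `NA`.
#'
#' @param estimates Data frame of per-study estimates ([study_effect()]).
#' @return List with `Q`, `Q_df`, `Q_p`, `I2`, `tau2`.
#' @export
heterogeneity <- function(estimates) {
  .check_estimates(estimates)
  k <- nrow(estimates)
  if (k == 1)
    return(list(Q = 0, Q_df = 0L, Q_p = NA_real_, I2 = 0, tau2 = 0))
  theta <- estimates$log_effect
  w <- 1 / estimates$se^2
  fixed <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - fixed)^2)
  df <- k - 1L
  Q_p <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, 100 * (Q - df) / Q) else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, Q_df = df, Q_p = Q_p, I2 = I2, tau2 = tau2)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' @param estimates Data frame of per-study estimates.
#' @return Pooled-result list: `model`, `k`, `log_effect`, `se`, `effect`,
#'   `ci_low`, `ci_high`, `z`, `p_value`, `Q`, `Q_df`, `Q_p`, `I2`, `tau2`.
#' @export
pool_fixed <- function(estimates) {
  .check_estimates(estimates)
  het <- heterogeneity(estimates)
  w <- 1 / estimates$se^2
  .pool_with_weights(estimates$log_effect, w, "Fixed", nrow(estimates), het)
}

#' Random-effects (DerSimonian-Laird) pooling
#'
#' Adjusted weights `w*_i = 1 / (se_i^2 + tau2)` with the DL `tau2` from
#' [heterogeneity()]. When `tau2` truncates to zero the result equals
#' [pool_fixed()] exactly.
#'
#' @param estimates Data frame of per-study estimates.
#' @return Pooled-result list as in [pool_fixed()], `model = "Random"`.
#' @export
pool_random <- function(estimates) {
  .check_estimates(estimates)
  het <- heterogeneity(estimates)
  w <- 1 / (estimates$se^2 + het$tau2)
  .pool_with_weights(estimates$log_effect, w, "Random", nrow(estimates), het)
}

#' Model-selection rule
#'
#' Random effects are used when the heterogeneity test is significant:
#' `Q_p < alpha` (strict). A single study (`Q_p` `NA`) is always pooled
#' fixed.
#'
#' @param Q_p Heterogeneity p-value (may be `NA` for k = 1).
#' @param alpha Significance level, default 0.05.
#' @return `"Random"` or `"Fixed"`.
#' @export
select_model <- function(Q_p, alpha = 0.05) {
  if (is.na(Q_p)) return("Fixed")
  if (Q_p < alpha) "Random" else "Fixed"
}

#' Meta-analysis of one genetic contrast across studies
#'
#' Builds each study's 2x2 via [contrast_table()], estimates per-study
#' effects, computes heterogeneity, selects the pooling model with
#' [select_model()] and pools. Double-zero studies are excluded from the
#' contrast with their ids recorded in the result.
#'
#' @param studies Study data frame (see [study_columns()]).
#' @param contrast One of [genetic_contrasts()].
#' @param measure `"RR"` or `"OR"`.
#' @param alpha Heterogeneity significance level for model selection.
#' @param correction Continuity-correction constant.
#' @return Pooled-result list plus `estimates` (per-study data frame),
#'   `excluded` (study ids) and `contrast`.
#' @export
meta_analyze <- function(studies, contrast, measure = c("RR", "OR"),
                         alpha = 0.05, correction = 0.5) {
  measure <- match.arg(measure)
  if (!nrow(studies)) stop("meta_analyze: no studies")
  est <- lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    tab <- contrast_table(
      genotype_counts(s$case_wild, s$case_het, s$case_var),
      genotype_counts(s$ctrl_wild, s$ctrl_het, s$ctrl_var),
      contrast)
    study_effect(tab, measure, correction, study_id = s$study_id)
  })
  est <- do.call(rbind, est)
  excluded <- est$study_id[est$excluded]
  est <- est[!est$excluded, , drop = FALSE]
  if (!nrow(est))
    stop("meta_analyze: all studies excluded for contrast ", contrast)
  het <- heterogeneity(est)
  model <- select_model(het$Q_p, alpha)
  pooled <- if (model == "Random") pool_random(est) else pool_fixed(est)
  pooled$estimates <- est
  pooled$excluded <- excluded
  pooled$contrast <- contrast
  pooled
}

#' Egger regression test for funnel asymmetry
#'
#' Unweighted OLS of the standardized effect `theta_i / se_i` on the
#' precision `1 / se_i`; the intercept estimates small-study bias, tested
#' with `t = intercept / se(intercept)` on `k - 2` df.
#'
#' @param estimates Data frame of per-study estimates; needs `k >= 3`.
#' @return List: `intercept`, `intercept_se`, `t`, `df`, `p_value`, `slope`.
#' @export
egger_test <- function(estimates) {
  .check_estimates(estimates)
  k <- nrow(estimates)
  if (k < 3) stop("egger_test: needs at least 3 studies, got ", k)
  y <- estimates$log_effect / estimates$se
  x <- 1 / estimates$se
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  t <- cf[1, "t value"]
  list(intercept = cf[1, "Estimate"], intercept_se = cf[1, "Std. Error"],
       t = t, df = k - 2L,
       p_value = 2 * stats::pt(-abs(t), df = k - 2),
       slope = cf[2, "Estimate"])
}

#' Funnel-plot coordinates
#'
#' @param estimates Data frame of per-study estimates.
#' @return List with `points` (data frame `study_id`, `effect`,
#'   `log_effect`, `se`) and `center` (fixed-effect pooled effect).
#' @export
funnel_data <- function(estimates) {
  .check_estimates(estimates)
  pooled <- pool_fixed(estimates)
  list(points = estimates[c("study_id", "effect", "log_effect", "se")],
       center = pooled$effect)
}
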