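# Independent brute-force oracles: direct transcriptions of the defining
# formulas, kept free of any package internals they are used to check.

oracle_hwe_chisq <- function(wild, het, var) {
  n <- wild + het + var
  q <- (2 * var + het) / (2 * n)
  p <- 1 - q
  expected <- c(p^2, 2 * p * q, q^2) * n
  observed <- c(wild, het, var)
  sum((observed - expected)^2 / expected)
}

oracle_q <- function(theta, se) {
  w <- 1 / se^2
  fixed <- sum(w * theta) / sum(w)
  sum(w * (theta - fixed)^2)
}

oracle_dl_tau2 <- function(theta, se) {
  w <- 1 / se^2
  Q <- oracle_q(theta, se)
  df <- length(theta) - 1
  max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
}

oracle_dl_pooled <- function(theta, se) {
  tau2 <- oracle_dl_tau2(theta, se)
  w <- 1 / (se^2 + tau2)
  list(pooled = sum(w * theta) / sum(w), se = 1 / sqrt(sum(w)),
       tau2 = tau2)
}

# Egger intercept by the normal equations for y = b0 + b1 x,
# y_i = theta_i / se_i, x_i = 1 / se_i.
oracle_egger <- function(theta, se) {
  y <- theta / se
  x <- 1 / se
  n <- length(x)
  b1 <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  b0 <- mean(y) - b1 * mean(x)
  resid <- y - b0 - b1 * x
  s2 <- sum(resid^2) / (n - 2)
  se_b0 <- sqrt(s2 * (1 / n + mean(x)^2 / (sum((x - mean(x))^2))))
  list(intercept = b0, intercept_se = se_b0, slope = b1,
       t = b0 / se_b0)
}

oracle_aicc <- function(sse, n, k) {
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Exhaustive partition search: every contiguous binary split plus the
# no-split model, scored with oracle_aicc; ties keep the simpler model.
oracle_partition <- function(values, levels, min_leaf = 5) {
  lv <- sort(unique(levels))
  sse_of <- function(groups) {
    sum(unlist(lapply(split(values, groups),
                      function(v) sum((v - mean(v))^2))))
  }
  n <- length(values)
  cands <- list(list(label = "no split",
                     aicc = oracle_aicc(sse_of(rep(1, n)), n, 2)))
  for (cut in seq_len(length(lv) - 1)) {
    left <- lv[seq_len(cut)]
    grp <- levels %in% left
    if (min(sum(grp), sum(!grp)) < min_leaf) next
    cands[[length(cands) + 1]] <- list(
      label = paste0("{", paste(left, collapse = ","), "}|{",
                     paste(lv[-seq_len(cut)], collapse = ","), "}"),
      aicc = oracle_aicc(sse_of(grp), n, 3))
  }
  best <- 1
  for (i in seq_along(cands))
    if (cands[[i]]$aicc < cands[[best]]$aicc) best <- i
  cands[[best]]$label
}

# Random per-study estimate sets for property tests.
random_estimates <- function(k, seed) {
  set.seed(seed)
  data.frame(study_id = paste0("S", seq_len(k)), measure = "RR",
             log_effect = rnorm(k, 0, 0.5),
             se = runif(k, 0.05, 0.6),
             effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             continuity_corrected = FALSE, excluded = FALSE,
             stringsAsFactors = FALSE)
}
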