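#' Study-level outcome variables for meta-prediction
#'
#' Converts each study into the outcome variables analyzed against air
#' pollution: genotype percentages per arm (`pct_TT_case`, `pct_TT_ctrl`,
#' `pct_CT_*`, `pct_CC_*`, `pct_TTCT_*`, full precision) and per-study
#' risk ratios per contrast (`rr_TT`, `rr_CT`, `rr_CC`, `rr_TTCT`).
#' Double-zero risk ratios are omitted; the omitted study/variable pairs
#' are attached as attribute `"omitted"`.
#'
#' @param studies Study data frame with pollution levels already merged
#'   (see [merge_pollution_levels()]).
#' @param correction Continuity-correction constant for the risk ratios.
#' @return Long data frame: `study_id`, `variable`, `value`,
#'   `pollution_level`.
#' @export
compute_outcomes <- function(studies, correction = 0.5) {
  if (any(studies$air_pollution_level == 1L))
    stop("compute_outcomes: merge pollution levels first")
  pct_vars <- c(TT = "var", CT = "het", CC = "wild")
  rr_contrasts <- c(rr_TT = "TT", rr_CT = "CT", rr_CC = "CC",
                    rr_TTCT = "TT+CT")
  rows <- list(); omitted <- list()
  for (i in seq_len(nrow(studies))) {
    s <- studies[i, ]
    cases <- genotype_counts(s$case_wild, s$case_het, s$case_var)
    ctrls <- genotype_counts(s$ctrl_wild, s$ctrl_het, s$ctrl_var)
    add <- function(variable, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        study_id = s$study_id, variable = variable, value = value,
        pollution_level = s$air_pollution_level,
        stringsAsFactors = FALSE)
    }
    for (g in names(pct_vars)) {
      add(paste0("pct_", g, "_case"), 100 * cases[[pct_vars[g]]] / cases$total)
      add(paste0("pct_", g, "_ctrl"), 100 * ctrls[[pct_vars[g]]] / ctrls$total)
    }
    add("pct_TTCT_case", 100 * (cases$var + cases$het) / cases$total)
    add("pct_TTCT_ctrl", 100 * (ctrls$var + ctrls$het) / ctrls$total)
    for (v in names(rr_contrasts)) {
      est <- study_effect(contrast_table(cases, ctrls, rr_contrasts[[v]]),
                          "RR", correction, study_id = s$study_id)
      if (est$excluded) {
        omitted[[length(omitted) + 1L]] <-
          paste0(s$study_id, ":", v, " (double-zero)")
      } else {
        add(v, est$effect)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "omitted") <- unlist(omitted)
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' For a normal model with `n_params` mean/variance parameters fitted to
#' `n` observations with residual sum of squares `sse`:
#' `AICc = n log(sse/n) + 2k + 2k(k+1)/(n - k - 1)` with `k = n_params`.
#'
#' @param sse Residual sum of squares, `>= 0`.
#' @param n Number of observations.
#' @param n_params Number of parameters (group means + 1 variance).
#' @return AICc value (`-Inf` when `sse` is exactly 0).
#' @export
aicc <- function(sse, n, n_params) {
  if (sse < 0) stop("aicc: negative SSE")
  k <- n_params
  if (n <= k + 1) stop("aicc: n must exceed n_params + 1")
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.group_sse <- function(values, groups) {
  sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
}

#' AICc-judged binary partition of studies over pollution levels
#'
#' Enumerates the no-split model and every ordinal-contiguous binary split
#' of the observed pollution levels (on levels 2/3/4: `{2}|{3,4}` and
#' `{2,3}|{4}`), fits group-mean normal models, scores each candidate with
#' [aicc()] (parameters = group means + 1 common variance) and returns the
#' minimizer. Ties break toward the simpler model. Candidates with a group
#' below `min_leaf` observations are excluded; if every split is excluded
#' the no-split model is returned.
#'
#' @param outcomes Long outcome data frame for a single variable
#'   (columns `value`, `pollution_level`).
#' @param min_leaf Minimum observations per side of a split.
#' @return List: `variable`, `candidates` (label, aicc, n_groups),
#'   `chosen` (label), `split` (list `left`, `right`, or `NULL` for
#'   no-split), `groups` (levels, count, mean, sd).
#' @export
partition_split <- function(outcomes, min_leaf = 5) {
  stopifnot(all(c("value", "pollution_level") %in% names(outcomes)))
  if (length(unique(outcomes$variable)) > 1)
    stop("partition_split: one variable at a time")
  levels_obs <- sort(unique(outcomes$pollution_level))
  if (length(levels_obs) < 2)
    stop("partition_split: need at least 2 distinct pollution levels")
  v <- outcomes$value
  lev <- outcomes$pollution_level
  n <- length(v)

  candidates <- list(list(label = "no split",
                          assign = rep("all", n), n_groups = 1L,
                          split = NULL))
  for (cut in seq_len(length(levels_obs) - 1)) {
    left <- levels_obs[seq_len(cut)]
    right <- levels_obs[-seq_len(cut)]
    grp <- ifelse(lev %in% left, "left", "right")
    if (min(table(grp)) < min_leaf) next
    candidates[[length(candidates) + 1L]] <- list(
      label = paste0("{", paste(left, collapse = ","), "}|{",
                     paste(right, collapse = ","), "}"),
      assign = grp, n_groups = 2L,
      split = list(left = left, right = right))
  }

  cand_df <- do.call(rbind, lapply(candidates, function(cd) {
    data.frame(label = cd$label,
               aicc = aicc(.group_sse(v, cd$assign), n, cd$n_groups + 1L),
               n_groups = cd$n_groups, stringsAsFactors = FALSE)
  }))
  # argmin with ties toward the simpler model: candidates are ordered
  # no-split first, so strict improvement is required to switch
  best <- 1L
  for (i in seq_along(candidates))
    if (cand_df$aicc[i] < cand_df$aicc[best]) best <- i
  chosen <- candidates[[best]]

  group_stats <- function(sel_levels, label) {
    vv <- v[lev %in% sel_levels]
    data.frame(levels = label, count = length(vv), mean = mean(vv),
               sd = stats::sd(vv), stringsAsFactors = FALSE)
  }
  groups <- if (is.null(chosen$split)) {
    group_stats(levels_obs, paste(levels_obs, collapse = " and "))
  } else {
    rbind(group_stats(chosen$split$left,
                      paste(chosen$split$left, collapse = " and ")),
          group_stats(chosen$split$right,
                      paste(chosen$split$right, collapse = " and ")))
  }
  list(variable = unique(outcomes$variable) %||% NA_character_,
       candidates = cand_df, chosen = chosen$label, split = chosen$split,
       groups = groups)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Tukey-Kramer multiple comparison of level means
#'
#' Pairwise differences of group means with the Kramer unbalanced-group
#' standard error `sqrt(MSE (1/n_i + 1/n_j))`, simultaneous 95% CIs and
#' adjusted p-values from the studentized-range distribution with
#' (number of groups, error df). Pairs are reported once, larger mean
#' first, so differences are non-negative.
#'
#' @param values Numeric outcome values.
#' @param groups Grouping vector (pollution levels), same length.
#' @param conf_level Simultaneous confidence level.
#' @return Data frame: `level_a`, `level_b`, `difference`,
#'   `se_difference`, `lower`, `upper`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  labs <- sort(unique(groups))
  g <- length(labs)
  if (g < 2) stop("tukey_hsd: need at least 2 groups")
  ns <- tapply(values, groups, length)[labs]
  ms <- tapply(values, groups, mean)[labs]
  N <- length(values)
  df <- N - g
  if (df < 1) stop("tukey_hsd: no residual degrees of freedom")
  mse <- sum((values - ms[groups])^2) / df
  qcrit <- stats::qtukey(conf_level, g, df)
  rows <- list()
  for (i in seq_len(g - 1)) for (j in seq((i + 1), g)) {
    hi <- if (ms[i] >= ms[j]) i else j
    lo <- if (hi == i) j else i
    diff <- ms[hi] - ms[lo]
    se <- sqrt(mse * (1 / ns[hi] + 1 / ns[lo]))
    q_obs <- sqrt(2) * diff / se
    rows[[length(rows) + 1L]] <- data.frame(
      level_a = labs[hi], level_b = labs[lo],
      difference = unname(diff), se_difference = unname(se),
      lower = unname(diff - qcrit * se / sqrt(2)),
      upper = unname(diff + qcrit * se / sqrt(2)),
      p_adj = stats::ptukey(q_obs, g, df, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Polynomial trend of an outcome over pollution levels
#'
#' Least-squares polynomial (default quadratic) of the outcome on the
#' pollution level treated as numeric. The degree is reduced when fewer
#' distinct levels are observed than the requested degree + 1.
#'
#' @param outcomes Long outcome data frame for one variable.
#' @param degree Polynomial degree, default 2.
#' @return List: `degree`, `coefficients` (ascending powers), `fitted`
#'   (data frame `pollution_level`, `fitted`).
#' @export
nonlinear_fit <- function(outcomes, degree = 2) {
  v <- outcomes$value
  x <- outcomes$pollution_level
  if (length(v) < 2) stop("nonlinear_fit: need at least 2 points")
  m <- length(unique(x))
  degree <- as.integer(min(degree, m - 1))
  if (degree < 1) stop("nonlinear_fit: need at least 2 distinct levels")
  fit <- stats::lm(v ~ stats::poly(x, degree, raw = TRUE))
  co <- unname(stats::coef(fit))
  lv <- sort(unique(x))
  fitted_vals <- vapply(lv, function(l) sum(co * l^(0:degree)), numeric(1))
  list(degree = degree, coefficients = co,
       fitted = data.frame(pollution_level = lv, fitted = fitted_vals))
}

#' Heat-map density bins
#'
#' Counts outcomes per (pollution level, value bin). Bins are half-open
#' `[low, high)` with the last bin closed; values outside the grid are
#' clipped into the edge bins and counted in attribute `"clipped"`.
#'
#' @param outcomes Long outcome data frame for one variable.
#' @param x_levels Pollution levels forming the columns (default observed).
#' @param y_breaks Strictly increasing numeric bin boundaries.
#' @return Integer matrix, rows = value bins (labelled `[a,b)`),
#'   columns = levels; total equals `nrow(outcomes)`.
#' @export
heatmap_bins <- function(outcomes, x_levels = NULL, y_breaks) {
  if (is.unsorted(y_breaks, strictly = TRUE))
    stop("heatmap_bins: y_breaks must be strictly increasing")
  if (length(y_breaks) < 2) stop("heatmap_bins: need at least one bin")
  if (is.null(x_levels)) x_levels <- sort(unique(outcomes$pollution_level))
  v <- outcomes$value
  clipped <- sum(v < y_breaks[1] | v > y_breaks[length(y_breaks)])
  v <- pmin(pmax(v, y_breaks[1]),
            y_breaks[length(y_breaks)] - .Machine$double.eps^0.5)
  bin <- findInterval(v, y_breaks, rightmost.closed = TRUE)
  nb <- length(y_breaks) - 1
  mat <- matrix(0L, nrow = nb, ncol = length(x_levels),
                dimnames = list(
                  paste0("[", utils::head(y_breaks, -1), ",",
                         utils::tail(y_breaks, -1), ")"),
                  as.character(x_levels)))
  for (i in seq_along(bin)) {
    col <- as.character(outcomes$pollution_level[i])
    mat[bin[i], col] <- mat[bin[i], col] + 1L
  }
  attr(mat, "clipped") <- clipped
  mat
}
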