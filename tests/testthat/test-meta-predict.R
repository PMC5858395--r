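outcomes_for <- function(values_by_level, variable = "pct_TTCT_case") {
  do.call(rbind, lapply(names(values_by_level), function(lv) {
    v <- values_by_level[[lv]]
    data.frame(study_id = paste0("L", lv, "_", seq_along(v)),
               variable = variable, value = v,
               pollution_level = as.integer(lv),
               stringsAsFactors = FALSE)
  }))
}

test_that("study outcomes recompute directly from the raw counts", {
  df <- rbind(make_study("S001", case = c(40, 40, 20), ctrl = c(50, 40, 10)),
              make_study("S002", case = c(30, 30, 40), ctrl = c(30, 30, 40),
                         air_pollution_level = 4L))
  out <- compute_outcomes(df)
  g <- function(id, var) out$value[out$study_id == id & out$variable == var]
  expect_equal(g("S001", "pct_TT_case"), 20)
  expect_equal(g("S001", "pct_TTCT_ctrl"), 50)
  expect_equal(g("S002", "rr_TT"), 1)       # symmetric arms
  expect_equal(g("S001", "rr_TT"),
               study_effect(list(a = 20, n1 = 100, c = 10, n2 = 100),
                            "RR")$effect)
  expect_identical(unique(out$pollution_level[out$study_id == "S002"]), 4L)

  # double-zero risk ratio is omitted, percentages kept
  dz <- make_study("S003", case = c(60, 40, 0), ctrl = c(70, 30, 0))
  out2 <- compute_outcomes(rbind(df, dz))
  expect_false(any(out2$study_id == "S003" & out2$variable == "rr_TT"))
  expect_true(any(out2$study_id == "S003" & out2$variable == "pct_TT_case"))
  expect_match(attr(out2, "omitted"), "S003", all = FALSE)

  unmerged <- make_study("S004", air_pollution_level = 1L)
  expect_error(compute_outcomes(unmerged), "merge")
})

test_that("AICc transcribes its formula and is monotone in SSE", {
  expect_equal(aicc(10, 20, 2),
               20 * log(10 / 20) + 4 + 2 * 2 * 3 / (20 - 3),
               tolerance = 1e-12)
  expect_lt(aicc(5, 20, 2), aicc(10, 20, 2))
  expect_error(aicc(10, 3, 2), "exceed")
  expect_error(aicc(-1, 20, 2), "negative")
})

test_that("partition_split finds the level-4 break and honors ties", {
  out <- outcomes_for(list(`2` = rep(10, 6), `3` = rep(10, 6),
                           `4` = rep(20, 6)))
  # exact group means: add jitter-free separation, SSE 0 both sides
  ps <- partition_split(out)
  expect_identical(ps$chosen, "{2,3}|{4}")
  expect_identical(ps$split$left, c(2L, 3L))
  expect_identical(ps$split$right, 4L)
  expect_equal(ps$groups$mean, c(10, 20))
  expect_equal(ps$groups$count, c(12, 6))

  # all equal: the no-split model wins on the tie
  flat <- outcomes_for(list(`2` = rep(7, 6), `3` = rep(7, 6),
                            `4` = rep(7, 6)))
  expect_identical(partition_split(flat)$chosen, "no split")

  one <- outcomes_for(list(`4` = rep(3, 8)))
  expect_error(partition_split(one), "2 distinct")
})

test_that("partition_split agrees with exhaustive enumeration on random data", {
  set.seed(99)
  for (rep in 1:200) {
    vals <- list(`2` = rnorm(sample(5:10, 1), 10, 3),
                 `3` = rnorm(sample(5:10, 1), 10 + runif(1, 0, 6), 3),
                 `4` = rnorm(sample(5:10, 1), 10 + runif(1, 0, 12), 3))
    out <- outcomes_for(vals)
    ps <- partition_split(out)
    expect_identical(ps$chosen,
                     oracle_partition(out$value, out$pollution_level))
  }
})

test_that("Tukey-Kramer has symmetric structure and sane limits", {
  out <- outcomes_for(list(`2` = c(5, 5, 5, 5, 6, 4),
                           `3` = c(5, 5, 5, 5, 6, 4),
                           `4` = c(5, 5, 5, 5, 6, 4)))
  tk <- tukey_hsd(out$value, out$pollution_level)
  expect_identical(nrow(tk), 3L)
  expect_true(all(tk$difference == 0))
  expect_true(all(tk$p_adj > 0.999))
  expect_true(all(tk$lower <= tk$difference & tk$difference <= tk$upper))
})

test_that("two-group Tukey reduces to the pooled two-sample t-test", {
  set.seed(12)
  x <- rnorm(9, 10, 2); y <- rnorm(7, 12, 2)
  tk <- tukey_hsd(c(x, y), rep(c("2", "4"), c(9, 7)))
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(tk$difference, unname(diff(rev(tt$estimate))) * sign(1),
               tolerance = 1e-10)
})

test_that("Tukey results match TukeyHSD on unbalanced groups", {
  set.seed(13)
  values <- c(rnorm(8, 10), rnorm(12, 13), rnorm(5, 11))
  groups <- rep(c("2", "3", "4"), c(8, 12, 5))
  tk <- tukey_hsd(values, groups)
  ref <- TukeyHSD(aov(values ~ factor(groups)))$`factor(groups)`
  for (i in seq_len(nrow(tk))) {
    key <- paste0(tk$level_a[i], "-", tk$level_b[i])
    alt <- paste0(tk$level_b[i], "-", tk$level_a[i])
    if (key %in% rownames(ref)) {
      expect_equal(tk$difference[i], ref[key, "diff"], tolerance = 1e-8)
      expect_equal(tk$p_adj[i], ref[key, "p adj"], tolerance = 1e-8)
      expect_equal(tk$lower[i], ref[key, "lwr"], tolerance = 1e-8)
    } else {
      expect_equal(tk$difference[i], -ref[alt, "diff"], tolerance = 1e-8)
      expect_equal(tk$p_adj[i], ref[alt, "p adj"], tolerance = 1e-8)
      expect_equal(tk$lower[i], -ref[alt, "upr"], tolerance = 1e-8)
    }
  }
})

test_that("Tukey adjusted p is monotone nonincreasing in the difference", {
  base <- c(10, 11, 9, 10.5, 9.5, 10)
  p_at <- vapply(c(0.5, 1, 2, 4, 8), function(shift) {
    out <- outcomes_for(list(`2` = base, `4` = base + shift))
    tukey_hsd(out$value, out$pollution_level)$p_adj
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
})

test_that("nonlinear fit interpolates three level means exactly", {
  out <- outcomes_for(list(`2` = 10, `3` = 14, `4` = 13))
  fit <- nonlinear_fit(out)
  expect_identical(fit$degree, 2L)
  expect_equal(fit$fitted$fitted, c(10, 14, 13), tolerance = 1e-8)

  flat <- outcomes_for(list(`2` = rep(6, 4), `3` = rep(6, 4),
                            `4` = rep(6, 4)))
  cf <- nonlinear_fit(flat)$coefficients
  expect_equal(cf[2], 0, tolerance = 1e-10)
  expect_equal(cf[3], 0, tolerance = 1e-10)

  # coefficients match the normal-equations solution
  set.seed(14)
  out <- outcomes_for(list(`2` = rnorm(6, 10), `3` = rnorm(6, 12),
                           `4` = rnorm(6, 15)))
  fit <- nonlinear_fit(out)
  X <- cbind(1, out$pollution_level, out$pollution_level^2)
  beta <- solve(t(X) %*% X, t(X) %*% out$value)
  expect_equal(fit$coefficients, as.vector(beta), tolerance = 1e-8)

  expect_error(nonlinear_fit(outcomes_for(list(`2` = 3))), "2 points")
})

test_that("heat-map bins conserve counts and clip out-of-grid values", {
  out <- outcomes_for(list(`2` = c(5, 15, 25), `3` = c(35, 45),
                           `4` = c(55, 65, 75, 85)))
  m <- heatmap_bins(out, y_breaks = seq(0, 100, 20))
  expect_identical(sum(m), 9L)
  expect_identical(attr(m, "clipped"), 0L)

  single <- outcomes_for(list(`3` = 42))
  m1 <- heatmap_bins(single, x_levels = 2:4, y_breaks = seq(0, 100, 20))
  expect_identical(sum(m1), 1L)
  expect_identical(sum(m1 > 0), 1L)
  expect_identical(m1["[40,60)", "3"], 1L)

  # translation invariance
  shifted <- out; shifted$value <- shifted$value + 7
  m2 <- heatmap_bins(shifted, y_breaks = seq(0, 100, 20) + 7)
  expect_identical(unname(m2), unname(m))

  oob <- outcomes_for(list(`2` = c(-3, 105)))
  m3 <- heatmap_bins(oob, y_breaks = seq(0, 100, 20))
  expect_identical(attr(m3, "clipped"), 2L)
  expect_identical(sum(m3), 2L)
})
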