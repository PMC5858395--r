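#!/usr/bin/env Rscript
# Step 4: meta-prediction — study-level polymorphism summaries against
# ordinal air-pollution levels: AICc-judged binary partitions,
# Tukey-Kramer pairwise comparisons, quadratic trends, heat-map bins.

suppressPackageStartupMessages(library(hdpmeta))

studies <- merge_pollution_levels(read_studies("results/synthetic_studies.csv"))
outcomes <- compute_outcomes(studies)

vars <- c("pct_TTCT_case", "pct_TTCT_ctrl", "pct_CT_case", "pct_CT_ctrl",
          "pct_CC_case", "pct_CC_ctrl", "pct_TT_case", "pct_TT_ctrl",
          "rr_TT", "rr_CT", "rr_CC", "rr_TTCT")
rows <- list(); heat <- list()
for (v in vars) {
  ov <- outcomes[outcomes$variable == v, ]
  ps <- partition_split(ov)
  tk <- tukey_hsd(ov$value, ov$pollution_level)
  fit <- nonlinear_fit(ov)
  p42 <- tk$p_adj[(tk$level_a == "4" & tk$level_b == "2") |
                    (tk$level_a == "2" & tk$level_b == "4")]
  rows[[v]] <- data.frame(
    variable = v, chosen_split = ps$chosen,
    aicc = round(min(ps$candidates$aicc), 3),
    p_4_vs_2 = round(p42, 4),
    curvature = round(fit$coefficients[length(fit$coefficients)], 3))
  if (startsWith(v, "pct_"))
    heat[[v]] <- heatmap_bins(ov, y_breaks = seq(0, 100, 10))
}
summary_tab <- do.call(rbind, c(rows, make.row.names = FALSE))

heat_long <- do.call(rbind, lapply(names(heat), function(v) {
  m <- heat[[v]]
  data.frame(variable = v,
             bin = rep(rownames(m), ncol(m)),
             level = rep(colnames(m), each = nrow(m)),
             count = as.vector(m))
}))

write_report(list(partition_summary = summary_tab,
                  heatmap_bins = heat_long),
             "results/meta_predict")

cat("Partition and Tukey summary per outcome variable:\n")
print(summary_tab, row.names = FALSE)
sig <- summary_tab$variable[summary_tab$p_4_vs_2 < 0.05]
cat("\nVariables with a significant 4-vs-2 Tukey contrast:",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
cat("Case-arm polymorphism summaries should split at level 4 under the\n")
cat("generator's gradient; control-arm percentages should not.\n")
cat("Tables written under results/meta_predict/\n")
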