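#' Stratify studies by a declared field
#'
#' Groups study ids by one of `ethnic_group`, `hdp_subtype`, `country` or
#' `air_pollution_level`. Country labels are matched case-insensitively
#' and reported with their first-seen spelling. Group labels are sorted
#' for stable output; the groups partition the input.
#'
#' @param studies Study data frame.
#' @param key One of `"ethnic_group"`, `"hdp_subtype"`, `"country"`,
#'   `"air_pollution_level"`.
#' @return Named list mapping group label to a character vector of
#'   study ids.
#' @export
stratify <- function(studies,
                     key = c("ethnic_group", "hdp_subtype", "country",
                             "air_pollution_level")) {
  key <- match.arg(key)
  if (!nrow(studies)) return(structure(list(), names = character(0)))
  vals <- studies[[key]]
  if (key == "country") {
    lowered <- tolower(vals)
    labels <- vals[!duplicated(lowered)]
    names(labels) <- lowered[!duplicated(lowered)]
    groups <- split(studies$study_id, lowered)
    names(groups) <- unname(labels[names(groups)])
  } else {
    groups <- split(studies$study_id, as.character(vals))
  }
  groups[order(names(groups))]
}

#' Classify countries by the direction of their variant-homozygote risk
#'
#' A country whose study-level risk ratios all exceed 1 is a risk country
#' (`RiskAbove1`); all below 1, protective (`ProtectiveBelow1`); study RRs
#' straddling 1 (or any undefined RR), `Varied`. Classes are mutually
#' exclusive and exhaustive over the input countries.
#'
#' @param per_country Named list mapping country to a numeric vector of
#'   study-level risk ratios (`NA` allowed for undefined estimates).
#' @return Data frame with columns `country`, `class`, `n_studies`.
#' @export
classify_tt_direction <- function(per_country) {
  stopifnot(length(per_country) > 0)
  cls <- vapply(per_country, function(rr) {
    if (any(is.na(rr))) return("Varied")
    if (all(rr > 1)) return("RiskAbove1")
    if (all(rr < 1)) return("ProtectiveBelow1")
    "Varied"
  }, character(1))
  data.frame(country = names(per_country), class = unname(cls),
             n_studies = vapply(per_country, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

.group_counts <- function(studies, contrast) {
  case_gc <- genotype_counts(sum(studies$case_wild), sum(studies$case_het),
                             sum(studies$case_var))
  ctrl_gc <- genotype_counts(sum(studies$ctrl_wild), sum(studies$ctrl_het),
                             sum(studies$ctrl_var))
  list(case_exposed = contrast_exposed(case_gc, contrast),
       case_total = case_gc$total,
       ctrl_exposed = contrast_exposed(ctrl_gc, contrast),
       ctrl_total = ctrl_gc$total)
}

.summary_row <- function(studies, group, contrast, measure, alpha,
                         correction) {
  cc <- .group_counts(studies, contrast)
  base <- data.frame(
    contrast = contrast, group = group, n_studies = nrow(studies),
    case_exposed = cc$case_exposed, case_total = cc$case_total,
    case_pct = genotype_percentage(cc$case_exposed, cc$case_total),
    ctrl_exposed = cc$ctrl_exposed, ctrl_total = cc$ctrl_total,
    ctrl_pct = genotype_percentage(cc$ctrl_exposed, cc$ctrl_total),
    model = NA_character_, effect = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
    pooled = FALSE, stringsAsFactors = FALSE)
  pooled <- tryCatch(
    meta_analyze(studies, contrast, measure, alpha, correction),
    error = function(e) NULL)
  if (is.null(pooled)) return(base)   # all studies excluded: counts only
  base$model <- if (pooled$k == 1) "Single study" else pooled$model
  base$effect <- round_half_up(pooled$effect, 2)
  base$ci_low <- round_half_up(pooled$ci_low, 2)
  base$ci_high <- round_half_up(pooled$ci_high, 2)
  base$p_value <- pooled$p_value
  base$pooled <- pooled$k > 1
  base
}

#' Pooled summary table across contrasts and subgroups
#'
#' One row per contrast for the overall study set and per subgroup of the
#' chosen stratification: exposed counts with percentages in each arm, the
#' selected pooling model, the pooled effect with 95% CI (rounded to two
#' decimals at this reporting boundary) and its p-value. Single-study
#' groups carry that study's own effect, labelled `"Single study"`.
#' Deterministic: repeated calls on the same input are identical.
#'
#' @param studies Study data frame.
#' @param contrasts Contrast labels, default all of [genetic_contrasts()].
#' @param measure `"RR"` or `"OR"`.
#' @param alpha Heterogeneity alpha for model selection.
#' @param correction Continuity-correction constant.
#' @param by Stratification key passed to [stratify()].
#' @return Data frame in the pooled-report schema.
#' @export
build_summary_table <- function(studies, contrasts = genetic_contrasts(),
                                measure = c("RR", "OR"), alpha = 0.05,
                                correction = 0.5, by = "ethnic_group") {
  measure <- match.arg(measure)
  if (!nrow(studies)) stop("build_summary_table: no studies")
  groups <- stratify(studies, by)
  rows <- list()
  for (ct in contrasts) {
    rows[[length(rows) + 1L]] <-
      .summary_row(studies, "Overall", ct, measure, alpha, correction)
    for (g in names(groups)) {
      sub <- studies[studies$study_id %in% groups[[g]], , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        .summary_row(sub, g, ct, measure, alpha, correction)
    }
  }
  do.call(rbind, rows)
}

#' Schema table of significant findings
#'
#' Condenses a pooled summary table into one row per group listing the
#' contrasts that were significant risks (effect > 1, p < alpha) and
#' significant protectives (effect < 1, p < alpha), mirroring a
#' findings-at-a-glance report.
#'
#' @param summary_table Output of [build_summary_table()].
#' @param alpha Significance level for calling a finding.
#' @return Data frame with `group`, `n_studies`, `risk_contrasts`,
#'   `protective_contrasts`.
#' @export
significant_findings <- function(summary_table, alpha = 0.05) {
  tab <- summary_table[summary_table$pooled & !is.na(summary_table$p_value), ]
  groups <- unique(summary_table$group)
  out <- lapply(groups, function(g) {
    gt <- tab[tab$group == g, ]
    sig <- gt[gt$p_value < alpha, ]
    data.frame(
      group = g,
      n_studies = max(summary_table$n_studies[summary_table$group == g]),
      risk_contrasts = paste(sig$contrast[sig$effect > 1], collapse = "; "),
      protective_contrasts = paste(sig$contrast[sig$effect < 1],
                                   collapse = "; "),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
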