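#' Run configuration
#'
#' Bundles the knobs of a full analysis run. `input` may be `NULL` when a
#' `synthetic` block supplies a generator configuration instead.
#'
#' @param input Path to a study CSV/TSV, or `NULL`.
#' @param delim Field delimiter for `input`.
#' @param locus Locus to analyze; studies at other loci are dropped with
#'   a warning entry.
#' @param contrasts Genetic contrasts to pool.
#' @param measure `"RR"` or `"OR"`.
#' @param alpha_het Heterogeneity alpha for fixed/random model selection.
#' @param correction Continuity-correction constant.
#' @param outdir Output directory for report tables.
#' @param seed Random seed recorded in the run log (and used by the
#'   synthetic block when present).
#' @param synthetic Optional [synthetic_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, delim = ",", locus = "C677T",
                       contrasts = genetic_contrasts(),
                       measure = "RR", alpha_het = 0.05, correction = 0.5,
                       outdir = "results", seed = 1, synthetic = NULL) {
  stopifnot(alpha_het > 0, alpha_het < 1, correction >= 0)
  structure(list(input = input, delim = delim, locus = locus,
                 contrasts = contrasts, measure = measure,
                 alpha_het = alpha_het, correction = correction,
                 outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; an optional
#' `synthetic:` mapping mirrors [synthetic_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    sy <- y$synthetic
    if (!is.null(sy$level_alloc)) sy$level_alloc <- unlist(sy$level_alloc)
    if (!is.null(sy$exposure_scores))
      sy$exposure_scores <- unlist(sy$exposure_scores)
    syn <- do.call(synthetic_config, sy)
  }
  y$synthetic <- NULL
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, c(args, list(synthetic = syn)))
}

#' Run the full analysis pipeline
#'
#' Stages: read (or generate) and validate the study table; merge
#' pollution level 1 into 2; Hardy-Weinberg screening of each study's
#' controls (flags only, nothing is dropped); pooled meta-analysis per
#' contrast overall and by ethnic group and HDP subtype; Egger and funnel
#' publication-bias diagnostics on the variant-homozygote contrast;
#' study-level outcomes, AICc partitions over pollution levels,
#' Tukey-Kramer comparisons, nonlinear trend fits and heat-map bins;
#' report tables written under `config$outdir`. No study is silently
#' dropped: every exclusion appears in the manifest warnings.
#'
#' @param config A [run_config()].
#' @return A manifest list: `config`, `n_studies`, `warnings`, `outputs`,
#'   `tables` (the in-memory report tables), `hwe` (per-study flags),
#'   `partitions`, `tukey`, `elapsed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  studies <- if (!is.null(config$input)) {
    read_studies(config$input, config$delim)
  } else if (!is.null(config$synthetic)) {
    generate_studies(config$synthetic)
  } else stop("run_pipeline: neither input nor synthetic block given")

  off_locus <- studies$locus != config$locus
  if (any(off_locus)) {
    note(sprintf("dropped %d studies at other loci (%s)",
                 sum(off_locus),
                 paste(studies$study_id[off_locus], collapse = ", ")))
    studies <- studies[!off_locus, , drop = FALSE]
  }
  if (!nrow(studies)) stop("run_pipeline: no studies at locus ", config$locus)
  if (any(studies$air_pollution_level == 5L))
    note("level-5 air pollution records retained")
  studies <- merge_pollution_levels(studies)

  hwe <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    h <- hwe_test(genotype_counts(s$ctrl_wild, s$ctrl_het, s$ctrl_var))
    data.frame(study_id = s$study_id, chi_square = h$chi_square,
               p_value = h$p_value, in_equilibrium = h$in_equilibrium,
               monomorphic = h$monomorphic, stringsAsFactors = FALSE)
  }))
  n_hwe_out <- sum(!hwe$in_equilibrium)
  if (n_hwe_out > 0)
    note(sprintf("%d studies out of Hardy-Weinberg equilibrium (flagged, retained)",
                 n_hwe_out))

  summary_eth <- build_summary_table(studies, config$contrasts,
                                     config$measure, config$alpha_het,
                                     config$correction, by = "ethnic_group")
  summary_sub <- build_summary_table(studies, config$contrasts,
                                     config$measure, config$alpha_het,
                                     config$correction, by = "hdp_subtype")
  findings <- significant_findings(rbind(summary_eth,
                                         summary_sub[summary_sub$group != "Overall", ]))

  tt <- meta_analyze(studies, "TT", config$measure, config$alpha_het,
                     config$correction)
  if (length(tt$excluded))
    note(paste("excluded from TT pooling (double-zero):",
               paste(tt$excluded, collapse = ", ")))
  egger <- if (tt$k >= 3) egger_test(tt$estimates) else NULL
  if (is.null(egger)) note("Egger test skipped: fewer than 3 studies")
  funnel <- funnel_data(tt$estimates)

  outcomes <- compute_outcomes(studies, config$correction)
  omitted <- attr(outcomes, "omitted")
  if (length(omitted))
    note(paste("outcomes omitted:", paste(omitted, collapse = "; ")))

  vars <- unique(outcomes$variable)
  partitions <- list(); tukey <- list(); trend <- list()
  table3_rows <- list()
  multi_level <- length(unique(outcomes$pollution_level)) >= 2
  if (!multi_level)
    note("partition stage skipped: fewer than 2 pollution levels")
  for (v in vars) {
    ov <- outcomes[outcomes$variable == v, ]
    if (!multi_level || length(unique(ov$pollution_level)) < 2) next
    ps <- tryCatch(partition_split(ov), error = function(e) NULL)
    if (is.null(ps)) {
      note(sprintf("partition skipped for %s: too few studies", v))
      next
    }
    tk <- tukey_hsd(ov$value, ov$pollution_level)
    fit <- nonlinear_fit(ov)
    partitions[[v]] <- ps; tukey[[v]] <- tk; trend[[v]] <- fit
    n_pairs <- nrow(tk)
    n_grp <- nrow(ps$groups)
    pad <- function(x, n) c(x, rep(NA, n - length(x)))
    nr <- max(n_pairs, n_grp)
    table3_rows[[v]] <- data.frame(
      variable = c(v, rep("", nr - 1)),
      aicc = pad(min(ps$candidates$aicc), nr),
      split_group = pad(ps$groups$levels, nr),
      count = pad(ps$groups$count, nr),
      mean = pad(ps$groups$mean, nr),
      sd = pad(ps$groups$sd, nr),
      levels_compared = pad(paste0(tk$level_a, "/", tk$level_b), nr),
      difference = pad(tk$difference, nr),
      se_difference = pad(tk$se_difference, nr),
      lower_ci = pad(tk$lower, nr),
      upper_ci = pad(tk$upper, nr),
      p = pad(tk$p_adj, nr),
      stringsAsFactors = FALSE)
  }

  tables <- list(
    table1_schema = findings,
    table2_schema = summary_eth,
    table2_subtype = summary_sub,
    hwe_flags = hwe,
    funnel = funnel$points)
  if (!is.null(egger))
    tables$egger <- data.frame(intercept = egger$intercept,
                               intercept_se = egger$intercept_se,
                               t = egger$t, df = egger$df,
                               p_value = egger$p_value, slope = egger$slope)
  if (length(table3_rows))
    tables$table3_schema <- do.call(rbind, c(table3_rows,
                                             make.row.names = FALSE))

  outputs <- write_report(tables, config$outdir,
                          config = unclass(config)[setdiff(names(config),
                                                           "synthetic")])
  list(config = config, n_studies = nrow(studies), warnings = warnings,
       outputs = outputs, tables = tables, hwe = hwe,
       partitions = partitions, tukey = tukey, trend = trend,
       elapsed = proc.time()[["elapsed"]] - t0)
}
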