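#' @title Study table input, validation and report output
#' @description Per-study genotype-count records travel through the package
#'   as a data frame with one row per case-control study. The columns are
#'   fixed by `study_columns()`; every reader and writer round-trips them
#'   unchanged.
#' @name study_io
NULL

.ethnic_groups <- c("Caucasian", "Hispanic", "SouthAmerican", "EastAsian",
                    "SouthAsian", "MiddleEast", "African")
.hdp_subtypes  <- c("PE_E", "GH", "Mixed")
.loci          <- c("C677T", "A1298C")

#' Required columns of a study table
#' @return Character vector of column names, in canonical order.
#' @export
study_columns <- function() {
  c("study_id", "country", "ethnic_group", "hdp_subtype", "locus",
    "case_wild", "case_het", "case_var", "case_total",
    "ctrl_wild", "ctrl_het", "ctrl_var", "ctrl_total",
    "air_pollution_level", "quality_score", "year")
}

.count_cols <- c("case_wild", "case_het", "case_var", "case_total",
                 "ctrl_wild", "ctrl_het", "ctrl_var", "ctrl_total",
                 "air_pollution_level", "quality_score", "year")

#' Read a study table
#'
#' Reads a delimited text file of per-study genotype counts, checks the
#' schema, coerces count columns to integer and validates every row.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @return A validated study data frame (row order preserved).
#' @export
read_studies <- function(path, delim = ",") {
  if (!file.exists(path)) stop("read_studies: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  missing <- setdiff(study_columns(), names(df))
  if (length(missing))
    stop("read_studies: missing column(s): ", paste(missing, collapse = ", "))
  df <- df[study_columns()]
  for (col in .count_cols) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                     suppressWarnings(as.numeric(v)) != round(suppressWarnings(as.numeric(v))))
      stop(sprintf("read_studies: non-integer value in '%s' (row %s)",
                   col, paste(utils::head(bad, 3), collapse = ", ")))
    }
    df[[col]] <- as.integer(v)
  }
  df$study_id <- as.character(df$study_id)
  df$country <- as.character(df$country)
  viol <- validate_studies(df)
  if (nrow(viol))
    stop("read_studies: invalid rows:\n",
         paste(sprintf("  row %d, %s: %s", viol$row, viol$field, viol$message),
               collapse = "\n"))
  if (any(df$air_pollution_level == 5))
    warning("read_studies: level-5 air pollution records present; retained")
  df
}

#' Validate one study record
#'
#' @param record A one-row study data frame or a named list with the
#'   columns of `study_columns()`.
#' @return Character vector of violations, named by the offending field;
#'   empty when the record is valid. Violations are data, not errors.
#' @export
validate_study <- function(record) {
  r <- as.list(record)
  v <- character(0)
  chk <- function(cond, field, msg) {
    if (isTRUE(cond)) v[[field]] <<- msg
  }
  for (arm in c("case", "ctrl")) {
    cols <- paste0(arm, c("_wild", "_het", "_var"))
    cts <- unlist(r[cols])
    for (col in cols)
      chk(r[[col]] < 0, col, "negative count")
    tot <- r[[paste0(arm, "_total")]]
    chk(all(cts >= 0) && tot != sum(cts), paste0(arm, "_total"),
        sprintf("total %s != sum of genotype counts %s", tot, sum(cts)))
    chk(tot < 1, paste0(arm, "_total"), "arm total must be >= 1")
  }
  chk(!r$ethnic_group %in% .ethnic_groups, "ethnic_group",
      paste0("unknown ethnic group '", r$ethnic_group, "'"))
  chk(!r$hdp_subtype %in% .hdp_subtypes, "hdp_subtype",
      paste0("unknown HDP subtype '", r$hdp_subtype, "'"))
  chk(!r$locus %in% .loci, "locus", paste0("unknown locus '", r$locus, "'"))
  chk(!r$air_pollution_level %in% 1:5, "air_pollution_level",
      "air pollution level must be in 1..5")
  chk(r$quality_score < 0 || r$quality_score > 28, "quality_score",
      "quality score must be in 0..28")
  v
}

#' Validate all rows of a study table
#'
#' @param studies A study data frame.
#' @return Data frame with columns `row`, `study_id`, `field`, `message`;
#'   zero rows when everything is valid.
#' @export
validate_studies <- function(studies) {
  out <- list()
  for (i in seq_len(nrow(studies))) {
    v <- validate_study(studies[i, ])
    if (length(v))
      out[[length(out) + 1L]] <- data.frame(
        row = i, study_id = studies$study_id[i],
        field = names(v), message = unname(v),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(row = integer(0), study_id = character(0),
                      field = character(0), message = character(0)))
  do.call(rbind, out)
}

#' Merge air-pollution level 1 into level 2
#'
#' The analyzed pollution scale has levels 2 (<= 100 deaths per million),
#' 3 (101-250) and 4 (> 251); the single sparsely populated level-1 band
#' is folded into level 2 before any analysis. Idempotent.
#'
#' @param studies A study data frame.
#' @return The same data frame with every level-1 record recoded to 2.
#' @export
merge_pollution_levels <- function(studies) {
  studies$air_pollution_level[studies$air_pollution_level == 1L] <- 2L
  studies
}

#' Write a study table
#'
#' @param studies A study data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  utils::write.csv(studies[study_columns()], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write report tables and a run log
#'
#' Writes each table in `tables` as `<name>.csv` under `outdir` with a
#' deterministic column order, plus `run_log.json` capturing the
#' configuration (including the seed) so a run can be reproduced.
#'
#' @param tables Named list of data frames.
#' @param outdir Output directory (created if absent).
#' @param config Optional configuration list echoed into the run log.
#' @return Character vector of files written.
#' @export
write_report <- function(tables, outdir, config = NULL) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("write_report: cannot create ", outdir)
  written <- character(0)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    written <- c(written, f)
  }
  log_file <- file.path(outdir, "run_log.json")
  jsonlite::write_json(
    list(package = "hdpmeta",
         config = config,
         tables = names(tables)),
    log_file, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  c(written, log_file)
}
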