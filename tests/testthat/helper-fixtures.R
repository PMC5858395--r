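# Shared fixtures built in code.

# One well-formed study row; override fields as needed.
make_study <- function(study_id = "S001", country = "Italy",
                       ethnic_group = "Caucasian", hdp_subtype = "PE_E",
                       locus = "C677T",
                       case = c(40, 40, 20), ctrl = c(50, 40, 10),
                       air_pollution_level = 2L, quality_score = 20L,
                       year = 2010L) {
  data.frame(study_id = study_id, country = country,
             ethnic_group = ethnic_group, hdp_subtype = hdp_subtype,
             locus = locus,
             case_wild = case[1], case_het = case[2], case_var = case[3],
             case_total = sum(case),
             ctrl_wild = ctrl[1], ctrl_het = ctrl[2], ctrl_var = ctrl[3],
             ctrl_total = sum(ctrl),
             air_pollution_level = air_pollution_level,
             quality_score = quality_score, year = year,
             stringsAsFactors = FALSE)
}

table2_counts <- function() {
  path <- system.file("extdata", "table2_pooled_counts.csv",
                      package = "hdpmeta")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
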