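#' Genotype counts for one study arm
#'
#' A triple of biallelic genotype counts in the locus-agnostic order
#' wild-type homozygote, heterozygote, variant homozygote (CC/CT/TT for
#' MTHFR C677T; AA/AC/CC for A1298C), plus the arm total.
#'
#' @param wild Count of wild-type homozygotes.
#' @param het Count of heterozygotes.
#' @param var Count of variant homozygotes.
#' @return An object of class `genotype_counts`: a list with elements
#'   `wild`, `het`, `var` and `total`.
#' @examples
#' genotype_counts(190, 360, 215)
#' @export
genotype_counts <- function(wild, het, var) {
  counts <- c(wild = wild, het = het, var = var)
  if (any(is.na(counts))) stop("genotype counts must not be NA")
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  structure(
    list(wild = as.integer(wild), het = as.integer(het),
         var = as.integer(var), total = as.integer(wild + het + var)),
    class = "genotype_counts"
  )
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> wild=%d het=%d var=%d (total %d)\n",
              x$wild, x$het, x$var, x$total))
  invisible(x)
}

# Genetic contrasts: exposed genotype set vs the arm total.
# Labels follow the C677T convention; for A1298C read TT as 1298-CC etc.
.contrast_defs <- list(
  TT      = function(g) g$var,
  CT      = function(g) g$het,
  CC      = function(g) g$wild,
  `TT+CT` = function(g) g$var + g$het,
  `CC+CT` = function(g) g$wild + g$het
)

#' Genetic contrasts available for pooling
#'
#' Returns the contrast labels recognised throughout the package:
#' variant homozygote (`"TT"`), heterozygote (`"CT"`), wild type (`"CC"`),
#' dominant carrier (`"TT+CT"`) and non-recessive (`"CC+CT"`).
#'
#' @return Character vector of contrast names.
#' @export
genetic_contrasts <- function() names(.contrast_defs)

#' Exposed count under a genetic contrast
#'
#' @param counts A [genotype_counts()] object.
#' @param contrast One of [genetic_contrasts()].
#' @return Integer count of individuals carrying the contrast's exposed
#'   genotype(s); never exceeds `counts$total`.
#' @export
contrast_exposed <- function(counts, contrast) {
  contrast <- match.arg(contrast, genetic_contrasts())
  .contrast_defs[[contrast]](counts)
}

#' Build the 2x2 table for a genetic contrast
#'
#' Uses the arm totals as denominators for every contrast (the
#' standardized-ratio convention): `a` exposed among `n1` cases, `c`
#' exposed among `n2` controls.
#'
#' @param cases,controls [genotype_counts()] for each arm.
#' @param contrast One of [genetic_contrasts()].
#' @return A list with elements `a`, `n1`, `c`, `n2`.
#' @export
contrast_table <- function(cases, controls, contrast) {
  if (cases$total < 1 || controls$total < 1)
    stop("both arms need at least one subject")
  list(a  = contrast_exposed(cases, contrast),    n1 = cases$total,
       c  = contrast_exposed(controls, contrast), n2 = controls$total)
}

#' Variant allele frequency
#'
#' @param counts A [genotype_counts()] object with `total >= 1`.
#' @return Frequency of the variant allele, `(2*var + het) / (2*total)`.
#' @export
allele_frequency <- function(counts) {
  if (counts$total < 1) stop("allele_frequency: empty sample")
  (2 * counts$var + counts$het) / (2 * counts$total)
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson 1-df chi-square of observed genotype counts against the
#' expectations implied by the sample allele frequency. Conventionally run
#' on the control arm; departures flag population stratification or
#' genotyping problems. Studies are flagged, never dropped.
#'
#' @param controls A [genotype_counts()] object.
#' @param alpha Significance level for the `in_equilibrium` flag.
#' @return List with `allele_frequency_variant`, `expected` (wild, het,
#'   var), `chi_square`, `p_value`, `in_equilibrium`, `monomorphic`.
#' @examples
#' hwe_test(genotype_counts(25, 50, 25))  # exact HWE proportions
#' @export
hwe_test <- function(controls, alpha = 0.05) {
  n <- controls$total
  if (n < 1) stop("hwe_test: empty sample")
  q <- allele_frequency(controls)     # variant allele
  p <- 1 - q
  if (q == 0 || q == 1) {
    expected <- c(wild = p^2, het = 2 * p * q, var = q^2) * n
    return(list(allele_frequency_variant = q, expected = expected,
                chi_square = 0, p_value = 1, in_equilibrium = TRUE,
                monomorphic = TRUE))
  }
  expected <- c(wild = p^2, het = 2 * p * q, var = q^2) * n
  observed <- c(controls$wild, controls$het, controls$var)
  chi <- sum((observed - expected)^2 / expected)
  pval <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  list(allele_frequency_variant = q, expected = expected,
       chi_square = chi, p_value = pval,
       in_equilibrium = pval >= alpha, monomorphic = FALSE)
}

#' Genotype percentage in reporting convention
#'
#' Percentages are computed at full precision and rounded half-up to two
#' decimals only here, the reporting boundary.
#'
#' @param exposed Exposed count, `0 <= exposed <= total`.
#' @param total Arm total, `>= 1`.
#' @return Percentage rounded half-up to 2 decimals.
#' @examples
#' genotype_percentage(1087, 8064)  # 13.48
#' @export
genotype_percentage <- function(exposed, total) {
  if (total < 1) stop("genotype_percentage: zero denominator")
  if (exposed < 0 || exposed > total)
    stop("genotype_percentage: exposed outside [0, total]")
  round_half_up(100 * exposed / total, 2)
}

# round() ties-to-even would print 23.585 as 23.58; reports use half-up.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + sqrt(.Machine$double.eps)) / m
}
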