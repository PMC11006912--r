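read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "equiburden")
  if (!nzchar(path)) stop("bundled table not found: ", file, call. = FALSE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Published impact-overlap cross-tabulation (605-horse equine catalog)
#'
#' The 3x3 (SnpEff impact x VEP impact) variant counts over HIGH, MODERATE
#' and LOW reported for the published 605-horse whole-genome equine variant
#' catalog. Feeding these counts through [crosstab_burden_total()] reproduces
#' that study's predicted-genetic-burden total from the consensus rule.
#'
#' @return Tibble: `snpeff_impact`, `vep_impact`, `count`.
#' @export
published_impact_overlap <- function() {
  read_extdata("published_impact_overlap.tsv")
}

#' Published variant-type pair counts among burden variants
#'
#' The per-(SnpEff term, VEP term) counts over the published predicted
#' genetic burden, both the agreeing and disagreeing pairs. Feeding them
#' through [type_concordance()] reproduces the published concordant count
#' and percentage.
#'
#' @return Tibble: `snpeff_term`, `vep_term`, `n`.
#' @export
published_type_pairs <- function() {
  read_extdata("published_type_pairs.tsv")
}

#' Published cohort-level variant counts
#'
#' @return Tibble: `metric`, `count` — total variants and their SNP/indel
#'   split, plus the SNP/indel split of the burden variants, as published
#'   for the 605-horse cohort.
#' @export
published_cohort_counts <- function() {
  read_extdata("published_cohort_counts.tsv")
}

#' Published known-variant category counts
#'
#' Per-category catalog sizes and detected counts (with frequency summaries)
#' as published for the 605-horse cohort.
#'
#' @return Tibble: `category`, `n_catalog`, `n_detected`, `median_vf_pct`,
#'   `vf_iqr_low_pct`, `vf_iqr_high_pct`.
#' @export
published_catalog_categories <- function() {
  read_extdata("published_catalog_categories.tsv")
}
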