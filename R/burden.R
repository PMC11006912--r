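#' Dual-annotator consensus burden rule
#'
#' A variant belongs to the predicted genetic burden exactly when it is
#' called high impact by both annotators, or high impact by one and moderate
#' impact by the other: the qualifying (SnpEff, VEP) impact pairs are
#' (HIGH, HIGH), (HIGH, MODERATE) and (MODERATE, HIGH).
#'
#' @param snpeff_impact,vep_impact Character vectors of impact labels.
#' @return Logical vector.
#' @export
classify_burden <- function(snpeff_impact, vep_impact) {
  s <- toupper(snpeff_impact)
  v <- toupper(vep_impact)
  (s == "HIGH" & v == "HIGH") |
    (s == "HIGH" & v == "MODERATE") |
    (s == "MODERATE" & v == "HIGH")
}

#' Dual-annotator loss-of-function rule
#'
#' A burden variant is loss of function when both annotators' primary
#' consequence terms are in the LOF term set (frameshift, splice
#' acceptor/donor, start lost, stop lost, stop gained). The two terms need
#' not be equal to each other; a LOF call by only one annotator does not
#' qualify.
#'
#' @param snpeff_term,vep_term Character vectors of primary consequence terms
#'   (any dialect; normalized internally).
#' @param terms Canonical LOF term set, default [lof_terms()].
#' @return Logical vector.
#' @export
classify_lof <- function(snpeff_term, vep_term, terms = lof_terms()) {
  is_lof_term(snpeff_term, terms) & is_lof_term(vep_term, terms)
}

#' Per-variant consensus burden calls for a cohort
#'
#' Combines the per-annotator primary annotations into one verdict per
#' variant: burden membership from the impact-pair consensus rule, LOF from
#' dual-annotator LOF term membership (so LOF implies burden), and
#' type concordance (normalized term equality).
#'
#' @param cohort A `horse_cohort`.
#' @param severity_table Term severity rank map for primary selection.
#' @param lof_term_set Canonical LOF term set.
#' @return Tibble with variant key columns, both primary terms and impacts,
#'   `is_burden`, `is_lof`, `type_concordant`, `gene_id`, `hgnc_symbol`.
#' @export
burden_calls <- function(cohort, severity_table = default_severity_table(),
                         lof_term_set = lof_terms()) {
  prim <- primary_annotations(cohort, severity_table)
  if (any(is.na(prim$snpeff_impact)) || any(is.na(prim$vep_impact))) {
    stop("every variant needs a primary impact from both annotators; ",
         sum(is.na(prim$snpeff_impact) | is.na(prim$vep_impact)),
         " variant(s) lack one", call. = FALSE)
  }
  out <- dplyr::bind_cols(cohort$variants, prim[-1])
  out$is_burden <- classify_burden(out$snpeff_impact, out$vep_impact)
  out$is_lof <- out$is_burden &
    classify_lof(out$snpeff_term, out$vep_term, lof_term_set)
  out$type_concordant <-
    normalize_term(out$snpeff_term) == normalize_term(out$vep_term)
  out
}

#' Impact cross-tabulation between the two annotators
#'
#' @param snpeff_impact,vep_impact Impact label vectors (one element per
#'   variant), or a single data frame with those two columns.
#' @return A 4x4 integer table (SnpEff impact x VEP impact) over the full
#'   severity-ordered impact vocabulary; cells sum to the input length.
#' @export
impact_crosstab <- function(snpeff_impact, vep_impact = NULL) {
  if (is.data.frame(snpeff_impact)) {
    vep_impact <- snpeff_impact$vep_impact
    snpeff_impact <- snpeff_impact$snpeff_impact
  }
  lv <- impact_levels()
  table(snpeff = factor(toupper(snpeff_impact), lv),
        vep = factor(toupper(vep_impact), lv))
}

#' Burden total implied by an impact-pair count table
#'
#' Applies the consensus rule to a table of (SnpEff impact, VEP impact) pair
#' counts and sums the qualifying cells. Useful for checking printed
#' cross-tabulations.
#'
#' @param counts Data frame with columns `snpeff_impact`, `vep_impact`,
#'   `count`.
#' @return The burden total (numeric scalar).
#' @export
crosstab_burden_total <- function(counts) {
  stopifnot(all(c("snpeff_impact", "vep_impact", "count") %in% names(counts)))
  sum(counts$count[classify_burden(counts$snpeff_impact, counts$vep_impact)])
}

#' Alt-allele frequency of one site
#'
#' @param genotypes Integer vector of alt-allele dosages (0/1/2, `NA`
#'   missing); at least one call must be non-missing.
#' @return Tibble: `alt_count`, `called_alleles`, `vf` (alt-allele
#'   frequency), `maf` (min(vf, 1 - vf)).
#' @export
site_allele_frequency <- function(genotypes) {
  called <- sum(!is.na(genotypes))
  if (called == 0) stop("all genotypes missing at site", call. = FALSE)
  alt <- sum(genotypes, na.rm = TRUE)
  vf <- alt / (2 * called)
  tibble::tibble(alt_count = alt, called_alleles = 2L * called,
                 vf = vf, maf = pmin(vf, 1 - vf))
}

#' Per-variant allele frequencies for a whole cohort
#'
#' @param cohort A `horse_cohort`.
#' @return Tibble with the variant key plus `alt_count`, `called_alleles`,
#'   `vf`, `maf`.
#' @export
variant_frequencies <- function(cohort) {
  g <- cohort$geno
  called <- rowSums(!is.na(g))
  if (any(called == 0)) {
    stop(sum(called == 0), " site(s) have all genotypes missing", call. = FALSE)
  }
  alt <- rowSums(g, na.rm = TRUE)
  vf <- alt / (2 * called)
  dplyr::bind_cols(
    cohort$variants[c("chrom", "pos", "ref", "alt")],
    tibble::tibble(alt_count = alt, called_alleles = 2L * called,
                   vf = vf, maf = pmin(vf, 1 - vf))
  )
}

#' Per-sample burden statistics
#'
#' For every sample: sites carrying at least one alt allele (`n_variants`),
#' sites where the sample is the cohort's only alt carrier (`n_private`),
#' burden sites carried and carried homozygously, and likewise for LOF.
#'
#' @param cohort A `horse_cohort`.
#' @param calls Burden-call tibble from [burden_calls()] covering every
#'   cohort variant (row-aligned).
#' @return Tibble, one row per sample.
#' @export
per_sample_burden <- function(cohort, calls) {
  stopifnot(nrow(calls) == nrow(cohort$variants))
  g <- cohort$geno
  carrier <- !is.na(g) & g > 0
  hom <- !is.na(g) & g == 2
  sole <- rowSums(carrier) == 1
  b <- calls$is_burden
  l <- calls$is_lof
  tibble::tibble(
    sample_id = colnames(g),
    n_variants = unname(colSums(carrier)),
    n_private = unname(colSums(carrier & sole)),
    n_burden = unname(colSums(carrier[b, , drop = FALSE])),
    n_burden_hom = unname(colSums(hom[b, , drop = FALSE])),
    n_lof = unname(colSums(carrier[l, , drop = FALSE])),
    n_lof_hom = unname(colSums(hom[l, , drop = FALSE]))
  )
}

# median/IQR with the documented linear-interpolation quantile convention
# (stats::quantile type 7)
median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], iqr_low = q[1], iqr_high = q[3])
}

#' Cohort-level burden summary
#'
#' @param calls Burden-call tibble ([burden_calls()]).
#' @param frequencies Row-aligned frequency tibble ([variant_frequencies()]).
#' @return List: totals, SNP/indel split of burden variants, burden fraction
#'   of all variants (and as a percentage), LOF totals, and median/IQR of the
#'   variant frequency for burden and non-burden variants.
#' @export
burden_summary <- function(calls, frequencies) {
  stopifnot(nrow(calls) == nrow(frequencies))
  b <- calls$is_burden
  vf_b <- median_iqr(frequencies$vf[b])
  vf_nb <- if (any(!b)) median_iqr(frequencies$vf[!b]) else
    list(median = NA_real_, iqr_low = NA_real_, iqr_high = NA_real_)
  list(
    n_variants = nrow(calls),
    n_burden = sum(b),
    n_burden_snp = sum(b & calls$variant_class == "SNP"),
    n_burden_indel = sum(b & calls$variant_class == "indel"),
    n_lof = sum(calls$is_lof),
    burden_fraction = sum(b) / nrow(calls),
    burden_pct = 100 * sum(b) / nrow(calls),
    vf_burden = vf_b,
    vf_non_burden = vf_nb
  )
}

#' Variant-type concordance among burden variants
#'
#' Counts burden variants whose two primary consequence terms agree (after
#' dialect normalization) and tabulates every (SnpEff term, VEP term) pair.
#' Accepts either per-variant calls or a pre-counted pair table with an `n`
#' column (e.g. a printed cross-tabulation).
#'
#' @param calls Tibble with `snpeff_term` and `vep_term`, restricted to
#'   burden variants; optional `n` count column (default 1 per row).
#' @return List: `n_concordant`, `n_discordant`, `n_total`,
#'   `pct_concordant`, and the per-pair breakdown tibble `pairs`.
#' @export
type_concordance <- function(calls) {
  n <- if ("n" %in% names(calls)) calls$n else rep(1L, nrow(calls))
  conc <- normalize_term(calls$snpeff_term) == normalize_term(calls$vep_term)
  pairs <- tibble::tibble(snpeff_term = calls$snpeff_term,
                          vep_term = calls$vep_term,
                          concordant = conc, n = n) |>
    dplyr::count(.data$snpeff_term, .data$vep_term, .data$concordant,
                 wt = .data$n, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$concordant), dplyr::desc(.data$n))
  total <- sum(n)
  list(
    n_concordant = sum(n[conc]),
    n_discordant = sum(n[!conc]),
    n_total = total,
    pct_concordant = 100 * sum(n[conc]) / total,
    pairs = pairs
  )
}

#' Aggregate burden variants by gene
#'
#' Each burden variant contributes once to the gene id of its primary
#' annotation; variants without a gene id are pooled into a reported
#' "unassigned" bucket.
#'
#' @param calls Burden-call tibble ([burden_calls()]).
#' @param frequencies Row-aligned frequency tibble.
#' @return List with `genes` (tibble: `gene_id`, `hgnc_symbol`,
#'   `n_burden_variants`, `n_lof_variants`, `median_vf`, `mean_vf`, `max_vf`)
#'   and `n_unassigned`.
#' @export
aggregate_by_gene <- function(calls, frequencies) {
  stopifnot(nrow(calls) == nrow(frequencies))
  b <- which(calls$is_burden)
  df <- tibble::tibble(
    gene_id = calls$gene_id[b],
    hgnc_symbol = calls$hgnc_symbol[b],
    is_lof = calls$is_lof[b],
    vf = frequencies$vf[b]
  )
  unassigned <- sum(is.na(df$gene_id))
  genes <- df |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      hgnc_symbol = dplyr::first(.data$hgnc_symbol[!is.na(.data$hgnc_symbol)],
                                 default = NA_character_),
      n_burden_variants = dplyr::n(),
      n_lof_variants = sum(.data$is_lof),
      median_vf = stats::median(.data$vf),
      mean_vf = mean(.data$vf),
      max_vf = max(.data$vf),
      .groups = "drop"
    )
  list(genes = genes, n_unassigned = unassigned)
}

#' Select gene sets for downstream functional clustering
#'
#' List A: genes with strictly more than `min_variants` burden variants.
#' List B: genes with a burden variant above `vf_threshold` — by default any
#' single variant's frequency qualifies (`vf_mode = "any"`, i.e. `max_vf`),
#' with `vf_mode = "mean"` using the gene's mean variant frequency instead.
#' Both inequalities are strict.
#'
#' @param aggregates Gene aggregate result from [aggregate_by_gene()] (its
#'   `genes` tibble, or the full list).
#' @param min_variants Count threshold (default 5).
#' @param vf_threshold Frequency threshold as a fraction (default 0.05).
#' @param vf_mode `"any"` (default) or `"mean"`.
#' @return List with character vectors `multi_variant` and `high_frequency`.
#' @export
select_gene_sets <- function(aggregates, min_variants = 5, vf_threshold = 0.05,
                             vf_mode = c("any", "mean")) {
  vf_mode <- match.arg(vf_mode)
  stopifnot(min_variants > 0, vf_threshold > 0)
  genes <- if (is.data.frame(aggregates)) aggregates else aggregates$genes
  metric <- if (vf_mode == "any") genes$max_vf else genes$mean_vf
  list(
    multi_variant = genes$gene_id[genes$n_burden_variants > min_variants],
    high_frequency = genes$gene_id[metric > vf_threshold]
  )
}
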