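test_that("consensus rule admits exactly the three qualifying impact pairs", {
  qualifying <- list(c("HIGH", "HIGH"), c("HIGH", "MODERATE"),
                     c("MODERATE", "HIGH"))
  for (s in impact_levels()) {
    for (v in impact_levels()) {
      expected <- any(vapply(qualifying, function(q)
        identical(q, c(s, v)), logical(1)))
      expect_identical(classify_burden(s, v), expected,
                       label = paste(s, v))
    }
  }
})

test_that("LOF needs both annotators in the LOF set, terms may differ", {
  expect_true(classify_lof("frameshift", "frameshift"))
  expect_true(classify_lof("splice acceptor", "splice donor"))
  expect_false(classify_lof("frameshift", "inframe deletion"))
  expect_false(classify_lof("missense", "missense"))
  # exhaustive pair check against set-membership oracle
  pool <- c("frameshift", "splice acceptor", "splice donor", "start lost",
            "stop lost", "stop gained", "missense", "inframe deletion",
            "synonymous")
  for (a in pool) {
    for (b in pool) {
      oracle <- (normalize_term(a) %in% lof_terms()) &&
        (normalize_term(b) %in% lof_terms())
      expect_identical(classify_lof(a, b), oracle, label = paste(a, b))
    }
  }
})

test_that("impact crosstab counts every pair once and matches an oracle", {
  ct <- impact_crosstab(c("HIGH", "MODERATE", "LOW"),
                        c("HIGH", "HIGH", "LOW"))
  expect_equal(sum(ct), 3)
  expect_equal(unname(ct["HIGH", "HIGH"]), 1)
  expect_equal(unname(ct["MODERATE", "HIGH"]), 1)
  expect_equal(unname(ct["LOW", "LOW"]), 1)
  expect_equal(sum(ct != 0), 3)
  expect_equal(sum(impact_crosstab(character(), character())), 0)

  withr::local_seed(33)
  s <- sample(impact_levels(), 500, replace = TRUE)
  v <- sample(impact_levels(), 500, replace = TRUE)
  ct <- impact_crosstab(s, v)
  for (a in impact_levels()) {
    for (b in impact_levels()) {
      n <- 0
      for (i in 1:500) if (s[i] == a && v[i] == b) n <- n + 1
      expect_equal(unname(ct[a, b]), n)
    }
  }
})

test_that("site allele frequency handles missing and homozygous calls", {
  # 605 samples, one het
  g <- c(1L, rep(0L, 604))
  f <- site_allele_frequency(g)
  expect_equal(f$vf, 1 / 1210)
  expect_equal(f$called_alleles, 1210L)
  # one hom-alt among 10
  expect_equal(site_allele_frequency(c(2L, rep(0L, 9)))$vf, 0.1)
  # missing removed from the denominator
  f <- site_allele_frequency(c(1L, NA, 2L, 0L))
  expect_equal(f$vf, 0.5)
  expect_equal(f$maf, 0.5)
  expect_error(site_allele_frequency(c(NA_integer_, NA_integer_)),
               "missing")
})

test_that("per-sample burden counts carriage, homozygosity, privacy", {
  geno <- rbind(c(1L, 0L), c(1L, 1L), c(2L, 0L), c(0L, 1L))
  colnames(geno) <- c("S1", "S2")
  variants <- tibble::tibble(chrom = "1", pos = 1:4 * 10L, ref = "A",
                             alt = "T", variant_class = "SNP", indel_len = 0L)
  md <- tibble::tibble(sample_id = c("S1", "S2"), breed = "B", doc = 10)
  cohort <- new_horse_cohort(variants, geno, empty_ann_with_variant(),
                             empty_ann_with_variant(), md)
  calls <- tibble::tibble(is_burden = c(TRUE, TRUE, TRUE, FALSE),
                          is_lof = c(TRUE, FALSE, FALSE, FALSE))
  sb <- per_sample_burden(cohort, calls)
  s1 <- sb[sb$sample_id == "S1", ]
  expect_equal(s1$n_burden, 3)
  expect_equal(s1$n_burden_hom, 1)
  expect_equal(s1$n_lof, 1)
  expect_equal(s1$n_private, 2)  # sole carrier at sites 1 and 3
  s2 <- sb[sb$sample_id == "S2", ]
  expect_equal(s2$n_burden, 1)
  expect_equal(s2$n_burden_hom, 0)
  expect_equal(s2$n_private, 1)
  # invariants
  expect_true(all(sb$n_burden_hom <= sb$n_burden))
  expect_true(all(sb$n_lof <= sb$n_burden))
  expect_true(all(sb$n_private <= sb$n_variants))
})

test_that("type concordance splits agreeing and disagreeing term pairs", {
  tc <- type_concordance(tibble::tibble(
    snpeff_term = c("frameshift", "frameshift"),
    vep_term = c("frameshift", "stop gained")))
  expect_equal(tc$n_concordant, 1)
  expect_equal(tc$n_discordant, 1)
  expect_equal(tc$n_total, 2)
  # dialects agree after normalization
  tc2 <- type_concordance(tibble::tibble(
    snpeff_term = "Frameshift", vep_term = "frameshift_variant"))
  expect_equal(tc2$n_concordant, 1)
})

test_that("gene aggregation matches a brute-force group-and-summarize oracle", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2", NA),
    hgnc_symbol = c("A", "A", "A", NA, NA),
    is_burden = TRUE,
    is_lof = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  freqs <- tibble::tibble(vf = c(0.001, 0.002, 0.003, 0.1, 0.2))
  agg <- aggregate_by_gene(calls, freqs)
  g1 <- agg$genes[agg$genes$gene_id == "g1", ]
  expect_equal(g1$n_burden_variants, 3)
  expect_equal(g1$median_vf, 0.002)
  expect_equal(agg$genes$n_burden_variants[agg$genes$gene_id == "g2"], 1)
  expect_equal(agg$n_unassigned, 1)
  expect_equal(sum(agg$genes$n_burden_variants) + agg$n_unassigned,
               sum(calls$is_burden))

  withr::local_seed(12)
  n <- 300
  rc <- tibble::tibble(
    gene_id = sample(c(paste0("g", 1:40), NA), n, replace = TRUE),
    hgnc_symbol = NA_character_,
    is_burden = sample(c(TRUE, FALSE), n, replace = TRUE),
    is_lof = FALSE)
  rc$is_lof <- rc$is_burden & sample(c(TRUE, FALSE), n, replace = TRUE)
  rf <- tibble::tibble(vf = runif(n, 0, 0.5))
  agg <- aggregate_by_gene(rc, rf)
  for (g in agg$genes$gene_id) {
    rows <- which(rc$is_burden & !is.na(rc$gene_id) & rc$gene_id == g)
    row <- agg$genes[agg$genes$gene_id == g, ]
    expect_equal(row$n_burden_variants, length(rows))
    expect_equal(row$n_lof_variants, sum(rc$is_lof[rows]))
    expect_equal(row$median_vf, median(rf$vf[rows]))
    expect_equal(row$max_vf, max(rf$vf[rows]))
  }
  expect_equal(sum(agg$genes$n_burden_variants) + agg$n_unassigned,
               sum(rc$is_burden))
})

test_that("gene-set thresholds are strict and mode-switchable", {
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    n_burden_variants = c(6L, 5L, 1L),
    mean_vf = c(0.02, 0.01, 0.04),
    max_vf = c(0.03, 0.02, 0.06))
  sets <- select_gene_sets(genes)
  expect_identical(sets$multi_variant, "a")
  expect_identical(sets$high_frequency, "c")
  sets_mean <- select_gene_sets(genes, vf_mode = "mean")
  expect_identical(sets_mean$high_frequency, character(0))
  low <- select_gene_sets(genes, min_variants = 10, vf_threshold = 0.5)
  expect_length(low$multi_variant, 0)
  expect_length(low$high_frequency, 0)
})

test_that("burden summary reproduces forced arithmetic", {
  calls <- tibble::tibble(
    variant_class = c("SNP", "indel", "SNP"),
    is_burden = c(TRUE, TRUE, FALSE),
    is_lof = c(TRUE, FALSE, FALSE))
  freqs <- tibble::tibble(vf = c(0.001, 0.002, 0.2))
  s <- burden_summary(calls, freqs)
  expect_equal(s$n_burden, 2)
  expect_equal(s$n_burden_snp, 1)
  expect_equal(s$n_burden_indel, 1)
  expect_equal(s$burden_fraction, 2 / 3)
  # a single variant that is burden -> fraction 100%
  s1 <- burden_summary(tibble::tibble(variant_class = "SNP",
                                      is_burden = TRUE, is_lof = FALSE),
                       tibble::tibble(vf = 0.01))
  expect_equal(s1$burden_pct, 100)
})

test_that("LOF is a subset of burden in full pipeline calls", {
  sim <- simulate_cohort(small_sim_config(n_sites = 300, seed = 5))
  calls <- burden_calls(sim$cohort)
  expect_true(all(!calls$is_lof | calls$is_burden))
  ct <- impact_crosstab(calls)
  expect_equal(sum(ct), nrow(calls))
  qualifying <- ct["HIGH", "HIGH"] + ct["HIGH", "MODERATE"] +
    ct["MODERATE", "HIGH"]
  expect_equal(unname(qualifying), sum(calls$is_burden))
})

test_that("burden variants are rarer than neutral variants by construction", {
  sim <- simulate_cohort(small_sim_config(n_sites = 2000, seed = 77))
  calls <- burden_calls(sim$cohort)
  freqs <- variant_frequencies(sim$cohort)
  expect_lt(median(freqs$vf[calls$is_burden]),
            median(freqs$vf[!calls$is_burden]))
})
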