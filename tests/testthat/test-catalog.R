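write_catalog <- function(rows, path = tempfile(fileext = ".tsv"),
                          pragma = "#build=EquCab3.0") {
  writeLines(c(pragma,
               paste(c("entry_id", "phenotype", "category", "chrom", "pos",
                       "ref", "alt"), collapse = "\t"),
               rows), path)
  path
}

cat_row <- function(id, cat, chrom = "1", pos = 100, ref = "G", alt = "A",
                    phen = "pheno") {
  paste(id, phen, cat, chrom, pos, ref, alt, sep = "\t")
}

test_that("catalog loading validates vocabulary, alleles, duplicates", {
  ok <- load_catalog(write_catalog(c(
    cat_row("e1", "disease_trait_causing", pos = 100),
    cat_row("e2", "coat_color", pos = 200),
    cat_row("e3", "disease_associated", pos = 300),
    cat_row("e4", "trait_associated", pos = 400))))
  expect_equal(nrow(ok), 4)
  expect_equal(attr(ok, "build"), "EquCab3.0")

  expect_error(load_catalog(write_catalog(c(
    cat_row("e1", "disease_trait_causing"),
    cat_row("e2", "color", pos = 200)))), "row 2.*color")
  expect_error(load_catalog(write_catalog(
    cat_row("e1", "coat_color", alt = strrep("A", 25)))),
    "longer than 20")
  expect_error(load_catalog(write_catalog(c(
    cat_row("e1", "coat_color"), cat_row("e2", "coat_color")))),
    "duplicate")
})

# cohort with one known site: 3 het + 1 hom among the breed's samples
catalog_cohort <- function() {
  n <- 120
  md <- tibble::tibble(
    sample_id = sprintf("H%03d", 1:n),
    breed = rep(c("QH", "TB"), each = 60),
    doc = 10)
  g1 <- c(rep(1L, 3), 2L, rep(0L, 56), rep(0L, 60))  # QH carries, TB not
  g2 <- rep(0L, n)
  geno <- rbind(g1, g2)
  colnames(geno) <- md$sample_id
  variants <- tibble::tibble(chrom = c("5", "5"), pos = c(500L, 900L),
                             ref = "G", alt = "A", variant_class = "SNP",
                             indel_len = 0L)
  new_horse_cohort(variants, geno, empty_ann_with_variant(),
                   empty_ann_with_variant(), md)
}

test_that("catalog matching computes per-breed genotype frequencies", {
  cohort <- catalog_cohort()
  catalog <- load_catalog(write_catalog(c(
    cat_row("hit", "disease_trait_causing", chrom = "5", pos = 500),
    cat_row("miss", "coat_color", chrom = "5", pos = 777))))
  res <- match_catalog(cohort, catalog)
  hit <- res$matches[res$matches$entry_id == "hit", ]
  expect_true(hit$detected)
  expect_equal(hit$n_carriers, 4)
  expect_equal(hit$vf, 5 / 240)
  qh <- res$by_breed[res$by_breed$entry_id == "hit" &
                       res$by_breed$breed == "QH", ]
  expect_equal(qh$het, 3)
  expect_equal(qh$hom_alt, 1)
  expect_equal(qh$vf, 5 / 120)
  miss <- res$matches[res$matches$entry_id == "miss", ]
  expect_false(miss$detected)
  expect_equal(miss$n_carriers, 0)
})

test_that("per-breed frequencies aggregate to the overall frequency", {
  sim <- simulate_cohort(small_sim_config(n_sites = 200, seed = 31))
  catalog <- load_catalog(system.file("extdata", "catalog_synthetic.tsv",
                                      package = "equiburden"))
  res <- match_catalog(sim$cohort, catalog)
  det <- res$matches[res$matches$detected, ]
  for (i in seq_len(nrow(det))) {
    bb <- res$by_breed[res$by_breed$entry_id == det$entry_id[i], ]
    pooled <- sum(bb$vf * 2 * bb$n_called) / sum(2 * bb$n_called)
    expect_equal(pooled, det$vf[i], tolerance = 1e-12)
  }
})

test_that("detection is monotone in added samples", {
  cohort <- catalog_cohort()
  catalog <- load_catalog(write_catalog(
    cat_row("hit", "disease_trait_causing", chrom = "5", pos = 500)))
  full <- match_catalog(cohort, catalog)
  # subset to the carrier-containing half plus extras
  keep <- 1:80
  sub <- new_horse_cohort(cohort$variants,
                          cohort$geno[, keep, drop = FALSE],
                          cohort$snpeff, cohort$vep,
                          cohort$metadata[keep, ])
  part <- match_catalog(sub, catalog)
  expect_true(part$matches$detected)   # detected in subset
  expect_true(full$matches$detected)   # still detected with more samples
  expect_gte(full$matches$n_carriers, part$matches$n_carriers)
})

test_that("category summaries report detection percent and frequencies", {
  m <- tibble::tibble(
    entry_id = sprintf("e%d", 1:6),
    phenotype = "p", variant = NA_integer_,
    category = c(rep("trait_associated", 3), rep("coat_color", 3)),
    detected = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    vf = c(0.0558, 0.1315, 0.3165, NA, NA, NA),
    maf = c(0.0558, 0.1315, 0.3165, NA, NA, NA),
    n_carriers = c(5, 5, 5, 0, 0, 0), carrier_ids = "")
  s <- summarize_categories(m)
  ta <- s$categories[s$categories$category == "trait_associated", ]
  expect_equal(ta$detection_pct, 100)
  expect_equal(ta$median_vf_pct, 13.15)
  cc <- s$categories[s$categories$category == "coat_color", ]
  expect_equal(cc$detection_pct, 0)
  expect_true(is.na(cc$median_vf_pct))
  expect_equal(s$overall_median_vf_pct, 13.15)
})

test_that("unexpected genotypes are flagged per inheritance rules", {
  cohort <- catalog_cohort()
  catalog <- load_catalog(write_catalog(
    cat_row("lethal", "disease_trait_causing", chrom = "5", pos = 500)))
  res <- match_catalog(cohort, catalog)
  rules <- tibble::tibble(entry_id = "lethal", lethal_homozygote = TRUE,
                          expected_breeds = "QH")
  flags <- flag_unexpected_genotypes(res, rules, cohort)
  # one QH homozygote for a reported lethal
  expect_equal(sum(flags$rule == "lethal_homozygote"), 1)
  expect_equal(flags$genotype[flags$rule == "lethal_homozygote"], "hom_alt")
  # no carriers outside QH, so no breed violations
  expect_equal(sum(flags$rule == "unexpected_breed"), 0)

  # plant a TB carrier -> breed violation
  cohort2 <- catalog_cohort()
  cohort2$geno[1, 61] <- 1L
  res2 <- match_catalog(cohort2, catalog)
  flags2 <- flag_unexpected_genotypes(res2, rules, cohort2)
  expect_equal(sum(flags2$rule == "unexpected_breed"), 1)
  expect_equal(flags2$breed[flags2$rule == "unexpected_breed"], "TB")

  # no violations at all -> empty report
  rules_none <- tibble::tibble(entry_id = "lethal",
                               lethal_homozygote = FALSE,
                               expected_breeds = "")
  expect_equal(nrow(flag_unexpected_genotypes(res, rules_none, cohort)), 0)
})
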