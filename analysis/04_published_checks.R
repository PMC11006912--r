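#!/usr/bin/env Rscript
# Arithmetic checks on the bundled published reference tabulations from the
# 605-horse equine WGS catalog: the consensus rule applied to the impact
# overlap, variant-type concordance, cohort count identities, and catalog
# detection percentages. Writes results/published_checks.json.

library(equiburden)

overlap <- published_impact_overlap()
burden_total <- crosstab_burden_total(overlap)
tc <- type_concordance(published_type_pairs())
counts <- published_cohort_counts()
g <- function(m) counts$count[counts$metric == m]
cats <- published_catalog_categories()
det_pct <- 100 * cats$n_detected / cats$n_catalog

cat("Burden total from impact overlap:", burden_total, "\n")
cat("Concordant variant types:", tc$n_concordant,
    sprintf("(%.1f%% of burden)", 100 * tc$n_concordant / burden_total), "\n")
cat("SNPs + indels =", g("n_snps") + g("n_indels"),
    "(printed total", g("n_total"), ")\n")
cat("Catalog detection by category (%):",
    paste(sprintf("%s=%.1f", cats$category, det_pct), collapse = ", "), "\n")

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(burden_total = burden_total,
       burden_pct = 100 * burden_total / g("n_total"),
       concordant_types = tc$n_concordant,
       concordance_pct = 100 * tc$n_concordant / burden_total,
       snp_indel_total = g("n_snps") + g("n_indels"),
       max_detection_pct = max(det_pct)),
  "results/published_checks.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/published_checks.json\n")
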