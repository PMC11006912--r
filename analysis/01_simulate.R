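#!/usr/bin/env Rscript
# Generate the reference synthetic cohort: 12 target breeds x 20 horses plus
# an "Other" pool, DOC-dependent genotype dropout, rare-skewed deleterious
# sites, dual-annotator labels, and planted catalog variants. Writes the
# cohort VCF, metadata, truth JSON and the synthetic Ne table under
# scratch/cohort/ (bulky run artifacts live under scratch/, summary tables
# under results/).

library(equiburden)

seed <- 1L
ne <- read_ne_table(system.file("extdata", "ne_estimates_synthetic.tsv",
                                package = "equiburden"))
sim <- simulate_cohort(cohort_sim_config(seed = seed),
                       write_dir = "scratch/cohort", ne_table = ne)

cat("Simulated cohort:", nrow(sim$cohort$variants), "variants x",
    nrow(sim$cohort$metadata), "samples\n")
cat("Planted site classes:\n")
print(table(sim$truth$sites$class))
cat("Planted breed burden means span",
    round(min(sim$truth$breeds$planted_burden_mean)), "-",
    round(max(sim$truth$breeds$planted_burden_mean)), "carried sites\n")
cat("Files written under scratch/cohort/\n")
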