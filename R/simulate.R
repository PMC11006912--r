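#' Default breed table for the synthetic cohort
#'
#' Twelve target breeds of 20 horses each plus a 30-horse "Other" pool, with
#' breed-mean depths of coverage spanning roughly 5.5-17.5 X and planted
#' multiplicative breed effects on the deleterious allele-frequency
#' distribution (so planted breed-mean burden carriage spans roughly
#' 607-860 carried deleterious sites per horse under the default site count).
#'
#' @return Tibble: `name`, `n_samples`, `doc_mean`, `doc_sd`,
#'   `burden_multiplier`.
#' @export
default_breed_table <- function() {
  tibble::tibble(
    name = c("Thoroughbred", "Shetland", "Warmblood", "Arabian",
             "Franches-Montagnes", "Quarter Horse", "Welsh Pony",
             "Clydesdale", "Morgan", "Belgian", "Standardbred", "Icelandic",
             "Other"),
    n_samples = c(rep(20L, 12), 30L),
    doc_mean = c(14, 5.5, 12, 17.5, 9, 11, 7, 8, 10, 9.5, 13, 6.5, 10),
    doc_sd = rep(1.5, 13),
    burden_multiplier = c(0.85, 0.91, 0.94, 0.97, 1.00, 1.03, 1.06, 1.09,
                          1.12, 1.18, 1.21, 1.24, 0.88)
  )
}

#' Default planted known-variant entries and per-breed frequencies
#'
#' A small synthetic catalog in the shape of an OMIA-style table (phenotype,
#' category, coordinates, alleles) with planted per-breed allele frequencies;
#' breeds not listed carry frequency 0. Entry `syn_gbed` mimics a lethal
#' recessive confined to one breed; `syn_absent` is planted at frequency 0
#' everywhere so the undetected path is exercised.
#'
#' @return List with `entries` (tibble: `entry_id`, `phenotype`, `category`,
#'   `chrom`, `pos`, `ref`, `alt`) and `freqs` (tibble: `entry_id`, `breed`,
#'   `freq`).
#' @export
default_planted_entries <- function() {
  entries <- tibble::tibble(
    entry_id = c("syn_gbed", "syn_myhm", "syn_gait", "syn_coat1", "syn_coat2",
                 "syn_assoc1", "syn_assoc2", "syn_trait1", "syn_trait2",
                 "syn_absent"),
    phenotype = c("GBED-like", "MYHM-like", "gait-like", "coat-dilution",
                  "coat-white", "myopathy-assoc", "fracture-assoc",
                  "height-assoc", "gait-assoc", "never-observed"),
    category = c("disease_trait_causing", "disease_trait_causing",
                 "trait_associated", "coat_color", "coat_color",
                 "disease_associated", "disease_associated",
                 "trait_associated", "trait_associated",
                 "disease_trait_causing"),
    chrom = rep("26", 10),
    pos = as.integer(seq(1000L, by = 1000L, length.out = 10)),
    ref = c("G", "C", "A", "G", "C", "T", "A", "G", "CTTG", "T"),
    alt = c("A", "T", "G", "A", "T", "C", "G", "T", "C", "G")
  )
  freqs <- dplyr::bind_rows(
    tibble::tibble(entry_id = "syn_gbed", breed = "Quarter Horse", freq = 0.028),
    tibble::tibble(entry_id = "syn_myhm", breed = c("Quarter Horse", "Belgian"),
                   freq = c(0.071, 0.01)),
    tibble::tibble(entry_id = "syn_gait",
                   breed = c("Icelandic", "Standardbred", "Morgan"),
                   freq = c(0.9, 0.6, 0.045)),
    tibble::tibble(entry_id = "syn_coat1",
                   breed = c("Arabian", "Belgian", "Morgan", "Thoroughbred",
                             "Quarter Horse", "Other"),
                   freq = c(0.86, 0.9, 0.88, 0.87, 0.9, 0.5)),
    tibble::tibble(entry_id = "syn_coat2",
                   breed = c("Clydesdale", "Warmblood", "Shetland"),
                   freq = c(0.95, 0.25, 0.10)),
    tibble::tibble(entry_id = "syn_assoc1",
                   breed = c("Quarter Horse", "Warmblood", "Welsh Pony",
                             "Morgan", "Other"),
                   freq = c(0.3, 0.25, 0.2, 0.15, 0.2)),
    tibble::tibble(entry_id = "syn_assoc2",
                   breed = c("Thoroughbred", "Standardbred", "Other"),
                   freq = c(0.51, 0.2, 0.1)),
    tibble::tibble(entry_id = "syn_trait1",
                   breed = c("Shetland", "Welsh Pony", "Icelandic"),
                   freq = c(0.4, 0.35, 0.25)),
    tibble::tibble(entry_id = "syn_trait2",
                   breed = c("Icelandic", "Standardbred"), freq = c(0.5, 0.3)),
    tibble::tibble(entry_id = "syn_absent", breed = "Thoroughbred", freq = 0)
  )
  list(entries = entries, freqs = freqs)
}

#' Build a simulation configuration
#'
#' Defaults define the package's reference synthetic conditions: a
#' multi-breed diploid cohort with Hardy-Weinberg genotypes, a rare-skewed
#' deleterious site-frequency spectrum against a common neutral one, dual
#' annotator impact labels with controlled agreement, depth-of-coverage
#' dependent genotype dropout, and planted catalog variants.
#'
#' @param breeds Breed table ([default_breed_table()]).
#' @param n_sites Number of core (non-planted) sites.
#' @param burden_site_fraction Fraction of core sites planted deleterious.
#' @param sfs_deleterious,sfs_neutral Beta(a, b) shape pairs for allele
#'   frequencies of deleterious and neutral sites.
#' @param burden_pairs Impact-pair distribution for deleterious sites
#'   (data frame `snpeff`, `vep`, `prob`; all pairs must satisfy the burden
#'   consensus rule).
#' @param neutral_pairs Impact-pair distribution for neutral sites (no pair
#'   may satisfy the rule).
#' @param lof_fraction Fraction of deleterious sites given LOF terms by both
#'   annotators.
#' @param type_agreement Probability that the two annotators emit the same
#'   consequence term at a site.
#' @param dropout `list(rate0, doc_ref, doc_scale)`: per-genotype missing
#'   probability `rate0 * exp(-(doc - doc_ref)/doc_scale)`, clamped to
#'   [0, 0.5]; `rate0 = 0` disables dropout.
#' @param planted [default_planted_entries()]-shaped list, or NULL for none.
#' @param n_genes,hgnc_fraction Synthetic gene-model size and the fraction of
#'   genes given an HGNC-style symbol.
#' @param seed Default RNG seed.
#' @return A validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(breeds = default_breed_table(),
                              n_sites = 9000,
                              burden_site_fraction = 0.6,
                              sfs_deleterious = c(0.4, 5),
                              sfs_neutral = c(0.5, 1),
                              burden_pairs = data.frame(
                                snpeff = c("HIGH", "HIGH", "MODERATE"),
                                vep = c("HIGH", "MODERATE", "HIGH"),
                                prob = c(0.985, 0.013, 0.002)),
                              neutral_pairs = data.frame(
                                snpeff = c("MODERATE", "LOW", "MODIFIER",
                                           "MODERATE", "LOW", "MODERATE", "LOW"),
                                vep = c("MODERATE", "LOW", "MODIFIER",
                                        "LOW", "MODERATE", "MODIFIER", "MODIFIER"),
                                prob = c(0.18, 0.28, 0.40, 0.04, 0.04,
                                         0.03, 0.03)),
                              lof_fraction = 0.75,
                              type_agreement = 0.887,
                              dropout = list(rate0 = 0.08, doc_ref = 5,
                                             doc_scale = 10),
                              planted = default_planted_entries(),
                              n_genes = 3000,
                              hgnc_fraction = 0.1,
                              seed = 1L) {
  cfg <- list(breeds = breeds, n_sites = as.integer(n_sites),
              burden_site_fraction = burden_site_fraction,
              sfs_deleterious = sfs_deleterious, sfs_neutral = sfs_neutral,
              burden_pairs = burden_pairs, neutral_pairs = neutral_pairs,
              lof_fraction = lof_fraction, type_agreement = type_agreement,
              dropout = dropout, planted = planted, n_genes = n_genes,
              hgnc_fraction = hgnc_fraction, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "cohort_sim_config")
}

validate_sim_config <- function(cfg) {
  b <- cfg$breeds
  stopifnot(all(b$n_samples >= 1), all(b$doc_mean > 0), all(b$doc_sd >= 0))
  for (nm in c("burden_pairs", "neutral_pairs")) {
    p <- cfg$b
    p <- cfg[[nm]]$prob
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
      stop(nm, " probabilities must lie in [0,1] and sum to 1", call. = FALSE)
    }
  }
  if (any(classify_burden(cfg$neutral_pairs$snpeff, cfg$neutral_pairs$vep))) {
    stop("neutral_pairs contains a pair satisfying the burden rule",
         call. = FALSE)
  }
  if (!all(classify_burden(cfg$burden_pairs$snpeff, cfg$burden_pairs$vep))) {
    stop("burden_pairs contains a pair not satisfying the burden rule",
         call. = FALSE)
  }
  ok <- function(x) length(x) == 1 && x >= 0 && x <= 1
  stopifnot(ok(cfg$burden_site_fraction), ok(cfg$lof_fraction),
            ok(cfg$type_agreement), ok(cfg$dropout$rate0))
  invisible(cfg)
}

dropout_prob <- function(doc, dropout) {
  pmin(pmax(dropout$rate0 * exp(-(doc - dropout$doc_ref) / dropout$doc_scale),
            0), 0.5)
}

# draw a companion term: same as `term` with prob `agreement`, else another
# member of `pool`
companion_terms <- function(term, pool, agreement) {
  out <- term
  flip <- stats::runif(length(term)) >= agreement
  if (any(flip) && length(pool) > 1) {
    alt <- vapply(term[flip], function(t) {
      others <- setdiff(pool, t)
      others[sample.int(length(others), 1)]
    }, character(1))
    out[flip] <- alt
  }
  out
}

#' Simulate an annotated multi-breed cohort with recorded truth
#'
#' Genotypes are Hardy-Weinberg draws from per-site, breed-adjusted allele
#' frequencies; low-DOC samples lose genotypes to missingness per the dropout
#' model; each site gets one annotation per annotator according to the
#' configured impact-pair and term-agreement model; planted catalog entries
#' are appended at their per-breed frequencies. Identical config + seed gives
#' identical output (byte-identical files when written).
#'
#' @param config A `cohort_sim_config`.
#' @param seed RNG seed; defaults to `config$seed`.
#' @param write_dir Optional directory: writes `cohort.vcf`, `metadata.tsv`,
#'   `truth.json` (plus `ne_estimates.tsv` if `ne_table` given).
#' @param ne_table Optional Ne table to write alongside.
#' @return List: `cohort` (a `horse_cohort`), `truth` (list of truth tables),
#'   `paths` (written file paths, if any).
#' @export
simulate_cohort <- function(config = cohort_sim_config(),
                            seed = config$seed, write_dir = NULL,
                            ne_table = NULL) {
  validate_sim_config(config)
  set.seed(seed)
  b <- config$breeds

  # ---- samples ----
  metadata <- dplyr::bind_rows(lapply(seq_len(nrow(b)), function(i) {
    n <- b$n_samples[i]
    tibble::tibble(
      sample_id = sprintf("%s_%02d", gsub("[^A-Za-z]", "", b$name[i]),
                          seq_len(n)),
      breed = b$name[i],
      doc = round(pmax(stats::rnorm(n, b$doc_mean[i], b$doc_sd[i]), 1), 2)
    )
  }))
  n_samp <- nrow(metadata)
  breed_of <- match(metadata$breed, b$name)

  # ---- core sites ----
  n_burden <- round(config$n_sites * config$burden_site_fraction)
  n_neutral <- config$n_sites - n_burden
  clampf <- function(p) pmin(pmax(p, 5e-4), 0.95)
  p_del <- clampf(stats::rbeta(n_burden, config$sfs_deleterious[1],
                               config$sfs_deleterious[2]))
  p_neu <- clampf(stats::rbeta(n_neutral, config$sfs_neutral[1],
                               config$sfs_neutral[2]))
  # per-breed deleterious frequencies (breed effect planted here)
  p_del_breed <- clampf(outer(p_del, b$burden_multiplier))

  # ---- annotations for core sites ----
  bp <- config$burden_pairs
  np <- config$neutral_pairs
  pair_b <- sample.int(nrow(bp), n_burden, replace = TRUE, prob = bp$prob)
  pair_n <- sample.int(nrow(np), n_neutral, replace = TRUE, prob = np$prob)
  is_lof_site <- stats::runif(n_burden) < config$lof_fraction
  lof_pool <- c("frameshift_variant", "splice_acceptor_variant",
                "splice_donor_variant", "start_lost", "stop_lost",
                "stop_gained")
  high_pool <- c("exon_loss_variant", "transcript_ablation", "gene_fusion")
  se_term_b <- ifelse(is_lof_site,
                      lof_pool[sample.int(6, n_burden, replace = TRUE)],
                      high_pool[sample.int(3, n_burden, replace = TRUE)])
  ve_term_b <- character(n_burden)
  ve_term_b[is_lof_site] <- companion_terms(se_term_b[is_lof_site], lof_pool,
                                            config$type_agreement)
  ve_term_b[!is_lof_site] <- companion_terms(se_term_b[!is_lof_site],
                                             high_pool, config$type_agreement)
  neutral_term <- function(impact) {
    c(HIGH = "exon_loss_variant", MODERATE = "missense_variant",
      LOW = "synonymous_variant", MODIFIER = "intron_variant")[impact]
  }
  se_term_n <- unname(neutral_term(np$snpeff[pair_n]))
  ve_term_n <- unname(neutral_term(np$vep[pair_n]))

  # ---- planted catalog entries ----
  planted <- config$planted
  n_plant <- if (is.null(planted)) 0L else nrow(planted$entries)
  n_total <- config$n_sites + n_plant

  gene_idx <- sample.int(config$n_genes, n_total, replace = TRUE)
  gene_id <- sprintf("ENSECAG%08d", gene_idx)
  hgnc <- ifelse(gene_idx <= config$n_genes * config$hgnc_fraction,
                 sprintf("GENE%04d", gene_idx), NA_character_)

  bases <- c("A", "C", "G", "T")
  core_ref <- sample(bases, config$n_sites, replace = TRUE)
  core_alt <- bases[(match(core_ref, bases) - 1L +
                       sample.int(3, config$n_sites, replace = TRUE)) %% 4L + 1L]
  variants <- tibble::tibble(
    chrom = "1", pos = seq_len(config$n_sites) * 50L,
    ref = unname(core_ref), alt = unname(core_alt),
    variant_class = "SNP", indel_len = 0L
  )
  if (n_plant > 0) {
    e <- planted$entries
    variants <- dplyr::bind_rows(variants, tibble::tibble(
      chrom = e$chrom, pos = e$pos, ref = e$ref, alt = e$alt,
      variant_class = ifelse(nchar(e$ref) == 1 & nchar(e$alt) == 1,
                             "SNP", "indel"),
      indel_len = abs(nchar(e$ref) - nchar(e$alt))
    ))
  }

  se_imp <- c(bp$snpeff[pair_b], np$snpeff[pair_n], rep("MODERATE", n_plant))
  ve_imp <- c(bp$vep[pair_b], np$vep[pair_n], rep("MODERATE", n_plant))
  se_term <- c(se_term_b, se_term_n, rep("missense_variant", n_plant))
  ve_term <- c(ve_term_b, ve_term_n, rep("missense_variant", n_plant))

  snpeff <- tibble::tibble(
    variant = seq_len(n_total), annotator = "snpeff", allele = variants$alt,
    term = se_term, terms = se_term, impact = se_imp, gene_id = gene_id,
    hgnc_symbol = hgnc,
    transcript_id = sprintf("ENSECAT%08d", gene_idx), rank_in_field = 0L)
  vep <- tibble::tibble(
    variant = seq_len(n_total), annotator = "vep", allele = variants$alt,
    term = ve_term, terms = ve_term, impact = ve_imp, gene_id = gene_id,
    hgnc_symbol = hgnc,
    transcript_id = sprintf("ENSECAT%08d", gene_idx), rank_in_field = 0L)

  # ---- genotypes (Hardy-Weinberg per breed) ----
  geno <- matrix(0L, n_total, n_samp)
  for (bi in seq_len(nrow(b))) {
    cols <- which(breed_of == bi)
    p_core <- c(p_del_breed[, bi], p_neu)
    geno[seq_len(config$n_sites), cols] <-
      stats::rbinom(config$n_sites * length(cols), 2, p_core)
  }
  if (n_plant > 0) {
    fmat <- matrix(0, n_plant, nrow(b),
                   dimnames = list(planted$entries$entry_id, b$name))
    for (j in seq_len(nrow(planted$freqs))) {
      fmat[planted$freqs$entry_id[j], planted$freqs$breed[j]] <-
        planted$freqs$freq[j]
    }
    for (bi in seq_len(nrow(b))) {
      cols <- which(breed_of == bi)
      geno[config$n_sites + seq_len(n_plant), cols] <-
        stats::rbinom(n_plant * length(cols), 2, fmat[, bi])
    }
  }

  # ---- truth (pre-dropout) ----
  is_burden_site <- c(rep(TRUE, n_burden), rep(FALSE, n_neutral + n_plant))
  site_is_lof <- c(is_lof_site, rep(FALSE, n_neutral + n_plant))
  carrier0 <- geno > 0L
  hom0 <- geno == 2L
  sole0 <- rowSums(carrier0) == 1L
  truth_samples <- tibble::tibble(
    sample_id = metadata$sample_id,
    n_variants = unname(colSums(carrier0)),
    n_private = unname(colSums(carrier0 & sole0)),
    n_burden = unname(colSums(carrier0[is_burden_site, , drop = FALSE])),
    n_burden_hom = unname(colSums(hom0[is_burden_site, , drop = FALSE])),
    n_lof = unname(colSums(carrier0[site_is_lof, , drop = FALSE])),
    n_lof_hom = unname(colSums(hom0[site_is_lof, , drop = FALSE]))
  )
  d_ref <- dropout_prob(mean(metadata$doc), config$dropout)
  truth_breeds <- tibble::tibble(
    breed = b$name,
    planted_burden_mean = vapply(seq_len(nrow(b)), function(bi)
      sum(1 - (1 - p_del_breed[, bi])^2), numeric(1)),
    planted_lof_mean = vapply(seq_len(nrow(b)), function(bi)
      sum((1 - (1 - p_del_breed[, bi])^2)[is_lof_site]), numeric(1))
  )
  truth_breeds$expected_burden_at_ref_doc <-
    truth_breeds$planted_burden_mean * (1 - d_ref)
  truth_breeds$expected_lof_at_ref_doc <-
    truth_breeds$planted_lof_mean * (1 - d_ref)
  truth_sites <- tibble::tibble(
    variant = seq_len(n_total),
    class = ifelse(seq_len(n_total) > config$n_sites, "planted",
                   ifelse(site_is_lof, "lof",
                          ifelse(is_burden_site, "burden", "neutral"))),
    freq = c(p_del, p_neu, rep(NA_real_, n_plant))
  )
  truth <- list(
    cohort_id = sprintf("sim-seed-%d", seed),
    samples = truth_samples,
    breeds = truth_breeds,
    sites = truth_sites,
    planted = if (n_plant > 0) planted$freqs else NULL,
    dropout_at_ref_doc = d_ref
  )

  # ---- dropout ----
  if (config$dropout$rate0 > 0) {
    d <- dropout_prob(metadata$doc, config$dropout)
    miss <- matrix(stats::runif(n_total * n_samp), n_total, n_samp) <
      matrix(d, n_total, n_samp, byrow = TRUE)
    geno[miss] <- NA_integer_
  }
  colnames(geno) <- metadata$sample_id

  cohort <- new_horse_cohort(variants, geno, snpeff, vep, metadata)
  attr(cohort, "cohort_id") <- truth$cohort_id

  paths <- NULL
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(write_dir, "cohort.vcf"),
      metadata = file.path(write_dir, "metadata.tsv"),
      truth = file.path(write_dir, "truth.json")
    )
    write_cohort_vcf(cohort, paths$vcf)
    md <- metadata
    names(md)[names(md) == "sample_id"] <- "sample"
    utils::write.table(md, paths$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE)
    if (!is.null(ne_table)) {
      paths$ne <- file.path(write_dir, "ne_estimates.tsv")
      utils::write.table(ne_table, paths$ne, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  list(cohort = cohort, truth = truth, paths = paths)
}

#' Check pipeline outputs against generator truth
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param sample_burden Per-sample burden table computed by the pipeline.
#' @param emmeans Optional EMMEAN table (from [estimate_emmeans()]) checked
#'   for CI coverage of the planted breed means at the reference DOC.
#' @param match_result Optional [match_catalog()] result checked against the
#'   planted per-breed frequencies.
#' @param response Which planted breed mean the EMMEANs target
#'   (`"n_burden"` or `"n_lof"`).
#' @return List of recovery metrics: `samples_exact`, `max_abs_count_error`,
#'   `emmean_covered` (per breed logical), `planted_freq` (per entry x breed
#'   errors in binomial SE units).
#' @export
evaluate_recovery <- function(truth, sample_burden, emmeans = NULL,
                              match_result = NULL, response = "n_burden") {
  if (!setequal(truth$samples$sample_id, sample_burden$sample_id)) {
    stop("sample ids in outputs do not match the generated cohort",
         call. = FALSE)
  }
  j <- dplyr::inner_join(truth$samples, sample_burden, by = "sample_id",
                         suffix = c("_true", "_obs"))
  count_cols <- c("n_variants", "n_private", "n_burden", "n_burden_hom",
                  "n_lof", "n_lof_hom")
  errs <- vapply(count_cols, function(cc)
    max(abs(j[[paste0(cc, "_true")]] - j[[paste0(cc, "_obs")]])), numeric(1))
  out <- list(samples_exact = all(errs == 0), max_abs_count_error = max(errs))

  if (!is.null(emmeans)) {
    tcol <- if (response == "n_lof") "expected_lof_at_ref_doc" else
      "expected_burden_at_ref_doc"
    tb <- truth$breeds[match(emmeans$breed, truth$breeds$breed), ]
    if (anyNA(tb$breed)) stop("EMMEAN breed absent from truth", call. = FALSE)
    out$emmean_covered <- stats::setNames(
      emmeans$ci_low <= tb[[tcol]] & tb[[tcol]] <= emmeans$ci_high,
      emmeans$breed)
  }
  if (!is.null(match_result) && !is.null(truth$planted)) {
    bb <- match_result$by_breed
    pf <- dplyr::left_join(truth$planted, bb, by = c("entry_id", "breed"))
    est <- ifelse(is.na(pf$vf), 0, pf$vf)
    n_alleles <- ifelse(is.na(pf$n_called), 0L, 2L * pf$n_called)
    se <- sqrt(pmax(pf$freq * (1 - pf$freq), 1e-12) / pmax(n_alleles, 1))
    z <- ifelse(pf$freq == 0 & est == 0, 0, (est - pf$freq) / se)
    out$planted_freq <- tibble::tibble(
      entry_id = pf$entry_id, breed = pf$breed, planted = pf$freq,
      estimated = est, z = z)
  }
  out
}
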