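#' Build a pipeline run configuration
#'
#' @param vcf,metadata Input paths (required).
#' @param ne_table,catalog,catalog_rules Optional input paths; the breed-Ne
#'   correlation and catalog stages run only when their inputs are given.
#' @param out_dir Output directory (created if absent).
#' @param min_n,min_mean_doc Breed-inclusion thresholds.
#' @param gene_min_variants,vf_threshold,vf_mode Gene-set selection options.
#' @param max_indel_len Longest admitted indel (bases).
#' @param chrom_aliases Optional named chromosome alias vector.
#' @return Validated `run_config` list.
#' @export
pipeline_config <- function(vcf, metadata, out_dir, ne_table = NULL,
                            catalog = NULL, catalog_rules = NULL,
                            min_n = 17, min_mean_doc = 5,
                            gene_min_variants = 5, vf_threshold = 0.05,
                            vf_mode = c("any", "mean"), max_indel_len = 20,
                            chrom_aliases = NULL) {
  vf_mode <- match.arg(vf_mode)
  for (p in c(vcf, metadata, ne_table, catalog, catalog_rules)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  stopifnot(min_n > 0, min_mean_doc > 0, gene_min_variants > 0,
            vf_threshold > 0, max_indel_len > 0)
  structure(list(vcf = vcf, metadata = metadata, out_dir = out_dir,
                 ne_table = ne_table, catalog = catalog,
                 catalog_rules = catalog_rules, min_n = min_n,
                 min_mean_doc = min_mean_doc,
                 gene_min_variants = gene_min_variants,
                 vf_threshold = vf_threshold, vf_mode = vf_mode,
                 max_indel_len = max_indel_len,
                 chrom_aliases = chrom_aliases),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full burden pipeline
#'
#' Executes ingestion -> consensus burden calling -> breed statistics ->
#' catalog matching, writing every report table (tab-separated), a summary
#' JSON and a manifest with input checksums into `config$out_dir`. A stage
#' failure aborts with a stage-tagged error and leaves a `FAILED` marker next
#' to any partial outputs. Given identical inputs and config, a rerun
#' produces byte-identical outputs (the manifest and summary carry no
#' timestamps).
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(out, "FAILED")
  if (file.exists(failed)) file.remove(failed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)), failed)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  res <- list()
  stage("ingest", {
    meta <- read_metadata(config$metadata)
    res$cohort <- read_cohort_vcf(config$vcf, meta,
                                   max_indel_len = config$max_indel_len,
                                   chrom_aliases = config$chrom_aliases)
  })
  cohort <- res$cohort

  stage("burden", {
    res$calls <- burden_calls(cohort)
    res$freqs <- variant_frequencies(cohort)
    res$crosstab <- impact_crosstab(res$calls)
    res$sample_burden <- per_sample_burden(cohort, res$calls)
    res$summary <- burden_summary(res$calls, res$freqs)
    res$concordance <- type_concordance(
      res$calls[res$calls$is_burden, c("snpeff_term", "vep_term")])
    res$genes <- aggregate_by_gene(res$calls, res$freqs)
    res$gene_sets <- select_gene_sets(res$genes,
                                       min_variants = config$gene_min_variants,
                                       vf_threshold = config$vf_threshold,
                                       vf_mode = config$vf_mode)
    write_annotation_table(cohort, file.path(out, "annotation_table.tsv"))
    write_tsv(res$calls, file.path(out, "burden_calls.tsv"))
    write_tsv(res$sample_burden, file.path(out, "sample_burden.tsv"))
    write_tsv(res$genes$genes, file.path(out, "gene_aggregates.tsv"))
    ct <- as.data.frame(res$crosstab)
    names(ct) <- c("snpeff_impact", "vep_impact", "count")
    write_tsv(ct, file.path(out, "impact_crosstab.tsv"))
    write_tsv(res$concordance$pairs, file.path(out, "type_concordance.tsv"))
  })

  stage("breeds", {
    sel <- select_target_breeds(cohort$metadata, min_n = config$min_n,
                                min_mean_doc = config$min_mean_doc)
    res$targets <- sel$targets
    res$metadata_grouped <- sel$metadata
    emms <- list()
    for (resp in c("n_burden", "n_burden_hom", "n_lof", "n_lof_hom")) {
      fit <- fit_count_model(res$sample_burden, sel$metadata, resp)
      emm <- estimate_emmeans(fit)
      emms[[resp]] <- emm
      write_tsv(emm, file.path(out, paste0("emmeans_", resp, ".tsv")))
    }
    res$emmeans <- emms
    if (!is.null(config$ne_table)) {
      ne <- read_ne_table(config$ne_table)
      res$ne_correlations <- correlate_burden_ne(res$sample_burden,
                                                  sel$metadata, ne)
      write_tsv(res$ne_correlations, file.path(out, "ne_correlations.tsv"))
    }
    res$freq_comparison <- compare_frequencies(
      res$freqs$vf[res$calls$is_burden], res$freqs$vf[!res$calls$is_burden])
  })

  stage("catalog", {
    if (!is.null(config$catalog)) {
      catalog <- load_catalog(config$catalog)
      cohort$metadata <- res$metadata_grouped
      res$catalog_matches <- match_catalog(
        cohort, catalog, breed_col = "breed_group",
        chrom_aliases = config$chrom_aliases)
      res$catalog_summary <- summarize_categories(res$catalog_matches)
      write_tsv(res$catalog_matches$matches,
                file.path(out, "catalog_matches.tsv"))
      write_tsv(res$catalog_matches$by_breed,
                file.path(out, "catalog_by_breed.tsv"))
      write_tsv(res$catalog_summary$categories,
                file.path(out, "catalog_categories.tsv"))
      if (!is.null(config$catalog_rules)) {
        rules <- tibble::as_tibble(utils::read.delim(config$catalog_rules,
                                                     stringsAsFactors = FALSE))
        res$catalog_flags <- flag_unexpected_genotypes(
          res$catalog_matches, rules, cohort, breed_col = "breed_group")
        write_tsv(res$catalog_flags, file.path(out, "catalog_flags.tsv"))
      }
    }
  })

  stage("summarize", {
    ct <- res$crosstab
    s <- res$summary
    summary_json <- list(
      n_samples = nrow(cohort$metadata),
      n_variants = s$n_variants,
      n_burden = s$n_burden,
      burden_crosstab_qualifying = unname(
        ct["HIGH", "HIGH"] + ct["HIGH", "MODERATE"] + ct["MODERATE", "HIGH"]),
      n_burden_snp = s$n_burden_snp,
      n_burden_indel = s$n_burden_indel,
      n_lof = s$n_lof,
      burden_pct = s$burden_pct,
      vf_burden = s$vf_burden,
      vf_non_burden = s$vf_non_burden,
      type_concordant = res$concordance$n_concordant,
      type_concordance_pct = res$concordance$pct_concordant,
      n_genes_with_burden = nrow(res$genes$genes),
      n_gene_unassigned = res$genes$n_unassigned,
      gene_set_multi_variant = length(res$gene_sets$multi_variant),
      gene_set_high_frequency = length(res$gene_sets$high_frequency),
      target_breeds = res$targets,
      excluded_indels_gt_max = cohort$dropped$indel_gt_max,
      freq_comparison = res$freq_comparison[c("p", "mean_diff", "ci_low",
                                              "ci_high")]
    )
    jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    inputs <- c(vcf = config$vcf, metadata = config$metadata,
                ne_table = config$ne_table, catalog = config$catalog,
                catalog_rules = config$catalog_rules)
    manifest <- list(
      package_version = as.character(utils::packageVersion("equiburden")),
      config = config[setdiff(names(config), "out_dir")],
      input_md5 = as.list(tools::md5sum(unlist(inputs)))
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(res)
}
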