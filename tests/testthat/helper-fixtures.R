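# In-code fixtures: a tiny handcrafted annotated VCF plus random generators
# used by the property-style tests.

ann_header_line <- function() {
  paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
         "annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name",
         " | Gene_ID | Feature_Type | Feature_ID'\">")
}

csq_header_line <- function() {
  paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
         "annotations from Ensembl VEP. Format: ",
         "Allele|Consequence|IMPACT|SYMBOL|Gene|Feature\">")
}

vcf_header <- function(samples, with_ann = TRUE, with_csq = TRUE) {
  c("##fileformat=VCFv4.2",
    if (with_ann) ann_header_line(),
    if (with_csq) csq_header_line(),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

ann_block <- function(allele, term, impact, gene = "ENSECAG00000000001",
                      symbol = "GENE1", feature = "T1") {
  paste(allele, term, impact, symbol, gene, "transcript", feature, sep = "|")
}

csq_block <- function(allele, term, impact, gene = "ENSECAG00000000001",
                      symbol = "GENE1", feature = "T1") {
  paste(allele, term, impact, symbol, gene, feature, sep = "|")
}

vcf_record <- function(chrom, pos, ref, alt, info, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT", gts),
        collapse = "\t")
}

# two-sample fixture: biallelic SNP, multi-allelic site, an over-long
# deletion (excluded), and a half-call site
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  long_ref <- paste0("G", strrep("A", 25))
  lines <- c(
    vcf_header(c("S1", "S2")),
    vcf_record("1", 100, "G", "A",
               paste0("ANN=", ann_block("A", "stop_gained", "HIGH"),
                      ";CSQ=", csq_block("A", "stop_gained", "HIGH")),
               c("0/1", "1/1")),
    vcf_record("1", 200, "C", "A,T",
               paste0("ANN=", ann_block("A", "missense_variant", "MODERATE"),
                      ",", ann_block("T", "stop_gained", "HIGH"),
                      ";CSQ=", csq_block("A", "missense_variant", "MODERATE"),
                      ",", csq_block("T", "stop_gained", "HIGH")),
               c("1/2", "0/1")),
    vcf_record("1", 300, long_ref, "G",
               paste0("ANN=", ann_block("G", "frameshift_variant", "HIGH"),
                      ";CSQ=", csq_block("G", "frameshift_variant", "HIGH")),
               c("0/0", "0/1")),
    vcf_record("1", 400, "T", "C",
               paste0("ANN=", ann_block("C", "missense_variant", "MODERATE"),
                      ";CSQ=", csq_block("C", "missense_variant", "MODERATE")),
               c("./1", "0/0"))
  )
  writeLines(lines, path)
  path
}

fixture_metadata <- function() {
  tibble::tibble(sample_id = c("S1", "S2"),
                 breed = c("BreedA", "BreedB"),
                 doc = c(10, 12))
}

empty_ann_with_variant <- function() {
  tibble::tibble(
    variant = integer(), annotator = character(), allele = character(),
    term = character(), terms = character(), impact = character(),
    gene_id = character(), hgnc_symbol = character(),
    transcript_id = character(), rank_in_field = integer())
}

# random annotation list for select_primary_annotation property tests
rand_annotation_tbl <- function(n, terms, impacts = impact_levels()) {
  tibble::tibble(
    annotator = "snpeff",
    allele = "A",
    term = sample(terms, n, replace = TRUE),
    terms = NA_character_,
    impact = sample(impacts, n, replace = TRUE),
    gene_id = NA_character_, hgnc_symbol = NA_character_,
    transcript_id = NA_character_,
    rank_in_field = seq_len(n) - 1L
  )
}

# brute-force oracle: scan all rows, keep the best by (impact severity,
# term severity, earliest field rank) using explicit comparisons
oracle_select_primary <- function(ann, severity_table) {
  best <- 1
  for (i in seq_len(nrow(ann))[-1]) {
    bi <- impact_rank(ann$impact[best]); ii <- impact_rank(ann$impact[i])
    bt <- severity_table[normalize_term(ann$term[best])]
    it <- severity_table[normalize_term(ann$term[i])]
    bt <- if (is.na(bt)) 0 else bt
    it <- if (is.na(it)) 0 else it
    if (ii > bi ||
        (ii == bi && it > bt) ||
        (ii == bi && it == bt &&
         ann$rank_in_field[i] < ann$rank_in_field[best])) {
      best <- i
    }
  }
  ann[best, ]
}

# small no-dropout simulation config for fast deterministic tests
small_sim_config <- function(n_sites = 400, dropout0 = 0, seed = 42) {
  cohort_sim_config(n_sites = n_sites,
                    dropout = list(rate0 = dropout0, doc_ref = 5,
                                   doc_scale = 10),
                    seed = seed)
}
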