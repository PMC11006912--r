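#' Cohort container
#'
#' A `horse_cohort` bundles the decomposed biallelic variant records of a
#' multi-sample VCF with per-sample genotype codes, the two annotators'
#' transcript-level annotations in long form, and the sample metadata.
#'
#' @param variants Tibble: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `variant_class` ("SNP"/"indel"), `indel_len`.
#' @param geno Integer matrix, variants x samples; entries are alt-allele
#'   dosages 0/1/2 with `NA` for missing (half-calls count as missing).
#' @param snpeff,vep Long annotation tibbles with a `variant` index column.
#' @param metadata Tibble: `sample_id`, `breed`, `doc`.
#' @param dropped Named list of exclusion counters.
#' @return A `horse_cohort` object.
#' @export
new_horse_cohort <- function(variants, geno, snpeff, vep, metadata,
                             dropped = list(indel_gt_max = 0L, allele_unmatched = 0L)) {
  stopifnot(nrow(variants) == nrow(geno),
            ncol(geno) == nrow(metadata),
            identical(colnames(geno), metadata$sample_id))
  if (nrow(variants) > 0 && any(variants$ref == variants$alt)) {
    stop("variant with ref == alt", call. = FALSE)
  }
  structure(
    list(variants = variants, geno = geno, snpeff = snpeff, vep = vep,
         metadata = metadata, dropped = dropped),
    class = "horse_cohort"
  )
}

#' @export
print.horse_cohort <- function(x, ...) {
  cat(sprintf("<horse_cohort> %d variants x %d samples (%d breeds)\n",
              nrow(x$variants), nrow(x$metadata),
              length(unique(x$metadata$breed))))
  invisible(x)
}

#' Read sample metadata
#'
#' Tab-separated with header `sample<TAB>breed<TAB>doc`; `doc` is the mean
#' sequencing depth of coverage in X units.
#'
#' @param path File path.
#' @return Tibble `sample_id`, `breed`, `doc` (plus any extra columns kept).
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "breed", "doc")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  names(df)[names(df) == "sample"] <- "sample_id"
  out <- tibble::as_tibble(df)
  if (any(!nzchar(out$breed)) || any(is.na(out$breed))) {
    stop("metadata has empty breed labels", call. = FALSE)
  }
  out$doc <- as.numeric(out$doc)
  if (any(is.na(out$doc)) || any(out$doc <= 0)) {
    stop("metadata DOC values must be positive", call. = FALSE)
  }
  out
}

#' Read a breed effective-population-size table
#'
#' Tab-separated with header `breed<TAB>ne<TAB>source`.
#' @param path File path.
#' @return Tibble `breed`, `ne`, `source`; (breed, source) must be unique.
#' @export
read_ne_table <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("breed", "ne", "source") %in% names(df)))
  if (any(df$ne <= 0)) stop("Ne estimates must be positive", call. = FALSE)
  if (anyDuplicated(df[c("breed", "source")])) {
    stop("duplicate (breed, source) rows in Ne table", call. = FALSE)
  }
  df
}

# -- header descriptor extraction ---------------------------------------------

extract_ann_columns <- function(meta) {
  line <- grep("^##INFO=<ID=ANN[,>]", meta, value = TRUE)
  if (length(line) == 0) {
    stop("VCF header has no INFO/ANN declaration (SnpEff annotations absent)",
         call. = FALSE)
  }
  m <- regmatches(line[1], regexpr("'[^']+'", line[1]))
  if (length(m) == 1) {
    trimws(strsplit(gsub("'", "", m), "|", fixed = TRUE)[[1]])
  } else {
    default_ann_columns()
  }
}

extract_csq_columns <- function(meta) {
  line <- grep("^##INFO=<ID=CSQ[,>]", meta, value = TRUE)
  if (length(line) == 0) {
    stop("VCF header has no INFO/CSQ declaration (VEP annotations absent)",
         call. = FALSE)
  }
  m <- regmatches(line[1], regexpr("Format: ?[A-Za-z0-9_|]+", line[1]))
  if (length(m) == 0) {
    stop("INFO/CSQ declaration lacks a Format= column descriptor", call. = FALSE)
  }
  trimws(strsplit(sub("Format: ?", "", m), "|", fixed = TRUE)[[1]])
}

info_subfield <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

# alt-allele dosage codes for allele k from GT strings, via a lookup over the
# (small) set of distinct genotype strings; any "." token makes the call missing
gt_dosage <- function(gt_row, k, lookup_env) {
  key <- paste0(gt_row, "#", k)
  u <- unique(key)
  miss <- !(u %in% names(lookup_env$map))
  if (any(miss)) {
    for (uk in u[miss]) {
      parts <- strsplit(uk, "#", fixed = TRUE)[[1]]
      tok <- strsplit(parts[1], "[/|]")[[1]]
      lookup_env$map[[uk]] <- if (any(tok == ".") || length(tok) == 0) {
        NA_integer_
      } else {
        sum(tok == parts[2])
      }
    }
  }
  unname(vapply(key, function(x) lookup_env$map[[x]], integer(1)))
}

#' Read an annotated multi-sample cohort VCF
#'
#' Reads a VCF v4.2 whose INFO carries both a SnpEff-style `ANN` field and a
#' VEP-style `CSQ` field, decomposes multi-allelic sites into one record per
#' alternate allele, maps genotypes to per-allele dosage codes (half-calls are
#' treated as missing), and drops indels longer than `max_indel_len` bases
#' with a logged count.
#'
#' @param path VCF path (plain or bgzipped).
#' @param metadata Sample metadata tibble from [read_metadata()]; every VCF
#'   sample must appear in it.
#' @param max_indel_len Longest admitted indel, in bases (default 20).
#' @param chrom_aliases Optional named character vector mapping VCF chromosome
#'   names to harmonized names (e.g. `c(chr1 = "1")`). No silent renaming
#'   happens without it.
#' @return A [new_horse_cohort()] object. Annotations whose allele matches no
#'   alternate allele of their site are dropped with a warning.
#' @export
read_cohort_vcf <- function(path, metadata, max_indel_len = 20,
                            chrom_aliases = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  ann_cols <- extract_ann_columns(meta)
  csq_cols <- extract_csq_columns(meta)
  if (nrow(vcf@fix) == 0) {
    stop("VCF contains no variant records", call. = FALSE)
  }
  samples <- colnames(vcf@gt)[-1]
  absent <- setdiff(samples, metadata$sample_id)
  if (length(absent) > 0) {
    stop("VCF sample(s) absent from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  metadata <- metadata[match(samples, metadata$sample_id), ]

  chrom <- unname(vcf@fix[, "CHROM"])
  if (!is.null(chrom_aliases)) {
    hit <- chrom %in% names(chrom_aliases)
    chrom[hit] <- unname(chrom_aliases[chrom[hit]])
  }
  pos <- as.integer(unname(vcf@fix[, "POS"]))
  ref <- unname(vcf@fix[, "REF"])
  alt_field <- unname(vcf@fix[, "ALT"])
  info <- unname(vcf@fix[, "INFO"])
  ann_txt <- info_subfield(info, "ANN")
  csq_txt <- info_subfield(info, "CSQ")
  gt_raw <- vcf@gt[, -1, drop = FALSE]
  gt <- matrix(sub(":.*$", "", gt_raw), nrow = nrow(gt_raw))

  lookup <- new.env(parent = emptyenv()); lookup$map <- list()
  rec_var <- vector("list", length(pos))
  rec_geno <- vector("list", length(pos))
  rec_se <- vector("list", length(pos))
  rec_ve <- vector("list", length(pos))
  n_long <- 0L
  n_unmatched <- 0L
  idx <- 0L

  for (i in seq_along(pos)) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    se_all <- if (!is.na(ann_txt[i])) parse_snpeff_ann(ann_txt[i], ann_cols) else empty_annotation_tbl()
    ve_all <- if (!is.na(csq_txt[i])) parse_vep_csq(csq_txt[i], csq_cols) else empty_annotation_tbl()
    n_unmatched <- n_unmatched +
      sum(!(se_all$allele %in% alts)) + sum(!(ve_all$allele %in% alts))
    for (k in seq_along(alts)) {
      alt_k <- alts[k]
      if (alt_k == ref[i]) stop("variant with ref == alt at ", chrom[i], ":",
                                pos[i], call. = FALSE)
      ilen <- abs(nchar(ref[i]) - nchar(alt_k))
      if (ilen > max_indel_len) {
        n_long <- n_long + 1L
        next
      }
      idx <- idx + 1L
      vclass <- if (nchar(ref[i]) == 1 && nchar(alt_k) == 1) "SNP" else "indel"
      rec_var[[idx]] <- tibble::tibble(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt_k,
        variant_class = vclass, indel_len = ilen
      )
      rec_geno[[idx]] <- gt_dosage(gt[i, ], k, lookup)
      se_k <- se_all[se_all$allele == alt_k, , drop = FALSE]
      ve_k <- ve_all[ve_all$allele == alt_k, , drop = FALSE]
      if (nrow(se_k) > 0) rec_se[[idx]] <- cbind(variant = idx, se_k)
      if (nrow(ve_k) > 0) rec_ve[[idx]] <- cbind(variant = idx, ve_k)
    }
  }
  if (idx == 0L) stop("no variant records admitted from VCF", call. = FALSE)
  if (n_unmatched > 0) {
    warning(n_unmatched, " annotation block(s) had alleles matching no ALT ",
            "allele and were dropped", call. = FALSE)
  }
  if (n_long > 0) {
    message(n_long, " record(s) with indel length > ", max_indel_len,
            " bp excluded")
  }
  variants <- dplyr::bind_rows(rec_var[seq_len(idx)])
  geno <- do.call(rbind, rec_geno[seq_len(idx)])
  colnames(geno) <- samples
  new_horse_cohort(
    variants, geno,
    snpeff = dplyr::bind_rows(rec_se[seq_len(idx)]) |> fix_empty_ann(),
    vep = dplyr::bind_rows(rec_ve[seq_len(idx)]) |> fix_empty_ann(),
    metadata = metadata,
    dropped = list(indel_gt_max = n_long, allele_unmatched = n_unmatched)
  )
}

fix_empty_ann <- function(x) {
  if (nrow(x) == 0) cbind(variant = integer(), empty_annotation_tbl()) else tibble::as_tibble(x)
}

serialize_ann_blocks <- function(ann, annotator) {
  if (nrow(ann) == 0) return(NA_character_)
  blank <- function(x) ifelse(is.na(x), "", x)
  if (annotator == "snpeff") {
    paste(ann$allele, ann$terms, ann$impact, blank(ann$hgnc_symbol),
          blank(ann$gene_id), "transcript", blank(ann$transcript_id),
          sep = "|")
  } else {
    paste(ann$allele, ann$terms, ann$impact, blank(ann$hgnc_symbol),
          blank(ann$gene_id), blank(ann$transcript_id), sep = "|")
  }
}

#' Write a cohort back to VCF v4.2
#'
#' Emits one biallelic record per variant with `ANN` and `CSQ` INFO fields
#' serialized from the stored annotations, and GT genotypes from the dosage
#' codes. Plain text, deterministic byte-for-byte for a given cohort.
#'
#' @param cohort A `horse_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: '", paste(default_ann_columns(), collapse = " | "),
           "'\">"),
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations from Ensembl VEP. Format: ",
           paste(default_csq_columns(), collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$metadata$sample_id), collapse = "\t")
  )
  se_by <- split(cohort$snpeff, factor(cohort$snpeff$variant, seq_len(nrow(v))))
  ve_by <- split(cohort$vep, factor(cohort$vep$variant, seq_len(nrow(v))))
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- c()
    a <- serialize_ann_blocks(se_by[[i]], "snpeff")
    b <- serialize_ann_blocks(ve_by[[i]], "vep")
    if (!is.na(a)) parts <- c(parts, paste0("ANN=", paste(a, collapse = ",")))
    if (!is.na(b)) parts <- c(parts, paste0("CSQ=", paste(b, collapse = ",")))
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))
  gt_txt <- matrix(c("0/0", "0/1", "1/1")[cohort$geno + 1L],
                   nrow = nrow(cohort$geno))
  gt_txt[is.na(cohort$geno)] <- "./."
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt_txt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Default VEP CSQ column layout used by the writer and simulator
#' @return Character vector of CSQ column names.
#' @export
default_csq_columns <- function() {
  c("Allele", "Consequence", "IMPACT", "SYMBOL", "Gene", "Feature")
}

#' Write the per-variant primary annotation table
#'
#' Tab-separated: chrom, pos, ref, alt, snpeff_term, snpeff_impact, vep_term,
#' vep_impact, gene_id.
#'
#' @param cohort A `horse_cohort`.
#' @param path Output path.
#' @param severity_table Term severity rank map.
#' @return The table, invisibly.
#' @export
write_annotation_table <- function(cohort, path,
                                   severity_table = default_severity_table()) {
  prim <- primary_annotations(cohort, severity_table)
  out <- dplyr::bind_cols(
    cohort$variants[c("chrom", "pos", "ref", "alt")],
    prim[c("snpeff_term", "snpeff_impact", "vep_term", "vep_impact", "gene_id")]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
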