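#' @importFrom rlang .data
NULL

# Shared worker for ANN/CSQ style INFO fields: comma-separated annotation
# blocks, each pipe-delimited with a layout named by the VCF header.
parse_annotation_blocks <- function(info_text, columns, annotator,
                                    required = character()) {
  missing_cols <- setdiff(required, columns)
  if (length(missing_cols) > 0) {
    stop(sprintf("%s descriptor lacks required column(s): %s",
                 annotator, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (is.na(info_text) || !nzchar(info_text)) {
    return(empty_annotation_tbl())
  }
  blocks <- strsplit(info_text, ",", fixed = TRUE)[[1]]
  n_col <- length(columns)
  # subfield count = pipe count + 1 (trailing subfields may be empty)
  lens <- vapply(gregexpr("|", blocks, fixed = TRUE), function(m) {
    if (m[1] == -1L) 1L else length(m) + 1L
  }, integer(1))
  if (any(lens != n_col)) {
    bad <- which(lens != n_col)[1]
    stop(sprintf("%s block %d has %d subfields but the header declares %d",
                 annotator, bad, lens[bad], n_col), call. = FALSE)
  }
  fields <- strsplit(blocks, "|", fixed = TRUE)
  fields <- lapply(fields, function(f) c(f, rep("", n_col - length(f))))
  mat <- do.call(rbind, fields)
  colnames(mat) <- columns
  get_col <- function(nm) if (nm %in% columns) unname(mat[, nm]) else NA_character_
  term_raw <- unname(mat[, required[1]])
  if (any(!nzchar(term_raw))) {
    stop(sprintf("%s block %d has an empty consequence term",
                 annotator, which(!nzchar(term_raw))[1]), call. = FALSE)
  }
  impact <- toupper(unname(mat[, required[2]]))
  bad_imp <- which(!impact %in% impact_levels())
  if (length(bad_imp) > 0) {
    stop(sprintf("%s block %d has unknown impact '%s'",
                 annotator, bad_imp[1], impact[bad_imp[1]]), call. = FALSE)
  }
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(x), NA_character_, x)
  gene_col <- if (annotator == "snpeff") "Gene_ID" else "Gene"
  sym_col <- if (annotator == "snpeff") "Gene_Name" else "SYMBOL"
  feat_col <- if (annotator == "snpeff") "Feature_ID" else "Feature"
  tibble::tibble(
    annotator = annotator,
    allele = get_col("Allele"),
    term = vapply(strsplit(term_raw, "&", fixed = TRUE), `[[`, character(1), 1L),
    terms = term_raw,
    impact = impact,
    gene_id = blank_to_na(get_col(gene_col)),
    hgnc_symbol = blank_to_na(get_col(sym_col)),
    transcript_id = blank_to_na(get_col(feat_col)),
    rank_in_field = seq_along(blocks) - 1L
  )
}

empty_annotation_tbl <- function() {
  tibble::tibble(
    annotator = character(), allele = character(), term = character(),
    terms = character(), impact = character(), gene_id = character(),
    hgnc_symbol = character(), transcript_id = character(),
    rank_in_field = integer()
  )
}

#' Default SnpEff ANN subfield layout
#'
#' The layout actually used is always taken from the VCF header's ANN
#' description; this is the conventional SnpEff layout used as a fallback and
#' by the simulator.
#' @return Character vector of subfield names.
#' @export
default_ann_columns <- function() {
  c("Allele", "Annotation", "Annotation_Impact", "Gene_Name", "Gene_ID",
    "Feature_Type", "Feature_ID")
}

#' Parse a SnpEff-style ANN INFO field
#'
#' One annotation per comma-separated block; blocks are pipe-delimited with
#' subfields named by `columns`. Ampersand-joined compound consequence terms
#' are preserved in `terms` and the first (most severe by annotator
#' convention) becomes `term`.
#'
#' @param info_text The ANN field value (without the `ANN=` prefix).
#' @param columns Subfield names from the VCF header;
#'   defaults to [default_ann_columns()].
#' @return A tibble with one row per annotation block: `annotator`, `allele`,
#'   `term`, `terms`, `impact`, `gene_id`, `hgnc_symbol`, `transcript_id`,
#'   `rank_in_field` (0-based block index).
#' @export
parse_snpeff_ann <- function(info_text, columns = default_ann_columns()) {
  parse_annotation_blocks(info_text, columns, "snpeff",
                          required = c("Annotation", "Annotation_Impact"))
}

#' Parse a VEP-style CSQ INFO field
#'
#' @param info_text The CSQ field value (without the `CSQ=` prefix).
#' @param format_descriptor The header's `Format: a|b|c` column list, either
#'   as the raw `"A|B|C"` string or a character vector of names. Must include
#'   `Consequence` and `IMPACT`.
#' @inherit parse_snpeff_ann return
#' @export
parse_vep_csq <- function(info_text, format_descriptor) {
  columns <- if (length(format_descriptor) == 1 &&
                 grepl("|", format_descriptor, fixed = TRUE)) {
    strsplit(format_descriptor, "|", fixed = TRUE)[[1]]
  } else {
    as.character(format_descriptor)
  }
  parse_annotation_blocks(info_text, trimws(columns), "vep",
                          required = c("Consequence", "IMPACT"))
}

#' Select the primary (most deleterious) annotation for one variant
#'
#' Among transcript-level annotations of one annotator for one variant, the
#' annotation with the most severe impact class wins; ties on impact are
#' broken by the severity rank of the (normalized) consequence term; any
#' remaining tie is broken by field order (first listed wins).
#'
#' @param annotations A tibble as returned by the parsers; must be nonempty.
#' @param severity_table Named rank map, canonical term -> rank (larger = more
#'   severe); defaults to [default_severity_table()]. Terms absent from the
#'   table rank below all listed terms.
#' @return The selected single-row tibble.
#' @export
select_primary_annotation <- function(annotations,
                                      severity_table = default_severity_table()) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    stop("cannot select a primary annotation from an empty list", call. = FALSE)
  }
  key <- annotation_priority(annotations, severity_table)
  annotations[which.max(key), , drop = FALSE]
}

# Single comparable priority so the vectorized per-variant selection and the
# one-variant path use the same ordering. Higher = preferred.
annotation_priority <- function(annotations, severity_table) {
  imp <- impact_rank(annotations$impact)
  term_rank <- severity_table[normalize_term(annotations$term)]
  term_rank[is.na(term_rank)] <- 0
  max_rank <- max(c(severity_table, 1))
  n <- nrow(annotations) + max(annotations$rank_in_field) + 1
  imp * (max_rank + 1) * n + unname(term_rank) * n - annotations$rank_in_field
}

#' Per-variant primary annotations for a cohort
#'
#' Reduces each annotator's transcript-level annotations to one primary
#' consequence per variant (see [select_primary_annotation()]).
#'
#' @param cohort A `horse_cohort`.
#' @param severity_table Term severity rank map.
#' @return A tibble with one row per variant: `variant`, `snpeff_term`,
#'   `snpeff_impact`, `vep_term`, `vep_impact`, `gene_id`, `hgnc_symbol`
#'   (gene columns from the SnpEff primary, falling back to VEP).
#' @export
primary_annotations <- function(cohort, severity_table = default_severity_table()) {
  stopifnot(inherits(cohort, "horse_cohort"))
  pick <- function(ann) {
    if (nrow(ann) == 0) {
      return(tibble::tibble(variant = integer(), term = character(),
                            impact = character(), gene_id = character(),
                            hgnc_symbol = character()))
    }
    pri <- annotation_priority(ann, severity_table)
    ord <- order(ann$variant, -pri)
    first <- ord[!duplicated(ann$variant[ord])]
    ann[first, c("variant", "term", "impact", "gene_id", "hgnc_symbol")]
  }
  se <- pick(cohort$snpeff)
  ve <- pick(cohort$vep)
  out <- tibble::tibble(variant = seq_len(nrow(cohort$variants))) |>
    dplyr::left_join(
      dplyr::rename(se, snpeff_term = "term", snpeff_impact = "impact"),
      by = "variant") |>
    dplyr::left_join(
      dplyr::rename(ve, vep_term = "term", vep_impact = "impact",
                    vep_gene_id = "gene_id", vep_hgnc = "hgnc_symbol"),
      by = "variant")
  out$gene_id <- ifelse(is.na(out$gene_id), out$vep_gene_id, out$gene_id)
  out$hgnc_symbol <- ifelse(is.na(out$hgnc_symbol), out$vep_hgnc, out$hgnc_symbol)
  dplyr::select(out, -"vep_gene_id", -"vep_hgnc")
}
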