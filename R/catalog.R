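catalog_categories <- function() {
  c("disease_trait_causing", "coat_color", "disease_associated",
    "trait_associated")
}

#' Load a known-variant catalog
#'
#' Tab-separated text with header
#' `entry_id phenotype category chrom pos ref alt` (an optional leading
#' `#build=` pragma line records the genome build). Categories must come
#' from the controlled vocabulary (disease_trait_causing, coat_color,
#' disease_associated, trait_associated); alleles are capped at 20 bases;
#' duplicate (chrom, pos, ref, alt) coordinates are rejected.
#'
#' @param path File path.
#' @return Tibble of validated entries with a `build` attribute.
#' @export
load_catalog <- function(path) {
  lines <- readLines(path)
  build <- NA_character_
  pragma <- grepl("^#", lines) & !grepl("^#entry_id", lines)
  if (any(pragma)) {
    b <- grep("^#build=", lines, value = TRUE)
    if (length(b) > 0) build <- sub("^#build=", "", b[1])
  }
  df <- utils::read.delim(text = lines[!pragma], stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("entry_id", "phenotype", "category", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  bad_cat <- which(!df$category %in% catalog_categories())
  if (length(bad_cat) > 0) {
    stop(sprintf("catalog row %d has unknown category '%s'",
                 bad_cat[1], df$category[bad_cat[1]]), call. = FALSE)
  }
  too_long <- which(nchar(df$ref) > 20 | nchar(df$alt) > 20)
  if (length(too_long) > 0) {
    stop(sprintf("catalog row %d has an allele longer than 20 bases",
                 too_long[1]), call. = FALSE)
  }
  if (any(df$ref == df$alt)) {
    stop("catalog entry with ref == alt", call. = FALSE)
  }
  dup <- duplicated(df[c("chrom", "pos", "ref", "alt")])
  if (any(dup)) {
    stop(sprintf("duplicate catalog coordinates at row %d", which(dup)[1]),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "build") <- build
  out
}

#' Match a known-variant catalog against a cohort
#'
#' Exact match on normalized (chrom, pos, ref, alt) after optional
#' chromosome-alias harmonization; unmatched entries are reported with
#' `detected = FALSE` (a mismatch is a result, not an error). For detected
#' entries, genotype counts and frequencies are computed per breed group.
#'
#' @param cohort A `horse_cohort` (decomposed, biallelic records).
#' @param catalog Tibble from [load_catalog()].
#' @param breed_col Metadata column holding the breed grouping (default
#'   `"breed"`; use `"breed_group"` after [select_target_breeds()]).
#' @param chrom_aliases Optional named vector harmonizing catalog chromosome
#'   names to cohort names.
#' @param near_miss Also list cohort variants at a matched position with
#'   different alleles (surfacing normalization problems). Default TRUE.
#' @return List with `matches` (one row per entry: `entry_id`, `phenotype`,
#'   `category`, `detected`, `vf`, `maf`, `n_carriers`, `carrier_ids`),
#'   `by_breed` (per entry x breed: `n_called`, `het`, `hom_alt`, `vf`,
#'   `maf`) and `near_misses`.
#' @export
match_catalog <- function(cohort, catalog, breed_col = "breed",
                          chrom_aliases = NULL, near_miss = TRUE) {
  stopifnot(breed_col %in% names(cohort$metadata))
  v <- cohort$variants
  cat_chrom <- catalog$chrom
  if (!is.null(chrom_aliases)) {
    hit <- cat_chrom %in% names(chrom_aliases)
    cat_chrom[hit] <- unname(chrom_aliases[cat_chrom[hit]])
  }
  key_v <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  key_c <- paste(cat_chrom, catalog$pos, catalog$ref, catalog$alt, sep = ":")
  hit_idx <- match(key_c, key_v)
  breeds <- cohort$metadata[[breed_col]]

  matches <- vector("list", nrow(catalog))
  by_breed <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    vi <- hit_idx[i]
    if (is.na(vi)) {
      matches[[i]] <- tibble::tibble(
        entry_id = catalog$entry_id[i], phenotype = catalog$phenotype[i],
        category = catalog$category[i], detected = FALSE, variant = NA_integer_,
        vf = NA_real_, maf = NA_real_, n_carriers = 0L, carrier_ids = "")
      next
    }
    g <- cohort$geno[vi, ]
    freq <- site_allele_frequency(g)
    carriers <- colnames(cohort$geno)[!is.na(g) & g > 0]
    detected <- length(carriers) > 0
    matches[[i]] <- tibble::tibble(
      entry_id = catalog$entry_id[i], phenotype = catalog$phenotype[i],
      category = catalog$category[i], detected = detected, variant = vi,
      vf = freq$vf, maf = freq$maf,
      n_carriers = length(carriers),
      carrier_ids = paste(carriers, collapse = ","))
    bb <- tibble::tibble(breed = breeds, g = g) |>
      dplyr::filter(!is.na(.data$g)) |>
      dplyr::group_by(.data$breed) |>
      dplyr::summarise(
        n_called = dplyr::n(),
        het = sum(.data$g == 1L),
        hom_alt = sum(.data$g == 2L),
        .groups = "drop")
    bb$vf <- (bb$het + 2 * bb$hom_alt) / (2 * bb$n_called)
    bb$maf <- pmin(bb$vf, 1 - bb$vf)
    by_breed[[i]] <- dplyr::bind_cols(
      tibble::tibble(entry_id = catalog$entry_id[i],
                     phenotype = catalog$phenotype[i]), bb)
  }
  nm <- tibble::tibble(entry_id = character(), chrom = character(),
                       pos = integer(), cohort_ref = character(),
                       cohort_alt = character())
  if (near_miss) {
    pos_key_v <- paste(v$chrom, v$pos, sep = ":")
    pos_key_c <- paste(cat_chrom, catalog$pos, sep = ":")
    for (i in which(is.na(hit_idx))) {
      j <- which(pos_key_v == pos_key_c[i])
      if (length(j) > 0) {
        nm <- dplyr::bind_rows(nm, tibble::tibble(
          entry_id = catalog$entry_id[i], chrom = v$chrom[j],
          pos = v$pos[j], cohort_ref = v$ref[j], cohort_alt = v$alt[j]))
      }
    }
  }
  list(matches = dplyr::bind_rows(matches),
       by_breed = dplyr::bind_rows(by_breed),
       near_misses = nm)
}

#' Summarize catalog detection by category
#'
#' @param match_result Result of [match_catalog()] (or its `matches` tibble).
#' @return List with `categories` (per category: `n_catalog`, `n_detected`,
#'   `detection_pct`, `median_vf_pct`, `vf_iqr_low_pct`, `vf_iqr_high_pct`;
#'   frequency summaries over detected entries only, absent (NA) when none
#'   detected) and `overall_median_vf_pct` across all detected entries.
#' @export
summarize_categories <- function(match_result) {
  m <- if (is.data.frame(match_result)) match_result else match_result$matches
  cats <- m |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_catalog = dplyr::n(),
      n_detected = sum(.data$detected),
      detection_pct = 100 * sum(.data$detected) / dplyr::n(),
      median_vf_pct = if (any(.data$detected))
        100 * stats::median(.data$vf[.data$detected]) else NA_real_,
      vf_iqr_low_pct = if (any(.data$detected))
        100 * stats::quantile(.data$vf[.data$detected], 0.25, names = FALSE)
        else NA_real_,
      vf_iqr_high_pct = if (any(.data$detected))
        100 * stats::quantile(.data$vf[.data$detected], 0.75, names = FALSE)
        else NA_real_,
      .groups = "drop")
  overall <- if (any(m$detected))
    100 * stats::median(m$vf[m$detected]) else NA_real_
  list(categories = cats, overall_median_vf_pct = overall)
}

#' Flag catalog entries with genotypes conflicting with reported inheritance
#'
#' Rules supply per-entry expectations: `lethal_homozygote = TRUE` flags any
#' homozygous-alt sample (e.g. an adult homozygote for a reported lethal
#' recessive); `expected_breeds` (comma-separated) flags carriers outside the
#' listed breeds. Read-level review of flagged genotypes is out of scope.
#'
#' @param match_result Result of [match_catalog()].
#' @param rules Tibble: `entry_id`, `lethal_homozygote` (logical),
#'   `expected_breeds` (comma-separated breed list, empty = no restriction).
#' @param cohort The matched `horse_cohort` (for per-sample genotypes).
#' @param breed_col Metadata breed column (default `"breed"`).
#' @return Tibble of violations: `entry_id`, `rule`, `sample_id`, `breed`,
#'   `genotype`. Empty when nothing conflicts.
#' @export
flag_unexpected_genotypes <- function(match_result, rules, cohort,
                                      breed_col = "breed") {
  m <- match_result$matches
  stopifnot(all(c("entry_id", "lethal_homozygote", "expected_breeds")
                %in% names(rules)))
  gt_label <- function(g) unname(ifelse(is.na(g), "missing",
                                        c("hom_ref", "het", "hom_alt")[g + 1L]))
  out <- list()
  for (i in seq_len(nrow(rules))) {
    row <- m[m$entry_id == rules$entry_id[i], ]
    if (nrow(row) != 1 || !row$detected) next
    g <- cohort$geno[row$variant, ]
    ids <- colnames(cohort$geno)
    breeds <- cohort$metadata[[breed_col]]
    carrier <- !is.na(g) & g > 0
    if (isTRUE(as.logical(rules$lethal_homozygote[i]))) {
      hom <- which(!is.na(g) & g == 2L)
      if (length(hom) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          entry_id = row$entry_id, rule = "lethal_homozygote",
          sample_id = ids[hom], breed = breeds[hom],
          genotype = gt_label(g[hom]))
      }
    }
    exp_b <- rules$expected_breeds[i]
    if (!is.na(exp_b) && nzchar(exp_b)) {
      allowed <- trimws(strsplit(exp_b, ",", fixed = TRUE)[[1]])
      outside <- which(carrier & !(breeds %in% allowed))
      if (length(outside) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          entry_id = row$entry_id, rule = "unexpected_breed",
          sample_id = ids[outside], breed = breeds[outside],
          genotype = gt_label(g[outside]))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(entry_id = character(), rule = character(),
                          sample_id = character(), breed = character(),
                          genotype = character()))
  }
  dplyr::bind_rows(out)
}
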