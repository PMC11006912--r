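#' Impact classes and consequence-term vocabulary
#'
#' Variant-effect annotators label every transcript consequence with one of
#' four impact classes. The total severity order used throughout the package
#' is HIGH > MODERATE > LOW > MODIFIER.
#'
#' @return Character vector of the four impact labels, most severe first.
#' @export
impact_levels <- function() {
  c("HIGH", "MODERATE", "LOW", "MODIFIER")
}

#' Numeric severity rank of impact labels
#'
#' @param impact Character vector of impact labels.
#' @return Integer vector; 4 = HIGH down to 1 = MODIFIER. Unknown labels error.
#' @export
impact_rank <- function(impact) {
  impact <- toupper(impact)
  bad <- setdiff(unique(impact), impact_levels())
  if (length(bad) > 0) {
    stop("unknown impact label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  match(impact, rev(impact_levels()))
}

# Dialect synonyms: SnpEff and VEP spell several Sequence Ontology terms
# differently ("Frameshift" vs "frameshift_variant", space vs underscore).
# Normalization lower-cases, converts separators to "_", strips a trailing
# "_variant", then applies this map so membership tests are dialect-free.
.term_synonyms <- c(
  frameshift_variant            = "frameshift",
  splice_acceptor_variant       = "splice_acceptor",
  splice_donor_variant          = "splice_donor",
  initiator_codon_variant       = "start_lost",
  exon_loss_variant             = "exon_loss",
  disruptive_inframe_deletion   = "inframe_deletion",
  conservative_inframe_deletion = "inframe_deletion",
  disruptive_inframe_insertion  = "inframe_insertion",
  conservative_inframe_insertion = "inframe_insertion",
  missense_variant              = "missense",
  protein_altering_variant      = "protein_altering",
  synonymous_variant            = "synonymous",
  intron_variant                = "intron",
  intergenic_region             = "intergenic",
  intergenic_variant            = "intergenic"
)

#' Normalize consequence terms across annotator dialects
#'
#' Lower-cases, converts spaces/hyphens to underscores, strips a trailing
#' `_variant`, and applies a documented synonym map, so that e.g.
#' `"Splice acceptor"`, `"splice_acceptor_variant"` and `"splice_acceptor"`
#' all compare equal.
#'
#' @param term Character vector of consequence terms.
#' @return Character vector of canonical terms.
#' @export
normalize_term <- function(term) {
  x <- tolower(trimws(term))
  x <- gsub("[ -]+", "_", x)
  mapped <- .term_synonyms[x]
  x <- ifelse(is.na(mapped), x, mapped)
  x <- sub("_variant$", "", x)
  unname(x)
}

#' Loss-of-function consequence terms
#'
#' A variant is considered loss of function when its predicted consequence
#' abolishes the gene product: frameshift, splice acceptor or donor
#' alteration, start lost, stop lost, or stop gained. Membership is tested on
#' normalized terms (see [normalize_term()]), so annotator spelling dialects
#' are covered.
#'
#' @return Character vector of canonical LOF terms.
#' @export
lof_terms <- function() {
  c("frameshift", "splice_acceptor", "splice_donor",
    "start_lost", "stop_lost", "stop_gained")
}

#' Test terms for loss-of-function membership
#'
#' @param term Character vector of consequence terms (any dialect).
#' @param terms Character vector of canonical LOF terms; defaults to
#'   [lof_terms()].
#' @return Logical vector.
#' @export
is_lof_term <- function(term, terms = lof_terms()) {
  normalize_term(term) %in% terms
}

#' Default consequence-severity table
#'
#' The annotators never publish an explicit within-impact ordering, so the
#' package ships one: an explicit canonical-term to rank map (larger = more
#' severe) used identically for both annotators when breaking ties between
#' annotations of equal impact class. It is a package construction, exposed
#' so callers can override it.
#'
#' @return Named integer vector mapping canonical term to severity rank.
#' @export
default_severity_table <- function() {
  terms <- c(
    # HIGH-class consequences
    "transcript_ablation", "exon_loss", "frameshift", "stop_gained",
    "stop_lost", "start_lost", "splice_acceptor", "splice_donor",
    "gene_fusion",
    # MODERATE
    "missense", "inframe_deletion", "inframe_insertion", "protein_altering",
    # LOW
    "splice_region", "synonymous", "start_retained", "stop_retained",
    # MODIFIER
    "5_prime_utr", "3_prime_utr", "upstream_gene", "downstream_gene",
    "intron", "intergenic", "non_coding_transcript_exon"
  )
  stats::setNames(rev(seq_along(terms)), terms)
}
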