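# Variant retention rules: functional category, CADD deleteriousness,
# reference-population allele frequency, and the known-gene screen.
# Missing CADD/AF (the "." sentinel, parsed to NA) are always RETAINED so
# that novel variants are never silently lost.

.category_components <- function(category) {
  # ANNOVAR writes composites either as "exonic;splicing" or with the
  # escaped separator "exonic\x3bsplicing"
  category <- gsub("\\\\x3b", ";", category)
  strsplit(tolower(category), ";", fixed = TRUE)
}

#' Retain variants by functional category
#'
#' Keeps records whose functional category matches any of the retained
#' categories (case-insensitive). Composite categories such as
#' `"exonic;splicing"` are split on `";"` and retained if any component
#' matches.
#'
#' @param annot annotation data.frame (see [read_annotation_table()]).
#' @param categories categories to retain; default exonic and splicing.
#' @return the retained subset of `annot`.
#' @export
filter_functional <- function(annot, categories = c("exonic", "splicing")) {
  if (!nrow(annot)) return(annot)
  wanted <- tolower(categories)
  keep <- vapply(.category_components(annot$category),
                 function(x) any(x %in% wanted), logical(1))
  annot[keep, , drop = FALSE]
}

#' Retain variants by CADD deleteriousness
#'
#' Keeps records with CADD phred at or above the threshold, or with a missing
#' CADD score (boundary inclusive).
#'
#' @param annot annotation data.frame.
#' @param threshold minimum CADD phred; default 15.
#' @return the retained subset of `annot`.
#' @export
filter_cadd <- function(annot, threshold = 15) {
  stopifnot(threshold >= 0)
  annot[is.na(annot$cadd_phred) | annot$cadd_phred >= threshold, , drop = FALSE]
}

#' Retain rare variants by reference allele frequency
#'
#' Keeps records with population allele frequency at or below `max_af`, or
#' with a missing frequency (boundary inclusive).
#'
#' @param annot annotation data.frame.
#' @param max_af maximum allele frequency; default 0.01 (1%).
#' @return the retained subset of `annot`.
#' @export
filter_maf <- function(annot, max_af = 0.01) {
  stopifnot(max_af >= 0, max_af <= 1)
  annot[is.na(annot$exac_all_af) | annot$exac_all_af <= max_af, , drop = FALSE]
}

#' Restrict variants to a list of known genes
#'
#' Intended to run *before* genome-wide discovery, so the result for
#' previously reported disease genes is reported separately.
#'
#' @param annot annotation data.frame.
#' @param gene_list character vector of gene symbols.
#' @return the subset of `annot` in listed genes.
#' @export
screen_known_genes <- function(annot, gene_list) {
  if (!length(gene_list)) stop("gene_list must be non-empty")
  annot[annot$gene %in% gene_list, , drop = FALSE]
}
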