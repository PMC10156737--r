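# Orchestration: the full discovery analysis (filter -> segregate -> collapse
# -> rank, with a separate known-gene screen) and the per-variant carrier
# burden comparison against a reference cohort.

.subset_variant_set <- function(vs, keys) {
  idx <- match(keys, vs$variants$key)
  idx <- idx[!is.na(idx)]
  variant_set(vs$variants[idx, !(names(vs$variants) %in% "key"), drop = FALSE],
              vs$genotypes[idx, , drop = FALSE])
}

.run_discovery_chain <- function(vs, ped, annot, categories, cadd_min, maf_max,
                                 tolerance, require_absent_in_unaffected) {
  f_func <- filter_functional(annot, categories)
  f_cadd <- filter_cadd(f_func, cadd_min)
  f_maf <- filter_maf(f_cadd, maf_max)
  joined_keys <- intersect(f_maf$key, vs$variants$key)
  vs_f <- .subset_variant_set(vs, joined_keys)
  seg <- segregate_variants(vs_f, ped, tolerance, require_absent_in_unaffected)
  hits <- rank_genes(collapse_to_genes(seg, f_maf))
  list(hits = hits, segregation = seg,
       counts = c(functional = nrow(f_func), cadd = nrow(f_cadd),
                  maf = nrow(f_maf), joined = length(joined_keys),
                  passing_pairs = sum(seg$passes), genes = nrow(hits)))
}

#' Run the family-based variant prioritization analysis
#'
#' Applies the retention filters (functional category, CADD, allele
#' frequency), tests dominant segregation per family with the configured
#' discordance tolerance, collapses passing variants to gene-level hits
#' across families and ranks them. When a known-gene list is supplied, the
#' same chain restricted to those genes runs first and is reported
#' separately, so "no qualifying segregating variant in previously reported
#' genes" is an explicit result rather than an absence.
#'
#' @param vcf a [variant_set()], a `famseg_sim`, or a path to a VCF file.
#' @param ped pedigree data.frame or path to a PED file (ignored when `vcf`
#'   is a `famseg_sim`).
#' @param annot annotation data.frame or path to an annotation TSV (ignored
#'   when `vcf` is a `famseg_sim`).
#' @param cadd_min minimum CADD phred (missing retained); default 15.
#' @param maf_max maximum reference AF (missing retained); default 0.01.
#' @param categories retained functional categories.
#' @param tolerance segregation discordance tolerance; default 1.
#' @param known_genes optional character vector (or file path) of previously
#'   reported genes to screen first.
#' @param require_absent_in_unaffected strict segregation mode; default off.
#' @param verbose log per-stage record counts with [message()].
#' @return object of class `famseg_prioritization`: `hits` (ranked gene
#'   table), `known_gene_hits` (or NULL), `segregation` (per family x
#'   variant), `stage_counts`.
#' @export
run_prioritization <- function(vcf, ped = NULL, annot = NULL,
                               cadd_min = 15, maf_max = 0.01,
                               categories = c("exonic", "splicing"),
                               tolerance = 1, known_genes = NULL,
                               require_absent_in_unaffected = FALSE,
                               verbose = FALSE) {
  if (inherits(vcf, "famseg_sim")) {
    ped <- vcf$ped
    annot <- vcf$annotations
    vcf <- vcf$vs
  }
  vs <- if (is.character(vcf)) read_vcf(vcf) else vcf
  stopifnot(inherits(vs, "variant_set"))
  if (is.character(ped)) ped <- read_ped(ped)
  if (is.character(annot)) annot <- read_annotation_table(annot)
  if (is.character(known_genes) && length(known_genes) == 1L && file.exists(known_genes)) {
    known_genes <- read_gene_list(known_genes)
  }

  overlap <- intersect(vs$samples, ped$individual_id)
  if (!length(overlap)) stop("no VCF sample overlaps the pedigree members")
  dropped <- setdiff(vs$samples, overlap)
  if (length(dropped)) {
    message("dropping ", length(dropped), " VCF sample(s) absent from the pedigree: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    vs <- variant_set(vs$variants[, !(names(vs$variants) %in% "key"), drop = FALSE],
                      vs$genotypes[, overlap, drop = FALSE])
  }

  n_annotated <- sum(vs$variants$key %in% annot$key)
  unannotated <- nrow(vs$variants) - n_annotated
  if (unannotated && verbose) {
    message(unannotated, " VCF variant(s) without annotation are excluded from ",
            "annotation-dependent filters")
  }

  known_gene_hits <- NULL
  if (!is.null(known_genes)) {
    known <- .run_discovery_chain(
      vs, ped, screen_known_genes(annot, known_genes),
      categories, cadd_min, maf_max, tolerance, require_absent_in_unaffected
    )
    known_gene_hits <- known$hits
    if (verbose) {
      message("known-gene screen: ", nrow(known_gene_hits),
              " gene(s) with qualifying segregating variants")
    }
  }

  disc <- .run_discovery_chain(vs, ped, annot, categories, cadd_min, maf_max,
                               tolerance, require_absent_in_unaffected)
  stage_counts <- c(
    vcf_variants = nrow(vs$variants), annotated = n_annotated, disc$counts
  )
  if (verbose) {
    for (nm in names(stage_counts)) message(nm, ": ", stage_counts[[nm]])
  }
  structure(
    list(hits = disc$hits, known_gene_hits = known_gene_hits,
         segregation = disc$segregation, stage_counts = stage_counts),
    class = "famseg_prioritization"
  )
}

#' @export
print.famseg_prioritization <- function(x, ...) {
  cat("famseg_prioritization:", x$stage_counts[["vcf_variants"]], "variants ->",
      x$stage_counts[["genes"]], "ranked gene(s)\n")
  if (nrow(x$hits)) {
    top <- utils::head(.hits_to_table(x$hits), 5)
    print(top[, c("rank", "gene", "n_families", "n_variants", "total_affected_carriers")])
  }
  invisible(x)
}

.safe_odds_ratio <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  if (b == 0 || cc == 0) return(if (a == 0 || d == 0) NA_real_ else Inf)
  (a * d) / (b * cc)
}

#' Per-variant carrier burden versus a reference cohort
#'
#' For each variant of interest: tallies case carriers, assembles the 2x2
#' case-vs-reference table, and reports carrier frequencies, the odds ratio,
#' the two-sided Fisher exact p-value and the chi-squared expected carrier
#' counts. A requested variant absent from the case genotypes yields a
#' flagged row, not an error.
#'
#' @param case a [variant_set()] of case genotypes (cases only), or a path to
#'   a VCF.
#' @param reference a [carrier_counts()] object used for every variant, or a
#'   named list of them keyed by variant key (a list with a single unnamed
#'   element is recycled), or a path to a carrier table TSV (first row used).
#' @param variants_of_interest character vector of variant keys
#'   (`chrom:pos:ref:alt`); default all case variants.
#' @param case_label cohort label for the case tallies.
#' @return data.frame, one row per requested variant, with carrier counts,
#'   frequencies, `odds_ratio`, `fisher_p`, `chi2_statistic`,
#'   `expected_case_carriers`, `expected_ref_carriers`, `flag`.
#' @export
run_burden <- function(case, reference, variants_of_interest = NULL,
                       case_label = "case") {
  vs <- if (is.character(case)) read_vcf(case) else case
  stopifnot(inherits(vs, "variant_set"))
  if (is.character(reference)) reference <- read_carrier_table(reference)
  single_ref <- inherits(reference, "carrier_counts")
  if (!single_ref && is.list(reference) && length(reference) == 1L) {
    reference <- reference[[1]]
    single_ref <- TRUE
  }
  keys <- variants_of_interest
  if (is.null(keys)) keys <- vs$variants$key

  rows <- lapply(keys, function(k) {
    base <- data.frame(
      variant = k, case_n_het = NA_integer_, case_n_hom = NA_integer_,
      case_carriers = NA_integer_, case_genotyped = NA_integer_,
      case_carrier_freq = NA_real_, ref_carriers = NA_integer_,
      ref_genotyped = NA_integer_, ref_carrier_freq = NA_real_,
      odds_ratio = NA_real_, fisher_p = NA_real_, chi2_statistic = NA_real_,
      expected_case_carriers = NA_real_, expected_ref_carriers = NA_real_,
      flag = NA_character_, stringsAsFactors = FALSE
    )
    if (!k %in% vs$variants$key) {
      base$flag <- "variant_absent"
      return(base)
    }
    cc_case <- count_carriers(vs$genotypes[k, ], case_label)
    ref <- if (single_ref) reference else reference[[k]]
    if (is.null(ref)) {
      base$flag <- "no_reference_counts"
      return(base)
    }
    tab <- build_case_vs_reference(cc_case, ref)
    p <- fisher_exact_two_sided(tab)
    chi <- chi2_expected(tab)
    base$case_n_het <- cc_case$n_het
    base$case_n_hom <- cc_case$n_hom
    base$case_carriers <- cc_case$carriers
    base$case_genotyped <- cc_case$genotyped
    base$case_carrier_freq <- carrier_frequency(cc_case)
    base$ref_carriers <- ref$carriers
    base$ref_genotyped <- ref$genotyped
    base$ref_carrier_freq <- carrier_frequency(ref)
    base$odds_ratio <- .safe_odds_ratio(tab)
    base$fisher_p <- as.numeric(p)
    base$chi2_statistic <- chi$statistic
    base$expected_case_carriers <- chi$expected[1, 1]
    base$expected_ref_carriers <- chi$expected[2, 1]
    base$flag <- if (!is.null(attr(p, "flag"))) attr(p, "flag") else NA_character_
    base
  })
  do.call(rbind, rows)
}
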