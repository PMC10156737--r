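# Per-family autosomal dominant segregation with a configurable discordance
# tolerance, and cross-family gene-level collapsing/ranking.

#' Dominant-model carrier status of a genotype call
#'
#' Under an autosomal dominant model one variant allele suffices: `het` and
#' `hom_alt` are carriers, `hom_ref` is not. `missing` is not a carrier;
#' callers tally missing genotypes separately.
#'
#' @param g character vector of genotype states.
#' @return logical vector.
#' @export
is_carrier <- function(g) {
  g %in% c("het", "hom_alt")
}

#' Test dominant segregation of one variant in one family
#'
#' Among genotyped affected members, let n be their number and c the carriers.
#' The variant segregates when at most `tolerance` affected individuals are
#' non-carriers (`n - c <= tolerance`) and at least one affected carries it
#' (`c >= 1`; without this guard a small family could "pass" on tolerance
#' alone with the variant entirely absent). Affected members with missing or
#' absent genotypes shrink the denominator — absence of data is not evidence
#' of non-carriage — and are reported in `n_affected_missing`.
#'
#' @param ped pedigree data.frame for one family (rows of other families are
#'   ignored if `family_id` is given).
#' @param genotypes named character vector of genotype states, one per
#'   genotyped sample.
#' @param tolerance maximum number of non-carrier affecteds; default 1.
#' @param family_id optional family to test when `ped` holds several.
#' @param require_absent_in_unaffected strict mode: additionally require that
#'   no genotyped unaffected member carries the variant. Off by default (the
#'   disease modeled is late-onset with incomplete penetrance, so unaffected
#'   carriers are expected).
#' @return list of class `segregation_result`: `family_id`,
#'   `n_affected_genotyped`, `n_affected_carriers`, `n_affected_missing`,
#'   `passes`, `flag` (`NA` or `"no_genotyped_affected"`).
#' @export
test_family_segregation <- function(ped, genotypes, tolerance = 1,
                                    family_id = NULL,
                                    require_absent_in_unaffected = FALSE) {
  stopifnot(tolerance >= 0)
  if (!is.null(family_id)) ped <- ped[ped$family_id == family_id, , drop = FALSE]
  fam <- unique(ped$family_id)
  if (length(fam) != 1L) stop("ped must describe exactly one family (or pass family_id)")

  affected <- affected_members(ped)
  states <- genotypes[intersect(affected, names(genotypes))]
  genotyped <- states[states != "missing"]
  n <- length(genotyped)
  c_aff <- sum(is_carrier(genotyped))
  n_missing <- length(affected) - n

  flag <- NA_character_
  if (n == 0L) {
    passes <- FALSE
    flag <- "no_genotyped_affected"
  } else {
    passes <- (n - c_aff) <= tolerance && c_aff >= 1L
    if (passes && require_absent_in_unaffected) {
      unaff <- ped$individual_id[ped$affection == "unaffected"]
      ustates <- genotypes[intersect(unaff, names(genotypes))]
      passes <- !any(is_carrier(ustates[ustates != "missing"]))
    }
  }

  structure(
    list(family_id = fam, n_affected_genotyped = n, n_affected_carriers = c_aff,
         n_affected_missing = n_missing, passes = passes, flag = flag),
    class = "segregation_result"
  )
}

#' Segregation test of every variant in every family
#'
#' Vectorized application of the rule in [test_family_segregation()] across a
#' genotype matrix; one row per (family, variant).
#'
#' @param vs a [variant_set()].
#' @param ped pedigree data.frame covering one or more families.
#' @param tolerance maximum number of non-carrier affecteds; default 1.
#' @param require_absent_in_unaffected strict mode, see
#'   [test_family_segregation()].
#' @return data.frame with columns `family_id`, `key`,
#'   `n_affected_genotyped`, `n_affected_carriers`, `n_affected_missing`,
#'   `passes`.
#' @export
segregate_variants <- function(vs, ped, tolerance = 1,
                               require_absent_in_unaffected = FALSE) {
  stopifnot(inherits(vs, "variant_set"))
  gt <- vs$genotypes
  fams <- unique(ped$family_id)
  res <- lapply(fams, function(fam) {
    p <- ped[ped$family_id == fam, , drop = FALSE]
    affected <- affected_members(p)
    cols <- intersect(affected, colnames(gt))
    sub <- gt[, cols, drop = FALSE]
    nonmiss <- sub != "missing"
    carrier <- sub == "het" | sub == "hom_alt"
    n <- as.integer(rowSums(nonmiss))
    c_aff <- as.integer(rowSums(carrier))
    passes <- (n - c_aff) <= tolerance & c_aff >= 1L & n > 0L
    if (require_absent_in_unaffected) {
      unaff <- intersect(p$individual_id[p$affection == "unaffected"], colnames(gt))
      usub <- gt[, unaff, drop = FALSE]
      ucarrier <- rowSums(usub == "het" | usub == "hom_alt")
      passes <- passes & ucarrier == 0L
    }
    data.frame(
      family_id = rep(fam, nrow(vs$variants)), key = vs$variants$key,
      n_affected_genotyped = n, n_affected_carriers = c_aff,
      n_affected_missing = length(affected) - n,
      passes = passes, stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, res)
}

#' Collapse passing segregation results to gene-level hits
#'
#' Variant-level evidence is combined per gene across families: distinct
#' variants in the same gene, each segregating in a different family, support
#' the same gene hit; a single variant segregating in several families does
#' too. Passing variants without an annotation are reported under the gene
#' `"UNANNOTATED"` rather than dropped.
#'
#' @param seg segregation results from [segregate_variants()] (or a rbind of
#'   per-variant results).
#' @param annot annotation data.frame with `key` and `gene`.
#' @return data.frame with one row per gene having at least one passing
#'   family: `gene`, `n_families`, `families` (list column), `n_variants`,
#'   `variants` (list column), `total_affected_carriers`.
#' @export
collapse_to_genes <- function(seg, annot) {
  passing <- seg[seg$passes, , drop = FALSE]
  if (!nrow(passing)) {
    return(data.frame(
      gene = character(0), n_families = integer(0), families = I(list()),
      n_variants = integer(0), variants = I(list()),
      total_affected_carriers = integer(0), stringsAsFactors = FALSE
    ))
  }
  gene <- annot$gene[match(passing$key, annot$key)]
  if (anyNA(gene)) {
    message(sum(is.na(gene)), " passing variant(s) without annotation reported as UNANNOTATED")
    gene[is.na(gene)] <- "UNANNOTATED"
  }
  passing$gene <- gene
  split_by_gene <- split(passing, passing$gene)
  out <- lapply(split_by_gene, function(g) {
    data.frame(
      gene = g$gene[1],
      n_families = length(unique(g$family_id)),
      families = I(list(sort(unique(g$family_id)))),
      n_variants = length(unique(g$key)),
      variants = I(list(sort(unique(g$key)))),
      total_affected_carriers = sum(g$n_affected_carriers),
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits
}

#' Rank gene hits
#'
#' Descending by number of supporting families, ties broken by total affected
#' carriers (descending) then gene symbol (ascending); deterministic and
#' invariant under input order.
#'
#' @param hits gene hits from [collapse_to_genes()].
#' @return `hits` reordered.
#' @export
rank_genes <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(-hits$n_families, -hits$total_affected_carriers, hits$gene)
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
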