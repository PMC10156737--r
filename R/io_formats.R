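# Readers/writers for the formats the pipeline touches: multi-sample VCF
# (via vcfR), 6-column PED, ANNOVAR-style annotation TSV, reference carrier
# tables, and the ranked-gene / burden reports.

.GT_STATES <- c("hom_ref", "het", "hom_alt", "missing")

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a variant set
#'
#' A variant set bundles a variant table with a genotype-state matrix. It is
#' the in-memory currency of the pipeline: [read_vcf()] produces one and
#' [simulate_family_study()] produces one without touching disk.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes character matrix (variants x samples) of genotype states
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`; column names are sample
#'   ids.
#' @return object of class `variant_set` with elements `variants` (the table,
#'   plus a `key` column `chrom:pos:ref:alt`), `genotypes`, `samples`.
#' @export
variant_set <- function(variants, genotypes) {
  stopifnot(is.data.frame(variants), is.matrix(genotypes),
            nrow(variants) == nrow(genotypes))
  if (!all(genotypes %in% .GT_STATES)) {
    stop("genotype matrix contains values outside the four genotype states")
  }
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(variants$key)) {
    stop("duplicate variant keys after normalization: ",
         paste(unique(variants$key[duplicated(variants$key)]), collapse = ", "))
  }
  rownames(genotypes) <- variants$key
  structure(
    list(variants = variants, genotypes = genotypes, samples = colnames(genotypes)),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x", length(x$samples), "samples\n")
  invisible(x)
}

.split_gt_strings <- function(gt) {
  gt[is.na(gt)] <- "."
  strsplit(gt, "[/|]")
}

# Genotype state of each sample with respect to one alt allele index.
# Any "." allele (including half-calls) -> missing; haploid calls are treated
# as diploid homozygous (sex chromosomes handled as diploid throughout).
.states_for_allele <- function(allele_lists, allele_index) {
  target <- as.character(allele_index)
  vapply(allele_lists, function(a) {
    if (!length(a) || any(a == ".") || !all(grepl("^[0-9]+$", a))) {
      return("missing")
    }
    if (length(a) == 1L) a <- c(a, a)
    if (length(a) != 2L) return("missing")
    dosage <- sum(a == target)
    .GT_STATES[dosage + 1L]
  }, character(1))
}

#' Split a (possibly multiallelic) VCF record into biallelic records
#'
#' For alt allele i, a sample's state is determined by its allele-i dosage:
#' carriers of only *other* alt alleles are `hom_ref` with respect to allele i,
#' so per-sample dosage is conserved across the split records.
#'
#' @param chrom,pos,ref scalars identifying the site.
#' @param alt comma-separated ALT string (or character vector of alt alleles).
#' @param gt named character vector of raw GT strings (e.g. `"0/1"`, `"1|2"`,
#'   `"./."`) per sample.
#' @return list of records, one per alt allele, each a list with `chrom`,
#'   `pos`, `ref`, `alt` and `genotypes` (named state vector).
#' @export
split_multiallelic <- function(chrom, pos, ref, alt, gt) {
  alts <- if (length(alt) == 1L) strsplit(alt, ",", fixed = TRUE)[[1]] else alt
  if (!length(alts)) stop("record has no alt allele")
  allele_lists <- .split_gt_strings(gt)
  lapply(seq_along(alts), function(i) {
    states <- .states_for_allele(allele_lists, i)
    names(states) <- names(gt)
    list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alts[i],
         genotypes = states)
  })
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF 4.x file (plain or bgzipped) with `vcfR`, normalizes genotype
#' calls to the four states (phase is discarded; any `.` allele including
#' half-calls becomes `missing`) and splits multiallelic rows into biallelic
#' records via [split_multiallelic()].
#'
#' @param path path to the VCF file.
#' @return a [variant_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2L) {
    stop("VCF has no sample genotype columns: ", path)
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE), function(f) "GT" %in% f, logical(1)))) {
    stop("VCF rows lack a GT FORMAT field: ", path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  fix <- v@fix

  recs <- list()
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    if (is.na(pos) || pos < 1L) {
      stop("malformed VCF row ", i, ": POS '", fix[i, "POS"], "' is not a positive integer")
    }
    alt <- fix[i, "ALT"]
    if (is.na(alt) || alt == "." || alt == "") {
      stop("malformed VCF row ", i, ": missing ALT allele")
    }
    row_gt <- gt[i, , drop = TRUE]
    names(row_gt) <- samples
    recs <- c(recs, split_multiallelic(fix[i, "CHROM"], pos, fix[i, "REF"], alt, row_gt))
  }

  variants <- data.frame(
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    pos = vapply(recs, `[[`, integer(1), "pos"),
    ref = vapply(recs, `[[`, character(1), "ref"),
    alt = vapply(recs, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE
  )
  bad <- variants$ref == variants$alt
  if (any(bad)) stop("malformed VCF: REF equals ALT at row ", which(bad)[1])
  genotypes <- do.call(rbind, lapply(recs, `[[`, "genotypes"))
  colnames(genotypes) <- samples
  variant_set(variants, genotypes)
}

#' Read a 6-column PED file
#'
#' Whitespace-delimited: family_id, individual_id, father_id, mother_id,
#' sex (1 = male, 2 = female, 0 = unknown), affection (2 = affected,
#' 1 = unaffected, 0 or -9 = unknown). `"0"` denotes an unknown parent.
#'
#' @param path path to the PED file.
#' @return pedigree data.frame (see [validate_pedigree()]).
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 6L) stop("PED file must have at least 6 columns: ", path)
  ped <- data.frame(
    family_id = raw[[1]], individual_id = raw[[2]],
    father_id = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother_id = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex = c("unknown", "male", "female")[match(raw[[5]], c("0", "1", "2"))],
    affection = ifelse(raw[[6]] == "2", "affected",
                       ifelse(raw[[6]] == "1", "unaffected", "unknown")),
    stringsAsFactors = FALSE
  )
  if (anyNA(ped$sex)) {
    stop("PED sex column must be 0/1/2 (line ", which(is.na(ped$sex))[1], ")")
  }
  ped
}

#' Write a pedigree as a 6-column PED file
#' @param ped pedigree data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex_code <- match(ped$sex, c("male", "female")) # NA -> 0 below
  sex_code[is.na(sex_code)] <- 0L
  aff_code <- ifelse(ped$affection == "affected", 2L,
                     ifelse(ped$affection == "unaffected", 1L, 0L))
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex_code, aff_code
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.default_annotation_cols <- c(
  chrom = "Chr", pos = "Start", ref = "Ref", alt = "Alt",
  gene = "Gene.refGene", category = "Func.refGene",
  cadd_phred = "CADD_phred", exac_all_af = "ExAC_all"
)

.parse_dot_numeric <- function(x, column) {
  out <- rep(NA_real_, length(x))
  present <- !is.na(x) & x != "."
  val <- suppressWarnings(as.numeric(x[present]))
  if (anyNA(val)) {
    bad <- which(present)[which(is.na(val))[1]]
    stop("unparseable value '", x[bad], "' in column '", column, "' (line ", bad + 1L, ")")
  }
  out[present] <- val
  out
}

#' Read an ANNOVAR-style annotation table
#'
#' Tab-separated with a header. The `.` sentinel in the CADD and allele
#' frequency columns parses to `NA` (a distinguished missing value, never
#' zero). Column names can be remapped for other annotation dialects.
#'
#' @param path path to the TSV.
#' @param col_map named character vector mapping canonical names (`chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `category`, `cadd_phred`, `exac_all_af`) to
#'   the file's column headers; defaults to the ANNOVAR refGene convention.
#' @return data.frame with the canonical columns plus `key`.
#' @export
read_annotation_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  cmap <- .default_annotation_cols
  if (!is.null(col_map)) cmap[names(col_map)] <- col_map
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(cmap), names(raw))
  if (length(missing_cols)) {
    stop("annotation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  annot <- data.frame(
    chrom = raw[[cmap["chrom"]]],
    pos = as.integer(.parse_dot_numeric(raw[[cmap["pos"]]], cmap["pos"])),
    ref = raw[[cmap["ref"]]],
    alt = raw[[cmap["alt"]]],
    gene = raw[[cmap["gene"]]],
    category = raw[[cmap["category"]]],
    cadd_phred = .parse_dot_numeric(raw[[cmap["cadd_phred"]]], cmap["cadd_phred"]),
    exac_all_af = .parse_dot_numeric(raw[[cmap["exac_all_af"]]], cmap["exac_all_af"]),
    stringsAsFactors = FALSE
  )
  bad_af <- !is.na(annot$exac_all_af) & (annot$exac_all_af < 0 | annot$exac_all_af > 1)
  if (any(bad_af)) {
    stop("allele frequency outside [0,1] at line ", which(bad_af)[1] + 1L)
  }
  if (any(!nzchar(annot$gene))) stop("empty gene symbol at line ",
                                     which(!nzchar(annot$gene))[1] + 1L)
  annot$key <- variant_key(annot$chrom, annot$pos, annot$ref, annot$alt)
  annot
}

#' Write an annotation table in ANNOVAR-style layout
#' @param annot annotation data.frame (canonical columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annot, path) {
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  out <- data.frame(
    Chr = annot$chrom, Start = annot$pos, Ref = annot$ref, Alt = annot$alt,
    `Gene.refGene` = annot$gene, `Func.refGene` = annot$category,
    CADD_phred = fmt_num(annot$cadd_phred), ExAC_all = fmt_num(annot$exac_all_af),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference carrier-count table
#'
#' TSV with columns `cohort`, `n_het`, `n_hom`, `n_noncarrier` (one row per
#' cohort; labels must be unique, counts non-negative).
#'
#' @param path path to the TSV.
#' @return named list of [carrier_counts()] objects, keyed by cohort label.
#' @export
read_carrier_table <- function(path) {
  if (!file.exists(path)) stop("carrier table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("cohort", "n_het", "n_hom", "n_noncarrier")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("carrier table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$cohort)) {
    stop("duplicate cohort label: ", raw$cohort[duplicated(raw$cohort)][1])
  }
  out <- lapply(seq_len(nrow(raw)), function(i) {
    carrier_counts(raw$cohort[i], raw$n_het[i], raw$n_hom[i], raw$n_noncarrier[i])
  })
  names(out) <- raw$cohort
  out
}

#' Write a carrier-count table
#' @param counts a [carrier_counts()] object or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_carrier_table <- function(counts, path) {
  if (inherits(counts, "carrier_counts")) counts <- list(counts)
  out <- do.call(rbind, lapply(counts, function(cc) {
    data.frame(cohort = cc$cohort, n_het = cc$n_het, n_hom = cc$n_hom,
               n_noncarrier = cc$n_noncarrier, stringsAsFactors = FALSE)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-gene list (one symbol per line)
#' @param path path to the text file.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

.hits_to_table <- function(hits) {
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(
      rank = integer(0), gene = character(0), n_families = integer(0),
      families = character(0), n_variants = integer(0), variants = character(0),
      total_affected_carriers = integer(0), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    rank = seq_len(nrow(hits)),
    gene = hits$gene,
    n_families = hits$n_families,
    families = vapply(hits$families, function(f) paste(sort(f), collapse = ","), character(1)),
    n_variants = hits$n_variants,
    variants = vapply(hits$variants, function(v) paste(sort(v), collapse = ","), character(1)),
    total_affected_carriers = hits$total_affected_carriers,
    stringsAsFactors = FALSE
  )
}

#' Write the ranked-gene report (and optional burden section)
#'
#' Emits a deterministic TSV — fixed column order, one row per gene in rank
#' order — so that identical inputs produce byte-identical files. When burden
#' results are supplied they are written alongside as
#' `<path minus extension>_burden.tsv`, and a short human-readable summary as
#' `<path minus extension>_summary.txt`.
#'
#' @param hits ranked gene hits from [rank_genes()] / [run_prioritization()].
#' @param path output TSV path.
#' @param burden optional burden result data.frame from [run_burden()].
#' @param known_gene_hits optional gene hits from the known-gene screen.
#' @return `path`, invisibly.
#' @export
write_report <- function(hits, path, burden = NULL, known_gene_hits = NULL) {
  tab <- .hits_to_table(hits)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  stem <- tools::file_path_sans_ext(path)
  if (!is.null(burden)) {
    utils::write.table(burden, paste0(stem, "_burden.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  lines <- c(
    "Family-based rare-variant prioritization report",
    sprintf("Ranked genes: %d", nrow(tab)),
    if (nrow(tab)) sprintf(
      "Top gene: %s (%d families, %d variants, %d affected carriers)",
      tab$gene[1], tab$n_families[1], tab$n_variants[1], tab$total_affected_carriers[1]
    ) else "No gene passed the segregation filter.",
    if (!is.null(known_gene_hits)) sprintf(
      "Known-gene screen: %d gene(s) with segregating qualifying variants",
      if (is.null(nrow(known_gene_hits))) 0L else nrow(known_gene_hits)
    )
  )
  writeLines(lines, paste0(stem, "_summary.txt"))
  invisible(path)
}
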