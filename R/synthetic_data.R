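# Fully synthetic study generator: multigenerational pedigrees, gene-dropped
# dominant causal variants with incomplete penetrance, a neutral annotated
# variant background, and a Hardy-Weinberg reference cohort. Everything is
# driven by R's seeded RNG; a seed fully determines all outputs.

#' Simulation configuration
#'
#' Defaults describe the study design the package is validated against:
#' four multiplex families, three generations, mean sibship of three, a
#' highly (but incompletely) penetrant dominant causal variant, a low
#' phenocopy rate appropriate for a common late-onset disease, and an
#' exome-scale background of two thousand annotated neutral variants.
#'
#' @param n_families number of families (>= 1).
#' @param n_generations generations per family (>= 2).
#' @param mean_sibship mean sibship size; sibships are 1 + Poisson(mean - 1).
#' @param penetrance probability an affected phenotype manifests in a carrier.
#' @param phenocopy_rate probability a non-carrier is affected anyway; must be
#'   below `penetrance` for a nondegenerate signal.
#' @param causal_gene symbol assigned to the causal variant(s).
#' @param causal_af reference-population allele frequency annotated on the
#'   causal variant (default 0.0014, ultra-rare).
#' @param causal_cadd CADD phred annotated on the causal variant.
#' @param distinct_causal_variants if TRUE each family segregates its own
#'   variant in `causal_gene`; if FALSE (default) all families share one.
#' @param n_background_variants number of neutral background variants.
#' @param background_af_shape `c(alpha, beta)` of the Beta distribution the
#'   background allele frequencies are drawn from.
#' @param cadd_mixture list with `p_damaging`, `damaging_mean`, `damaging_sd`,
#'   `benign_mean`, `benign_sd`: two-component normal mixture for background
#'   CADD scores (truncated at 0).
#' @param category_weights named probabilities over functional categories.
#' @param genotype_missing_rate per-genotype missingness in the emitted
#'   matrix.
#' @param annotation_missing_rate probability the true AF (and CADD) is
#'   written as the `.` sentinel, emulating novel variants.
#' @param p_marry probability a non-terminal-generation child marries in.
#' @param min_affected_carriers multiplex ascertainment: each family's causal
#'   gene-drop and phenotype draw are repeated until the family presents at
#'   least this many affected carriers, emulating how multiplex families are
#'   recruited into segregation studies (families are noticed *because*
#'   several relatives are affected). Set to 0 to disable ascertainment.
#' @param seed optional default seed carried in the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_families = 4L, n_generations = 3L, mean_sibship = 3,
                       penetrance = 0.95, phenocopy_rate = 0.01,
                       causal_gene = "GENE_CAUSAL", causal_af = 0.0014,
                       causal_cadd = 25, distinct_causal_variants = FALSE,
                       n_background_variants = 2000L,
                       background_af_shape = c(0.3, 30),
                       cadd_mixture = list(p_damaging = 0.25,
                                           damaging_mean = 22, damaging_sd = 4,
                                           benign_mean = 6, benign_sd = 4),
                       category_weights = c(exonic = 0.50, splicing = 0.05,
                                            intronic = 0.30, UTR5 = 0.05,
                                            UTR3 = 0.05, intergenic = 0.05),
                       genotype_missing_rate = 0.02,
                       annotation_missing_rate = 0.02,
                       p_marry = 0.8, min_affected_carriers = 3L,
                       seed = NULL) {
  probs <- c(penetrance, phenocopy_rate, genotype_missing_rate,
             annotation_missing_rate, p_marry)
  stopifnot(
    n_families >= 1, n_generations >= 2, mean_sibship > 0,
    all(probs >= 0 & probs <= 1), penetrance > phenocopy_rate,
    min_affected_carriers >= 0,
    n_background_variants >= 0, length(background_af_shape) == 2,
    all(background_af_shape > 0), abs(sum(category_weights) - 1) < 1e-8
  )
  structure(
    list(n_families = as.integer(n_families),
         n_generations = as.integer(n_generations),
         mean_sibship = mean_sibship, penetrance = penetrance,
         phenocopy_rate = phenocopy_rate, causal_gene = causal_gene,
         causal_af = causal_af, causal_cadd = causal_cadd,
         distinct_causal_variants = distinct_causal_variants,
         n_background_variants = as.integer(n_background_variants),
         background_af_shape = background_af_shape,
         cadd_mixture = cadd_mixture, category_weights = category_weights,
         genotype_missing_rate = genotype_missing_rate,
         annotation_missing_rate = annotation_missing_rate,
         p_marry = p_marry,
         min_affected_carriers = as.integer(min_affected_carriers),
         seed = seed),
    class = "sim_config"
  )
}

#' Simulate a multigenerational pedigree
#'
#' One founder couple; sibship sizes are drawn from a shifted Poisson
#' (`1 + Poisson(mean_sibship - 1)`); children in non-terminal generations
#' marry in founder spouses (at least one per couple, so the requested number
#' of generations is always realized). The output always satisfies
#' [validate_pedigree()].
#'
#' @param family_id family label (also prefixes individual ids).
#' @param n_generations,mean_sibship,p_marry see [sim_config()].
#' @return pedigree data.frame with an extra `generation` column.
#' @export
simulate_pedigree <- function(family_id, n_generations = 3L, mean_sibship = 3,
                              p_marry = 0.8) {
  stopifnot(n_generations >= 2, mean_sibship > 0)
  counter <- 0L
  rows <- list()
  new_member <- function(father, mother, sex, gen) {
    counter <<- counter + 1L
    id <- sprintf("%s_I%02d", family_id, counter)
    rows[[id]] <<- data.frame(
      family_id = family_id, individual_id = id,
      father_id = father, mother_id = mother, sex = sex,
      affection = "unknown", amd_grade = NA_integer_,
      generation = gen, stringsAsFactors = FALSE
    )
    id
  }
  f1 <- new_member(NA, NA, "male", 1L)
  m1 <- new_member(NA, NA, "female", 1L)
  couples <- list(c(f1, m1))
  for (g in seq(2L, n_generations)) {
    next_couples <- list()
    for (cp in couples) {
      k <- 1L + stats::rpois(1L, max(mean_sibship - 1, 0))
      forced <- if (g < n_generations) sample.int(k, 1L) else 0L
      for (j in seq_len(k)) {
        sex <- sample(c("male", "female"), 1L)
        child <- new_member(cp[1], cp[2], sex, g)
        if (g < n_generations && (j == forced || stats::runif(1) < p_marry)) {
          spouse <- new_member(NA, NA, if (sex == "male") "female" else "male", g)
          next_couples[[length(next_couples) + 1L]] <-
            if (sex == "male") c(child, spouse) else c(spouse, child)
        }
      }
    }
    couples <- next_couples
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped
}

.dosage_to_state <- function(dosage) {
  matrix(c("hom_ref", "het", "hom_alt")[dosage + 1L],
         nrow = nrow(dosage), dimnames = dimnames(dosage))
}

# Mendelian transmission of allele dosages down a pedigree. founder_dosages:
# integer matrix (founder id x variant). Each child draws one allele from
# each parent: a het parent transmits the alt allele with probability 1/2,
# hom_alt always, hom_ref never.
.drop_dosages <- function(ped, founder_dosages) {
  ids <- ped$individual_id
  n_var <- ncol(founder_dosages)
  dos <- matrix(0L, nrow = length(ids), ncol = n_var,
                dimnames = list(ids, colnames(founder_dosages)))
  for (id in .topological_order(ped)) {
    i <- match(id, ids)
    if (.unknown_parent(ped$father_id[i])) {
      dos[id, ] <- founder_dosages[id, ]
    } else {
      dos[id, ] <- stats::rbinom(n_var, 1L, dos[ped$father_id[i], ] / 2) +
        stats::rbinom(n_var, 1L, dos[ped$mother_id[i], ] / 2)
    }
  }
  dos
}

.founder_ids <- function(ped) {
  ped$individual_id[.unknown_parent(ped$father_id) & .unknown_parent(ped$mother_id)]
}

#' Gene-drop a single founder variant through a pedigree
#'
#' The seed carrier (a founder, heterozygous) transmits the variant allele to
#' each child independently with probability 1/2; all other founders are
#' homozygous reference.
#'
#' @param ped pedigree data.frame for one family.
#' @param founder_carrier_id id of the founder carrying the variant.
#' @return named character vector of genotype states for every member.
#' @export
gene_drop <- function(ped, founder_carrier_id) {
  if (!.is_founder(ped, founder_carrier_id)) {
    stop("seed carrier '", founder_carrier_id, "' is not a founder")
  }
  founders <- .founder_ids(ped)
  fd <- matrix(0L, nrow = length(founders), ncol = 1L,
               dimnames = list(founders, NULL))
  fd[founder_carrier_id, 1L] <- 1L
  dos <- .drop_dosages(ped, fd)
  stats::setNames(c("hom_ref", "het", "hom_alt")[dos[, 1L] + 1L], rownames(dos))
}

#' Assign affection status under incomplete penetrance
#'
#' Carriers become affected with probability `penetrance`, non-carriers with
#' probability `phenocopy_rate`, independently across members.
#'
#' @param ped pedigree data.frame.
#' @param genotypes named character vector of genotype states (carrier status
#'   is taken under the dominant model).
#' @param penetrance,phenocopy_rate probabilities.
#' @return named character vector of `"affected"` / `"unaffected"` per member.
#' @export
assign_phenotypes <- function(ped, genotypes, penetrance, phenocopy_rate) {
  stopifnot(penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1)
  ids <- ped$individual_id
  carrier <- is_carrier(genotypes[ids])
  p <- ifelse(carrier, penetrance, phenocopy_rate)
  stats::setNames(ifelse(stats::runif(length(ids)) < p, "affected", "unaffected"), ids)
}

#' Simulate the neutral annotated variant background
#'
#' Per variant: an allele frequency is drawn from the configured Beta
#' distribution; founders are genotyped under Hardy-Weinberg at that
#' frequency and the alleles gene-dropped; the functional category comes from
#' `category_weights`, the CADD score from the two-component mixture, and the
#' true AF is written to the annotation with probability
#' `1 - annotation_missing_rate` (otherwise the `.` sentinel, emulating a
#' novel variant). Genes are assigned round-robin from a synthetic symbol
#' pool that excludes the causal gene. Variants are unlinked (independent
#' drops).
#'
#' @param cfg a [sim_config()].
#' @param ped pedigree data.frame (may span several families).
#' @return list with `variants`, `genotypes` (dosage-derived state matrix,
#'   no missingness applied), `annotations`, `af` (true frequencies).
#' @export
simulate_background_variants <- function(cfg, ped) {
  n <- cfg$n_background_variants
  if (n == 0L) {
    return(list(
      variants = data.frame(chrom = character(0), pos = integer(0),
                            ref = character(0), alt = character(0),
                            stringsAsFactors = FALSE),
      genotypes = matrix(character(0), nrow = 0, ncol = nrow(ped),
                         dimnames = list(NULL, ped$individual_id)),
      annotations = data.frame(), af = numeric(0)
    ))
  }
  af <- stats::rbeta(n, cfg$background_af_shape[1], cfg$background_af_shape[2])
  founders <- .founder_ids(ped)
  fd <- matrix(0L, nrow = length(founders), ncol = n,
               dimnames = list(founders, NULL))
  for (f in founders) fd[f, ] <- stats::rbinom(n, 2L, af)
  dos <- .drop_dosages(ped, fd)
  genotypes <- t(.dosage_to_state(dos))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  variants <- data.frame(
    chrom = "1", pos = 1000000L + (seq_len(n) - 1L) * 10L,
    ref = ref, alt = unname(alt), stringsAsFactors = FALSE
  )

  n_genes <- max(1L, ceiling(n / 10))
  pool <- sprintf("GENE%04d", seq_len(n_genes))
  pool <- setdiff(pool, cfg$causal_gene)
  mix <- cfg$cadd_mixture
  damaging <- stats::runif(n) < mix$p_damaging
  cadd <- pmax(0, ifelse(damaging,
                         stats::rnorm(n, mix$damaging_mean, mix$damaging_sd),
                         stats::rnorm(n, mix$benign_mean, mix$benign_sd)))
  cadd <- round(cadd, 2)
  hide <- stats::runif(n) < cfg$annotation_missing_rate
  annotations <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt,
    gene = pool[(seq_len(n) - 1L) %% length(pool) + 1L],
    category = sample(names(cfg$category_weights), n, replace = TRUE,
                      prob = cfg$category_weights),
    cadd_phred = ifelse(hide, NA_real_, cadd),
    exac_all_af = ifelse(hide, NA_real_, round(af, 6)),
    stringsAsFactors = FALSE
  )
  annotations$key <- variant_key(annotations$chrom, annotations$pos,
                                 annotations$ref, annotations$alt)
  list(variants = variants, genotypes = genotypes,
       annotations = annotations, af = af)
}

#' Simulate a reference cohort's carrier counts under Hardy-Weinberg
#'
#' Carriers are drawn as Binomial(n, 1 - (1 - af)^2) and split into
#' heterozygous and homozygous carriers in Hardy-Weinberg proportions.
#'
#' @param n cohort size (>= 1).
#' @param af allele frequency in \[0,1\].
#' @param cohort cohort label.
#' @return a [carrier_counts()] object.
#' @export
simulate_reference_cohort <- function(n, af, cohort = "reference") {
  stopifnot(n >= 1, af >= 0, af <= 1)
  p_carrier <- 1 - (1 - af)^2
  carriers <- stats::rbinom(1L, n, p_carrier)
  n_hom <- if (carriers > 0L) {
    stats::rbinom(1L, carriers, af^2 / p_carrier)
  } else 0L
  carrier_counts(cohort, n_het = carriers - n_hom, n_hom = n_hom,
                 n_noncarrier = n - carriers)
}

#' Simulate a complete family study
#'
#' Generates pedigrees, seeds one heterozygous causal founder per family,
#' gene-drops the causal variant(s), assigns affection from true carrier
#' status under incomplete penetrance (grades 4-5 for affected, 1-3 weighted
#' toward 1 for unaffected), simulates the annotated neutral background,
#' applies genotype missingness to the emitted matrix, and draws a
#' Hardy-Weinberg reference cohort at the causal allele frequency.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; defaults to `cfg$seed`; a given seed fully
#'   determines the output.
#' @return object of class `famseg_sim`: `ped`, `vs` (a [variant_set()]),
#'   `annotations`, `reference` (a [carrier_counts()]), `truth` (causal gene,
#'   causal variant keys, per-family founder carriers and true carrier
#'   lists), `config`.
#' @export
simulate_family_study <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)

  peds <- lapply(seq_len(cfg$n_families), function(i) {
    simulate_pedigree(sprintf("FAM%d", i), cfg$n_generations,
                      cfg$mean_sibship, cfg$p_marry)
  })
  ped <- do.call(rbind, peds)

  n_causal <- if (cfg$distinct_causal_variants) cfg$n_families else 1L
  causal_variants <- data.frame(
    chrom = "1", pos = 500000L + (seq_len(n_causal) - 1L) * 10L,
    ref = "G", alt = "A", stringsAsFactors = FALSE
  )

  # one het founder carrier per family, seeded in the founding couple; the
  # gene-drop and phenotype draw are repeated until the family presents at
  # least min_affected_carriers affected carriers (multiplex ascertainment:
  # segregation studies recruit families *because* several relatives are
  # affected, so an unascertained draw in which the variant lineage dies out
  # would never have entered the study)
  founder_carriers <- character(cfg$n_families)
  causal_dos <- matrix(0L, nrow = nrow(ped), ncol = n_causal,
                       dimnames = list(ped$individual_id, NULL))
  affection <- stats::setNames(character(nrow(ped)), ped$individual_id)
  for (i in seq_len(cfg$n_families)) {
    p <- peds[[i]]
    col <- if (cfg$distinct_causal_variants) i else 1L
    fam_founders <- .founder_ids(p)
    for (attempt in seq_len(1000L)) {
      carrier_founder <- sample(p$individual_id[p$generation == 1L], 1L)
      fd <- matrix(0L, nrow = length(fam_founders), ncol = n_causal,
                   dimnames = list(fam_founders, NULL))
      fd[carrier_founder, col] <- 1L
      dos <- .drop_dosages(p, fd)
      carrier <- dos[, col] > 0L
      p_aff <- ifelse(carrier, cfg$penetrance, cfg$phenocopy_rate)
      aff <- stats::runif(nrow(p)) < p_aff
      if (sum(aff & carrier) >= cfg$min_affected_carriers) break
    }
    founder_carriers[i] <- carrier_founder
    causal_dos[p$individual_id, ] <- dos
    affection[p$individual_id] <- ifelse(aff, "affected", "unaffected")
  }
  names(founder_carriers) <- vapply(peds, function(p) p$family_id[1], character(1))
  causal_states <- t(.dosage_to_state(causal_dos))

  # per member: carrier of any causal variant (rows of causal_dos are members)
  carrier_any <- rowSums(causal_dos > 0L) >= 1L
  ped$affection <- unname(affection[ped$individual_id])
  ped$amd_grade <- ifelse(
    ped$affection == "affected",
    sample(4:5, nrow(ped), replace = TRUE),
    sample(1:3, nrow(ped), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  )

  bg <- simulate_background_variants(cfg, ped)

  variants <- rbind(causal_variants, bg$variants)
  genotypes <- rbind(causal_states, bg$genotypes)
  miss <- matrix(stats::runif(length(genotypes)) < cfg$genotype_missing_rate,
                 nrow = nrow(genotypes))
  genotypes[miss] <- "missing"
  vs <- variant_set(variants, genotypes)

  causal_keys <- vs$variants$key[seq_len(n_causal)]
  causal_annot <- data.frame(
    chrom = causal_variants$chrom, pos = causal_variants$pos,
    ref = causal_variants$ref, alt = causal_variants$alt,
    gene = cfg$causal_gene, category = "exonic",
    cadd_phred = cfg$causal_cadd, exac_all_af = cfg$causal_af,
    key = causal_keys, stringsAsFactors = FALSE
  )
  annotations <- rbind(causal_annot, bg$annotations)

  true_carriers <- lapply(peds, function(p) {
    ids <- p$individual_id
    ids[carrier_any[ids]]
  })
  names(true_carriers) <- names(founder_carriers)

  reference <- simulate_reference_cohort(60706L, cfg$causal_af)

  structure(
    list(ped = ped, vs = vs, annotations = annotations, reference = reference,
         truth = list(causal_gene = cfg$causal_gene, causal_keys = causal_keys,
                      founder_carriers = as.list(founder_carriers),
                      causal_carriers = true_carriers),
         config = cfg),
    class = "famseg_sim"
  )
}

#' @export
print.famseg_sim <- function(x, ...) {
  cat(sprintf(
    "famseg_sim: %d families, %d members, %d variants (causal gene %s)\n",
    length(unique(x$ped$family_id)), nrow(x$ped), nrow(x$vs$variants),
    x$truth$causal_gene
  ))
  invisible(x)
}

.write_vcf <- function(vs, path) {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famseg_simulator",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t")
  )
  gt <- matrix(gt_code[vs$genotypes], nrow = nrow(vs$genotypes))
  body <- vapply(seq_len(nrow(vs$variants)), function(i) {
    paste(c(vs$variants$chrom[i], vs$variants$pos[i], ".",
            vs$variants$ref[i], vs$variants$alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated study to disk as a fixture
#'
#' Emits `study.vcf`, `study.ped`, `annotations.tsv`, `carriers.tsv` and a
#' `truth.json` manifest (causal gene, causal variant keys, per-family
#' carrier lists) into `out_dir`. All files are plain text, parse back
#' through the package's readers, and are byte-identical for identical seeds.
#'
#' @param x a `famseg_sim` from [simulate_family_study()], or a
#'   [sim_config()] (simulated first, using `seed`).
#' @param out_dir output directory (created if needed).
#' @param seed seed used when `x` is a config.
#' @return named character vector of the five file paths, invisibly.
#' @export
emit_fixture <- function(x, out_dir, seed = NULL) {
  if (inherits(x, "sim_config")) x <- simulate_family_study(x, seed = seed)
  stopifnot(inherits(x, "famseg_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "study.vcf"),
    ped = file.path(out_dir, "study.ped"),
    annotations = file.path(out_dir, "annotations.tsv"),
    carriers = file.path(out_dir, "carriers.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  .write_vcf(x$vs, paths["vcf"])
  write_ped(x$ped, paths["ped"])
  write_annotation_table(x$annotations, paths["annotations"])
  write_carrier_table(x$reference, paths["carriers"])
  jsonlite::write_json(x$truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
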