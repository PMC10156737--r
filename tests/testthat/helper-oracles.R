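# Independent oracles and small pedigree builders shared across tests.
# Each oracle deliberately takes a different computational route than the
# implementation it checks.

# Two-sided Fisher p by explicit enumeration of every table compatible with
# the margins, probabilities from log-binomial coefficients (lchoose), never
# dhyper. Degenerate margins sum every table -> 1, matching the flagged path.
oracle_fisher <- function(a, b, c, d) {
  n_total <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  support <- max(0, col1 - (n_total - row1)):min(row1, col1)
  logp <- lchoose(col1, support) + lchoose(n_total - col1, row1 - support) -
    lchoose(n_total, row1)
  logp_obs <- logp[match(a, support)]
  sum(exp(logp[logp <= logp_obs + log1p(1e-12)]))
}

# Segregation rule oracle straight from the stated rule, over a labelled
# configuration: states is a character vector in
# {"carrier", "noncarrier", "missing"} describing the affected members.
oracle_segregation <- function(states, tolerance) {
  n <- sum(states != "missing")
  carriers <- sum(states == "carrier")
  n > 0 && carriers >= 1 && (n - carriers) <= tolerance
}

# Exact two-sided rank-sum p by enumerating group assignments and scoring
# each with the Mann-Whitney U statistic computed from pairwise comparisons
# (ties scored 1/2) -- not rank sums.
oracle_wilcoxon <- function(x, y) {
  v <- c(x, y)
  n <- length(x)
  total <- length(v)
  u_stat <- function(xi, yi) sum(outer(xi, yi, function(a, b) (a > b) + 0.5 * (a == b)))
  u_obs <- u_stat(x, y)
  idx <- utils::combn(total, n)
  us <- apply(idx, 2, function(i) u_stat(v[i], v[-i]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Trio-consistency checker for a dominant-state genotype matrix (rows are
# variants, columns individuals): every non-missing child/parent combination
# must admit a Mendelian allele assignment. Dosage transmission sets:
# hom_ref -> {0}, het -> {0,1}, hom_alt -> {1}.
mendelian_consistent <- function(ped, genotypes) {
  dosage_of <- function(s) {
    c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = NA_integer_)[s]
  }
  transmit <- list(0L, c(0L, 1L), 1L)
  allowed <- array(FALSE, c(3, 3, 3))
  for (f in 1:3) {
    for (m in 1:3) {
      for (d in unique(as.vector(outer(transmit[[f]], transmit[[m]], `+`)))) {
        allowed[f, m, d + 1L] <- TRUE
      }
    }
  }
  for (i in seq_len(nrow(ped))) {
    f <- ped$father_id[i]
    m <- ped$mother_id[i]
    if (is.na(f) || is.na(m)) next
    dc <- dosage_of(genotypes[, ped$individual_id[i]])
    df <- dosage_of(genotypes[, f])
    dm <- dosage_of(genotypes[, m])
    idx <- which(!(is.na(dc) | is.na(df) | is.na(dm)))
    if (length(idx) &&
        !all(allowed[cbind(df[idx] + 1L, dm[idx] + 1L, dc[idx] + 1L)])) {
      return(FALSE)
    }
  }
  TRUE
}

# A minimal valid trio pedigree.
make_trio <- function(family_id = "TRIO") {
  data.frame(
    family_id = family_id,
    individual_id = c("F", "M", "C"),
    father_id = c(NA, NA, "F"),
    mother_id = c(NA, NA, "M"),
    sex = c("male", "female", "male"),
    affection = c("unaffected", "unaffected", "affected"),
    stringsAsFactors = FALSE
  )
}

# One family: a founder couple plus n_affected affected children and
# n_unaffected unaffected children.
make_sibship <- function(n_affected, n_unaffected = 0, family_id = "FAM") {
  n <- n_affected + n_unaffected
  kids <- sprintf("C%d", seq_len(n))
  data.frame(
    family_id = family_id,
    individual_id = c("F", "M", kids),
    father_id = c(NA, NA, rep("F", n)),
    mother_id = c(NA, NA, rep("M", n)),
    sex = c("male", "female", rep(c("male", "female"), length.out = n)),
    affection = c("unaffected", "unaffected",
                  rep("affected", n_affected), rep("unaffected", n_unaffected)),
    stringsAsFactors = FALSE
  )
}

# Random annotation table for filter property tests.
random_annotations <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cats <- c("exonic", "splicing", "exonic;splicing", "intronic", "UTR5",
            "UTR3", "intergenic", "ncRNA_exonic", "Exonic", "SPLICING")
  data.frame(
    chrom = rep("1", n), pos = seq_len(n), ref = rep("A", n), alt = rep("G", n),
    gene = sprintf("G%03d", sample(50, n, replace = TRUE)),
    category = sample(cats, n, replace = TRUE),
    cadd_phred = ifelse(runif(n) < 0.1, NA_real_, runif(n, 0, 40)),
    exac_all_af = ifelse(runif(n) < 0.1, NA_real_, runif(n, 0, 0.1)),
    key = sprintf("1:%d:A:G", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

# Write a small VCF from raw field strings, for reader tests.
write_test_vcf <- function(path, samples, rows, format = "GT") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(rows, function(r) {
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", format, r$gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Knock one affected carrier of each causal variant down to hom_ref in every
# family; returns the modified sim. Used for the discordance-tolerance tests.
perturb_one_affected_per_family <- function(sim) {
  gt <- sim$vs$genotypes
  for (fam in unique(sim$ped$family_id)) {
    p <- sim$ped[sim$ped$family_id == fam, ]
    affected <- p$individual_id[p$affection == "affected"]
    for (key in sim$truth$causal_keys) {
      states <- gt[key, affected]
      carriers <- affected[states %in% c("het", "hom_alt")]
      if (length(carriers)) gt[key, carriers[1]] <- "hom_ref"
    }
  }
  sim$vs <- variant_set(
    sim$vs$variants[, setdiff(names(sim$vs$variants), "key"), drop = FALSE], gt
  )
  sim
}
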