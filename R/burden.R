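# Cohort-level carrier statistics: carrier tallies, the 2x2 case-vs-reference
# comparison (two-sided Fisher's exact test and chi-squared expected counts),
# and two-locus phenotype co-occurrence rates.

#' Construct carrier counts for a cohort
#'
#' @param cohort cohort label.
#' @param n_het,n_hom,n_noncarrier,n_missing non-negative integer tallies.
#' @return object of class `carrier_counts` with derived `carriers`
#'   (`n_het + n_hom`; each person counted once) and `genotyped`
#'   (`carriers + n_noncarrier`).
#' @export
carrier_counts <- function(cohort, n_het, n_hom, n_noncarrier, n_missing = 0L) {
  counts <- c(n_het = n_het, n_hom = n_hom, n_noncarrier = n_noncarrier,
              n_missing = n_missing)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("carrier counts must be non-negative integers")
  }
  structure(
    list(cohort = as.character(cohort), n_het = as.integer(n_het),
         n_hom = as.integer(n_hom), n_noncarrier = as.integer(n_noncarrier),
         n_missing = as.integer(n_missing),
         carriers = as.integer(n_het + n_hom),
         genotyped = as.integer(n_het + n_hom + n_noncarrier)),
    class = "carrier_counts"
  )
}

#' @export
print.carrier_counts <- function(x, ...) {
  cat(sprintf("carrier_counts [%s]: %d het + %d hom carriers, %d non-carriers, %d missing\n",
              x$cohort, x$n_het, x$n_hom, x$n_noncarrier, x$n_missing))
  invisible(x)
}

#' Tally carriers from genotype states
#'
#' Partitions samples into heterozygous carriers, homozygous carriers,
#' non-carriers and missing. Each carrier is counted once regardless of
#' zygosity (person-level carriage).
#'
#' @param genotypes character vector of genotype states.
#' @param cohort cohort label for the result.
#' @return a [carrier_counts()] object.
#' @export
count_carriers <- function(genotypes, cohort = "cohort") {
  carrier_counts(
    cohort,
    n_het = sum(genotypes == "het"),
    n_hom = sum(genotypes == "hom_alt"),
    n_noncarrier = sum(genotypes == "hom_ref"),
    n_missing = sum(genotypes == "missing")
  )
}

#' Carrier frequency of a cohort
#'
#' `(n_het + n_hom) / (n_het + n_hom + n_noncarrier)`; missing genotypes are
#' excluded from the denominator.
#'
#' @param cc a [carrier_counts()] object.
#' @return proportion in \[0,1\]; `NA` with a warning when nobody is genotyped.
#' @export
carrier_frequency <- function(cc) {
  stopifnot(inherits(cc, "carrier_counts"))
  if (cc$genotyped == 0L) {
    warning("carrier frequency undefined: no genotyped individuals in cohort '",
            cc$cohort, "'")
    return(NA_real_)
  }
  cc$carriers / cc$genotyped
}

#' Assemble the 2x2 case-vs-reference carrier table
#'
#' Rows are cohorts (case, reference); columns carrier / non-carrier.
#'
#' @param case,ref [carrier_counts()] objects with at least one genotyped
#'   individual each.
#' @return 2x2 integer matrix with dimnames.
#' @export
build_case_vs_reference <- function(case, ref) {
  stopifnot(inherits(case, "carrier_counts"), inherits(ref, "carrier_counts"))
  if (case$genotyped < 1L || ref$genotyped < 1L) {
    stop("both cohorts must have at least one genotyped individual")
  }
  matrix(
    c(case$carriers, case$n_noncarrier, ref$carriers, ref$n_noncarrier),
    nrow = 2, byrow = TRUE,
    dimnames = list(c(case$cohort, ref$cohort), c("carrier", "noncarrier"))
  )
}

.as_table2x2 <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(nrow(tab) == 2L, ncol(tab) == 2L)
    tab <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  }
  stopifnot(length(tab) == 4L, all(tab >= 0), all(tab == floor(tab)))
  as.numeric(tab)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-ordering definition (the convention of mainstream statistics
#' packages): with margins fixed, p is the sum of hypergeometric probabilities
#' of all tables at most as probable as the observed one, within a relative
#' inclusion tolerance of 1e-12 to absorb floating-point ties. Probabilities
#' are accumulated on the log scale for numerical stability, so large cohorts
#' (tens of thousands of reference exomes) are handled exactly.
#'
#' @param tab 2x2 matrix or length-4 vector `(a, b, c, d)` read row-wise:
#'   rows case/reference, columns carrier/non-carrier.
#' @return the two-sided p-value in (0, 1]. A degenerate table (a zero row or
#'   column margin) returns 1 with attribute `flag = "degenerate_margin"`.
#' @export
fisher_exact_two_sided <- function(tab) {
  t4 <- .as_table2x2(tab)
  a <- t4[1]; b <- t4[2]; cc <- t4[3]; d <- t4[4]
  n_total <- a + b + cc + d
  if (n_total < 1) stop("table total must be at least 1")
  row1 <- a + b
  col1 <- a + cc
  if (row1 == 0 || col1 == 0 || row1 == n_total || col1 == n_total) {
    return(structure(1, flag = "degenerate_margin"))
  }
  support <- max(0, col1 - (n_total - row1)):min(row1, col1)
  logp <- stats::dhyper(support, col1, n_total - col1, row1, log = TRUE)
  logp_obs <- stats::dhyper(a, col1, n_total - col1, row1, log = TRUE)
  include <- logp <= logp_obs + log1p(1e-12)
  p <- sum(exp(logp[include]))
  min(p, 1)
}

#' Chi-squared expected counts and statistic for a 2x2 table
#'
#' Expected counts under independence (`row total x column total / N`) are the
#' primary output — they show how many carriers each cohort would contribute
#' were carriage unrelated to case status; the Pearson statistic (no
#' continuity correction, df = 1) accompanies them.
#'
#' @param tab 2x2 matrix or length-4 vector `(a, b, c, d)` row-wise.
#' @return list with `expected` (2x2 matrix), `statistic`, `df = 1`, and
#'   `flag` (`"zero_margin"` when a margin is empty and the statistic is
#'   undefined, otherwise `NA`).
#' @export
chi2_expected <- function(tab) {
  t4 <- .as_table2x2(tab)
  obs <- matrix(t4, nrow = 2, byrow = TRUE)
  n_total <- sum(obs)
  stopifnot(n_total >= 1)
  expected <- outer(rowSums(obs), colSums(obs)) / n_total
  if (any(expected == 0)) {
    nz <- expected > 0
    stat <- if (any(nz)) sum((obs[nz] - expected[nz])^2 / expected[nz]) else NA_real_
    return(list(expected = expected, statistic = stat, df = 1L, flag = "zero_margin"))
  }
  list(expected = expected, statistic = sum((obs - expected)^2 / expected),
       df = 1L, flag = NA_character_)
}

.round_half_away <- function(x) trunc(x + 0.5 * sign(x))

.eval_predicate <- function(pred, individuals) {
  if (is.function(pred)) pred <- pred(individuals)
  pred <- as.logical(pred)
  if (length(pred) != nrow(individuals)) {
    stop("predicate must yield one logical per individual")
  }
  pred & !is.na(pred)
}

#' Two-locus phenotype co-occurrence rate
#'
#' Among individuals satisfying both genotype predicates (e.g. homozygous for
#' a common risk allele at one locus AND carrying a rare variant at another),
#' the fraction also satisfying an outcome predicate (e.g. any neovascular
#' involvement). The percentage is rounded to the nearest integer, half away
#' from zero. No significance test is attached — at the handful-of-patients
#' scale where this is used, a test would be meaningless.
#'
#' @param individuals data.frame, one row per individual.
#' @param predicate_a,predicate_b logical vectors over rows, or functions of
#'   `individuals` returning them (both genotype conditions).
#' @param outcome logical vector or function: the phenotype outcome.
#' @return list with `k` (outcome-positive), `n` (qualifying), `percentage`
#'   (integer, `NA` with flag `"no_qualifying_individuals"` when n = 0).
#' @export
cooccurrence_rate <- function(individuals, predicate_a, predicate_b, outcome) {
  pa <- .eval_predicate(predicate_a, individuals)
  pb <- .eval_predicate(predicate_b, individuals)
  po <- .eval_predicate(outcome, individuals)
  qualifying <- pa & pb
  n <- sum(qualifying)
  if (n == 0L) {
    return(list(k = 0L, n = 0L, percentage = NA_real_,
                flag = "no_qualifying_individuals"))
  }
  k <- sum(po & qualifying)
  list(k = as.integer(k), n = as.integer(n),
       percentage = .round_half_away(100 * k / n), flag = NA_character_)
}
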