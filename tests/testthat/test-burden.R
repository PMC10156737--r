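test_that("carrier counting partitions samples into the four tallies", {
  cc <- count_carriers(c("het", "hom_alt", "hom_ref", "missing"))
  expect_identical(c(cc$n_het, cc$n_hom, cc$n_noncarrier, cc$n_missing),
                   c(1L, 1L, 1L, 1L))
  expect_identical(cc$carriers, 2L)
  expect_identical(count_carriers(rep("hom_ref", 5))$carriers, 0L)
  cc0 <- count_carriers(character(0))
  expect_identical(cc0$genotyped, 0L)
  expect_error(carrier_counts("x", -1, 0, 0), "non-negative")
})

test_that("carrier frequency excludes missing and flags empty cohorts", {
  expect_equal(carrier_frequency(carrier_counts("r", 10, 1, 989)), 0.011)
  expect_identical(carrier_frequency(carrier_counts("r", 0, 0, 50)), 0)
  expect_identical(carrier_frequency(carrier_counts("r", 3, 2, 0)), 1)
  expect_warning(f <- carrier_frequency(carrier_counts("r", 0, 0, 0, 9)),
                 "undefined")
  expect_true(is.na(f))
})

test_that("case-vs-reference table assembly matches the cohort layout", {
  case <- carrier_counts("AMD", 3, 0, 2448)
  ref <- carrier_counts("ExAC", 85, 0, 60621)
  tab <- build_case_vs_reference(case, ref)
  expect_identical(as.vector(t(tab)), c(3L, 2448L, 85L, 60621L))
  expect_identical(case$genotyped, 2451L)
  expect_identical(rownames(tab), c("AMD", "ExAC"))

  zero <- build_case_vs_reference(carrier_counts("AMD", 0, 0, 100), ref)
  expect_identical(zero[1, 1], 0L)
  ident <- build_case_vs_reference(case, case)
  expect_equal((ident[1, 1] * ident[2, 2]) / (ident[1, 2] * ident[2, 1]), 1)
})

test_that("two-sided Fisher p matches frozen enumeration values", {
  expect_equal(as.numeric(fisher_exact_two_sided(c(3, 1, 1, 3))),
               oracle_fisher(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(as.numeric(fisher_exact_two_sided(c(3, 1, 1, 3))),
               0.485714285714286, tolerance = 1e-9)
  expect_equal(as.numeric(fisher_exact_two_sided(c(0, 5, 5, 0))), 2 / 252,
               tolerance = 1e-12)
  expect_identical(as.numeric(fisher_exact_two_sided(c(2, 2, 2, 2))), 1)
  p <- fisher_exact_two_sided(c(0, 0, 5, 5))
  expect_identical(as.numeric(p), 1)
  expect_identical(attr(p, "flag"), "degenerate_margin")
})

test_that("Fisher p agrees with fisher.test and is swap-invariant", {
  set.seed(13)
  for (i in 1:100) {
    t4 <- as.vector(stats::rmultinom(1, sample(5:60, 1), prob = runif(4, 0.05, 1)))
    p <- as.numeric(fisher_exact_two_sided(t4))
    m <- matrix(t4, nrow = 2, byrow = TRUE)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-6)
    # simultaneous row and column swap leaves p unchanged
    swapped <- m[2:1, 2:1]
    expect_equal(as.numeric(fisher_exact_two_sided(swapped)), p, tolerance = 1e-12)
  }
})

test_that("log-scale accumulation keeps cohort-scale Fisher p finite and sane", {
  # case carriers enriched ~10x over a 60k reference
  p <- as.numeric(fisher_exact_two_sided(c(50, 2401, 121, 60585)))
  expect_true(is.finite(p) && p > 0 && p < 1e-10)
  expect_equal(p, stats::fisher.test(matrix(c(50, 2401, 121, 60585), 2,
                                            byrow = TRUE))$p.value,
               tolerance = 1e-6)
})

test_that("chi-squared expected counts conserve margins; statistic matches", {
  r <- chi2_expected(c(10, 10, 10, 10))
  expect_equal(r$expected, matrix(10, 2, 2))
  expect_identical(r$statistic, 0)

  r <- chi2_expected(c(20, 0, 0, 20))
  expect_equal(r$expected, matrix(10, 2, 2))
  expect_identical(r$statistic, 40)

  expect_equal(chi2_expected(c(1, 9, 2, 18))$statistic, 0)

  set.seed(17)
  for (i in 1:50) {
    t4 <- as.vector(stats::rmultinom(1, sample(10:200, 1), prob = runif(4, 0.05, 1)))
    obs <- matrix(t4, 2, byrow = TRUE)
    r <- chi2_expected(t4)
    expect_equal(rowSums(r$expected), rowSums(obs))
    expect_equal(colSums(r$expected), colSums(obs))
    if (all(r$expected > 0)) {
      expect_equal(r$statistic,
                   suppressWarnings(stats::chisq.test(obs, correct = FALSE)$statistic[[1]]),
                   tolerance = 1e-10)
    }
  }

  z <- chi2_expected(c(0, 0, 3, 7))
  expect_identical(z$flag, "zero_margin")
})

test_that("co-occurrence rate reproduces the printed two-locus worked example", {
  # six risk-homozygous rare-variant carriers: 4 nAMD, 1 GA, 1 nAMD+GA
  patients <- data.frame(
    cfh_risk_genotype = rep("hom", 6),
    c8_carrier = rep(TRUE, 6),
    phenotype = c("nAMD", "nAMD", "nAMD", "nAMD", "GA", "nAMD+GA"),
    stringsAsFactors = FALSE
  )
  r <- cooccurrence_rate(
    patients,
    function(d) d$cfh_risk_genotype == "hom",
    function(d) d$c8_carrier,
    function(d) grepl("nAMD", d$phenotype)
  )
  expect_identical(r$k, 5L)
  expect_identical(r$n, 6L)
  expect_identical(r$percentage, 83)

  none <- cooccurrence_rate(patients, rep(TRUE, 6), rep(TRUE, 6), rep(FALSE, 6))
  expect_identical(none$percentage, 0)
  all6 <- cooccurrence_rate(patients, rep(TRUE, 6), rep(TRUE, 6), rep(TRUE, 6))
  expect_identical(all6$percentage, 100)

  empty <- cooccurrence_rate(patients, rep(FALSE, 6), rep(TRUE, 6), rep(TRUE, 6))
  expect_identical(empty$flag, "no_qualifying_individuals")
  expect_true(is.na(empty$percentage))

  # half rounds away from zero: 1/8 -> 12.5% -> 13
  eight <- data.frame(x = rep(TRUE, 8), y = c(TRUE, rep(FALSE, 7)))
  expect_identical(cooccurrence_rate(eight, eight$x, eight$x, eight$y)$percentage, 13)
})

test_that("Fisher has power on strongly enriched synthetic cohorts", {
  # case carrier probability boosted 5x over reference; median p over 200
  # seeded replicates must be clearly significant
  set.seed(2024)
  p_ref <- 0.002
  ps <- replicate(200, {
    a <- stats::rbinom(1, 2000, 5 * p_ref)
    c_ <- stats::rbinom(1, 60706, p_ref)
    as.numeric(fisher_exact_two_sided(c(a, 2000 - a, c_, 60706 - c_)))
  })
  expect_lt(stats::median(ps), 0.05)
})
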