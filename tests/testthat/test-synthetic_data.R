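test_that("simulated pedigrees are valid, reproducible, and multigenerational", {
  for (seed in 1:10) {
    set.seed(seed)
    ped <- simulate_pedigree("F1", n_generations = 3)
    expect_identical(nrow(validate_pedigree(ped)), 0L)
    expect_identical(max(ped$generation), 3L)
  }
  set.seed(123)
  a <- simulate_pedigree("F1")
  set.seed(123)
  b <- simulate_pedigree("F1")
  expect_identical(a, b)
})

test_that("gene drop is Mendelian and requires a founder seed carrier", {
  ped <- make_trio()
  expect_error(gene_drop(ped, "C"), "founder")

  # no carrier founder: every drop is hom_ref throughout
  ped_big <- simulate_pedigree("F1", 3)
  founders <- ped_big$individual_id[is.na(ped_big$father_id)]
  set.seed(1)
  g <- gene_drop(ped_big, founders[2])
  expect_true(all(g[setdiff(names(g), founders[2])] %in% c("hom_ref", "het", "hom_alt")))

  # het x hom_ref: child carrier fraction ~ 1/2
  set.seed(5)
  hits <- replicate(4000, is_carrier(gene_drop(ped, "F")[["C"]]))
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("phenotype assignment follows penetrance and phenocopy exactly at the extremes", {
  ped <- make_sibship(3, 3)
  g <- stats::setNames(c("het", "hom_ref", rep(c("het", "hom_ref"), 3)),
                       ped$individual_id)
  set.seed(2)
  aff <- assign_phenotypes(ped, g, penetrance = 1, phenocopy_rate = 0)
  expect_identical(unname(aff == "affected"), unname(is_carrier(g[names(aff)])))
  aff0 <- assign_phenotypes(ped, g, penetrance = 0, phenocopy_rate = 0)
  expect_true(all(aff0 == "unaffected"))

  set.seed(3)
  carrier_ped <- make_sibship(1)
  frac <- mean(replicate(4000, {
    assign_phenotypes(carrier_ped,
                      stats::setNames(rep("het", 3), carrier_ped$individual_id),
                      0.9, 0)[["C1"]] == "affected"
  }))
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 4000))
})

test_that("background variants track their Beta allele-frequency model", {
  cfg <- sim_config(n_background_variants = 0L)
  ped <- make_trio()
  empty <- simulate_background_variants(cfg, ped)
  expect_identical(nrow(empty$variants), 0L)

  cfg <- sim_config(n_background_variants = 3000L, background_af_shape = c(2, 48))
  set.seed(9)
  ped2 <- simulate_pedigree("F1", 2)
  bg <- simulate_background_variants(cfg, ped2)
  founders <- ped2$individual_id[is.na(ped2$father_id)]
  dosage <- (bg$genotypes[, founders] == "het") +
    2 * (bg$genotypes[, founders] == "hom_alt")
  mean_af <- mean(dosage) / 2
  beta_mean <- 2 / 50
  se <- sqrt(beta_mean * (1 - beta_mean) / (2 * length(founders) * 3000))
  # allow for Beta sampling variance on top of the binomial term
  expect_lt(abs(mean_af - beta_mean), 6 * se)
  expect_false(cfg$causal_gene %in% bg$annotations$gene)
})

test_that("reference cohort carrier draws follow Hardy-Weinberg expectations", {
  set.seed(4)
  expect_identical(simulate_reference_cohort(1000, 0)$carriers, 0L)
  all_hom <- simulate_reference_cohort(1000, 1)
  expect_identical(all_hom$n_hom, 1000L)
  expect_identical(all_hom$n_noncarrier, 0L)

  n <- 60706
  af <- 0.001
  expected <- n * (1 - (1 - af)^2) # ~121.3
  draws <- replicate(50, simulate_reference_cohort(n, af)$carriers)
  se <- sqrt(n * (1 - (1 - af)^2) * (1 - af)^2)
  expect_true(all(abs(draws - expected) < 5 * se))
  expect_lt(abs(mean(draws) - expected), 4 * se / sqrt(50))
})

test_that("a fully penetrant causal variant segregates in every family at tolerance 0", {
  cfg <- sim_config(penetrance = 1, phenocopy_rate = 0,
                    n_background_variants = 0L, genotype_missing_rate = 0)
  for (seed in 1:5) {
    sim <- simulate_family_study(cfg, seed = seed)
    seg <- segregate_variants(sim$vs, sim$ped, tolerance = 0)
    seg_causal <- seg[seg$key %in% sim$truth$causal_keys, ]
    with_gt <- seg_causal[seg_causal$n_affected_genotyped > 0, ]
    expect_true(all(with_gt$passes))
  }
})

test_that("simulated genotype matrices are Mendelian-consistent", {
  for (seed in 1:3) {
    sim <- simulate_family_study(sim_config(n_background_variants = 200L),
                                 seed = seed)
    expect_true(mendelian_consistent(sim$ped, sim$vs$genotypes))
  }
})

test_that("identical seeds produce byte-identical fixtures", {
  cfg <- sim_config(n_background_variants = 100L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_fixture(cfg, d1, seed = 77)
  p2 <- emit_fixture(cfg, d2, seed = 77)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), info = f)
  }
  # truth manifest marks exactly the causal variants with the causal gene
  annot <- read_annotation_table(p1["annotations"])
  truth <- jsonlite::read_json(p1["truth"], simplifyVector = TRUE)
  expect_setequal(annot$key[annot$gene == truth$causal_gene], truth$causal_keys)
})

test_that("distinct causal variants per family collapse into one gene hit", {
  cfg <- sim_config(distinct_causal_variants = TRUE,
                    n_background_variants = 100L)
  sim <- simulate_family_study(cfg, seed = 15)
  expect_identical(length(sim$truth$causal_keys), 4L)
  res <- run_prioritization(sim)
  top <- res$hits[1, ]
  expect_identical(top$gene, cfg$causal_gene)
  expect_identical(top$n_families, 4L)
  expect_gte(top$n_variants, 2L)
})
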