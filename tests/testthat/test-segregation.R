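test_that("dominant carrier status covers the three genotype states", {
  expect_identical(is_carrier(c("het", "hom_alt", "hom_ref", "missing")),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("family segregation applies the all-but-tolerance rule", {
  ped <- make_sibship(3)
  gt <- function(...) c(F = "hom_ref", M = "hom_ref", ...)

  r <- test_family_segregation(ped, gt(C1 = "het", C2 = "het", C3 = "het"))
  expect_true(r$passes)
  expect_identical(r$n_affected_carriers, 3L)

  r <- test_family_segregation(ped, gt(C1 = "het", C2 = "het", C3 = "hom_ref"))
  expect_true(r$passes) # one discordant tolerated

  r <- test_family_segregation(ped, gt(C1 = "het", C2 = "hom_ref", C3 = "hom_ref"))
  expect_false(r$passes) # two discordant

  # hom_alt counts as a carrier exactly once
  r <- test_family_segregation(ped, gt(C1 = "hom_alt", C2 = "het", C3 = "het"))
  expect_true(r$passes)
  expect_identical(r$n_affected_carriers, 3L)

  # single affected non-carrier must not pass on tolerance alone
  ped1 <- make_sibship(1)
  r <- test_family_segregation(ped1, c(F = "hom_ref", M = "hom_ref", C1 = "hom_ref"))
  expect_false(r$passes)
})

test_that("missing genotypes shrink the denominator instead of discording", {
  ped <- make_sibship(3)
  gt <- c(F = "hom_ref", M = "hom_ref", C1 = "het", C2 = "het", C3 = "missing")
  r <- test_family_segregation(ped, gt, tolerance = 0)
  expect_true(r$passes)
  expect_identical(r$n_affected_genotyped, 2L)
  expect_identical(r$n_affected_missing, 1L)

  # an affected with no genotype entry at all counts the same way
  r2 <- test_family_segregation(ped, gt[names(gt) != "C3"], tolerance = 0)
  expect_identical(r2$n_affected_missing, 1L)
  expect_true(r2$passes)
})

test_that("a family with no genotyped affected is flagged, not an error", {
  ped <- make_sibship(2)
  r <- test_family_segregation(ped, c(F = "het", M = "hom_ref",
                                      C1 = "missing", C2 = "missing"))
  expect_false(r$passes)
  expect_identical(r$flag, "no_genotyped_affected")
})

test_that("strict mode vetoes variants carried by genotyped unaffecteds", {
  ped <- make_sibship(2, 1)
  gt <- c(F = "hom_ref", M = "hom_ref", C1 = "het", C2 = "het", C3 = "het")
  expect_true(test_family_segregation(ped, gt)$passes)
  expect_false(test_family_segregation(ped, gt,
                                       require_absent_in_unaffected = TRUE)$passes)
})

test_that("segregation matches the exhaustive rule oracle up to 6 affecteds", {
  ped <- make_sibship(6)
  states <- c("carrier", "noncarrier", "missing")
  to_gt <- c(carrier = "het", noncarrier = "hom_ref", missing = "missing")
  grids <- expand.grid(rep(list(states), 4), stringsAsFactors = FALSE)
  for (tol in 0:1) {
    for (i in seq_len(nrow(grids))) {
      cfg <- unlist(grids[i, ])
      gt <- c(F = "hom_ref", M = "hom_ref",
              stats::setNames(to_gt[cfg], sprintf("C%d", 1:4)))
      r <- test_family_segregation(ped[ped$individual_id != "C5" &
                                         ped$individual_id != "C6", ], gt,
                                   tolerance = tol)
      expect_identical(r$passes, oracle_segregation(cfg, tol),
                       info = paste(tol, paste(cfg, collapse = ",")))
    }
  }
})

test_that("tolerance is monotone: passing at t implies passing at t+1", {
  ped <- make_sibship(5)
  set.seed(7)
  for (i in 1:100) {
    gt <- c(F = "hom_ref", M = "hom_ref",
            stats::setNames(sample(c("het", "hom_ref", "hom_alt", "missing"),
                                   5, replace = TRUE), sprintf("C%d", 1:5)))
    for (t in 0:3) {
      if (test_family_segregation(ped, gt, tolerance = t)$passes) {
        expect_true(test_family_segregation(ped, gt, tolerance = t + 1)$passes)
      }
    }
  }
})

test_that("vectorized segregation agrees with the single-variant test", {
  sim <- simulate_family_study(sim_config(n_background_variants = 50L), seed = 21)
  seg <- segregate_variants(sim$vs, sim$ped)
  for (i in sample(nrow(seg), 40)) {
    row <- seg[i, ]
    single <- test_family_segregation(sim$ped, sim$vs$genotypes[row$key, ],
                                      family_id = row$family_id)
    expect_identical(single$passes, row$passes)
    expect_identical(single$n_affected_carriers, row$n_affected_carriers)
    expect_identical(single$n_affected_genotyped, row$n_affected_genotyped)
  }
})

test_that("gene collapsing unions families and conserves variant evidence", {
  annot <- data.frame(gene = c("C8B", "C8B", "C8A"),
                      key = c("v1", "v2", "v3"), stringsAsFactors = FALSE)
  seg <- data.frame(
    family_id = c("F1", "F2", "F3", "F2", "F1", "F1"),
    key = c("v1", "v1", "v1", "v2", "v3", "v1"),
    n_affected_carriers = c(3L, 2L, 4L, 2L, 1L, 3L),
    passes = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  hits <- collapse_to_genes(seg, annot)
  c8b <- hits[hits$gene == "C8B", ]
  # one variant passing in three families plus a second variant in one of them
  expect_identical(c8b$n_families, 3L)
  expect_identical(c8b$n_variants, 2L)
  expect_setequal(c8b$families[[1]], c("F1", "F2", "F3"))
  c8a <- hits[hits$gene == "C8A", ]
  expect_identical(c8a$n_families, 1L)

  # evidence conservation: total distinct (gene, variant) passing pairs
  passing <- seg[seg$passes, ]
  expect_identical(sum(hits$n_variants),
                   nrow(unique(passing[c("key")])))

  # unannotated passing variants surface under UNANNOTATED
  seg2 <- seg; seg2$key[1] <- "v_unknown"
  expect_message(hits2 <- collapse_to_genes(seg2, annot), "UNANNOTATED")
  expect_true("UNANNOTATED" %in% hits2$gene)
})

test_that("gene ranking is deterministic and shuffle-invariant", {
  hits <- data.frame(
    gene = c("C8A", "C8B", "AAA", "BBB"),
    n_families = c(1L, 3L, 1L, 1L),
    families = I(list("F1", c("F1", "F2", "F3"), "F2", "F3")),
    n_variants = c(1L, 1L, 1L, 1L),
    variants = I(list("v3", "v1", "v4", "v5")),
    total_affected_carriers = c(4L, 9L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  ranked <- rank_genes(hits)
  expect_identical(ranked$gene, c("C8B", "C8A", "AAA", "BBB"))
  set.seed(1)
  for (i in 1:10) {
    shuffled <- hits[sample(nrow(hits)), ]
    expect_identical(rank_genes(shuffled)$gene, ranked$gene)
  }
  expect_identical(nrow(rank_genes(hits[0, ])), 0L)
})
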