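spec2 <- function() {
  list(
    list(locus_id = "d1", groups_x = c("A", "B"), scope = c("A", "B", "C"),
         allele_x = "A", allele_y = "G"),
    list(locus_id = "d2", groups_x = "B", scope = c("B", "C"),
         allele_x = "T", allele_y = "C")
  )
}

test_that("simulated matrices are reproducible and carry planted structure", {
  gs <- c(A = 5, B = 4, C = 6)
  s1 <- simulate_genotype_matrix(gs, spec2(), n_background_loci = 20,
                                 missing_rate = 0, seed = 99)
  s2 <- simulate_genotype_matrix(gs, spec2(), n_background_loci = 20,
                                 missing_rate = 0, seed = 99)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$samples), 15)
  expect_equal(nrow(s1$loci), 22)

  # planted fixed differences hold exactly without noise
  d1 <- dplyr::inner_join(
    s1$genotypes[s1$genotypes$locus_id == "d1", ], s1$samples, "sample_id"
  )
  expect_true(all(d1$call[d1$group %in% c("A", "B")] == "A/A"))
  expect_true(all(d1$call[d1$group == "C"] == "G/G"))
  # scope-restricted locus: out-of-scope group gets all three states
  d2 <- dplyr::inner_join(
    s1$genotypes[s1$genotypes$locus_id == "d2", ], s1$samples, "sample_id"
  )
  expect_true(all(d2$call[d2$group == "B"] == "T/T"))
  expect_true(all(d2$call[d2$group == "C"] == "C/C"))
  expect_true(all(d2$call[d2$group == "A"] %in% c("T/T", "C/T", "C/C")))

  # truth records the allele-space state of every diagnostic call
  expect_setequal(unique(s1$truth$call_truth$marker), c("d1", "d2"))
  expect_true(all(s1$truth$call_truth$state %in% c("XX", "XY", "YY")))
})

test_that("invalid bipartitions and rates are rejected", {
  bad <- list(list(groups_x = "A", scope = "A", allele_x = "A",
                   allele_y = "G"))
  expect_error(simulate_genotype_matrix(c(A = 2, B = 2), bad),
               "proper split")
  bad2 <- list(list(groups_x = "Z", scope = c("A", "Z"), allele_x = "A",
                    allele_y = "G"))
  expect_error(simulate_genotype_matrix(c(A = 2, B = 2), bad2),
               "absent|subset")
  expect_error(simulate_genotype_matrix(c(A = 2), list(), missing_rate = 1),
               "missing_rate")
  expect_error(simulate_genotype_matrix(2, list()), "named")
})

test_that("missingness converges to its nominal rate", {
  sim <- simulate_genotype_matrix(c(A = 40, B = 40), list(),
                                  n_background_loci = 50,
                                  missing_rate = 0.1, seed = 3)
  n <- nrow(sim$genotypes)
  frac <- mean(geno_is_missing(sim$genotypes$call))
  tol <- 3 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), tol)
})

test_that("allelic dropout behaves at the extremes and at binomial scale", {
  het <- geno_tbl(matrix("A/G", 100, 100,
                         dimnames = list(sprintf("s%d", 1:100),
                                         sprintf("L%d", 1:100))))
  expect_identical(apply_allelic_dropout(het, 0, seed = 1), het)
  all_dropped <- apply_allelic_dropout(het, 1, seed = 1)
  expect_false(any(geno_is_het(all_dropped$call)))
  expect_true(all(all_dropped$call %in% c("A/A", "G/G")))

  # dropout_rate 0.2 over 10,000 het calls: within 3 binomial SD
  d <- apply_allelic_dropout(het, 0.2, seed = 7)
  frac <- mean(!geno_is_het(d$call))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  # homozygous and missing calls are never touched
  mixed <- geno_tbl(matrix(c("A/A", "./.", "A/G", "G/G"), 2, 2,
                           dimnames = list(c("a", "b"), c("L1", "L2"))))
  out <- apply_allelic_dropout(mixed, 1, seed = 1)
  untouched <- which(!geno_is_het(mixed$call))
  expect_equal(out$call[untouched], mixed$call[untouched])
})

test_that("simulated plates honour geometry, NTC count and determinism", {
  panel <- load_canonical_panel()
  truth <- toy_truth(30, seed = 5)
  p1 <- simulate_plate(panel, truth, noise_sd = 0, n_ntc = 3, seed = 2)
  p2 <- simulate_plate(panel, truth, noise_sd = 0, n_ntc = 3, seed = 2)
  expect_identical(p1$wells, p2$wells)
  expect_equal(sum(p1$wells$role == "NTC"), 3)
  expect_equal(sum(p1$wells$role == "sample"), 30)

  # noise-free wells sit exactly on their cluster rays
  w <- normalize_wells(p1$wells)
  pol <- polar_transform(w$fam, w$hex)
  smp <- which(w$role == "sample")
  want <- c(XX = 10, XY = 45, YY = 80)[p1$truth$state]
  expect_equal(pol$theta[smp], unname(want), tolerance = 1e-9)

  # unknown marker in truth is rejected
  bad <- tibble::tibble(sample_id = "s", marker = "NOPE", state = "XX")
  expect_error(simulate_plate(panel, bad), "absent from panel")
})
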