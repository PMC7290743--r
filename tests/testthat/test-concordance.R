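test_that("confusion matrices count pairs exactly and demand references", {
  a <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                      assignment = c("G1", "G2", "unresolved"))
  r <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                      ref_group = c("G1", "G1", "G2"))
  cm <- confusion_matrix(a, r)
  expect_equal(cm$total, 3)
  expect_equal(cm$matched, 1)
  expect_equal(cm$table["G1", "G2"], 1)
  expect_equal(cm$table["G2", "unresolved"], 1)
  expect_error(confusion_matrix(a, r[1:2, ]), "without reference")

  # identical label lists give a diagonal matrix
  ident <- confusion_matrix(
    tibble::tibble(sample_id = r$sample_id, assignment = r$ref_group), r
  )
  expect_equal(ident$matched, ident$total)

  # random labels: brute-force pair counting oracle
  withr::with_seed(5, {
    n <- 200
    ref <- sample(LETTERS[1:4], n, TRUE)
    asg <- sample(c(LETTERS[1:4], "unresolved"), n, TRUE)
    cm2 <- confusion_matrix(
      tibble::tibble(sample_id = as.character(1:n), assignment = asg),
      tibble::tibble(sample_id = as.character(1:n), ref_group = ref)
    )
    for (i in LETTERS[1:4]) {
      for (j in c(LETTERS[1:4], "unresolved")) {
        expect_equal(cm2$table[i, j], sum(ref == i & asg == j))
      }
    }
    # margins: row sums = per-reference counts, column sums = per-assignment
    expect_equal(rowSums(cm2$table), table(ref)[rownames(cm2$table)],
                 ignore_attr = TRUE)
    expect_equal(colSums(cm2$table)[unique(asg)],
                 table(asg)[unique(asg)], ignore_attr = TRUE)
    # invariant under group-order permutation
    perm <- sample(n)
    cm3 <- confusion_matrix(
      tibble::tibble(sample_id = as.character(1:n)[perm],
                     assignment = asg[perm]),
      tibble::tibble(sample_id = as.character(1:n), ref_group = ref)
    )
    expect_equal(overall_concordance(cm3), overall_concordance(cm2))
  })
})

test_that("overall concordance reproduces published roundings", {
  m <- diag(c(31, 41, 4, 41, 26, 8))
  m <- cbind(m, 0)
  m[1, 2] <- 1
  expect_equal(sum(diag(m[, 1:6])), 151)
  expect_equal(sum(m), 152)
  expect_equal(overall_concordance(m), 99.3)
  expect_equal(overall_concordance(diag(c(5, 5))), 100)
  expect_equal(overall_concordance(matrix(c(714, 7, 0, 0), 2)), 99.0)
  expect_error(overall_concordance(matrix(0, 2, 2)), "empty")
})

test_that("per-marker accuracy matches hand computation on sample data", {
  panel <- load_canonical_panel()
  # reconstruct the ECA/WA split marker cohort: 41 WA all G:G,
  # 32 ECA with 31 A:A and one G:G miscall from Kenya
  ref <- tibble::tibble(
    sample_id = sprintf("x%02d", 1:73),
    ref_group = rep(c("SSA-WA", "SSA-ECA"), c(41, 32)),
    country = c(rep("Ghana", 41), rep("Uganda", 31), "Kenya")
  )
  calls <- tibble::tibble(
    sample_id = ref$sample_id, marker = "BTS22-762",
    state = c(rep("G:G", 41), rep("A:A", 31), "G:G")
  )
  acc <- per_marker_accuracy(calls, ref, panel)
  expect_equal(acc$accuracy_pct[acc$class == "G:G"], 100.0)
  expect_equal(acc$accuracy_pct[acc$class == "A:A"], 96.9)
  expect_equal(acc$accuracy_pct[acc$class == "pooled"], 98.6)
  expect_equal(acc$mismatch_origin[acc$class == "A:A"], "Kenya")
  # heterozygous calls count as mismatches against a homozygous reference
  calls2 <- dplyr::mutate(calls, state = replace(state, 1, "A:G"))
  acc2 <- per_marker_accuracy(calls2, ref, panel)
  expect_equal(acc2$n_match[acc2$class == "G:G"], 40)

  # samples outside marker scope are excluded with a warning
  ref3 <- dplyr::mutate(ref, ref_group = replace(ref_group, 1, "SSA2"))
  expect_warning(per_marker_accuracy(calls, ref3, panel), "outside marker scope")

  # explicit exclusions (e.g. missing reference alleles) drop rows
  acc4 <- per_marker_accuracy(
    calls, ref, panel,
    exclude = tibble::tibble(sample_id = c("x01", "x02"),
                             marker = "BTS22-762")
  )
  expect_equal(acc4$n[acc4$class == "G:G"], 39)
})

test_that("count-table accuracies agree with the sample-level route", {
  counts <- load_validation_counts()$marker_classes
  acc <- marker_accuracy_from_counts(counts)
  # internal consistency: accuracy + mismatch = 100 on every row
  expect_true(all(abs(acc$accuracy_pct + acc$mismatch_pct - 100) < 0.051))
  # cross-check one marker against the sample-level function
  panel <- load_canonical_panel()
  ref <- tibble::tibble(sample_id = sprintf("y%02d", 1:73),
                        ref_group = rep(c("SSA-WA", "SSA-ECA"), c(41, 32)))
  calls <- tibble::tibble(sample_id = ref$sample_id, marker = "BTS22-762",
                          state = c(rep("G:G", 41), rep("A:A", 31), "G:G"))
  sample_level <- per_marker_accuracy(calls, ref, panel)
  count_level <- acc[acc$marker == "BTS22-762", ]
  expect_equal(
    sort(sample_level$accuracy_pct),
    sort(count_level$accuracy_pct)
  )
})

test_that("legacy-barcode mismatch counting follows the expectation map", {
  # perfectly concordant labels
  ref <- tibble::tibble(sample_id = c("a", "b"),
                        ref_group = c("SSA-ECA", "SSA2"),
                        coi = c("SSA1-SG1", "SSA2"))
  s <- coi_mismatch_summary(ref)
  expect_equal(s$count, 0)
  expect_equal(s$percent, 0)

  # brute-force oracle on random labels
  map <- c(L1 = "G1", L2 = "G2", L3 = NA)
  withr::with_seed(9, {
    ref2 <- tibble::tibble(
      sample_id = as.character(1:300),
      ref_group = sample(c("G1", "G2"), 300, TRUE),
      coi = sample(c("L1", "L2", "L3", "L9"), 300, TRUE)
    )
    s2 <- coi_mismatch_summary(ref2, map)
    implied <- map[ref2$coi]
    want_mis <- sum(
      (ref2$coi %in% names(map) & is.na(implied)) |
        (!is.na(implied) & implied != ref2$ref_group)
    )
    expect_equal(s2$count, want_mis)
    expect_equal(s2$n_unmappable, sum(ref2$coi == "L9"))
    expect_equal(sum(s2$breakdown$n), 300)
  })

  expect_error(
    coi_mismatch_summary(dplyr::mutate(ref, coi = NA_character_)),
    "both"
  )
})
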