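panel <- load_canonical_panel()

test_that("the packaged panel matches its published description", {
  expect_equal(nrow(panel$markers), 7)
  expect_setequal(panel$groups,
                  c("SSA-ECA", "SSA-WA", "SSA-ESA", "SSA-CA", "SSA2", "SSA4"))
  expect_true(all(panel$markers$allele_x %in% c("A", "C", "G", "T")))
  expect_true(all(panel$markers$allele_y %in% c("A", "C", "G", "T")))
  # partitions are disjoint, nonempty and union to scope
  for (i in seq_len(nrow(panel$markers))) {
    gx <- panel$markers$groups_x[[i]]
    gy <- panel$markers$groups_y[[i]]
    sc <- panel$markers$scope[[i]]
    expect_gt(length(gx), 0)
    expect_gt(length(gy), 0)
    expect_length(intersect(gx, gy), 0)
    expect_setequal(c(gx, gy), sc)
  }
  # the SSA2 marker isolates SSA2 from all five other haplogroups
  m <- panel$markers[panel$markers$marker_id == "BTS55-473", ]
  expect_equal(m$groups_x[[1]], "SSA2")
  expect_length(m$groups_y[[1]], 5)
})

test_that("published worked examples classify as published", {
  expect_equal(
    classify_sample(c("BTS99-319" = "A:A", "BTS22-762" = "A:A"),
                    panel)$assignment,
    "SSA-ECA"
  )
  expect_equal(
    classify_sample(c("BTS99-319" = "G:G", "BTS141" = "T:T",
                      "BTS55-473" = "T:T"), panel)$assignment,
    "SSA2"
  )
  res <- classify_sample(
    c("BTS99-319" = "G:G", "BTS141" = "C:C", "BTS613" = "G:G",
      "BTS46-203" = "A:G", "BTS1161" = "C:C"), panel
  )
  expect_equal(res$assignment, "SSA-ESA")
  expect_match(res$flags, "used_fallback")

  # total non-amplification is a species gate, not a genotype
  all_nc <- setNames(rep("no_call", 7), panel$markers$marker_id)
  expect_equal(classify_sample(all_nc, panel)$assignment, "non-target")
  expect_equal(classify_sample(c("BTS99-319" = "A:A"), panel,
                               amplified = FALSE)$assignment, "non-target")
})

test_that("ambiguity without fallback, and discordant confirmation, unresolve", {
  # het at the root (no fallback there)
  r1 <- classify_sample(c("BTS99-319" = "A:G", "BTS22-762" = "A:A"), panel)
  expect_equal(r1$assignment, "unresolved")
  expect_match(r1$flags, "inconsistent_profile")

  # missing decisive marker
  r2 <- classify_sample(c("BTS99-319" = "A:A"), panel, amplified = TRUE)
  expect_equal(r2$assignment, "unresolved")
  expect_match(r2$flags, "missing_marker")

  # BTS613 contradicting BTS141 is flagged, not silently resolved
  r3 <- classify_sample(
    c("BTS99-319" = "G:G", "BTS141" = "C:C", "BTS613" = "A:A"), panel
  )
  expect_equal(r3$assignment, "unresolved")
  expect_match(r3$flags, "confirmation_discordant")

  # fallback used when the primary is missing, with agreement
  r4 <- classify_sample(
    c("BTS99-319" = "G:G", "BTS141" = "no_call", "BTS613" = "G:G",
      "BTS46-203" = "A:A"), panel
  )
  expect_equal(r4$assignment, "SSA-ESA")
  expect_match(r4$flags, "used_fallback")
})

test_that("no named assignment ever stems from a decisive no-call", {
  # property: random partial call sets never reach a leaf through a
  # missing decisive marker without a fallback answering for it
  withr::with_seed(77, {
    for (i in 1:50) {
      states <- sample(c("XX", "XY", "YY", "no_call"), 7, replace = TRUE)
      calls <- setNames(states, panel$markers$marker_id)
      res <- classify_sample(calls, panel)
      if (res$assignment %in% panel$groups) {
        consulted <- kaspdx:::path_ids(strsplit(res$path, " > ")[[1]])
        expect_true(all(calls[consulted] != "no_call"))
      }
    }
  })
})

test_that("cohort classification preserves order, counts and errors", {
  sets <- tibble::tibble(
    sample_id = c("b", "b", "a"),
    marker = c("BTS99-319", "BTS22-762", "BTS99-319"),
    state = c("A:A", "G:G", "G:G")
  )
  res <- classify_cohort(sets, panel)
  expect_equal(res$sample_id, c("b", "a"))
  expect_equal(res$assignment[1], "SSA-WA")
  expect_equal(res$assignment[2], "unresolved")
  g <- glance(res)
  expect_equal(g$n_total, 2)
  expect_equal(g$unresolved, 1)

  expect_error(classify_cohort(sets[c(1, 1), ], panel), "duplicate")
  empty <- classify_cohort(sets[0, ], panel)
  expect_equal(nrow(empty), 0)
  expect_error(classify_sample(character(), panel), "empty call set")
})

test_that("perfect calls on a simulated cohort reproduce the truth exactly", {
  gs <- setNames(rep(30, 6),
                 c("SSA-ECA", "SSA-WA", "SSA-ESA", "SSA-CA", "SSA2", "SSA4"))
  sim <- simulate_genotype_matrix(gs, diagnostic_spec_from_panel(panel),
                                  n_background_loci = 0, missing_rate = 0,
                                  seed = 17)
  callsets <- dplyr::select(sim$truth$call_truth, sample_id, marker, state)
  res <- classify_cohort(callsets, panel)
  truth <- setNames(sim$samples$group, sim$samples$sample_id)
  expect_equal(res$assignment, unname(truth[res$sample_id]))
})
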