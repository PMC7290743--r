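# Independent oracles and fixture builders, kept deliberately dumb
# (base-R loops and direct tallies) so they share no code with the
# package implementation they check.

# long genotype tibble from a character matrix (samples x loci)
geno_tbl <- function(mat) {
  tibble::tibble(
    sample_id = rep(rownames(mat), times = ncol(mat)),
    locus_id = rep(colnames(mat), each = nrow(mat)),
    call = as.vector(mat)
  )
}

# brute-force diagnostic-locus search: per locus, per group, tally all
# calls directly; a locus qualifies when every scope group is 100%
# homozygous-fixed (call rate >= min_call_rate) and both alleles occur
brute_diagnostic <- function(genotypes, labels, loci, scope,
                             min_call_rate = 0.8) {
  grp <- setNames(labels$group, labels$sample_id)
  hits <- character()
  sides <- list()
  for (lid in unique(genotypes$locus_id)) {
    sub <- genotypes[genotypes$locus_id == lid, ]
    fixed <- character()
    ok <- TRUE
    for (g in scope) {
      calls <- sub$call[grp[sub$sample_id] == g]
      nm <- calls[calls != "./." & !is.na(calls)]
      if (length(calls) == 0 || length(nm) / length(calls) < min_call_rate) {
        ok <- FALSE; break
      }
      parts <- unique(unlist(strsplit(nm, "/", fixed = TRUE)))
      if (length(nm) == 0 || length(parts) != 1) { ok <- FALSE; break }
      fixed[g] <- parts
    }
    if (!ok || length(unique(fixed)) != 2) next
    meta <- loci[loci$locus_id == lid, ]
    if (!setequal(unique(fixed), c(meta$ref, meta$alt))) next
    hits <- c(hits, lid)
    sides[[lid]] <- sort(names(fixed)[fixed == meta$ref])
  }
  list(loci = sort(hits), sides = sides)
}

# random labelled genotype matrix, optionally with planted fixed
# differences, for property tests
random_matrix <- function(seed) {
  withr::with_seed(seed, {
    n_groups <- sample(2:4, 1)
    groups <- LETTERS[seq_len(n_groups)]
    n <- sample(6:20, 1)
    labels <- tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      group = sample(groups, n, replace = TRUE)
    )
    # guarantee every group has at least one sample
    labels$group[seq_len(n_groups)] <- groups
    n_loci <- sample(10:50, 1)
    loci <- tibble::tibble(
      locus_id = sprintf("L%03d", seq_len(n_loci)),
      contig = sprintf("c%03d", seq_len(n_loci)),
      pos = sample.int(1e6, n_loci),
      ref = "A", alt = "G"
    )
    mat <- matrix("", nrow = n, ncol = n_loci,
                  dimnames = list(labels$sample_id, loci$locus_id))
    for (j in seq_len(n_loci)) {
      style <- sample(c("random", "planted", "near_fixed"), 1,
                      prob = c(0.5, 0.3, 0.2))
      if (style == "planted") {
        side <- sample(groups, sample(seq_len(n_groups - 1), 1))
        mat[, j] <- ifelse(labels$group %in% side, "A/A", "G/G")
      } else if (style == "near_fixed") {
        side <- sample(groups, 1)
        mat[, j] <- ifelse(labels$group %in% side, "A/A", "G/G")
        mat[sample.int(n, 1), j] <- "A/G"
      } else {
        mat[, j] <- sample(c("A/A", "A/G", "G/G"), n, replace = TRUE)
      }
      miss <- runif(n) < 0.05
      mat[miss, j] <- "./."
    }
    list(genotypes = geno_tbl(mat), labels = labels, loci = loci,
         groups = groups)
  })
}

# published marker genotype patterns (columns in haplogroup order
# SSA-ECA, SSA-WA, SSA-ESA, SSA-CA, SSA2, SSA4; NA = out of scope)
canonical_patterns <- function() {
  tibble::tribble(
    ~marker, ~`SSA-ECA`, ~`SSA-WA`, ~`SSA-ESA`, ~`SSA-CA`, ~SSA2, ~SSA4,
    "BTS99-319", "A:A", "A:A", "G:G", "G:G", "G:G", "G:G",
    "BTS22-762", "A:A", "G:G", NA, NA, NA, NA,
    "BTS141", "C:C", "C:C", "C:C", "C:C", "T:T", "T:T",
    "BTS55-473", "C:C", "C:C", "C:C", "C:C", "T:T", "C:C",
    "BTS613", "A:A", "A:A", "G:G", "G:G", "A:A", "A:A",
    "BTS46-203", NA, NA, "A:A", "G:G", NA, NA,
    "BTS1161", NA, NA, "C:C", "A:A", NA, NA
  )
}

# the canonical marker call set of one haplogroup, from the published
# patterns (independent of the packaged panel JSON)
canonical_profile <- function(group) {
  pat <- canonical_patterns()
  calls <- setNames(pat[[group]], pat$marker)
  calls[!is.na(calls)]
}

# deterministic per-well truth table for plate simulation tests
toy_truth <- function(n, states = c("XX", "XY", "YY"), marker = "BTS99-319",
                      seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("w%04d", seq_len(n)),
    marker = marker,
    state = sample(states, n, replace = TRUE)
  ))
}
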