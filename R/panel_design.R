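#' Per-group allele profile of one locus
#'
#' Summarises a locus group by group within a scope: a group is "fixed"
#' for an allele only when every one of its non-missing calls is
#' homozygous for that allele *and* its call rate reaches
#' `min_call_rate`; any heterozygote or second allele makes it "mixed".
#' Groups with no samples in scope are flagged `no_samples` (never
#' fixed). This is the automated form of scanning a SNP matrix for
#' homozygous alleles that separate predefined populations.
#'
#' @param genotypes long call tibble (`sample_id`, `locus_id`, `call`).
#' @param labels sample labels (`sample_id`, `group`).
#' @param locus locus id to profile.
#' @param scope groups to consider (default: all groups in `labels`).
#' @param min_call_rate minimum fraction of non-missing calls for a group
#'   to be eligible as fixed (default 0.8).
#' @return tibble with one row per scope group: `group`, `n`, `n_called`,
#'   `call_rate`, `fixed_allele` (NA when mixed), `status` in
#'   \{fixed, mixed, no_samples\}.
#' @export
profile_locus <- function(genotypes, labels, locus, scope = NULL,
                          min_call_rate = 0.8) {
  check_cols(genotypes, c("sample_id", "locus_id", "call"), "`genotypes`")
  check_cols(labels, c("sample_id", "group"), "`labels`")
  scope <- scope %||% sort(unique(labels$group))
  if (length(scope) == 0) abort_fmt("`scope` must be nonempty")
  if (!locus %in% genotypes$locus_id) {
    abort_fmt("locus '%s' not present in `genotypes`", locus)
  }
  df <- genotypes |>
    dplyr::filter(.data$locus_id == !!locus) |>
    dplyr::inner_join(labels, by = "sample_id") |>
    dplyr::filter(.data$group %in% scope)
  profile_calls(df, scope, min_call_rate)
}

# shared per-group tally; df has columns group, call
profile_calls <- function(df, scope, min_call_rate) {
  prof <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_called = sum(!geno_is_missing(.data$call)),
      fixed_allele = {
        calls <- .data$call[!geno_is_missing(.data$call)]
        al <- unique(as.vector(geno_alleles(calls)))
        if (length(calls) > 0 && length(al) == 1) al else NA_character_
      },
      .groups = "drop"
    )
  tibble::tibble(group = scope) |>
    dplyr::left_join(prof, by = "group") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      n_called = dplyr::coalesce(.data$n_called, 0L),
      call_rate = ifelse(.data$n > 0, .data$n_called / .data$n, 0),
      fixed_allele = ifelse(
        !is.na(.data$fixed_allele) & .data$call_rate >= min_call_rate,
        .data$fixed_allele, NA_character_
      ),
      status = dplyr::case_when(
        n == 0 ~ "no_samples",
        !is.na(fixed_allele) ~ "fixed",
        .default = "mixed"
      )
    )
}

#' Find diagnostic loci (fixed homozygous differences) within a scope
#'
#' Scans every locus for a strict fixed difference among the scope
#' groups: every group must be fixed (100% of non-missing calls
#' homozygous for one allele, call rate at or above `min_call_rate`) and
#' both alleles must be represented by at least one group. Each
#' qualifying locus becomes a diagnostic marker whose bipartition is the
#' split of the scope by fixed allele. Scope-restricted markers (valid
#' only within a subset of groups because alleles are mixed outside it)
#' are found by calling this with the narrower `scope` - full-scope and
#' within-subset searches are deliberately separate calls.
#'
#' @inheritParams profile_locus
#' @param loci locus metadata (`locus_id`, `contig`, `pos`, `ref`,
#'   `alt`); determines marker coordinates and the X/Y allele
#'   orientation (`allele_x` = ref, `allele_y` = alt).
#' @return tibble of markers sorted by (contig, pos): `marker_id`,
#'   `contig`, `pos`, `allele_x`, `allele_y`, and list-columns `scope`,
#'   `groups_x`, `groups_y`. Empty (zero rows) when nothing qualifies.
#' @export
find_diagnostic_loci <- function(genotypes, labels, loci, scope = NULL,
                                 min_call_rate = 0.8) {
  check_cols(genotypes, c("sample_id", "locus_id", "call"), "`genotypes`")
  check_cols(labels, c("sample_id", "group"), "`labels`")
  check_cols(loci, c("locus_id", "contig", "pos", "ref", "alt"), "`loci`")
  scope <- scope %||% sort(unique(labels$group))
  if (length(scope) < 2) abort_fmt("`scope` must contain at least 2 groups")

  df <- genotypes |>
    dplyr::inner_join(labels, by = "sample_id") |>
    dplyr::filter(.data$group %in% scope)

  hits <- df |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::group_map(function(g, key) {
      prof <- profile_calls(g, scope, min_call_rate)
      if (any(prof$status != "fixed")) return(NULL)
      alleles <- unique(prof$fixed_allele)
      if (length(alleles) != 2) return(NULL)
      meta <- loci[loci$locus_id == key$locus_id, ]
      if (nrow(meta) != 1) return(NULL)
      if (!setequal(alleles, c(meta$ref, meta$alt))) return(NULL)
      tibble::tibble(
        marker_id = key$locus_id,
        contig = meta$contig, pos = as.integer(meta$pos),
        allele_x = meta$ref, allele_y = meta$alt,
        scope = list(scope),
        groups_x = list(prof$group[prof$fixed_allele == meta$ref]),
        groups_y = list(prof$group[prof$fixed_allele == meta$alt])
      )
    }) |>
    dplyr::bind_rows()

  if (nrow(hits) == 0) {
    return(tibble::tibble(
      marker_id = character(), contig = character(), pos = integer(),
      allele_x = character(), allele_y = character(),
      scope = list(), groups_x = list(), groups_y = list()
    ))
  }
  dplyr::arrange(hits, .data$contig, .data$pos)
}

#' Check that a marker has clean flanking sequence for assay design
#'
#' A KASP submission requires at least `flank` bases of reference
#' sequence on each side of the SNP, free of other segregating sites
#' (a nearby SNP under an allele-specific primer destabilises it).
#' Verifies both conditions against a reference and the full locus list.
#'
#' @param reference a `Biostrings::DNAStringSet` (or named character
#'   vector of sequences) keyed by contig name.
#' @param marker one-row tibble or list with `contig` and `pos`
#'   (1-based).
#' @param all_loci locus table (`locus_id`, `contig`, `pos`) used to
#'   detect interfering neighbours; the marker's own position is ignored.
#' @param flank required clean flank length in bp on each side
#'   (default 50).
#' @return list with `ok` (logical) and `reasons` (character, empty when
#'   ok).
#' @export
check_flanks <- function(reference, marker, all_loci, flank = 50) {
  seqs <- as_reference_lengths(reference)
  contig <- marker$contig
  pos <- as.integer(marker$pos)
  if (!contig %in% names(seqs)) {
    abort_fmt("marker contig '%s' absent from reference", contig)
  }
  len <- seqs[[contig]]
  if (pos < 1 || pos > len) {
    abort_fmt("marker position %d outside contig '%s' (length %d)",
              pos, contig, len)
  }
  reasons <- character()
  if (pos - 1 < flank) reasons <- c(reasons, "left flank short")
  if (len - pos < flank) reasons <- c(reasons, "right flank short")
  nb <- all_loci[all_loci$contig == contig &
                   abs(all_loci$pos - pos) <= flank &
                   all_loci$pos != pos, , drop = FALSE]
  if (nrow(nb) > 0) {
    reasons <- c(reasons, sprintf("interfering locus within %d bp: %s",
                                  flank, paste(nb$locus_id, collapse = ", ")))
  }
  list(ok = length(reasons) == 0, reasons = reasons)
}

# contig name -> length, from DNAStringSet or character vector
as_reference_lengths <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    stats::setNames(Biostrings::width(reference), names(reference))
  } else {
    stats::setNames(nchar(reference), names(reference))
  }
}

# contig sequence as plain character
reference_seq <- function(reference, contig) {
  if (inherits(reference, "DNAStringSet")) {
    as.character(reference[[contig]])
  } else {
    unname(reference[[contig]])
  }
}

#' Extract an assay-submission sequence with the SNP in bracket notation
#'
#' Returns the reference window centred on the marker SNP with the
#' variant base replaced by `[X/Y]` (alleles always in the marker's
#' X/Y order, regardless of which allele the reference carries) - the
#' conventional format for submitting a SNP flanking sequence to an
#' assay-design service. The window includes the SNP base, so the
#' returned string has `window - 1` plain bases plus the 5-character
#' bracket, e.g. 204 characters for a 200-bp window.
#'
#' @param reference as in [check_flanks()].
#' @param marker one-row tibble or list with `contig`, `pos`,
#'   `allele_x`, `allele_y`.
#' @param window total window size in bp including the SNP (default
#'   200).
#' @return character scalar; attribute `truncated` is TRUE when the
#'   contig end clipped the window.
#' @export
extract_submission_sequence <- function(reference, marker, window = 200) {
  seqs <- as_reference_lengths(reference)
  contig <- marker$contig
  pos <- as.integer(marker$pos)
  if (!contig %in% names(seqs)) {
    abort_fmt("marker contig '%s' absent from reference", contig)
  }
  len <- seqs[[contig]]
  if (pos < 1 || pos > len) {
    abort_fmt("marker position %d outside contig '%s'", pos, contig)
  }
  seq <- reference_seq(reference, contig)
  ref_base <- toupper(substr(seq, pos, pos))
  if (!ref_base %in% c(marker$allele_x, marker$allele_y)) {
    abort_fmt(
      "reference base '%s' at %s:%d matches neither marker allele (%s/%s); check strand or locus representation",
      ref_base, contig, pos, marker$allele_x, marker$allele_y
    )
  }
  left_want <- (window - 1L) %/% 2L
  right_want <- window - 1L - left_want
  left_from <- max(1L, pos - left_want)
  right_to <- min(len, pos + right_want)
  out <- paste0(
    substr(seq, left_from, pos - 1L),
    sprintf("[%s/%s]", marker$allele_x, marker$allele_y),
    substr(seq, pos + 1L, right_to)
  )
  attr(out, "truncated") <- (pos - left_from) < left_want ||
    (right_to - pos) < right_want
  out
}
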