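#' Confusion matrix of assignments against a reference labelling
#'
#' Tallies (reference group, assigned group) pairs. Named-group
#' assignments form the square part of the matrix; `unresolved` and
#' `non-target` assignments are tallied in separate columns and never
#' count as matches.
#'
#' @param assignments tibble with `sample_id` and `assignment` (e.g.
#'   from [classify_cohort()]).
#' @param reference sample metadata tibble with `sample_id` and
#'   `ref_group`; every assigned sample must have a reference label.
#' @return object of class `kasp_confusion`: list with `table` (counts
#'   matrix, reference in rows), `total` and `matched` (diagonal sum
#'   over named groups).
#' @export
confusion_matrix <- function(assignments, reference) {
  check_cols(assignments, c("sample_id", "assignment"), "`assignments`")
  check_cols(reference, c("sample_id", "ref_group"), "`reference`")
  missing_ref <- setdiff(assignments$sample_id, reference$sample_id)
  if (length(missing_ref) > 0) {
    abort_fmt("sample(s) without reference label: %s",
              paste(utils::head(missing_ref, 10), collapse = ", "))
  }
  df <- dplyr::inner_join(assignments, reference, by = "sample_id")
  groups <- sort(unique(c(df$ref_group,
                          setdiff(df$assignment,
                                  c("unresolved", "non-target")))))
  cols <- c(groups, "unresolved", "non-target")
  tab <- table(factor(df$ref_group, levels = groups),
               factor(df$assignment, levels = cols))
  tab <- matrix(tab, nrow = length(groups), ncol = length(cols),
                dimnames = list(reference = groups, assigned = cols))
  structure(
    list(table = tab, total = nrow(df),
         matched = sum(diag(tab[groups, groups, drop = FALSE]))),
    class = "kasp_confusion"
  )
}

#' @export
print.kasp_confusion <- function(x, ...) {
  cat(sprintf("<kasp_confusion> %d/%d matched (%.1f%%)\n",
              x$matched, x$total, 100 * x$matched / x$total))
  print(x$table)
  invisible(x)
}

#' @rdname confusion_matrix
#' @param x a `kasp_confusion`.
#' @param ... unused.
#' @return `tidy.kasp_confusion()` returns the long count table;
#'   `glance.kasp_confusion()` one row with `matched`, `total`,
#'   `concordance_pct`.
#' @export
tidy.kasp_confusion <- function(x, ...) {
  as.data.frame(as.table(x$table), stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    rlang::set_names(c("reference", "assigned", "n")) |>
    dplyr::filter(.data$n > 0 | .data$reference == .data$assigned)
}

#' @rdname confusion_matrix
#' @export
glance.kasp_confusion <- function(x, ...) {
  tibble::tibble(matched = x$matched, total = x$total,
                 concordance_pct = overall_concordance(x))
}

#' Overall concordance percentage
#'
#' `100 * matched / total`, rounded half away from zero to one decimal
#' place (the package-wide reporting convention; see
#' [round_half_up()]).
#'
#' @param x a `kasp_confusion`, or a plain square count matrix
#'   (reference in rows) whose diagonal holds the matches.
#' @return percentage scalar with one decimal.
#' @examples
#' m <- diag(c(31, 41, 4, 41, 26, 8))
#' m[1, 2] <- 1 # one reference-group-1 sample assigned to group 2
#' overall_concordance(m) # 99.3
#' @export
overall_concordance <- function(x) {
  if (inherits(x, "kasp_confusion")) {
    matched <- x$matched
    total <- x$total
  } else {
    x <- as.matrix(x)
    sq <- min(dim(x))
    matched <- sum(diag(x[seq_len(sq), seq_len(sq), drop = FALSE]))
    total <- sum(x)
  }
  if (total == 0) abort_fmt("empty confusion matrix")
  round_half_up(100 * matched / total, 1)
}

#' Per-marker accuracy against reference genotypes
#'
#' For one marker, groups the reference cohort into classes that share
#' an expected homozygous state (e.g. the two sides of the marker's
#' bipartition), tallies the observed call states within each class and
#' reports accuracy (percent of calls matching the expected state,
#' one decimal), mismatch percent and the countries the mismatching
#' samples came from, plus a pooled row per marker. Heterozygous calls
#' against a homozygous expectation count as mismatches. Samples whose
#' reference group lies outside the marker's scope are excluded (with a
#' warning giving the count), as are samples listed in `exclude`
#' (e.g. reference calls missing at that marker).
#'
#' @param calls long call tibble: `sample_id`, `marker`, `state`
#'   (allele-space or nucleotide genotype).
#' @param reference metadata tibble: `sample_id`, `ref_group`, optional
#'   `country`.
#' @param panel a [kasp_panel].
#' @param exclude optional tibble (`sample_id`, `marker`) of
#'   sample-marker pairs to drop from marker-level rows.
#' @return tibble with one row per (marker, class) plus a pooled row
#'   per marker (`class = "pooled"`): `marker`, `class`, `ref_groups`,
#'   `expected`, `n`, `n_match`, `accuracy_pct`, `mismatch_pct`,
#'   `mismatch_origin`, `observed` (compact "state(count)" summary).
#' @export
per_marker_accuracy <- function(calls, reference, panel, exclude = NULL) {
  check_cols(calls, c("sample_id", "marker", "state"), "`calls`")
  check_cols(reference, c("sample_id", "ref_group"), "`reference`")
  if (!"country" %in% names(reference)) reference$country <- NA_character_
  if (!is.null(exclude)) {
    calls <- dplyr::anti_join(calls, exclude, by = c("sample_id", "marker"))
  }
  purrr::map_dfr(unique(calls$marker), function(mid) {
    m <- panel_marker(panel, mid)
    if (is.null(m)) abort_fmt("marker '%s' not in panel", mid)
    df <- calls[calls$marker == mid, ] |>
      dplyr::inner_join(reference, by = "sample_id")
    out_scope <- sum(!df$ref_group %in% m$scope[[1]])
    if (out_scope > 0) {
      warning(sprintf("%s: %d sample(s) outside marker scope excluded",
                      mid, out_scope), call. = FALSE)
      df <- df[df$ref_group %in% m$scope[[1]], ]
    }
    expected_state <- ifelse(df$ref_group %in% m$groups_x[[1]], "XX", "YY")
    df$expected <- state_to_geno(expected_state, m$allele_x, m$allele_y)
    df$observed <- state_to_geno(geno_to_state(df$state, m$allele_x,
                                               m$allele_y),
                                 m$allele_x, m$allele_y)
    df$observed[df$observed == "./."] <- "no_call"
    rows <- df |>
      dplyr::group_by(.data$expected) |>
      dplyr::group_map(function(g, key) {
        accuracy_row(mid, key$expected, g$observed == key$expected,
                     g$observed, g$country)
      }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(class = .data$expected, .after = "marker")
    pooled <- accuracy_row(mid, "pooled", df$observed == df$expected,
                           df$observed, df$country) |>
      dplyr::mutate(class = "pooled", .after = "marker")
    dplyr::bind_rows(rows, pooled) |>
      dplyr::select(-"expected") |>
      dplyr::mutate(
        ref_groups = dplyr::if_else(
          .data$class == "pooled",
          paste(m$scope[[1]], collapse = "/"),
          purrr::map_chr(.data$class, function(cl) {
            side <- if (cl == state_to_geno("XX", m$allele_x, m$allele_y)) {
              m$groups_x[[1]]
            } else {
              m$groups_y[[1]]
            }
            paste(intersect(side, m$scope[[1]]), collapse = "/")
          })
        ),
        .after = "class"
      )
  })
}

# shared accuracy computation over parallel vectors
accuracy_row <- function(marker, expected_label, match, observed, country) {
  origins <- sort(unique(country[!match & !is.na(country)]))
  obs_tab <- sort(table(observed), decreasing = TRUE)
  n <- length(match)
  tibble::tibble(
    marker = marker,
    expected = expected_label,
    n = n,
    n_match = sum(match),
    accuracy_pct = round_half_up(100 * sum(match) / n, 1),
    mismatch_pct = round_half_up(100 * (1 - sum(match) / n), 1),
    mismatch_origin = paste(origins, collapse = "; "),
    observed = paste(sprintf("%s(%d)", names(obs_tab), obs_tab),
                     collapse = " ")
  )
}

#' Per-marker accuracy from published-style count rows
#'
#' Computes the same accuracy figures as [per_marker_accuracy()] but
#' from aggregated validation counts (one row per marker, reference
#' class and observed state), the shape in which assay validation
#' summaries are usually published.
#'
#' @param rows tibble with columns `marker`, `class` (reference-class
#'   label), `ref_groups`, `n_class` (reference class size), `expected`
#'   (the call state counted as a match), `observed_state`, `count`,
#'   optional `mismatch_origin`.
#' @return tibble per (marker, class) plus pooled rows, with
#'   `accuracy_pct` / `mismatch_pct` rounded to one decimal.
#' @export
marker_accuracy_from_counts <- function(rows) {
  check_cols(rows, c("marker", "class", "ref_groups", "n_class",
                     "expected", "observed_state", "count"), "`rows`")
  if (!"mismatch_origin" %in% names(rows)) rows$mismatch_origin <- ""
  per_class <- rows |>
    dplyr::group_by(.data$marker, .data$class, .data$ref_groups) |>
    dplyr::summarise(
      n = .data$n_class[[1]],
      n_match = sum(.data$count[.data$observed_state == .data$expected]),
      mismatch_origin = paste(
        sort(unique(.data$mismatch_origin[.data$mismatch_origin != "" &
                                            .data$observed_state != .data$expected])),
        collapse = "; "
      ),
      observed = paste(sprintf("%s(%d)", .data$observed_state, .data$count),
                       collapse = " "),
      .groups = "drop"
    )
  pooled <- per_class |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      class = "pooled",
      ref_groups = paste(.data$ref_groups, collapse = "/"),
      n = sum(.data$n), n_match = sum(.data$n_match),
      mismatch_origin = paste(
        unique(.data$mismatch_origin[.data$mismatch_origin != ""]),
        collapse = "; "
      ),
      observed = paste(.data$observed, collapse = " "),
      .groups = "drop"
    )
  dplyr::bind_rows(per_class, pooled) |>
    dplyr::mutate(
      accuracy_pct = round_half_up(100 * .data$n_match / .data$n, 1),
      mismatch_pct = round_half_up(100 * (1 - .data$n_match / .data$n), 1)
    ) |>
    dplyr::arrange(.data$marker, .data$class == "pooled")
}

#' Default legacy-barcode (COI) expectation map
#'
#' Maps mitochondrial COI identity labels of cassava *Bemisia tabaci*
#' to the genome-wide haplogroup each label is conventionally taken to
#' indicate. Labels mapped to `NA` are recorded in the literature but
#' ambiguous between haplogroups (SSA1-SG2 and SSA1-SG1/SG2 occur
#' within more than one SSA1 haplogroup; SSA3 straddles SSA2 and SSA4):
#' a sample carrying one cannot be correctly identified from COI alone
#' and is therefore counted as misidentified. Labels absent from the
#' map entirely are tallied separately as unmappable.
#'
#' @return named character vector (NA = known-ambiguous label).
#' @export
coi_expectation_map <- function() {
  c("SSA1-SG1" = "SSA-ECA",
    "SSA1-SG3" = "SSA-ESA",
    "SSA1-SG5" = "SSA-WA",
    "SSA2" = "SSA2",
    "SSA4" = "SSA4",
    "SSA1-SG2" = NA_character_,
    "SSA1-SG1/SG2" = NA_character_,
    "SSA3" = NA_character_)
}

#' Legacy-barcode misidentification summary
#'
#' Counts samples whose COI-implied haplogroup differs from the
#' reference (genome-wide) haplogroup. Samples with a known-ambiguous
#' COI label (mapped to `NA`) count as misidentified; samples whose
#' label is absent from the map are reported separately as unmappable
#' and excluded from the misidentified count.
#'
#' @param reference tibble with `sample_id`, `ref_group` and `coi`.
#' @param coi_map named character vector, see [coi_expectation_map()].
#' @return list with `count` (misidentified), `percent` (of all
#'   samples, one decimal), `n_unmappable`, `total` and `breakdown`
#'   (tibble per (coi, ref_group): `n`, `category` in
#'   concordant/misassigned/ambiguous_label/unmappable).
#' @export
coi_mismatch_summary <- function(reference, coi_map = coi_expectation_map()) {
  check_cols(reference, c("sample_id", "ref_group", "coi"), "`reference`")
  if (any(is.na(reference$coi)) || any(is.na(reference$ref_group))) {
    abort_fmt("every sample needs both a COI label and a reference group")
  }
  df <- reference |>
    dplyr::mutate(
      mapped = .data$coi %in% names(coi_map),
      implied = unname(coi_map[.data$coi]),
      category = dplyr::case_when(
        !mapped ~ "unmappable",
        is.na(implied) ~ "ambiguous_label",
        implied == .data$ref_group ~ "concordant",
        .default = "misassigned"
      )
    )
  breakdown <- df |>
    dplyr::count(.data$coi, .data$ref_group, .data$category, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  mis <- sum(df$category %in% c("misassigned", "ambiguous_label"))
  list(
    count = mis,
    percent = round_half_up(100 * mis / nrow(df), 1),
    n_unmappable = sum(df$category == "unmappable"),
    total = nrow(df),
    breakdown = breakdown
  )
}
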