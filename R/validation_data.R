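#' Packaged validation summaries for the cassava whitefly panel
#'
#' The package ships the published validation summaries of the
#' six-haplogroup cassava *Bemisia tabaci* KASP panel as plain-text
#' count tables: the haplogroup-level confusion counts (152 field
#' samples vs reference NextRAD haplogroups), the per-marker call
#' counts by reference class, and the legacy COI barcode labels by
#' haplogroup. `load_validation_counts()` returns them as tibbles;
#' `validation_cohort()` expands the haplogroup-level and COI counts
#' into a per-sample table (synthetic sample ids) so the sample-level
#' concordance functions can be exercised on the published numbers.
#'
#' @return `load_validation_counts()`: list of tibbles `confusion`
#'   (`ref_group`, `assignment`, `n`), `marker_classes` (see
#'   [marker_accuracy_from_counts()]) and `coi` (`coi`, `ref_group`,
#'   `n`).
#' @export
load_validation_counts <- function() {
  path <- function(f) system.file("extdata", f, package = "kaspdx",
                                  mustWork = TRUE)
  read <- function(f) {
    readr::read_csv(path(f), comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  }
  list(
    confusion = read("validation_confusion.csv"),
    marker_classes = read("validation_marker_classes.csv") |>
      dplyr::mutate(mismatch_origin = dplyr::coalesce(.data$mismatch_origin, "")),
    coi = read("validation_coi.csv")
  )
}

#' @rdname load_validation_counts
#' @return `validation_cohort()`: list of tibbles `assignments`
#'   (`sample_id`, `assignment`) and `reference` (`sample_id`,
#'   `ref_group`, `coi`), 152 samples each.
#' @export
validation_cohort <- function() {
  counts <- load_validation_counts()
  assign_long <- counts$confusion |>
    tidyr::uncount(.data$n) |>
    dplyr::arrange(.data$ref_group, .data$assignment)
  coi_long <- counts$coi |>
    tidyr::uncount(.data$n) |>
    dplyr::arrange(.data$ref_group, .data$coi)
  if (nrow(assign_long) != nrow(coi_long)) {
    abort_fmt("validation fixtures disagree on cohort size")
  }
  # align the two marginals within each reference group; sample ids are
  # synthetic (the per-sample appendix is not redistributed)
  coi_by_group <- split(coi_long$coi, coi_long$ref_group)
  assign_long <- assign_long |>
    dplyr::group_by(.data$ref_group) |>
    dplyr::mutate(coi = coi_by_group[[dplyr::cur_group()$ref_group]]) |>
    dplyr::ungroup() |>
    dplyr::mutate(sample_id = sprintf("V%03d", dplyr::row_number()))
  list(
    assignments = dplyr::select(assign_long, "sample_id", "assignment"),
    reference = dplyr::select(assign_long, "sample_id", "ref_group", "coi")
  )
}
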