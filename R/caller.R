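#' Caller parameters
#'
#' Tunable thresholds of the endpoint-fluorescence genotype caller, with
#' the package defaults. All angles are in degrees from the FAM (allele
#' X) axis.
#'
#' @param ntc_factor multiple of the no-template-control signal envelope
#'   below which a sample well is gated as "low signal" (default 2.0).
#' @param ntc_k how many NTC standard deviations define the envelope
#'   (mean + k SD, default 3).
#' @param quality silhouette threshold in \[-1, 1\]; wells whose angular
#'   cluster separation falls below it are not called (default 0.5,
#'   also the minimum mean silhouette for accepting a multi-cluster
#'   structure over a single cluster).
#' @param band_margin degrees around a genotype-band boundary within
#'   which a well is suspect when its cluster centre lies in a
#'   different band (default 5).
#' @param band_lo,band_hi genotype-band boundaries in degrees (defaults
#'   30, 60): `XX` is `[0, band_lo)`, `XY` is `[band_lo, band_hi]`,
#'   `YY` is `(band_hi, 90]` - the heterozygous band is symmetric
#'   around 45 degrees because dual dye incorporation yields
#'   intermediate signal.
#' @param ntc_free set TRUE to allow plates without NTC wells; an
#'   absolute magnitude floor (`abs_floor`) is then used instead of the
#'   NTC envelope.
#' @param abs_floor absolute magnitude floor used only in NTC-free mode.
#' @return named list of parameters.
#' @export
kasp_caller_params <- function(ntc_factor = 2.0, ntc_k = 3, quality = 0.5,
                               band_margin = 5, band_lo = 30, band_hi = 60,
                               ntc_free = FALSE, abs_floor = 0) {
  list(ntc_factor = ntc_factor, ntc_k = ntc_k, quality = quality,
       band_margin = band_margin, band_lo = band_lo, band_hi = band_hi,
       ntc_free = ntc_free, abs_floor = abs_floor)
}

#' Background-subtract endpoint reads
#'
#' Subtracts the pre-read (background) fluorescence from the post-read
#' on each channel, flooring at zero. The pre-read exists exactly for
#' this correction: it captures plate/dye background before
#' amplification.
#'
#' @param wells tibble with columns `fam_pre`, `fam_post`, `hex_pre`,
#'   `hex_post` (all non-negative).
#' @return the tibble with added `fam` and `hex` columns.
#' @export
normalize_wells <- function(wells) {
  check_cols(wells, c("fam_pre", "fam_post", "hex_pre", "hex_post"),
             "`wells`")
  raw <- c(wells$fam_pre, wells$fam_post, wells$hex_pre, wells$hex_post)
  if (any(is.na(raw)) || any(raw < 0)) {
    abort_fmt("fluorescence values must be non-negative and non-missing")
  }
  dplyr::mutate(wells,
                fam = pmax(.data$fam_post - .data$fam_pre, 0),
                hex = pmax(.data$hex_post - .data$hex_pre, 0))
}

#' Polar representation of a FAM/HEX signal pair
#'
#' @param fam,hex background-subtracted channel signals (vectors).
#' @return tibble with `theta` (degrees from the FAM axis toward the HEX
#'   axis; `NA` when both channels are zero) and `magnitude` (Euclidean
#'   norm).
#' @examples
#' polar_transform(300, 300) # theta 45, magnitude ~424.26
#' @export
polar_transform <- function(fam, hex) {
  theta <- atan2(hex, fam) * 180 / pi
  theta[fam == 0 & hex == 0] <- NA_real_
  tibble::tibble(theta = theta, magnitude = sqrt(fam^2 + hex^2))
}

# band of a theta value under caller params: "XX", "XY" or "YY"
theta_band <- function(theta, params) {
  dplyr::case_when(
    theta < params$band_lo ~ "XX",
    theta <= params$band_hi ~ "XY",
    .default = "YY"
  )
}

# deterministic 1-D k-means on theta; returns integer cluster ids
theta_kmeans <- function(theta, k) {
  centers <- stats::quantile(theta, probs = seq_len(k) / (k + 1),
                             names = FALSE, type = 7)
  centers <- unique(centers)
  if (length(centers) < k) return(NULL)
  km <- suppressWarnings(
    stats::kmeans(theta, centers = matrix(centers, ncol = 1),
                  algorithm = "Lloyd", iter.max = 100)
  )
  km$cluster
}

# cluster thetas with k in {1,2,3} chosen by mean silhouette; a
# multi-cluster candidate is only eligible when its cluster centres fall
# in distinct genotype bands (true genotype clusters are at least a band
# apart by assay design, so sub-band splits are noise, not structure).
# Returns list(cluster, sil (per-well), centers).
cluster_thetas <- function(theta, min_mean_sil, params) {
  n <- length(theta)
  single <- list(cluster = rep(1L, n), sil = rep(1, n),
                 centers = mean(theta))
  if (n < 3 || length(unique(theta)) < 2) return(single)
  d <- stats::dist(theta)
  best <- NULL
  best_sil <- -Inf
  for (k in 2:min(3, length(unique(theta)))) {
    cl <- theta_kmeans(theta, k)
    if (is.null(cl) || length(unique(cl)) < 2) next
    centers <- tapply(theta, cl, mean)
    if (anyDuplicated(theta_band(as.numeric(centers), params))) next
    sw <- cluster::silhouette(cl, d)
    msil <- mean(sw[, "sil_width"])
    if (msil > best_sil) {
      best_sil <- msil
      best <- list(cluster = cl, sil = sw[, "sil_width"], centers = centers)
    }
  }
  if (is.null(best) || best_sil < min_mean_sil) return(single)
  best
}

#' Call genotypes from an endpoint-fluorescence plate table
#'
#' Converts raw FAM/HEX endpoint reads into bi-allelic genotype calls
#' per well. The procedure, applied independently per plate and marker:
#'
#' 1. background subtraction ([normalize_wells()]) and polar transform;
#' 2. *NTC gate*: sample wells whose magnitude does not exceed
#'    `ntc_factor * (mean + ntc_k * SD)` of the plate's no-template
#'    controls are `no_call` ("low signal") - they are statistically
#'    indistinguishable from wells with no amplification;
#' 3. *band assignment*: remaining wells get the state of their angular
#'    band (XX below `band_lo`, XY up to `band_hi`, YY above);
#' 4. *cluster-quality gate*: well angles are clustered (k selected in
#'    1-3 by silhouette); wells with silhouette below `quality`, or
#'    sitting within `band_margin` degrees of a band boundary while
#'    their cluster centre lies in a different band, are `no_call`
#'    ("ambiguous cluster") - the numeric analogue of scoring only
#'    samples that fall in visually distinct clusters.
#'
#' No-template controls are never genotyped; a fluorescent NTC surfaces
#' as a QC warning, not a call.
#'
#' @param wells plate tibble (`plate_id`, `well`, `role`, `marker`,
#'   `sample`, `fam_pre`, `fam_post`, `hex_pre`, `hex_post`).
#' @param params caller thresholds, see [kasp_caller_params()].
#' @return tibble of class `kasp_calls`: `plate_id`, `well`, `sample`,
#'   `marker`, `state` (`XX`/`XY`/`YY`/`no_call`), `theta`, `magnitude`,
#'   `quality`, `reason` (empty for called wells).
#' @export
call_plate <- function(wells, params = kasp_caller_params()) {
  check_cols(wells, c("plate_id", "well", "role", "marker",
                      "fam_pre", "fam_post", "hex_pre", "hex_post"),
             "`wells`")
  if (!"sample" %in% names(wells)) wells$sample <- NA_character_

  wells <- normalize_wells(wells)
  pol <- polar_transform(wells$fam, wells$hex)
  wells$theta <- pol$theta
  wells$magnitude <- pol$magnitude

  out <- wells |>
    dplyr::group_by(.data$plate_id, .data$marker) |>
    dplyr::group_map(function(df, key) {
      call_plate_group(df, key, params)
    }) |>
    dplyr::bind_rows() |>
    dplyr::select("plate_id", "well", "sample", "marker", "state",
                  "theta", "magnitude", "quality", "reason")
  structure(out, class = c("kasp_calls", class(out)))
}

call_plate_group <- function(df, key, params) {
  df$plate_id <- key$plate_id
  df$marker <- key$marker
  ntc <- df[df$role == "NTC", ]
  smp <- df[df$role != "NTC", ]

  if (nrow(ntc) == 0 && !params$ntc_free) {
    abort_fmt(
      "plate %s / marker %s has no NTC wells; set ntc_free = TRUE to use an absolute floor",
      key$plate_id, key$marker
    )
  }
  floor_mag <- if (nrow(ntc) > 0) {
    sd_ntc <- stats::sd(ntc$magnitude)
    if (is.na(sd_ntc)) sd_ntc <- 0
    params$ntc_factor * (mean(ntc$magnitude) + params$ntc_k * sd_ntc)
  } else {
    params$abs_floor
  }

  res <- smp
  res$state <- NA_character_
  res$quality <- NA_real_
  res$reason <- ""

  low <- is.na(res$theta) | res$magnitude <= floor_mag
  res$state[low] <- "no_call"
  res$reason[low] <- "low signal"

  live <- which(!low)
  if (length(live) > 0) {
    th <- res$theta[live]
    cl <- cluster_thetas(th, min_mean_sil = params$quality, params = params)
    band <- theta_band(th, params)
    centre_band <- theta_band(as.numeric(cl$centers), params)[cl$cluster]
    near_boundary <- pmin(abs(th - params$band_lo),
                          abs(th - params$band_hi)) < params$band_margin
    ambiguous <- cl$sil < params$quality |
      (near_boundary & centre_band != band)
    res$state[live] <- ifelse(ambiguous, "no_call", band)
    res$quality[live] <- cl$sil
    res$reason[live] <- ifelse(ambiguous, "ambiguous cluster", "")
  }

  # NTC wells are reported but never genotyped; fluorescence above the
  # gate is flagged as possible contamination
  if (nrow(ntc) > 0) {
    ntc$state <- "no_call"
    ntc$quality <- NA_real_
    ntc$reason <- ifelse(ntc$magnitude > floor_mag,
                         "NTC fluorescent (contamination?)", "NTC")
    res <- dplyr::bind_rows(res, ntc)
  }
  res
}

#' Summarise a call table per marker
#'
#' @param x a `kasp_calls` tibble.
#' @param ... unused.
#' @return tibble per (marker, state) with well counts and mean quality.
#' @export
tidy.kasp_calls <- function(x, ...) {
  x |>
    dplyr::filter(!is.na(.data$sample)) |>
    dplyr::count(.data$marker, .data$state, name = "n_wells") |>
    dplyr::left_join(
      x |>
        dplyr::filter(!is.na(.data$sample)) |>
        dplyr::group_by(.data$marker, .data$state) |>
        dplyr::summarise(mean_quality = mean(.data$quality, na.rm = TRUE),
                         .groups = "drop"),
      by = c("marker", "state")
    )
}
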