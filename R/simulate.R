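#' Simulate a labelled diploid genotype matrix with planted diagnostic loci
#'
#' Generates a cohort of samples from named populations ("haplogroups")
#' genotyped at a mixture of planted diagnostic loci (fixed homozygous
#' differences between two sides of a group bipartition, optionally valid
#' only within a scope subset of groups) and background loci whose
#' genotypes are drawn independently of group membership under
#' Hardy-Weinberg proportions. This emulates the kind of
#' reduced-representation SNP matrix from which diagnostic KASP markers
#' are mined, with known truth so the discovery, calling and
#' classification machinery can be validated end to end.
#'
#' @param group_sizes named integer vector, samples per group. The default
#'   study-scale cohort of the packaged cassava *Bemisia tabaci* panel is
#'   `c("SSA-ECA" = 60, "SSA-WA" = 52, "SSA2" = 33, "SSA4" = 10,
#'   "SSA-ESA" = 50, "SSA-CA" = 12)` (217 samples).
#' @param diagnostic_spec list of diagnostic-locus specifications; each
#'   element is a list with fields `groups_x` (character, the groups fixed
#'   homozygous for `allele_x`), `scope` (character, the groups within
#'   which the locus is diagnostic; remaining scope groups are fixed for
#'   `allele_y`), `allele_x`, `allele_y` (single bases) and optionally
#'   `locus_id`, `contig`, `pos`. Samples outside `scope` receive a
#'   genotype drawn uniformly from \{XX, XY, YY\}. See
#'   [diagnostic_spec_from_panel()] to derive this from a panel.
#' @param n_background_loci number of non-diagnostic loci (default 100).
#'   Each gets two random alleles and a minor-allele frequency drawn
#'   uniformly on (0.05, 0.5); genotypes follow Hardy-Weinberg.
#' @param missing_rate per-call probability of replacement by `"./."`
#'   (default 0.02, a typical post-filtering missingness level).
#' @param het_rate per-call probability of replacement by the heterozygous
#'   genotype of the locus (default 0; planted fixed differences stay
#'   strictly fixed unless noise is requested explicitly).
#' @param seed integer seed; identical seeds give identical output. The
#'   global RNG state is left untouched.
#' @return an object of class `kasp_sim`: a list with tibbles
#'   * `genotypes`: long calls (`sample_id`, `locus_id`, `call`),
#'   * `loci`: `locus_id`, `contig`, `pos`, `ref`, `alt`, `role`,
#'   * `samples`: `sample_id`, `group`,
#'   * `truth$genotype_truth`: pre-noise calls, and
#'   * `truth$call_truth`: per (sample, diagnostic locus) allele-space
#'     state (`XX`/`XY`/`YY`) used as the oracle for plate simulation.
#' @examples
#' spec <- list(list(groups_x = "A", scope = c("A", "B"),
#'                   allele_x = "A", allele_y = "G"))
#' sim <- simulate_genotype_matrix(c(A = 5, B = 5), spec,
#'                                 n_background_loci = 10, seed = 1)
#' dplyr::count(sim$samples, group)
#' @export
simulate_genotype_matrix <- function(group_sizes,
                                     diagnostic_spec = list(),
                                     n_background_loci = 100,
                                     missing_rate = 0.02,
                                     het_rate = 0,
                                     seed = 1) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    abort_fmt("`group_sizes` must be a named vector of per-group counts")
  }
  if (any(group_sizes < 1)) abort_fmt("all group sizes must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1 || het_rate < 0 || het_rate >= 1) {
    abort_fmt("`missing_rate` and `het_rate` must lie in [0, 1)")
  }
  groups <- names(group_sizes)
  diagnostic_spec <- lapply(seq_along(diagnostic_spec), function(i) {
    d <- diagnostic_spec[[i]]
    d$scope <- d$scope %||% groups
    d$locus_id <- d$locus_id %||% sprintf("diag_%02d", i)
    d$contig <- d$contig %||% sprintf("ctg_%s", d$locus_id)
    d$pos <- d$pos %||% 5000L
    if (!all(d$groups_x %in% d$scope)) {
      abort_fmt("diagnostic locus %s: `groups_x` must be a subset of `scope`",
                d$locus_id)
    }
    if (length(d$groups_x) == 0 || length(setdiff(d$scope, d$groups_x)) == 0) {
      abort_fmt("diagnostic locus %s: bipartition must be a nonempty proper split of its scope",
                d$locus_id)
    }
    if (!all(d$scope %in% groups)) {
      abort_fmt("diagnostic locus %s: scope names groups absent from `group_sizes`",
                d$locus_id)
    }
    d
  })

  samples <- tibble::tibble(
    group = rep(groups, times = as.integer(group_sizes))
  ) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%03d", .data$group,
                          as.integer(stats::ave(seq_along(.data$group),
                                                .data$group, FUN = seq_along))),
      .before = 1
    )
  n <- nrow(samples)

  withr::with_seed(seed, {
    # diagnostic loci: fixed homozygous within scope, uniform outside
    diag_calls <- purrr::map(diagnostic_spec, function(d) {
      in_x <- samples$group %in% d$groups_x
      in_scope <- samples$group %in% d$scope
      g <- character(n)
      g[in_x] <- geno_hom(d$allele_x)
      g[in_scope & !in_x] <- geno_hom(d$allele_y)
      n_out <- sum(!in_scope)
      if (n_out > 0) {
        states <- sample(c("XX", "XY", "YY"), n_out, replace = TRUE)
        g[!in_scope] <- state_to_geno(states, d$allele_x, d$allele_y, sep = "/")
      }
      g
    })

    # background loci: HWE draws independent of group
    bg_ids <- if (n_background_loci > 0) {
      sprintf("bg_%03d", seq_len(n_background_loci))
    } else {
      character()
    }
    bg <- purrr::map(seq_len(n_background_loci), function(i) {
      alleles <- sample(c("A", "C", "G", "T"), 2)
      maf <- stats::runif(1, 0.05, 0.5)
      a1 <- ifelse(stats::runif(n) < maf, alleles[2], alleles[1])
      a2 <- ifelse(stats::runif(n) < maf, alleles[2], alleles[1])
      list(alleles = alleles, calls = geno(a1, a2))
    })

    loci <- dplyr::bind_rows(
      purrr::map_dfr(diagnostic_spec, function(d) {
        tibble::tibble(locus_id = d$locus_id, contig = d$contig,
                       pos = as.integer(d$pos),
                       ref = d$allele_x, alt = d$allele_y,
                       role = "diagnostic")
      }),
      purrr::map2_dfr(bg, bg_ids, function(b, id) {
        tibble::tibble(locus_id = id, contig = paste0("ctg_", id),
                       pos = 5000L, ref = b$alleles[1], alt = b$alleles[2],
                       role = "background")
      })
    )

    calls_mat <- c(diag_calls, purrr::map(bg, "calls"))
    names(calls_mat) <- loci$locus_id
    genotypes <- tidyr::expand_grid(locus_id = loci$locus_id,
                                    sample_id = samples$sample_id) |>
      dplyr::mutate(call = unlist(calls_mat, use.names = FALSE)) |>
      dplyr::select("sample_id", "locus_id", "call") |>
      dplyr::arrange(.data$sample_id, .data$locus_id)

    genotype_truth <- genotypes

    # noise: het conversion then missingness, per call
    if (het_rate > 0) {
      het_of <- stats::setNames(geno(loci$ref, loci$alt), loci$locus_id)
      flip <- stats::runif(nrow(genotypes)) < het_rate
      genotypes$call[flip] <- het_of[genotypes$locus_id[flip]]
    }
    if (missing_rate > 0) {
      drop <- stats::runif(nrow(genotypes)) < missing_rate
      genotypes$call[drop] <- "./."
    }

    call_truth <- purrr::map_dfr(diagnostic_spec, function(d) {
      g <- genotype_truth$call[genotype_truth$locus_id == d$locus_id]
      s <- genotype_truth$sample_id[genotype_truth$locus_id == d$locus_id]
      tibble::tibble(sample_id = s, marker = d$locus_id,
                     state = geno_to_state(g, d$allele_x, d$allele_y))
    })

    structure(
      list(genotypes = genotypes, loci = loci, samples = samples,
           truth = list(genotype_truth = genotype_truth,
                        call_truth = call_truth),
           seed = seed),
      class = "kasp_sim"
    )
  })
}

#' @export
print.kasp_sim <- function(x, ...) {
  cat(sprintf(
    "<kasp_sim> %d samples x %d loci (%d diagnostic), %d groups, seed %d\n",
    nrow(x$samples), nrow(x$loci), sum(x$loci$role == "diagnostic"),
    dplyr::n_distinct(x$samples$group), x$seed
  ))
  invisible(x)
}

#' Convert heterozygous calls to random homozygotes (allelic dropout)
#'
#' Emulates allele loss at low read depth in reduced-representation
#' sequencing: each heterozygous call independently collapses to one of
#' its two homozygous states with probability `dropout_rate` (the lost
#' allele chosen uniformly). Homozygous and missing calls are untouched.
#'
#' @param genotypes long call tibble (`sample_id`, `locus_id`, `call`).
#' @param dropout_rate probability in \[0, 1\] that a heterozygote drops.
#' @param seed integer seed (global RNG state untouched).
#' @return the tibble with perturbed `call` column.
#' @export
apply_allelic_dropout <- function(genotypes, dropout_rate, seed = 1) {
  check_cols(genotypes, c("sample_id", "locus_id", "call"), "`genotypes`")
  if (dropout_rate < 0 || dropout_rate > 1) {
    abort_fmt("`dropout_rate` must lie in [0, 1]")
  }
  het <- which(geno_is_het(genotypes$call))
  if (length(het) == 0 || dropout_rate == 0) return(genotypes)
  withr::with_seed(seed, {
    hit <- het[stats::runif(length(het)) < dropout_rate]
    if (length(hit) > 0) {
      al <- geno_alleles(genotypes$call[hit])
      keep <- ifelse(stats::runif(length(hit)) < 0.5, al[, 1], al[, 2])
      genotypes$call[hit] <- geno_hom(keep)
    }
  })
  genotypes
}

#' Default endpoint-fluorescence cluster geometry
#'
#' Cluster positions on the FAM/HEX plane, in polar form. `theta_deg` is
#' the angle in degrees measured from the FAM axis (allele X) toward the
#' HEX axis (allele Y); this convention is used throughout the package.
#' Defaults place the homozygous-X arm at 10 degrees, heterozygotes at 45
#' and homozygous-Y at 80, mimicking the three-arm cluster plots of a
#' well-behaved KASP assay; no-template controls sit near the origin at
#' 5% of the sample magnitude.
#'
#' @param theta_xx,theta_xy,theta_yy cluster angles in degrees.
#' @param magnitude_mean mean endpoint signal magnitude of sample wells.
#' @param ntc_magnitude mean magnitude of no-template-control wells.
#' @return named list of per-state `list(theta_deg, magnitude_mean)`.
#' @export
default_cluster_params <- function(theta_xx = 10, theta_xy = 45,
                                   theta_yy = 80, magnitude_mean = 1000,
                                   ntc_magnitude = magnitude_mean * 0.05) {
  list(
    XX = list(theta_deg = theta_xx, magnitude_mean = magnitude_mean),
    XY = list(theta_deg = theta_xy, magnitude_mean = magnitude_mean),
    YY = list(theta_deg = theta_yy, magnitude_mean = magnitude_mean),
    NTC = list(theta_deg = NA_real_, magnitude_mean = ntc_magnitude)
  )
}

#' Simulate endpoint-fluorescence plates for a marker panel
#'
#' Lays out one 96-well plate series per marker: each sample with a truth
#' state gets a well whose FAM/HEX post-read signal sits on the polar ray
#' of its genotype cluster (magnitude lognormal around the cluster mean)
#' plus Gaussian channel noise; `n_ntc` no-template-control wells per
#' plate sit near the origin. Pre-read values are a 5% baseline fraction
#' of the post-read (plus proportionally scaled noise), so that
#' background subtraction leaves the cluster angles intact.
#'
#' @param panel a [kasp_panel] whose markers appear in `truth`.
#' @param truth either a `kasp_sim` object or its `truth$call_truth`
#'   tibble (`sample_id`, `marker`, `state` in XX/XY/YY space).
#' @param cluster_params per-state cluster geometry, see
#'   [default_cluster_params()].
#' @param noise_sd Gaussian noise SD added to each channel, in signal
#'   units (default 50, i.e. 5% of the default cluster magnitude).
#' @param n_ntc no-template controls per plate (default 3).
#' @param magnitude_sdlog lognormal sdlog of along-ray magnitude spread.
#' @param pre_fraction pre-read baseline as a fraction of post-read.
#' @param seed integer seed (global RNG untouched).
#' @return class `kasp_plate_sim`: list with `wells` (tibble `plate_id`,
#'   `well`, `role`, `marker`, `sample`, `fam_pre`, `fam_post`,
#'   `hex_pre`, `hex_post`) and `truth` (per-well true state).
#' @export
simulate_plate <- function(panel, truth,
                           cluster_params = default_cluster_params(),
                           noise_sd = 50, n_ntc = 3,
                           magnitude_sdlog = 0.05,
                           pre_fraction = 0.05, seed = 1) {
  if (inherits(truth, "kasp_sim")) truth <- truth$truth$call_truth
  check_cols(truth, c("sample_id", "marker", "state"), "`truth`")
  if (n_ntc < 1) abort_fmt("`n_ntc` must be >= 1")
  if (!all(c("XX", "XY", "YY") %in% names(cluster_params))) {
    abort_fmt("`cluster_params` must define XX, XY and YY clusters")
  }
  bad <- setdiff(unique(truth$marker), panel$markers$marker_id)
  if (length(bad) > 0) {
    abort_fmt("truth references marker(s) absent from panel: %s",
              paste(bad, collapse = ", "))
  }

  well_names <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  per_plate <- 96L - as.integer(n_ntc)

  withr::with_seed(seed, {
    wells <- truth |>
      dplyr::group_by(.data$marker) |>
      dplyr::group_map(function(df, key) {
        m <- key$marker
        chunks <- split(df, (seq_len(nrow(df)) - 1L) %/% per_plate)
        purrr::imap_dfr(chunks, function(ch, i) {
          plate_id <- sprintf("%s_p%02d", m, as.integer(i) + 1L)
          smp <- tibble::tibble(
            plate_id = plate_id, role = "sample", marker = m,
            sample = ch$sample_id, state = ch$state
          )
          ntc <- tibble::tibble(
            plate_id = plate_id, role = "NTC", marker = m,
            sample = NA_character_, state = NA_character_,
            .rows = n_ntc
          )
          out <- dplyr::bind_rows(smp, ntc)
          out$well <- well_names[seq_len(nrow(out))]
          out
        })
      }) |>
      dplyr::bind_rows()

    k <- nrow(wells)
    is_ntc <- wells$role == "NTC"
    theta <- ifelse(is_ntc,
                    stats::runif(k, 0, 90),
                    purrr::map_dbl(wells$state, function(s) {
                      if (is.na(s)) NA_real_ else cluster_params[[s]]$theta_deg
                    }))
    mag_mean <- ifelse(is_ntc,
                       cluster_params$NTC$magnitude_mean %||% 50,
                       purrr::map_dbl(wells$state, function(s) {
                         if (is.na(s)) return(NA_real_)
                         cluster_params[[s]]$magnitude_mean
                       }))
    mag <- stats::rlnorm(k, meanlog = log(mag_mean), sdlog = magnitude_sdlog)
    fam <- mag * cospi(theta / 180) + stats::rnorm(k, 0, noise_sd)
    hex <- mag * sinpi(theta / 180) + stats::rnorm(k, 0, noise_sd)
    fam_post <- pmax(fam, 0)
    hex_post <- pmax(hex, 0)
    fam_pre <- pmax(pre_fraction * fam_post +
                      stats::rnorm(k, 0, noise_sd * pre_fraction), 0)
    hex_pre <- pmax(pre_fraction * hex_post +
                      stats::rnorm(k, 0, noise_sd * pre_fraction), 0)

    out <- wells |>
      dplyr::mutate(fam_pre = fam_pre, fam_post = fam_post,
                    hex_pre = hex_pre, hex_post = hex_post) |>
      dplyr::select("plate_id", "well", "role", "marker", "sample",
                    "fam_pre", "fam_post", "hex_pre", "hex_post",
                    true_state = "state")

    structure(
      list(
        wells = dplyr::select(out, -"true_state"),
        truth = out |>
          dplyr::filter(.data$role == "sample") |>
          dplyr::select("plate_id", "well", "marker", "sample",
                        state = "true_state"),
        seed = seed
      ),
      class = "kasp_plate_sim"
    )
  })
}

#' @export
print.kasp_plate_sim <- function(x, ...) {
  cat(sprintf(
    "<kasp_plate_sim> %d wells (%d samples, %d NTC) on %d plates, seed %d\n",
    nrow(x$wells), sum(x$wells$role == "sample"),
    sum(x$wells$role == "NTC"),
    dplyr::n_distinct(x$wells$plate_id), x$seed
  ))
  invisible(x)
}

#' Canonical six-haplogroup study cohort sizes
#'
#' The per-haplogroup sample counts of the cassava *Bemisia tabaci*
#' discovery cohort (217 whiteflies) used as the default simulation
#' scale.
#'
#' @return named integer vector of group sizes.
#' @export
canonical_group_sizes <- function() {
  c("SSA-ECA" = 60L, "SSA-WA" = 52L, "SSA2" = 33L, "SSA4" = 10L,
    "SSA-ESA" = 50L, "SSA-CA" = 12L)
}
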