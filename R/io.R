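#' Read and write genotype matrices
#'
#' A genotype matrix travels as a wide TSV (samples in rows, loci in
#' columns, calls like `A/G` with `./.` missing) or as a minimal VCF
#' (biallelic SNP records with a GT field). The VCF reader is backed by
#' the vcfR package; multi-allelic records are rejected with a count,
#' since a two-dye competitive assay can only interrogate two alleles.
#'
#' @param genotypes long call tibble (`sample_id`, `locus_id`, `call`).
#' @param loci locus table (`locus_id`, `contig`, `pos`, `ref`, `alt`).
#' @param path file path.
#' @return readers return `list(genotypes, loci)`; writers the path,
#'   invisibly.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  check_cols(genotypes, c("sample_id", "locus_id", "call"), "`genotypes`")
  wide <- genotypes |>
    tidyr::pivot_wider(names_from = "locus_id", values_from = "call")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-"sample_id", names_to = "locus_id",
                        values_to = "call") |>
    dplyr::mutate(call = geno_normalise(.data$call))
  list(genotypes = long, loci = infer_loci(long))
}

# minimal locus table from observed alleles (ref = first seen allele)
infer_loci <- function(genotypes) {
  genotypes |>
    dplyr::filter(!geno_is_missing(.data$call)) |>
    dplyr::group_by(locus_id = .data$locus_id) |>
    dplyr::summarise(alleles = list(sort(unique(as.vector(
      geno_alleles(.data$call)
    )))), .groups = "drop") |>
    dplyr::mutate(
      contig = .data$locus_id, pos = 1L,
      ref = purrr::map_chr(.data$alleles, 1),
      alt = purrr::map_chr(.data$alleles,
                           function(a) if (length(a) > 1) a[[2]] else NA_character_)
    ) |>
    dplyr::select("locus_id", "contig", "pos", "ref", "alt")
}

#' @rdname write_genotype_tsv
#' @export
write_genotype_vcf <- function(genotypes, loci, path) {
  check_cols(genotypes, c("sample_id", "locus_id", "call"), "`genotypes`")
  check_cols(loci, c("locus_id", "contig", "pos", "ref", "alt"), "`loci`")
  samples <- unique(genotypes$sample_id)
  wide <- genotypes |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "call")
  wide <- dplyr::left_join(loci, wide, by = "locus_id")
  gt_code <- function(call, ref, alt) {
    al <- geno_alleles(geno_normalise(call))
    code <- function(a) ifelse(a == ref, "0", ifelse(a == alt, "1", "."))
    out <- paste(code(al[, 1]), code(al[, 2]), sep = "/")
    out[geno_is_missing(call)] <- "./."
    # VCF convention: list the lower index first
    ifelse(out == "1/0", "0/1", out)
  }
  body <- vapply(seq_len(nrow(wide)), function(i) {
    paste(c(wide$contig[i], wide$pos[i], wide$locus_id[i], wide$ref[i],
            wide$alt[i], ".", "PASS", ".", "GT",
            gt_code(unlist(wide[i, samples]), wide$ref[i], wide$alt[i])),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kaspdx",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort_fmt("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi)) {
    warning(sprintf("%d non-biallelic-SNP record(s) rejected", sum(multi)),
            call. = FALSE)
    v <- v[!multi, ]
    fix <- fix[!multi, ]
  }
  loci <- tibble::tibble(
    locus_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, ":", fix$POS), fix$ID),
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  rownames(gt) <- loci$locus_id
  long <- tibble::as_tibble(gt, rownames = "locus_id") |>
    tidyr::pivot_longer(-"locus_id", names_to = "sample_id",
                        values_to = "gt") |>
    dplyr::left_join(loci, by = "locus_id") |>
    dplyr::mutate(
      call = decode_gt(.data$gt, .data$ref, .data$alt)
    ) |>
    dplyr::select("sample_id", "locus_id", "call")
  list(genotypes = long, loci = loci)
}

decode_gt <- function(gt, ref, alt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- stringr::str_split_fixed(gt, stringr::fixed("/"), 2)
  dec <- function(p) ifelse(p == "0", ref, ifelse(p == "1", alt, NA))
  a1 <- dec(parts[, 1])
  a2 <- dec(parts[, 2])
  out <- geno(a1, a2)
  out[is.na(a1) | is.na(a2)] <- "./."
  out
}

#' Read and write plate and call tables as CSV
#'
#' The plate dialect has one row per well with columns `plate_id`,
#' `well`, `role` (sample/NTC), `marker`, `sample`, `fam_pre`,
#' `fam_post`, `hex_pre`, `hex_post`; the call dialect is the
#' [call_plate()] output.
#'
#' @param wells,calls tibbles in the respective dialect.
#' @param path file path.
#' @return readers return the tibble; writers the path, invisibly.
#' @export
write_plate_csv <- function(wells, path) {
  check_cols(wells, c("plate_id", "well", "role", "marker", "sample",
                      "fam_pre", "fam_post", "hex_pre", "hex_post"),
             "`wells`")
  readr::write_csv(wells, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    plate_id = "c", well = "c", role = "c", marker = "c",
                    sample = "c", .default = "d"
                  ))
}

#' @rdname write_plate_csv
#' @export
write_calls_csv <- function(calls, path) {
  readr::write_csv(calls, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_calls_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  structure(out, class = c("kasp_calls", class(out)))
}

#' Read a sample-metadata CSV
#'
#' Accepts the columns `sample`/`sample_id`, `group`/`ref_group`
#' (reference haplogroup), and optionally `country` and
#' `coi`/`coi_identity`.
#'
#' @param path file path.
#' @return tibble with normalised column names (`sample_id`,
#'   `ref_group`, `country`, `coi` where present).
#' @export
read_metadata_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rename_map <- c(sample = "sample_id", group = "ref_group",
                  haplogroup = "ref_group", coi_identity = "coi")
  for (from in names(rename_map)) {
    if (from %in% names(df) && !rename_map[[from]] %in% names(df)) {
      names(df)[names(df) == from] <- rename_map[[from]]
    }
  }
  check_cols(df, c("sample_id", "ref_group"), "metadata")
  df
}

#' Write simulation truth as JSON
#'
#' @param sim a `kasp_sim`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_sim_truth <- function(sim, path) {
  jsonlite::write_json(
    list(
      seed = sim$seed,
      sample_to_group = stats::setNames(as.list(sim$samples$group),
                                        sim$samples$sample_id),
      locus_roles = stats::setNames(as.list(sim$loci$role),
                                    sim$loci$locus_id),
      call_truth = sim$truth$call_truth
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
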