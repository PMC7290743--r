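#' Genotype string helpers
#'
#' Diploid genotypes are stored as unordered nucleotide pairs in slash
#' notation, e.g. `"A/G"`, with alleles sorted alphabetically so that
#' `"A/G"` and `"G/A"` are the same call. Missing calls are `"./."`.
#' Reports use the colon convention (`"A:G"`); both are accepted on input.
#'
#' @param a1,a2 single-character allele vectors.
#' @return `geno()` returns the normalised genotype string.
#' @examples
#' geno("G", "A") # "A/G"
#' @export
geno <- function(a1, a2) {
  ifelse(a1 <= a2, paste(a1, a2, sep = "/"), paste(a2, a1, sep = "/"))
}

#' @rdname geno
#' @param x genotype strings (slash or colon notation).
#' @return `geno_normalise()` returns calls in sorted slash notation.
#' @export
geno_normalise <- function(x) {
  x <- toupper(gsub(":", "/", x, fixed = TRUE))
  ok <- !is.na(x) & grepl("^[ACGT]/[ACGT]$", x)
  parts <- stringr::str_split_fixed(ifelse(ok, x, "./."),
                                    stringr::fixed("/"), 2)
  out <- geno(parts[, 1], parts[, 2])
  out[!ok] <- "./." # anything malformed or half-called is missing
  out
}

#' @rdname geno
#' @return `geno_is_missing()` / `geno_is_het()` return logicals;
#'   `geno_alleles()` returns a 2-column character matrix.
#' @export
geno_is_missing <- function(x) is.na(x) | x == "./."

#' @rdname geno
#' @export
geno_is_het <- function(x) {
  al <- geno_alleles(x)
  !geno_is_missing(x) & al[, 1] != al[, 2]
}

#' @rdname geno
#' @export
geno_alleles <- function(x) {
  stringr::str_split_fixed(x, stringr::fixed("/"), 2)
}

# hom genotype for a single allele
geno_hom <- function(a) geno(a, a)

# map a genotype to allele-space state given marker alleles:
# "XX", "XY", "YY", "no_call", or "invalid"
geno_to_state <- function(x, allele_x, allele_y) {
  x <- geno_normalise(x)
  out <- rep("invalid", length(x))
  out[geno_is_missing(x)] <- "no_call"
  out[x == geno_hom(allele_x)] <- "XX"
  out[x == geno_hom(allele_y)] <- "YY"
  out[x == geno(allele_x, allele_y)] <- "XY"
  out
}

# inverse: allele-space state to genotype string (colon notation for reports)
state_to_geno <- function(state, allele_x, allele_y, sep = ":") {
  pair <- function(a, b) {
    ifelse(a <= b, paste(a, b, sep = sep), paste(b, a, sep = sep))
  }
  dplyr::case_match(
    state,
    "XX" ~ pair(allele_x, allele_x),
    "XY" ~ pair(allele_x, allele_y),
    "YY" ~ pair(allele_y, allele_y),
    .default = "./."
  )
}
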