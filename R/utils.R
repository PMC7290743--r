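#' Round half away from zero
#'
#' Fixed-precision rounding used for all reported percentages. Unlike
#' [base::round()] (banker's rounding), exact halves move away from zero,
#' so 99.345 prints as 99.3 and 151/152 = 99.342... prints as 99.3 while
#' 98.85 prints as 98.9.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep (default 1).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(100 * 151 / 152) # 99.3
#' round_half_up(0.25, 1) # 0.3
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a sprintf-style message, no call
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# check a data frame has the named columns
check_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort_fmt("%s is missing required column(s): %s", what,
              paste(miss, collapse = ", "))
  }
  invisible(df)
}
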