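# internal helpers

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for report tables, where 0.005 rounds
#' to 0.01 and -0.005 to -0.01, unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(13.595, 2) # 13.60
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# deterministic write of a data.frame as TSV (no quotes, fixed NA string)
write_tsv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = FALSE))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
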