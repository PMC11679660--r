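#' @keywords internal
"_PACKAGE"

## Round-half-up, used for the 3:2 split arithmetic (82.8 -> 83).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Variant identity throughout the package: chrom:pos:ref:alt.
## rsIDs are annotations, never keys (they duplicate after multiallelic
## splitting).
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

stop_schema <- function(what, missing_cols) {
  stop(sprintf("%s is missing required column(s): %s", what,
               paste(missing_cols, collapse = ", ")), call. = FALSE)
}

check_columns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop_schema(what, miss)
  invisible(TRUE)
}
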