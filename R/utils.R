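## internal helpers -----------------------------------------------------

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "mitoscreen_schema_error"
    )
  }
  invisible(df)
}

#' @noRd
as_gene_symbol <- function(x) toupper(trimws(as.character(x)))

## set.seed wrapper that leaves the caller's RNG state untouched
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    rlang::abort(sprintf("`%s` must be a single finite number >= %s", name, min),
                 class = "mitoscreen_parameter_error")
  }
  invisible(x)
}
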