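# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# half-up rounding to the nearest multiple of `unit`; accepts 0
round_half_up <- function(x, unit = 100) floor(x / unit + 0.5) * unit

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "stepgoals_input_error")
}

assert_columns <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}
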