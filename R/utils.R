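clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round to instrument grid after clamping
grid_round <- function(x, lo, hi) round(clamp(x, lo, hi))

assert_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

join_reasons <- function(...) {
  reasons <- c(...)
  paste(reasons[nzchar(reasons)], collapse = ";")
}
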