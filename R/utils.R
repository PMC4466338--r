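# Seed handling: every stochastic function takes an explicit seed and leaves
# the caller's RNG state untouched.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a stream-specific child seed from a base seed; keeps seeds < 2^31.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483629
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(miss, collapse = ", ")),
          class = "navlnp_invalid_argument")
  }
  invisible(df)
}
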