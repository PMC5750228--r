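# internal helpers shared across modules

# Derive a reproducible sub-seed for one named source of randomness from the
# scenario root seed. Keeps every derived seed < 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 127 + h) %% 2147483629)
}

# Evaluate code with a temporary RNG state restored afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# sign() that maps NA to NA and returns integer -1/0/+1
sign_int <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  out[ok] <- as.integer(sign(x[ok]))
  out
}
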