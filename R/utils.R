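# internal helpers shared across modules

# Deterministic 31-bit seed derived from arbitrary tags.  Used so that every
# randomized stage (simulation branches, bootstrap replicates per pair) has
# its own reproducible stream regardless of evaluation order.
derive_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "\r")
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 69069 + cc) %% 2147483647
  as.integer(h)
}

# Run code under a given seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lower median: for an even count, the smaller of the two middle values
median_low <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reverse_complement_chr <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
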