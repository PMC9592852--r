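# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller-visible RNG state afterwards. `code` is a promise from the
# caller, so assignments inside it land in the caller's frame.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a bounded child seed from a master seed and a stage offset, so each
# pipeline stage has its own reproducible stream.
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset) %% 2147483647
}

# Truncated-at-zero normal draw (redraws; for rates/latencies).
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) && guard < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
  }
  x[x <= 0] <- .Machine$double.eps
  x
}

# Recursively drop S3 classes so a config serialises as plain lists.
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, strip_classes)
    x
  } else x
}

# Deterministic polynomial rolling hash of a character scalar; provenance
# fingerprint only, no cryptographic intent.
config_fingerprint <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
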