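# Internal helpers shared across modules.

FORMAT_VERSION <- "1.0"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library functions never perturb user RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# FNV-1a 32-bit hash of a character scalar; used to stamp reports with the
# configuration they came from without external dependencies.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256                      # xor touches the low byte only
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopifnotScalarNumber <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop(what, " must be a single number", call. = FALSE)
}
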