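# Shared helpers: small deterministic records and cohorts built in code.

makeRecord <- function(n = 256, nch = 2, seed = 1, fs = 256,
                       labels = paste0("CH", seq_len(nch)),
                       classLabel = "NORMAL", subjectId = "s01") {
  set.seed(seed)
  eegRecord(matrix(rnorm(n * nch), n, nch), subjectId, classLabel, fs,
            labels)
}

# Tiny cohort for fast structural tests (not for accuracy claims).
makeTinyCohort <- function(nPerClass = 3, durationS = 0.5, seed = 7) {
  simulateCohort(cohortSpec(nSubjectsPerClass = nPerClass,
                            durationS = durationS, seed = seed))
}

# Independent brute-force a-trous SWT: direct time-domain summation with
# periodic indexing and the same phase convention as the package. Used as
# the in-suite oracle for the FFT implementation.
bruteForceSWT <- function(x, J, bank = db4Filters()) {
  N <- length(x)
  applyFilter <- function(a, f, j) {
    up <- 2^(j - 1)
    adv <- (length(f) %/% 2) * up
    out <- numeric(N)
    for (n in seq_len(N)) {
      acc <- 0
      for (m in seq_along(f)) {
        idx <- ((n - 1) - ((m - 1) * up - adv)) %% N
        acc <- acc + f[m] * a[idx + 1]
      }
      out[n] <- acc
    }
    out
  }
  a <- x
  details <- vector("list", J)
  for (j in seq_len(J)) {
    details[[j]] <- applyFilter(a, bank@decHi, j)
    a <- applyFilter(a, bank@decLo, j)
  }
  list(details = details, approximation = a)
}
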