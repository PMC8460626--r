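# evaluate `code` under a temporary RNG state; NULL seed = use current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# uniform integer draw(s) from [lo, hi], safe for lo == hi
sample_range <- function(lo, hi, n = 1) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# validate a frequency vector: nonnegative, sums to 1
check_freqs <- function(p, tol = 1e-9) {
  p <- as.numeric(p)
  if (length(p) < 1 || any(p < -tol) || abs(sum(p) - 1) > 1e-6) {
    abort("allele frequencies must be nonnegative and sum to 1")
  }
  p / sum(p)
}
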