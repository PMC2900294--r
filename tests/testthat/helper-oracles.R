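# Shared fixtures and independent brute-force oracles used across the suite.

random_windows <- function(n, W, seed = 1L,
                           probs = c(0.3, 0.2, 0.2, 0.3)) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), W, TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

# Sliding-window count of overlapping occurrences of m in s (one strand).
brute_count <- function(s, m) {
  k <- nchar(m)
  n <- nchar(s) - k + 1L
  if (n < 1L) return(0L)
  sum(vapply(seq_len(n),
             function(i) substr(s, i, i + k - 1L) == m, logical(1)))
}

# Per-position triangle-kernel summation: for every position, evaluate the
# kernel of every read (vectorized over reads, unlike the implementation's
# loop over reads with vectorized positions).
brute_triangle <- function(reads, len) {
  s <- reads$start
  e <- reads$end - 1L
  mid <- s + (reads$end - reads$start - 1L) %/% 2L
  out <- numeric(len)
  for (x in seq_len(len) - 1L) {
    inside <- x >= s & x <= e
    left <- ifelse(mid > s, (x - s) / pmax(mid - s, 1L), 1)
    right <- (e - x) / pmax(e - mid, 1L)
    out[x + 1L] <- sum(ifelse(x <= mid, left, right)[inside])
  }
  out
}

# Population-moment standardization (mean 0, variance 1).
.standardize_for_test <- function(v) {
  (v - mean(v)) / sqrt(mean((v - mean(v))^2))
}

# Mann-Whitney AUC by full pair enumeration.
brute_mw_auc <- function(pos, neg) {
  gt <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  mean(gt + 0.5 * eq)
}

# Brute-force windowed-local-maximum dyad calls with leftmost tie-break.
brute_calls <- function(trace, window) {
  h <- (window - 1L) %/% 2L
  n <- length(trace)
  calls <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    win <- trace[lo:hi]
    if (trace[i] > 0 && trace[i] == max(win) &&
        (length(calls) == 0L || i - calls[length(calls)] > h)) {
      calls <- c(calls, i)
    }
  }
  calls - 1L
}

# Small shared synthetic world (built once per test run).
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- generator_spec(genome_length = 60000, n_chromosomes = 2,
                             seed = 11L)
      sim <- simulate_genome(spec)
      cache <<- list(spec = spec, genome = sim$genome, dyads = sim$dyads)
    }
    cache
  }
})
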