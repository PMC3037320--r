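# Independent reference implementations used as oracles. These deliberately
# re-check every window / every pair the slow way and share no code with the
# package internals.

random_dna <- function(n, p_ambig = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_ambig) / 4, 4), p_ambig)),
        collapse = "")
}

# Greedy non-overlapping scan by literally re-checking every window.
# Returns 0-based start positions.
brute_scan <- function(sequence, words) {
  k <- nchar(words[[1]])
  n <- nchar(sequence)
  out <- integer(0)
  i <- 1L
  while (i <= n - k + 1L) {
    if (substr(sequence, i, i + k - 1L) %in% words) {
      out <- c(out, i - 1L)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  out
}

# Exhaustive enumeration of maximal runs with all consecutive distances
# <= d_max, from sorted occurrence coordinates (0-based half-open).
brute_clusters <- function(starts, ends, d_max) {
  n <- length(starts)
  empty <- tibble::tibble(start = integer(), end = integer(), n = integer())
  if (n < 2L) return(empty)
  d <- starts[-1] - ends[-n] + 1L
  rows <- list()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- all(d[i:(j - 1)] <= d_max)
      maximal <- ok &&
        (i == 1L || d[i - 1] > d_max) &&
        (j == n || d[j] > d_max)
      if (maximal) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(start = starts[i], end = ends[j], n = j - i + 1L)
      }
    }
  }
  if (length(rows) == 0L) empty else dplyr::bind_rows(rows)
}

# Exhaustive negative-binomial CDF: direct pmf summation with r = n - 1
# successes, P(X <= n_f) where X counts failures.
nbinom_cdf_oracle <- function(n, n_f, p) {
  r <- n - 1
  x <- 0:n_f
  sum(choose(x + r - 1, r - 1) * p^r * (1 - p)^x)
}

# All-pairs overlap test on 0-based half-open intervals.
brute_overlaps_any <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    any(y$seq_id == x$seq_id[i] &
          pmax(x$start[i], y$start) < pmin(x$end[i], y$end))
  }, logical(1))
}

# Jaccard index of two 0-based half-open intervals.
jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  inter / (pmax(e1, e2) - pmin(s1, s2))
}
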