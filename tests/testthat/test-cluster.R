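occ_at <- function(starts, k = 4L, seq_id = "s") {
  tibble::tibble(seq_id = seq_id, contig_start = 0L,
                 start = as.integer(starts), end = as.integer(starts + k))
}

test_that("build_clusters keeps maximal runs within d_max and drops singletons", {
  # consecutive distances 1, 2, 500 with d_max = 10: one cluster of three
  occ <- occ_at(cumsum(c(0, 4, 5, 503)))
  cl <- build_clusters(occ, 10)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n, 3L)
  expect_equal(cl$start, 0L)
  expect_equal(cl$end, 13L)
  expect_equal(cl$L_c, 13L)

  # all distances above the threshold: nothing
  expect_equal(nrow(build_clusters(occ_at(c(0, 100, 200)), 10)), 0L)

  # tie at d_max stays inside ("equal or below")
  cl <- build_clusters(occ_at(c(0, 13)), 10)  # distance = 13 - 4 + 1 = 10
  expect_equal(cl$n, 2L)
})

test_that("clusters never span contig boundaries", {
  occ <- tibble::tibble(seq_id = "s", contig_start = c(0L, 0L, 50L, 50L),
                        start = c(0L, 5L, 50L, 55L),
                        end = c(4L, 9L, 54L, 59L))
  cl <- build_clusters(occ, 100)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(0L, 50L))
})

test_that("cluster assembly matches exhaustive enumeration of maximal runs", {
  withr::local_seed(17)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    starts <- sort(sample(seq(0L, 400L, by = 5L), n))
    d_max <- sample(1:30, 1)
    got <- build_clusters(occ_at(starts), d_max)
    want <- brute_clusters(starts, starts + 4L, d_max)
    expect_equal(got[c("start", "end", "n")],
                 want[order(want$start), c("start", "end", "n")],
                 ignore_attr = TRUE)
  }
})

test_that("k-mer failures are the no-target bases: n_f = L_c - n k", {
  # the two canonical worked cases for target ATGC
  cl <- build_clusters(occ_at(c(0, 4)), 5)       # ATGCATGC
  expect_equal(failures_kmer(cl, 4)$n_f, 0L)
  cl <- build_clusters(occ_at(c(0, 5)), 5)       # ATGCAATGC
  expect_equal(failures_kmer(cl, 4)$n_f, 1L)
  cl <- build_clusters(occ_at(c(0, 4, 8)), 5)    # three adjacent copies
  expect_equal(failures_kmer(cl, 4)$n_f, 0L)
})

test_that("element failures count uncovered bases in mean-length units", {
  el <- tibble::tibble(seq_id = "s", start = c(0L, 300L),
                       end = c(300L, 600L))
  cl <- build_clusters(el, 10)
  expect_equal(failures_element(cl, el, 300)$n_f, 0L)  # L_no = 0

  el <- tibble::tibble(seq_id = "s", start = c(0L, 550L),
                       end = c(300L, 850L))
  cl <- build_clusters(el, 300)
  f <- failures_element(cl, el, 300)
  expect_equal(f$L_no, 250L)
  expect_equal(f$n_f, 1L)  # ceiling(250/300)

  # 5 elements of 300 bp with four 250-bp gaps: L_no = 1000 -> ceiling = 4
  starts <- (0:4) * 550L
  el <- tibble::tibble(seq_id = "s", start = starts, end = starts + 300L)
  cl <- build_clusters(el, 300)
  f <- failures_element(cl, el, 300)
  expect_equal(cl$L_c, 2500L)
  expect_equal(f$L_no, 1000L)
  expect_equal(f$n_f, 4L)
})

test_that("element success probability is N * L_mean / L_s, guarded at 1", {
  starts <- seq(0L, by = 300000L, length.out = 10)
  el <- tibble::tibble(seq_id = "s", start = starts, end = starts + 300L)
  sl <- tibble::tibble(seq_id = "s", length = 3000000L)
  st <- element_stats(el, sl)
  expect_equal(st$p, 0.001)
  expect_equal(st$L_mean, 300)

  whole <- tibble::tibble(seq_id = "s", start = 0L, end = 100L)
  expect_error(element_stats(whole, tibble::tibble(seq_id = "s",
                                                   length = 100L)),
               "0 < p < 1")
})

test_that("cluster p-value is the negative-binomial CDF with r = n - 1", {
  expect_equal(cluster_pvalue(2, 0, 0.5), 0.5)
  expect_equal(cluster_pvalue(2, 1, 0.5), 0.75)
  expect_equal(cluster_pvalue(3, 2, 0.25), nbinom_cdf_oracle(3, 2, 0.25))
  expect_equal(round(cluster_pvalue(3, 2, 0.25), 4), 0.2617)

  expect_error(cluster_pvalue(1, 0, 0.5), "n >= 2")
  expect_error(cluster_pvalue(2, -1, 0.5), ">= 0")
  expect_error(cluster_pvalue(2, 0, 1), "0, 1")
})

test_that("the negative-binomial pmf sums to 1 and the CDF is increasing in n_f", {
  for (n in 2:5) {
    for (p in c(0.05, 0.3, 0.7)) {
      r <- n - 1
      x <- 0:3000
      pmf_sum <- sum(choose(x + r - 1, r - 1) * p^r * (1 - p)^x)
      expect_equal(pmf_sum, 1, tolerance = 1e-9)
      cdf <- cluster_pvalue(n, 0:50, p)
      expect_true(all(diff(cdf) >= 0))
      # strictly increasing wherever the CDF has not saturated numerically
      unsat <- cdf[-length(cdf)] < 1 - 1e-12
      expect_true(all(diff(cdf)[unsat] > 0))
      expect_true(all(cdf > 0 & cdf <= 1))
    }
  }
})

test_that("for n = 2 the test reduces to the geometric closed form", {
  for (p in c(0.05, 0.25, 0.5, 0.9)) {
    for (nf in 0:20) {
      expect_equal(cluster_pvalue(2, nf, p), 1 - (1 - p)^(nf + 1),
                   tolerance = 1e-12)
    }
  }
})

test_that("filter_significant keeps exactly the qualifying clusters in order", {
  cl <- tibble::tibble(seq_id = "s", start = 1:4, end = 2:5,
                       p_value = c(1e-7, 0.2, 1e-6, 1))
  expect_equal(filter_significant(cl, 1), cl)
  expect_equal(nrow(filter_significant(cl, 1e-12)), 0L)
  expect_equal(filter_significant(cl, 1e-5)$start, c(1L, 3L))
  expect_error(filter_significant(cl, 0), "alpha")
  expect_error(filter_significant(cl, 1.5), "alpha")
})

test_that("cluster bookkeeping is conserved: L_c = n k + n_f = sum(d) + n k - (n-1)", {
  sim <- simulate_word_sequence(seq_length = 20000, n_windows = 4,
                                background_rate = 1, seed = 202)
  ctg <- segment_contigs(sim$seqs)
  occ <- scan_words(ctg, "ATGC")
  cl <- failures_kmer(build_clusters(occ, 8), 4)
  expect_gt(nrow(cl), 0)
  for (i in seq_len(nrow(cl))) {
    members <- occ[occ$start >= cl$start[i] & occ$end <= cl$end[i], ]
    expect_equal(nrow(members), cl$n[i])
    d <- pair_distances(members)$d
    expect_equal(cl$L_c[i], cl$n[i] * 4L + cl$n_f[i])
    expect_equal(cl$n_f[i], sum(d) - (cl$n[i] - 1L))
  }
})
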