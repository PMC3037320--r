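occ_tbl <- function(starts, ends, seq_id = "s", contig_start = 0L) {
  tibble::tibble(seq_id = seq_id, contig_start = contig_start,
                 start = as.integer(starts), end = as.integer(ends))
}

test_that("abutting copies are at distance 1; one intervening base gives 2", {
  expect_equal(pair_distances(occ_tbl(c(0, 4), c(4, 8)))$d, 1L)
  expect_equal(pair_distances(occ_tbl(c(0, 5), c(4, 9)))$d, 2L)
  expect_equal(nrow(pair_distances(occ_tbl(0, 4))), 0L)
})

test_that("distances are per contig and overlapping elements clamp to 1", {
  two_ctg <- tibble::tibble(seq_id = "s", contig_start = c(0L, 0L, 50L, 50L),
                            start = c(0L, 10L, 50L, 60L),
                            end = c(4L, 14L, 54L, 64L))
  d <- pair_distances(two_ctg)
  expect_equal(nrow(d), 2L)  # no cross-contig pair

  ovl <- tibble::tibble(seq_id = "s", start = c(0L, 5L, 20L),
                        end = c(10L, 15L, 30L))
  expect_equal(pair_distances(ovl)$d, c(1L, 6L))
})

test_that("distance counts conserve length(occurrences) - 1 per contig", {
  withr::local_seed(3)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    starts <- sort(sample(0:500, n)) * 10L
    d <- pair_distances(occ_tbl(starts, starts + 4L))
    expect_equal(nrow(d), max(0, n - 1))
    expect_true(all(d$d >= 1))
  }
})

test_that("the expected distance law is geometric in (0,1)", {
  expect_equal(expected_distance_pmf(1, 0.5), 0.5)
  expect_equal(expected_distance_pmf(3, 0.1), 0.081)
  expect_equal(sum(expected_distance_pmf(1:5000, 0.01)), 1, tolerance = 1e-12)
  expect_error(expected_distance_pmf(1, 1.2), "0, 1")
  expect_error(expected_distance_pmf(0, 0.5), ">= 1")
})

test_that("percentile_distance uses nearest-rank and is monotone in q", {
  expect_equal(percentile_distance(c(1, 1, 3), 50), 1)
  expect_equal(percentile_distance(c(1, 2, 3, 4), 100), 4)
  expect_equal(percentile_distance(2, 10), 2)
  expect_error(percentile_distance(numeric(0), 50), "empty")
  expect_error(percentile_distance(c(1, 2), 0), "0, 100")

  withr::local_seed(21)
  d <- sample(1:50, 200, replace = TRUE)
  qs <- c(5, 25, 50, 75, 95, 100)
  vals <- vapply(qs, function(q) percentile_distance(d, q), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("distance_distribution normalizes and carries the expected curve", {
  dd <- distance_distribution(c(1, 1, 2, 5), p = 0.2)
  expect_s3_class(dd, "wordclust_dist")
  expect_equal(sum(dd$count), attr(dd, "total"))
  expect_equal(sum(dd$obs_freq), 1)
  expect_equal(dd$exp_freq, expected_distance_pmf(dd$distance, 0.2))
  expect_error(distance_distribution(numeric(0), 0.2), "empty")
})

test_that("intersection_distance finds the observed/expected crossing", {
  # all observed mass at d = 1: the curves cross at d = 2
  dd <- distance_distribution(rep(1, 10), p = 0.5)
  expect_equal(intersection_distance(dd), 2)

  # observed above the expected curve over its whole support: the crossing
  # falls just past the largest observed distance — no separation inside
  dd <- distance_distribution(c(1, 1, 1, 1, 2, 2, 3), p = 0.5)
  expect_equal(intersection_distance(dd), 4)

  # two-regime data: crossing separates intra- from inter-cluster distances
  withr::local_seed(9)
  d <- c(sample(1:10, 200, replace = TRUE), sample(200:400, 40, replace = TRUE))
  dd <- distance_distribution(d, p = 0.02)
  cross <- intersection_distance(dd)
  expect_gt(cross, 10)
  expect_lt(cross, 200)
})

test_that("memoryless placement yields no stable separation point", {
  withr::local_seed(33)
  for (rep in 1:10) {
    p <- runif(1, 0.05, 0.2)
    d <- rgeom(400, p) + 1
    dd <- distance_distribution(d, p = p)
    res <- withCallingHandlers(
      intersection_distance(dd),
      wordclust_fallback = function(w) invokeRestart("muffleWarning"))
    # any crossing is sampling noise near/below the bulk of the distribution
    expect_lte(res, percentile_distance(d, 95))
    expect_gte(res, 1)
  }
})

test_that("resolve_dmax degenerates correctly across scopes", {
  block <- paste0(strrep("ATGCAA", 5), strrep("A", 100))
  ctg <- segment_contigs(tibble::tibble(
    seq_id = c("c1", "c2"),
    sequence = rep(paste(rep(block, 10), collapse = ""), 2)))
  occ <- scan_words(ctg, "ATGC")
  st <- word_stats(occ, ctg, 4)
  d <- pair_distances(occ)

  chrom <- resolve_dmax(d, st, model = "chrom_intersection")
  genome <- resolve_dmax(d, st, model = "genome_intersection")
  # identical per-sequence distance multisets: genome merge changes nothing
  expect_equal(chrom$d_max, genome$d_max)
  expect_equal(unique(genome$scope), "genome")

  one <- resolve_dmax(d[d$seq_id == "c1", ], st[st$seq_id == "c1", ],
                      model = "genome_intersection")
  expect_equal(one$d_max, chrom$d_max[chrom$seq_id == "c1"])

  fx <- resolve_dmax(d, st, model = "fixed", fixed_distance = 50)
  expect_equal(fx$d_max, c(50L, 50L))
  expect_error(resolve_dmax(d, st, model = "fixed"), "fixed_distance")
})
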