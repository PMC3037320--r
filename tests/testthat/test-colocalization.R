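make_gene <- function(gene_id = "g1", seq_id = "chr1", strand = "+",
                      tx = c(1000L, 2000L), cds = tx,
                      exon_starts = tx[1], exon_ends = tx[2]) {
  tibble::tibble(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 tx_start = tx[1], tx_end = tx[2],
                 cds_start = cds[1], cds_end = cds[2],
                 exon_starts = list(as.integer(exon_starts)),
                 exon_ends = list(as.integer(exon_ends)))
}

region <- function(regions, lab) {
  r <- regions[regions$label == lab, ]
  r[order(r$start), ]
}

test_that("TSS and promoter windows are strand-aware", {
  reg <- derive_regions(make_gene(strand = "+"))
  expect_equal(region(reg, "TSS")[c("start", "end")],
               tibble::tibble(start = 1000L, end = 1001L))
  expect_equal(region(reg, "TSS100")[c("start", "end")],
               tibble::tibble(start = 900L, end = 1101L))
  # upstream window clipped at zero
  expect_equal(region(reg, "R13")$start, 0L)

  reg <- derive_regions(make_gene(strand = "-"))
  expect_equal(region(reg, "TSS")[c("start", "end")],
               tibble::tibble(start = 1999L, end = 2000L))
  expect_equal(region(reg, "R13")[c("start", "end")],
               tibble::tibble(start = 1499L, end = 3500L))
})

test_that("promoter window spans 1500 bp upstream through 500 bp downstream", {
  reg <- derive_regions(make_gene(tx = c(5000L, 9000L), strand = "+"))
  r13 <- region(reg, "R13")
  expect_equal(r13$end - r13$start, 2001L)
  expect_equal(r13$start, 5000L - 1500L)
})

test_that("UTRs derive from CDS vs exon structure; single exons give no introns", {
  # + strand, two exons, CDS strictly inside
  g <- make_gene(strand = "+", tx = c(100L, 1000L), cds = c(300L, 800L),
                 exon_starts = c(100L, 600L), exon_ends = c(400L, 1000L))
  reg <- derive_regions(g)
  expect_equal(region(reg, "UTR5")[c("start", "end")],
               tibble::tibble(start = 100L, end = 300L))
  expect_equal(region(reg, "UTR3")[c("start", "end")],
               tibble::tibble(start = 800L, end = 1000L))
  expect_equal(region(reg, "intron")[c("start", "end")],
               tibble::tibble(start = 400L, end = 600L))

  # same structure on the - strand swaps the UTR labels
  g$strand <- "-"
  reg <- derive_regions(g)
  expect_equal(region(reg, "UTR3")$start, 100L)
  expect_equal(region(reg, "UTR5")$start, 800L)

  # single-exon coding gene: exactly zero introns
  reg <- derive_regions(make_gene())
  expect_equal(nrow(region(reg, "intron")), 0L)
})

test_that("overlap counting is half-open and counts each cluster once per label", {
  clusters <- tibble::tibble(seq_id = "chr1", start = 10L, end = 20L)
  touching <- tibble::tibble(label = "x", seq_id = "chr1",
                             start = 19L, end = 30L)
  abutting <- tibble::tibble(label = "x", seq_id = "chr1",
                             start = 20L, end = 30L)
  expect_equal(count_region_overlaps(clusters, touching)$n_overlap, 1L)
  expect_equal(count_region_overlaps(clusters, abutting)$n_overlap, 0L)

  # two intervals of one label hitting the same cluster count it once
  two <- tibble::tibble(label = "x", seq_id = "chr1",
                        start = c(11L, 15L), end = c(13L, 17L))
  expect_equal(count_region_overlaps(clusters, two)$n_overlap, 1L)
})

test_that("sweep overlap counts match the all-pairs reference", {
  withr::local_seed(29)
  for (rep in 1:20) {
    nx <- sample(1:25, 1)
    ny <- sample(1:25, 1)
    mk <- function(n) {
      s <- sample(0:500, n, replace = TRUE)
      tibble::tibble(seq_id = sample(c("c1", "c2"), n, replace = TRUE),
                     start = s, end = s + sample(1:50, n, replace = TRUE))
    }
    x <- mk(nx)
    y <- mk(ny)
    expect_equal(overlaps_any(x, y), brute_overlaps_any(x, y))
    y$label <- "custom"
    cnt <- count_region_overlaps(x, y)
    expect_equal(cnt$n_overlap, sum(brute_overlaps_any(x, y)))
    expect_lte(cnt$n_overlap, nrow(x))
  }
})

test_that("a cluster overlapping an exon overlaps its transcript span", {
  withr::local_seed(31)
  g <- make_gene(strand = "+", tx = c(100L, 1000L), cds = c(300L, 800L),
                 exon_starts = c(100L, 600L), exon_ends = c(400L, 1000L))
  reg <- derive_regions(g)
  tx_span <- tibble::tibble(label = "tx", seq_id = "chr1",
                            start = 100L, end = 1000L)
  for (rep in 1:30) {
    s <- sample(0:1200, 1)
    cl <- tibble::tibble(seq_id = "chr1", start = s,
                         end = s + sample(1:100, 1))
    hits_exon <- count_region_overlaps(cl, region(reg, "exon"))$n_overlap
    hits_tx <- count_region_overlaps(cl, tx_span)$n_overlap
    expect_true(hits_exon <= hits_tx)
  }
})
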