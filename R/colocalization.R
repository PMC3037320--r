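#' Derive gene regions from gene models
#'
#' From refFlat-style gene models, builds strand-aware interval sets for the
#' standard gene regions used in co-localization counts:
#' \describe{
#'   \item{TSS}{the 1-bp transcription start position (transcript start on
#'     the + strand, transcript end - 1 on the - strand).}
#'   \item{TSS100}{a 201-bp window centred on the TSS (TSS +/- 100 bp).}
#'   \item{R13}{the promoter window from 1500 bp upstream to 500 bp
#'     downstream of the TSS (2001 bp, inclusive of the TSS base), in
#'     transcription orientation.}
#'   \item{UTR5 / UTR3}{exonic bases outside the CDS, upstream/downstream in
#'     transcription orientation; non-coding genes contribute none.}
#'   \item{exon / intron}{the exons, and the transcript span minus the
#'     exons.}
#' }
#' Regions are clipped at zero and, when `seq_lengths` is given, at the
#' declared sequence length.
#'
#' @param genes Gene models from [read_refflat()] or an equivalent tibble.
#' @param seq_lengths Optional tibble (`seq_id`, `length`) for right-clipping.
#' @return A tibble with columns `label`, `seq_id`, `start`, `end`,
#'   `gene_id`; zero-length regions are dropped.
#' @export
derive_regions <- function(genes, seq_lengths = NULL) {
  rows <- purrr::pmap_dfr(genes, function(gene_id, seq_id, strand, tx_start,
                                          tx_end, cds_start, cds_end,
                                          exon_starts, exon_ends, ...) {
    plus <- strand == "+"
    tss <- if (plus) tx_start else tx_end - 1L
    out <- list(
      tibble(label = "TSS", start = tss, end = tss + 1L),
      tibble(label = "TSS100", start = tss - 100L, end = tss + 101L),
      if (plus) {
        tibble(label = "R13", start = tss - 1500L, end = tss + 501L)
      } else {
        tibble(label = "R13", start = tss - 500L, end = tss + 1501L)
      },
      tibble(label = "exon", start = exon_starts, end = exon_ends)
    )
    if (length(exon_starts) > 1L) {
      out <- c(out, list(tibble(label = "intron",
                                start = exon_ends[-length(exon_ends)],
                                end = exon_starts[-1L])))
    }
    if (cds_start < cds_end) {
      left <- clip_intervals(exon_starts, exon_ends, tx_start, cds_start)
      right <- clip_intervals(exon_starts, exon_ends, cds_end, tx_end)
      if (nrow(left) > 0L) {
        left$label <- if (plus) "UTR5" else "UTR3"
        out <- c(out, list(left))
      }
      if (nrow(right) > 0L) {
        right$label <- if (plus) "UTR3" else "UTR5"
        out <- c(out, list(right))
      }
    }
    res <- dplyr::bind_rows(out)
    res$seq_id <- seq_id
    res$gene_id <- gene_id
    res
  })
  rows$start <- pmax(0L, as.integer(rows$start))
  if (!is.null(seq_lengths)) {
    rows <- dplyr::left_join(rows, seq_lengths, by = "seq_id")
    rows$end <- as.integer(pmin(rows$end, dplyr::coalesce(rows$length,
                                                          rows$end)))
    rows$length <- NULL
  }
  rows <- dplyr::filter(rows, .data$end > .data$start)
  dplyr::arrange(
    dplyr::select(rows, "label", "seq_id", "start", "end", "gene_id"),
    .data$label, .data$seq_id, .data$start)
}

# Intersect exon intervals with [lo, hi); returns tibble(start, end).
clip_intervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo)
  e <- pmin(ends, hi)
  keep <- e > s
  tibble(start = as.integer(s[keep]), end = as.integer(e[keep]))
}

#' Count clusters co-localizing with each region label
#'
#' For each region label, counts the clusters that intersect at least one
#' region interval by at least 1 bp (half-open coordinates: a cluster ending
#' where a region starts does not overlap it). A cluster overlapping several
#' genes or several intervals of one label is counted once per label.
#'
#' @param clusters Cluster tibble (`seq_id`, `start`, `end`), e.g. `tidy()`
#'   of a [word_cluster()] result.
#' @param regions Region tibble with columns `label`, `seq_id`, `start`,
#'   `end` — from [derive_regions()], or any BED-derived table (e.g. custom
#'   tracks) with a `label` column attached.
#' @return A tibble with columns `label`, `n_overlap`, `n_clusters` (the
#'   total number of clusters, identical across rows).
#' @export
count_region_overlaps <- function(clusters, regions) {
  stopifnot(all(c("label", "seq_id", "start", "end") %in% names(regions)))
  labels <- unique(regions$label)
  n_overlap <- vapply(labels, function(lab) {
    reg <- regions[regions$label == lab, ]
    sum(overlaps_any(clusters, reg))
  }, integer(1))
  tibble(label = labels, n_overlap = unname(n_overlap),
         n_clusters = nrow(clusters))
}

#' Which query intervals overlap any subject interval?
#'
#' @param x,y Interval tibbles (`seq_id`, `start`, `end`, 0-based half-open).
#' @return A logical vector along the rows of `x`.
#' @export
overlaps_any <- function(x, y) {
  out <- logical(nrow(x))
  for (sid in unique(x$seq_id)) {
    xi <- which(x$seq_id == sid)
    ys <- y[y$seq_id == sid, ]
    if (nrow(ys) == 0L) next
    out[xi] <- IRanges::overlapsAny(
      IRanges::IRanges(x$start[xi] + 1L, x$end[xi]),
      IRanges::IRanges(ys$start + 1L, ys$end))
  }
  out
}
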