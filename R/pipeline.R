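#' Detect significant clusters of DNA words in sequences
#'
#' Full k-mer pipeline: segment sequences into N-free contigs, scan for
#' non-overlapping copies of the target words, resolve the maximum-distance
#' threshold under the chosen distance model, assemble maximal runs of copies
#' into clusters and assign each a negative-binomial p-value. Per-cluster GC
#' content and CpG observed/expected ratio are reported alongside, the
#' standard composition statistics for CpG-island style analyses.
#'
#' @param fasta Path to a FASTA file, or a tibble with columns `seq_id`,
#'   `sequence` (uppercase).
#' @param words Character vector of equal-length A/C/G/T target words.
#' @param pattern Alternatively, a single IUPAC-degenerate pattern (e.g.
#'   `"CWG"`); exactly one of `words`/`pattern` must be given.
#' @param model Distance model; one of `"chrom_intersection"` (default, one
#'   threshold per sequence at the observed/expected crossing),
#'   `"genome_intersection"` (one genome-wide threshold and success
#'   probability), `"percentile"` (observed-distribution percentile per
#'   sequence) or `"fixed"`.
#' @param percentile Percentile for the percentile model (default 50).
#' @param max_distance Threshold in bp for the fixed model.
#' @param alpha Significance cutoff on the cluster p-value (default 1e-5).
#' @return An object of class `wordclust` with components `clusters` (all
#'   candidate clusters with p-values and composition), `significant` (those
#'   with `p_value <= alpha`), `stats` (per-sequence N, L_s, p), `thresholds`
#'   (resolved d_max per sequence), `distances`, `contigs`, `words`, `k`,
#'   `mode`, `model`, `alpha` and `n_tested`. Use [tidy()] for the
#'   significant clusters, [glance()] for the per-sequence summary and
#'   [autoplot()] for a cluster map.
#' @export
#' @examples
#' sim <- simulate_word_sequence(seed = 1)
#' res <- word_cluster(sim$seqs, words = "ATGC", model = "genome_intersection")
#' tidy(res)
word_cluster <- function(fasta, words = NULL, pattern = NULL,
                         model = c("chrom_intersection", "genome_intersection",
                                   "percentile", "fixed"),
                         percentile = 50, max_distance = NULL, alpha = 1e-5) {
  model <- match.arg(model)
  if (is.null(words) == is.null(pattern)) {
    abort("supply exactly one of `words` or `pattern`")
  }
  if (!is.null(pattern)) words <- expand_iupac(pattern)
  words <- validate_words(words)
  k <- nchar(words[[1]])
  seqs <- if (is.data.frame(fasta)) {
    stopifnot(all(c("seq_id", "sequence") %in% names(fasta)))
    fasta
  } else {
    read_fasta(fasta)
  }
  contigs <- segment_contigs(seqs)
  if (nrow(contigs) == 0L) abort("no A/C/G/T contigs found in the input")
  occ <- scan_words(contigs, words)
  stats <- word_stats(occ, contigs, k)
  dists <- pair_distances(occ)
  if (nrow(dists) == 0L) {
    abort("fewer than two occurrences on every sequence; nothing to cluster")
  }
  thr <- resolve_dmax(dists, stats, model = model, percentile = percentile,
                      fixed_distance = max_distance)
  cl <- build_clusters(occ, thr)
  cl <- failures_kmer(cl, k)
  cl <- dplyr::left_join(cl, thr[c("seq_id", "p")], by = "seq_id")
  cl$p_value <- if (nrow(cl) > 0) {
    cluster_pvalue(cl$n, cl$n_f, cl$p)
  } else numeric(0)
  cl <- cluster_composition(cl, seqs)
  sig <- filter_significant(cl, alpha)
  structure(list(
    clusters = cl, significant = sig, stats = stats, thresholds = thr,
    distances = dists, contigs = contigs, words = words, k = k,
    mode = "kmer", model = model, alpha = alpha, n_tested = nrow(cl)
  ), class = "wordclust")
}

#' Detect significant clusters of genomic elements
#'
#' Element-mode pipeline: elements come pre-localized as BED intervals, so no
#' scanning is needed. Failures are counted in mean-element-length units
#' (`n_f = ceiling(L_no / L_mean)`) and the success probability is
#' `p = N * L_mean / L_s` per scope; clustering and significance are
#' otherwise identical to k-mer mode.
#'
#' @param elements Path to a BED file or a tibble with columns `seq_id`,
#'   `start`, `end` (0-based half-open).
#' @param seq_lengths Path to a two-column TSV (seq_id, length) or a tibble
#'   with those columns.
#' @inheritParams word_cluster
#' @return An object of class `wordclust` (see [word_cluster()]); element
#'   clusters additionally carry `L_no`.
#' @export
element_cluster <- function(elements, seq_lengths,
                            model = c("chrom_intersection",
                                      "genome_intersection",
                                      "percentile", "fixed"),
                            percentile = 50, max_distance = NULL,
                            alpha = 1e-5) {
  model <- match.arg(model)
  el <- if (is.data.frame(elements)) elements else read_bed(elements)
  if (nrow(el) == 0L) abort("no elements supplied")
  sl <- if (is.data.frame(seq_lengths)) seq_lengths else
    read_seq_lengths(seq_lengths)
  el <- dplyr::arrange(el, .data$seq_id, .data$start, .data$end)
  stats <- element_stats(el, sl)
  dists <- pair_distances(el)
  if (nrow(dists) == 0L) {
    abort("fewer than two elements on every sequence; nothing to cluster")
  }
  thr <- resolve_dmax(dists, stats, model = model, percentile = percentile,
                      fixed_distance = max_distance)
  cl <- build_clusters(el, thr)
  cl <- failures_element(cl, el, thr[c("seq_id", "L_mean")])
  cl <- dplyr::left_join(cl, thr[c("seq_id", "p")], by = "seq_id")
  cl$p_value <- if (nrow(cl) > 0) {
    cluster_pvalue(cl$n, cl$n_f, cl$p)
  } else numeric(0)
  sig <- filter_significant(cl, alpha)
  structure(list(
    clusters = cl, significant = sig, stats = stats, thresholds = thr,
    distances = dists, elements = el, mode = "elements", model = model,
    alpha = alpha, n_tested = nrow(cl)
  ), class = "wordclust")
}

# Per-cluster base composition: GC fraction and CpG observed/expected ratio
# O/E = (#CpG * L_c) / (#C * #G), the standard CpG-island statistics.
cluster_composition <- function(clusters, seqs) {
  if (nrow(clusters) == 0L) {
    clusters$gc <- numeric(0)
    clusters$cpg_oe <- numeric(0)
    return(clusters)
  }
  seq_map <- stats::setNames(seqs$sequence, seqs$seq_id)
  frag <- stringr::str_sub(seq_map[clusters$seq_id],
                           clusters$start + 1L, clusters$end)
  nC <- stringr::str_count(frag, stringr::fixed("C"))
  nG <- stringr::str_count(frag, stringr::fixed("G"))
  nCpG <- stringr::str_count(frag, stringr::fixed("CG"))
  clusters$gc <- (nC + nG) / clusters$L_c
  clusters$cpg_oe <- ifelse(nC > 0 & nG > 0,
                            nCpG * clusters$L_c / (nC * nG), NA_real_)
  clusters
}

#' @export
print.wordclust <- function(x, ...) {
  cat("Word/element cluster analysis (", x$mode, " mode, ",
      x$model, " distance model)\n", sep = "")
  if (x$mode == "kmer") {
    cat("  target words: ", paste(x$words, collapse = ", "),
        " (k = ", x$k, ")\n", sep = "")
  }
  cat("  sequences: ", nrow(x$stats),
      "; clusters tested: ", x$n_tested,
      "; significant at alpha = ", format(x$alpha), ": ",
      nrow(x$significant), "\n", sep = "")
  thr <- x$thresholds
  cat("  resolved d_max (bp): ",
      paste(paste0(thr$seq_id, "=", thr$d_max), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy the significant clusters of a cluster analysis
#'
#' @param x A `wordclust` object.
#' @param all If `TRUE`, return every tested cluster rather than only the
#'   significant ones.
#' @param ... Unused.
#' @return A tibble of clusters (`seq_id`, `start`, `end`, `n`, `L_c`,
#'   `n_f`, `p_value`, plus composition columns in k-mer mode).
#' @method tidy wordclust
#' @export
tidy.wordclust <- function(x, all = FALSE, ...) {
  as_tibble(if (all) x$clusters else x$significant)
}

#' One-row-per-sequence summary of a cluster analysis
#'
#' Reports, per sequence, the number of significant clusters, their mean
#' length with standard deviation, total coverage, mean GC and CpG O/E (k-mer
#' mode), the resolved distance threshold and the success probability.
#'
#' @param x A `wordclust` object.
#' @param ... Unused.
#' @return A tibble with one row per sequence.
#' @method glance wordclust
#' @export
glance.wordclust <- function(x, ...) {
  sig <- x$significant
  base <- dplyr::group_by(sig, .data$seq_id)
  smry <- dplyr::summarise(base,
    n_clusters = dplyr::n(),
    mean_length = mean(.data$L_c),
    sd_length = ifelse(dplyr::n() > 1, sd(.data$L_c), NA_real_),
    coverage_bp = sum(.data$L_c),
    mean_gc = if ("gc" %in% names(sig)) mean(.data$gc) else NA_real_,
    mean_cpg_oe = if ("cpg_oe" %in% names(sig)) {
      mean(.data$cpg_oe, na.rm = TRUE)
    } else NA_real_,
    .groups = "drop")
  out <- dplyr::left_join(x$thresholds[c("seq_id", "d_max", "p")], smry,
                          by = "seq_id")
  out$n_clusters <- dplyr::coalesce(out$n_clusters, 0L)
  out$coverage_bp <- dplyr::coalesce(out$coverage_bp, 0L)
  out$n_tested <- x$n_tested
  out$alpha <- x$alpha
  as_tibble(out)
}
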