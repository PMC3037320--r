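#' Assemble clusters of occurrences under a maximum distance
#'
#' A cluster is a maximal run of consecutive occurrences in which every
#' inter-copy distance is at or below the threshold ("equal or below", so a
#' tie at `d_max` stays inside the cluster). Runs never cross contig
#' boundaries; singletons are discarded because the significance test is
#' degenerate for a lone copy (its first appearance is trivial).
#'
#' @param occurrences Sorted occurrence/element tibble with columns `seq_id`,
#'   `start`, `end` (and `contig_start` in k-mer mode).
#' @param d_max Either a single threshold in bp, or a tibble with columns
#'   `seq_id`, `d_max` from [resolve_dmax()]. Sequences with `NA` thresholds
#'   are skipped.
#' @return A tibble of clusters with columns `seq_id`, `start`, `end`
#'   (0-based half-open span from the start of the first member to the end of
#'   the last), `n` (member count) and `L_c` (= end - start).
#' @export
build_clusters <- function(occurrences, d_max) {
  grp <- intersect(c("seq_id", "contig_start"), names(occurrences))
  occ <- dplyr::arrange(occurrences, .data$seq_id, .data$start)
  if (is.data.frame(d_max)) {
    occ <- dplyr::inner_join(occ, d_max[c("seq_id", "d_max")], by = "seq_id")
  } else {
    if (!is.numeric(d_max) || length(d_max) != 1L || d_max < 1) {
      abort("d_max must be a single threshold >= 1 bp or a resolve_dmax() table")
    }
    occ$d_max <- as.integer(d_max)
  }
  occ <- dplyr::filter(occ, !is.na(.data$d_max))
  if (nrow(occ) == 0L) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  n = integer(), L_c = integer()))
  }
  occ <- dplyr::group_by(occ, dplyr::across(dplyr::all_of(grp)))
  occ <- dplyr::mutate(occ,
    d_prev = pmax(1L, as.integer(.data$start - dplyr::lag(.data$end) + 1L)),
    new_run = is.na(.data$d_prev) | .data$d_prev > .data$d_max,
    run = cumsum(.data$new_run))
  occ <- dplyr::group_by(occ,
    dplyr::across(dplyr::all_of(c(grp, "run"))))
  cl <- dplyr::summarise(occ,
    start = min(.data$start), end = max(.data$end), n = dplyr::n(),
    .groups = "drop")
  cl <- dplyr::filter(cl, .data$n >= 2L)
  cl <- dplyr::arrange(cl, .data$seq_id, .data$start)
  tibble(seq_id = cl$seq_id, start = cl$start, end = cl$end,
         n = cl$n, L_c = cl$end - cl$start)
}

#' Failures inside a k-mer cluster
#'
#' Within a cluster of length `L_c` holding `n` non-overlapping copies of a
#' k-mer, the no-target content is `n_f = L_c - n k` bases — e.g. for target
#' ATGC the cluster ATGCATGC gives 0 failures and ATGCAATGC gives 1.
#'
#' @param clusters Cluster tibble from [build_clusters()].
#' @param k Word length.
#' @return The input with an `n_f` column added.
#' @export
failures_kmer <- function(clusters, k) {
  n_f <- clusters$L_c - clusters$n * as.integer(k)
  if (any(n_f < 0L)) {
    abort("negative failure count: cluster members overlap, which the non-overlapping scan forbids")
  }
  dplyr::mutate(clusters, n_f = as.integer(n_f))
}

#' Failures inside an element cluster
#'
#' For genomic elements the no-element content of a cluster is measured in
#' mean-element-length units: `n_f = ceiling(L_no / L_mean)`, where `L_no` is
#' the number of cluster bases not covered by any element (overlaps between
#' elements are collapsed before counting coverage).
#'
#' @param clusters Cluster tibble from [build_clusters()].
#' @param elements Element tibble (`seq_id`, `start`, `end`).
#' @param L_mean Mean element length of the analysis scope, in bp; a single
#'   number or a tibble with columns `seq_id`, `L_mean` (e.g. the
#'   [resolve_dmax()] output in element mode).
#' @return The input with `L_no` and `n_f` columns added.
#' @export
failures_element <- function(clusters, elements, L_mean) {
  if (is.data.frame(L_mean)) {
    cl <- dplyr::inner_join(clusters, L_mean[c("seq_id", "L_mean")],
                            by = "seq_id")
  } else {
    if (!is.numeric(L_mean) || L_mean <= 0) abort("L_mean must be > 0")
    cl <- dplyr::mutate(clusters, L_mean = as.numeric(L_mean))
  }
  covered <- covered_bases(cl, elements)
  L_no <- cl$L_c - covered
  if (any(L_no < 0)) abort("element coverage exceeds cluster length")
  out <- dplyr::mutate(cl, L_no = as.integer(L_no),
                       n_f = as.integer(ceiling(L_no / .data$L_mean)))
  dplyr::select(out, -"L_mean")
}

# Bases of each cluster covered by the union of the elements on its sequence.
covered_bases <- function(clusters, elements) {
  out <- numeric(nrow(clusters))
  for (sid in unique(clusters$seq_id)) {
    ci <- which(clusters$seq_id == sid)
    el <- elements[elements$seq_id == sid, ]
    if (nrow(el) == 0L) next
    red <- IRanges::reduce(IRanges::IRanges(el$start + 1L, el$end))
    cl_ir <- IRanges::IRanges(clusters$start[ci] + 1L, clusters$end[ci])
    hits <- IRanges::findOverlaps(cl_ir, red)
    if (length(hits) == 0L) next
    w <- IRanges::width(IRanges::pintersect(
      cl_ir[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[ci[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

#' Per-sequence statistics for genomic elements
#'
#' The success probability for elements is `p = N * L_mean / L_s`: the
#' fraction of the sequence expected to be covered by elements. Unlike k-mer
#' mode, `L_s` is the full declared sequence length (elements are annotated
#' on complete assemblies, gaps included).
#'
#' @param elements Element tibble (`seq_id`, `start`, `end`).
#' @param seq_lengths Tibble with columns `seq_id`, `length` (see
#'   [read_seq_lengths()]).
#' @return A tibble with one row per sequence: `seq_id`, `N`, `L_s`,
#'   `len_sum`, `L_mean`, `p`. Errors when p >= 1 (elements denser than the
#'   model allows) or when an element lies outside its declared sequence.
#' @export
element_stats <- function(elements, seq_lengths) {
  stopifnot(all(c("seq_id", "length") %in% names(seq_lengths)))
  missing <- setdiff(unique(elements$seq_id), seq_lengths$seq_id)
  if (length(missing) > 0L) {
    abort(paste0("no declared length for sequence(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(elements) == 0L) abort("no elements supplied")
  st <- dplyr::group_by(elements, .data$seq_id)
  st <- dplyr::summarise(st, N = dplyr::n(),
                         len_sum = sum(.data$end - .data$start),
                         .groups = "drop")
  st <- dplyr::inner_join(st, seq_lengths, by = "seq_id")
  over <- dplyr::group_by(elements, .data$seq_id)
  over <- dplyr::summarise(over, max_end = max(.data$end), .groups = "drop")
  over <- dplyr::inner_join(over, seq_lengths, by = "seq_id")
  if (any(over$max_end > over$length)) {
    bad <- over$seq_id[over$max_end > over$length][1]
    abort(paste0("element extends past the declared length of '", bad, "'"))
  }
  st$L_s <- as.integer(st$length)
  st$L_mean <- st$len_sum / st$N
  st$p <- st$N * st$L_mean / st$L_s
  if (any(st$p >= 1)) {
    bad <- st$seq_id[st$p >= 1][1]
    abort(paste0("sequence '", bad, "': element success probability >= 1 ",
                 "(elements cover the whole sequence); the model requires 0 < p < 1"))
  }
  dplyr::select(st, "seq_id", "N", "L_s", "len_sum", "L_mean", "p")
}

#' Negative-binomial cluster p-value
#'
#' The significance of a cluster with `n` members and `n_f` failures is the
#' probability of seeing at most `n_f` failures before the (n-1)-th success
#' under success probability `p` — the cumulative negative binomial with
#' r = n - 1 successes (the first member of a cluster is trivial, so it is
#' not counted as a success to be waited for):
#' P(X <= n_f), pmf C(n_f + r - 1, r - 1) p^r (1-p)^(n_f). Small p-values
#' indicate clusters far denser than chance.
#'
#' @param n Member count(s), >= 2.
#' @param n_f Failure count(s), >= 0.
#' @param p Success probability in (0, 1) (recycled).
#' @return p-value(s) in (0, 1].
#' @export
#' @examples
#' cluster_pvalue(2, 0, 0.5)  # geometric case: equals p
cluster_pvalue <- function(n, n_f, p) {
  if (any(n < 2)) abort("cluster p-values require n >= 2 members")
  if (any(n_f < 0)) abort("failure counts must be >= 0")
  if (any(p <= 0 | p >= 1)) abort("success probability p must lie in (0, 1)")
  pnbinom(n_f, size = n - 1, prob = p)
}

#' Filter clusters by significance
#'
#' @param clusters Cluster tibble with a `p_value` column.
#' @param alpha Significance threshold in (0, 1]; clusters with
#'   `p_value <= alpha` are kept, in their original order. The conventional
#'   default is 1e-5. No multiple-testing correction is applied; the number
#'   of clusters tested is reported by [glance()] so a Bonferroni factor can
#'   be applied externally.
#' @return The qualifying subset of `clusters`.
#' @export
filter_significant <- function(clusters, alpha = 1e-5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort("alpha must lie in (0, 1]")
  }
  dplyr::filter(clusters, .data$p_value <= alpha)
}
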