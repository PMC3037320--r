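#' Distances between consecutive occurrences
#'
#' The distance between two consecutive copies is the start coordinate of the
#' downstream copy minus the end coordinate of the upstream copy in 1-based
#' inclusive arithmetic — equivalently, intervening bases + 1 — so two
#' abutting copies are at distance 1. Distances are computed strictly within
#' a contig (when a `contig_start` column is present) and never across
#' sequences. Overlapping or bookended input intervals (possible in element
#' mode, where real annotations can overlap) are clamped to the minimum
#' distance 1.
#'
#' @param occurrences Tibble of occurrences ([scan_words()]) or elements
#'   ([read_bed()]) with columns `seq_id`, `start`, `end`.
#' @return A tibble with columns `seq_id` and `d` (bp, >= 1), one row per
#'   consecutive pair; a group with a single occurrence contributes no rows.
#' @export
pair_distances <- function(occurrences) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(occurrences)))
  grp <- intersect(c("seq_id", "contig_start"), names(occurrences))
  occ <- dplyr::arrange(occurrences, .data$seq_id, .data$start)
  occ <- dplyr::group_by(occ, dplyr::across(dplyr::all_of(grp)))
  occ <- dplyr::mutate(occ,
    d = pmax(1L, as.integer(dplyr::lead(.data$start) - .data$end + 1L)))
  occ <- dplyr::ungroup(occ)
  occ <- dplyr::filter(occ, !is.na(.data$d))
  dplyr::select(occ, "seq_id", "d")
}

#' Expected inter-copy distance frequency under the random (geometric) model
#'
#' If target copies fall independently with success probability p at each
#' slot, the distance to the next copy is memoryless and geometric:
#' P(d) = p (1 - p)^(d - 1), d >= 1.
#'
#' @param d Distance(s), bp >= 1.
#' @param p Success probability in (0, 1).
#' @return The expected relative frequency at each `d`.
#' @export
#' @examples
#' expected_distance_pmf(1, 0.5)
expected_distance_pmf <- function(d, p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    abort("success probability p must lie in (0, 1)")
  }
  if (any(d < 1)) abort("distances must be >= 1")
  dgeom(d - 1, prob = p)
}

#' Observed-vs-expected distance distribution
#'
#' Tabulates observed inter-copy distances and attaches the matched expected
#' geometric curve. For genomic elements, distances can first be converted to
#' mean-element-length "failure units" via `unit` so the geometric law is
#' taken over failure counts rather than base pairs.
#'
#' @param distances Tibble with column `d` (from [pair_distances()]) or a
#'   numeric vector of distances.
#' @param p Success probability for the expected curve.
#' @param unit Distance unit in bp (default 1; element mode passes the mean
#'   element length, and distances are binned by `ceiling(d / unit)`).
#' @return A tibble of class `wordclust_dist` with columns `distance` (in
#'   units of `unit`), `count`, `obs_freq`, `exp_freq`; attributes `p`,
#'   `total` and `unit`.
#' @export
distance_distribution <- function(distances, p, unit = 1) {
  d <- if (is.data.frame(distances)) distances$d else distances
  if (length(d) < 1L) abort("empty distance distribution")
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    abort("success probability p must lie in (0, 1)")
  }
  u <- as.integer(ceiling(d / unit))
  tab <- dplyr::count(tibble(distance = u), .data$distance, name = "count")
  tab$obs_freq <- tab$count / length(d)
  tab$exp_freq <- expected_distance_pmf(tab$distance, p)
  structure(tab,
            p = p, total = length(d), unit = unit,
            class = c("wordclust_dist", class(tab)))
}

#' Percentile of the observed distance distribution
#'
#' Nearest-rank percentile: the smallest observed distance whose cumulative
#' frequency reaches q/100. `q = 50` is the median, the classic default
#' threshold for CpG-island style clustering.
#'
#' @param distances Tibble with column `d`, numeric vector, or a
#'   `wordclust_dist` distribution.
#' @param q Percentile in (0, 100].
#' @return The distance at the given percentile (same units as the input).
#' @export
percentile_distance <- function(distances, q = 50) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100) {
    abort("percentile q must lie in (0, 100]")
  }
  d <- if (inherits(distances, "wordclust_dist")) {
    rep(distances$distance, distances$count)
  } else if (is.data.frame(distances)) distances$d else distances
  if (length(d) < 1L) abort("empty distance distribution")
  sorted <- sort(d)
  sorted[max(1L, ceiling(q / 100 * length(d)))]
}

#' Intersection of the observed and expected distance distributions
#'
#' The crossing point is the "reversal point" separating intra-cluster from
#' inter-cluster distances: below it, more copies lie at that distance than
#' expected by chance. The scan runs d = 1, 2, ... over the observed support
#' and returns the first distance where the normalized observed frequency
#' falls below the expected geometric curve after at least one distance with
#' nonzero observed count at or above the curve. When no such crossing exists
#' (flat or chance-like data) the median is returned as its approximation,
#' with a warning of class `wordclust_fallback`.
#'
#' @param dist A `wordclust_dist` distribution from [distance_distribution()].
#' @return The crossing distance (in the distribution's units).
#' @export
intersection_distance <- function(dist) {
  stopifnot(inherits(dist, "wordclust_dist"))
  p <- attr(dist, "p")
  total <- attr(dist, "total")
  # scan one bin past the observed support: a distribution still above the
  # expected curve at its largest observed distance crosses right after it
  dmax <- max(dist$distance) + 1L
  cnt <- integer(dmax)
  cnt[dist$distance] <- dist$count
  obs <- cnt / total
  expf <- expected_distance_pmf(seq_len(dmax), p)
  seen_above <- FALSE
  for (d in seq_len(dmax)) {
    if (seen_above && obs[d] < expf[d]) return(d)
    if (cnt[d] > 0L && obs[d] >= expf[d]) seen_above <- TRUE
  }
  warn(paste0("no observed/expected crossing found; falling back to the ",
              "median distance"),
       class = "wordclust_fallback")
  percentile_distance(dist, 50)
}

#' Resolve the maximum-distance threshold for each sequence
#'
#' Four distance models are available. `percentile` and `chrom_intersection`
#' resolve one threshold and success probability per sequence;
#' `genome_intersection` merges the distance distributions of all sequences
#' and uses a single genome-wide threshold and probability (totals summed
#' over sequences); `fixed` applies a user threshold with per-sequence
#' probabilities. For genomic elements (detected by an `L_mean` column in
#' `stats`) the intersection models operate in mean-element-length failure
#' units and the resolved threshold is converted back to bp.
#'
#' @param distances Tibble with columns `seq_id`, `d` from [pair_distances()].
#' @param stats Per-sequence statistics: [word_stats()] output (k-mer mode) or
#'   [element_stats()] output (element mode).
#' @param model One of `"chrom_intersection"` (default), `"genome_intersection"`,
#'   `"percentile"`, `"fixed"`.
#' @param percentile Percentile for the `percentile` model (default 50, the
#'   median).
#' @param fixed_distance Threshold in bp for the `fixed` model.
#' @return A tibble with one row per sequence: `seq_id`, `d_max` (bp; `NA`
#'   for sequences with no distances), `p`, `scope` (`"sequence"` or
#'   `"genome"`), and `L_mean` in element mode.
#' @export
resolve_dmax <- function(distances, stats,
                         model = c("chrom_intersection", "genome_intersection",
                                   "percentile", "fixed"),
                         percentile = 50, fixed_distance = NULL) {
  model <- match.arg(model)
  element_mode <- "L_mean" %in% names(stats)

  one_seq <- function(sid) {
    d <- distances$d[distances$seq_id == sid]
    row <- stats[stats$seq_id == sid, ]
    if (length(d) == 0L) return(NA_integer_)
    switch(model,
      percentile = percentile_distance(d, percentile),
      fixed = as.integer(fixed_distance),
      chrom_intersection = {
        unit <- if (element_mode) row$L_mean else 1
        dd <- distance_distribution(d, row$p, unit = unit)
        as.integer(floor(intersection_distance(dd) * unit))
      }
    )
  }

  if (model == "fixed") {
    if (is.null(fixed_distance) || !is.numeric(fixed_distance) ||
        fixed_distance < 1) {
      abort("the fixed distance model requires fixed_distance >= 1 bp")
    }
  }

  if (model == "genome_intersection") {
    gstats <- genome_stats(stats)
    unit <- if (element_mode) gstats$L_mean else 1
    dd <- distance_distribution(distances$d, gstats$p, unit = unit)
    d_max <- as.integer(floor(intersection_distance(dd) * unit))
    out <- tibble(seq_id = stats$seq_id, d_max = d_max, p = gstats$p,
                  scope = "genome")
    if (element_mode) out$L_mean <- gstats$L_mean
    return(out)
  }

  out <- tibble(
    seq_id = stats$seq_id,
    d_max = unname(vapply(stats$seq_id, one_seq, integer(1))),
    p = stats$p,
    scope = "sequence"
  )
  if (element_mode) out$L_mean <- stats$L_mean
  out
}

#' Pool per-sequence statistics into genome-wide totals
#'
#' Sums occurrence counts and effective lengths over sequences and recomputes
#' the success probability at genome scope: for k-mers
#' p = N / ((L_s - k + 1) - N(k - 1)) on the pooled slot count; for elements
#' p = N * L_mean / L_s with L_mean the pooled mean element length.
#'
#' @param stats Per-sequence statistics from [word_stats()] or
#'   [element_stats()].
#' @return A one-row tibble with the pooled `N`, `L_s`, `p` (and `L_mean`,
#'   `len_sum` in element mode; `slots`, `k` in k-mer mode).
#' @export
genome_stats <- function(stats) {
  if ("L_mean" %in% names(stats)) {
    N <- sum(stats$N)
    L_s <- sum(stats$L_s)
    L_mean <- sum(stats$len_sum) / N
    p <- N * L_mean / L_s
    if (p >= 1) {
      abort(paste0("genome-wide element success probability ", signif(p, 3),
                   " >= 1; elements cover too much of the sequence"))
    }
    return(tibble(N = N, L_s = L_s, len_sum = sum(stats$len_sum),
                  L_mean = L_mean, p = p))
  }
  k <- stats$k[[1]]
  N <- sum(stats$N)
  slots <- sum(stats$slots)
  denom <- slots - N * (k - 1L)
  if (denom <= 0L) abort("non-positive pooled k-mer slot count")
  p <- N / denom
  if (p >= 1) {
    abort(paste0("genome-wide success probability ", signif(p, 3), " >= 1"))
  }
  tibble(N = N, L_s = sum(stats$L_s), slots = slots, k = k, p = p)
}
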