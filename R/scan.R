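IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Expand an IUPAC-degenerate pattern into concrete words
#'
#' A degenerate pattern such as `"CWG"` (W = A or T) stands for the word set
#' \{CAG, CTG\}; each degenerate code multiplies the set by its cardinality.
#'
#' @param pattern A string over the IUPAC nucleotide alphabet.
#' @return A sorted character vector of the concrete A/C/G/T words matching
#'   the pattern.
#' @export
#' @examples
#' expand_iupac("CWG")
expand_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L) abort("empty pattern")
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_EXPANSION))
  if (length(bad) > 0L) {
    abort(paste0("invalid IUPAC code(s) in pattern: ",
                 paste(unique(bad), collapse = ", ")))
  }
  words <- Reduce(function(acc, ch) {
    as.vector(outer(acc, IUPAC_EXPANSION[[ch]], paste0))
  }, chars, init = "")
  sort(unique(words))
}

validate_words <- function(words) {
  stopifnot(is.character(words), length(words) >= 1L)
  words <- unique(toupper(words))
  if (any(grepl("[^ACGT]", words))) {
    abort("target words must be concrete A/C/G/T strings; expand degenerate patterns with expand_iupac()")
  }
  k <- unique(nchar(words))
  if (length(k) != 1L) {
    abort("all target words must have the same length; mixed-length word sets are not supported")
  }
  if (k < 1L) abort("target words must have length >= 1")
  words
}

#' Greedy non-overlapping scan for target words
#'
#' Scans each contig left to right: when the window starting at a position
#' equals any target word an occurrence is emitted and the scan resumes at the
#' end of that word, so copies never overlap; otherwise the window advances by
#' one base. Only the literal words given are searched — users wanting both
#' strands supply both words.
#'
#' @param contigs A contig tibble from [segment_contigs()].
#' @param words Character vector of equal-length A/C/G/T words (see
#'   [expand_iupac()] for degenerate patterns).
#' @return A tibble of occurrences with columns `seq_id`, `contig_start`,
#'   `start`, `end` (0-based half-open, absolute in the parent sequence) and
#'   `word`.
#' @export
#' @examples
#' ctg <- segment_contigs(tibble::tibble(seq_id = "s", sequence = "ATGCATGC"))
#' scan_words(ctg, "ATGC")
scan_words <- function(contigs, words) {
  words <- validate_words(words)
  k <- nchar(words[[1]])
  empty <- tibble(seq_id = character(), contig_start = integer(),
                  start = integer(), end = integer(), word = character())
  if (nrow(contigs) == 0L) return(empty)
  res <- purrr::pmap_dfr(
    contigs[c("seq_id", "start", "bases")],
    function(seq_id, start, bases) {
      if (nchar(bases) < k) return(empty)
      cand <- unlist(lapply(words, function(w) {
        m <- stringi::stri_locate_all_fixed(bases, w, overlap = TRUE)[[1]]
        m[!is.na(m[, 1]), 1]
      }), use.names = FALSE)
      if (length(cand) == 0L) return(empty)
      sel <- greedy_select(sort(cand), k)
      abs_start <- as.integer(start + sel - 1L)
      tibble(
        seq_id = seq_id,
        contig_start = as.integer(start),
        start = abs_start,
        end = abs_start + k,
        word = stringr::str_sub(bases, sel, sel + k - 1L)
      )
    }
  )
  dplyr::arrange(res, .data$seq_id, .data$start)
}

# Greedy left-to-right selection of non-overlapping candidate starts
# (1-based); equivalent to advancing the scan window by k after each hit.
greedy_select <- function(starts, k) {
  sel <- integer(length(starts))
  m <- 0L
  cursor <- 0L  # last selected end, 1-based inclusive
  for (s in starts) {
    if (s > cursor) {
      m <- m + 1L
      sel[m] <- s
      cursor <- s + k - 1L
    }
  }
  sel[seq_len(m)]
}

#' Per-sequence occurrence counts and success probability
#'
#' For a word of length k, the success probability is the number of
#' non-overlapping target occurrences divided by the number of k-mer slots in
#' the sequence: p = N / ((L_s - k + 1) - N (k - 1)), where the N(k-1)
#' positions swallowed by non-overlapping copies are removed from the slot
#' count. Slots are counted strictly inside contigs, so L_s is the summed
#' contig length and (L_s - k + 1) is accumulated per contig as
#' max(0, contig_length - k + 1).
#'
#' @param occurrences Occurrence tibble from [scan_words()].
#' @param contigs Contig tibble the occurrences were scanned from.
#' @param k Word length.
#' @return A tibble with one row per sequence: `seq_id`, `N`, `L_s`, `slots`,
#'   `k`, `p`. Errors if any sequence yields a non-positive denominator or
#'   p >= 1 (degenerate input too word-dense for the model).
#' @export
word_stats <- function(occurrences, contigs, k) {
  k <- as.integer(k)
  per_contig <- dplyr::group_by(contigs, .data$seq_id)
  cs <- dplyr::summarise(per_contig,
    L_s = sum(.data$end - .data$start),
    slots = sum(pmax(0L, (.data$end - .data$start) - k + 1L)),
    .groups = "drop")
  occ <- dplyr::count(occurrences, .data$seq_id, name = "N")
  stats <- dplyr::left_join(cs, occ, by = "seq_id")
  stats$N <- dplyr::coalesce(stats$N, 0L)
  stats$k <- k
  denom <- stats$slots - stats$N * (k - 1L)
  bad <- which(denom <= 0L)
  if (length(bad) > 0L) {
    abort(paste0("sequence '", stats$seq_id[bad[1]],
                 "': non-positive k-mer slot count (", denom[bad[1]],
                 "); sequence too short or too word-dense for the model"))
  }
  stats$p <- stats$N / denom
  sat <- which(stats$p >= 1)
  if (length(sat) > 0L) {
    abort(paste0("sequence '", stats$seq_id[sat[1]], "': success probability ",
                 signif(stats$p[sat[1]], 3),
                 " >= 1; the negative-binomial model requires 0 < p < 1"))
  }
  dplyr::select(stats, "seq_id", "N", "L_s", "slots", "k", "p")
}
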