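#' Simulate a sequence with planted word clusters
#'
#' Generates a random A/C/G/T sequence containing designated cluster windows,
#' inside which target-word copies are planted with small uniform gaps, and a
#' sparse Bernoulli background of isolated copies elsewhere. Filler bases
#' that happen to spell a target word are mutated away where feasible, so the
#' scan recovers exactly the planted copies; the returned truth tables record
#' every realized occurrence and the realized span of each window.
#'
#' Defaults describe the benchmark condition used throughout the package's
#' tests: a 50-kb sequence, eight windows of ten copies with 1-5 bp gaps
#' (inter-copy distances 2-6 bp) and a background of 0.5 words/kb kept at
#' least 100 bp away from any window.
#'
#' @param seq_length Sequence length in bp.
#' @param words Target word set (equal length, A/C/G/T).
#' @param windows Optional tibble (`start`, `end`, `copies`) of disjoint
#'   cluster windows; when `NULL`, `n_windows` windows of `copies` copies are
#'   spaced evenly along the sequence.
#' @param n_windows,copies Used only when `windows` is `NULL`.
#' @param gap_range Integer range (bp) for the gaps between planted copies
#'   inside a window; a gap of g puts consecutive copies at distance g + 1.
#' @param background_rate Expected background words per kb outside windows.
#' @param window_margin Minimum distance (bp) between a background copy and
#'   any window.
#' @param seq_id Sequence name.
#' @param seed Integer seed; the generator touches no global random state.
#' @return A list with `seqs` (tibble `seq_id`, `sequence`, `length`),
#'   `occurrences` (truth tibble `seq_id`, `start`, `end`, `word`, `origin`)
#'   and `windows` (truth tibble `seq_id`, `start`, `end`, `copies`,
#'   `span_start`, `span_end` — the realized first-to-last copy span).
#' @export
simulate_word_sequence <- function(seq_length = 50000, words = "ATGC",
                                   windows = NULL, n_windows = 8, copies = 10,
                                   gap_range = c(1, 5),
                                   background_rate = 0.5,
                                   window_margin = 100,
                                   seq_id = "sim1", seed) {
  if (missing(seed)) abort("an explicit integer seed is required")
  words <- validate_words(words)
  k <- nchar(words[[1]])
  withr::local_seed(seed)

  if (is.null(windows)) {
    win_len <- copies * k + (copies - 1L) * gap_range[2] + k
    gap_between <- floor((seq_length - n_windows * win_len) / (n_windows + 1))
    if (gap_between < 2 * window_margin) {
      abort("sequence too short for the requested windows")
    }
    starts <- round(gap_between + (seq_len(n_windows) - 1) *
                      (win_len + gap_between))
    windows <- tibble(start = as.integer(starts),
                      end = as.integer(starts + win_len),
                      copies = as.integer(copies))
  }
  windows <- dplyr::arrange(as_tibble(windows), .data$start)
  if (any(windows$end > seq_length) ||
      any(windows$start[-1] < windows$end[-nrow(windows)])) {
    abort("cluster windows must be disjoint and inside the sequence")
  }
  if (any(windows$copies * k +
          (windows$copies - 1L) * gap_range[1] > windows$end - windows$start)) {
    abort("a window is too short for its requested number of copies")
  }

  base <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE)

  occ <- list()
  for (i in seq_len(nrow(windows))) {
    pos <- windows$start[i]  # 0-based
    for (j in seq_len(windows$copies[i])) {
      w <- sample(words, 1L)
      if (pos + k > windows$end[i]) {
        abort("window overflow while planting copies; widen the window or shrink gap_range")
      }
      base[(pos + 1):(pos + k)] <- strsplit(w, "")[[1]]
      occ[[length(occ) + 1L]] <- tibble(start = pos, word = w,
                                        origin = paste0("window", i))
      if (j < windows$copies[i]) {
        pos <- pos + k + sample(gap_range[1]:gap_range[2], 1L)
      }
    }
  }

  # Bernoulli background outside the margined windows, non-overlapping
  cand <- which(stats::runif(seq_length) < background_rate / 1000) - 1L
  cand <- cand[cand + k <= seq_length]
  if (length(cand) > 0L && nrow(windows) > 0L) {
    near <- vapply(cand, function(s) {
      any(s + k > windows$start - window_margin &
            s < windows$end + window_margin)
    }, logical(1))
    cand <- cand[!near]
  }
  last_end <- -1L
  for (s in cand) {
    if (s < last_end) next
    w <- sample(words, 1L)
    base[(s + 1):(s + k)] <- strsplit(w, "")[[1]]
    occ[[length(occ) + 1L]] <- tibble(start = s, word = w,
                                      origin = "background")
    last_end <- s + k
  }

  if (length(occ) == 0L) {
    occ <- tibble(start = integer(), word = character(), origin = character())
  }
  occ <- dplyr::arrange(dplyr::bind_rows(occ), .data$start)
  occ$end <- occ$start + k
  base <- scrub_accidental_matches(base, words, k, occ$start)

  spans <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    m <- occ[occ$origin == paste0("window", i), ]
    tibble(seq_id = seq_id, start = windows$start[i], end = windows$end[i],
           copies = windows$copies[i],
           span_start = min(m$start), span_end = max(m$end))
  })

  list(
    seqs = tibble(seq_id = seq_id,
                  sequence = paste(base, collapse = ""),
                  length = seq_length),
    occurrences = tibble(seq_id = seq_id, start = occ$start, end = occ$end,
                         word = occ$word, origin = occ$origin),
    windows = spans
  )
}

# Mutate filler bases so the only target-word matches are the planted ones.
# Positions inside planted copies are immutable; a match with no mutable base
# is left in place (rare, and only possible when copies abut).
scrub_accidental_matches <- function(base, words, k, planted_starts) {
  planted_cov <- logical(length(base))
  for (s in planted_starts) planted_cov[(s + 1):(s + k)] <- TRUE
  planted_set <- planted_starts
  for (iter in 1:25) {
    s_chr <- paste(base, collapse = "")
    cand <- unlist(lapply(words, function(w) {
      m <- stringi::stri_locate_all_fixed(s_chr, w, overlap = TRUE)[[1]]
      m[!is.na(m[, 1]), 1]
    }), use.names = FALSE) - 1L
    accidental <- setdiff(cand, planted_set)
    if (length(accidental) == 0L) break
    fixed_any <- FALSE
    for (s in accidental) {
      mut <- which(!planted_cov[(s + 1):(s + k)]) + s
      if (length(mut) == 0L) next
      pos <- if (length(mut) == 1L) mut else sample(mut, 1L)
      base[pos] <- sample(setdiff(c("A", "C", "G", "T"), base[pos]), 1L)
      fixed_any <- TRUE
    }
    if (!fixed_any) break
  }
  base
}

#' Simulate genomic elements with planted cluster blocks
#'
#' Lays out fixed-length elements on a virtual sequence: each requested
#' cluster block places `n` elements separated by `gap` bp starting at
#' `start`; remaining background elements are scattered in the free space
#' with at least `background_gap` bp between them and away from the blocks.
#' With no blocks requested the layout degenerates to uniform gaps.
#'
#' @param seq_length Virtual sequence length (bp).
#' @param clusters Tibble (`start`, `n`, `gap`) of cluster blocks; may have
#'   zero rows.
#' @param n_background Number of isolated background elements.
#' @param element_length Length of every element (bp); the mean element
#'   length of the output is therefore exactly this value.
#' @param background_gap Minimum gap between background elements (bp).
#' @param seq_id Sequence name.
#' @param seed Integer seed.
#' @return A list with `elements` (BED-like tibble `seq_id`, `start`, `end`,
#'   `label`), `truth_clusters` (tibble `seq_id`, `start`, `end`, `n` giving
#'   each block's realized span) and `seq_lengths` (tibble `seq_id`,
#'   `length`).
#' @export
simulate_elements <- function(seq_length = 200000,
                              clusters = tibble(start = c(10000, 60000,
                                                          120000),
                                                n = c(5, 8, 6),
                                                gap = c(250, 400, 300)),
                              n_background = 10, element_length = 300,
                              background_gap = 5000, seq_id = "sim1", seed) {
  if (missing(seed)) abort("an explicit integer seed is required")
  withr::local_seed(seed)
  clusters <- as_tibble(clusters)
  el <- list()
  spans <- list()
  for (i in seq_len(nrow(clusters))) {
    st <- clusters$start[i]
    n <- clusters$n[i]
    gap <- clusters$gap[i]
    starts <- st + (seq_len(n) - 1) * (element_length + gap)
    ends <- starts + element_length
    if (max(ends) > seq_length) abort("cluster block extends past the sequence")
    el[[length(el) + 1L]] <- tibble(start = as.integer(starts),
                                    end = as.integer(ends),
                                    label = paste0("block", i))
    spans[[length(spans) + 1L]] <- tibble(seq_id = seq_id,
                                          start = as.integer(st),
                                          end = as.integer(max(ends)),
                                          n = as.integer(n))
  }
  blocks <- dplyr::bind_rows(el)
  if (n_background > 0L) {
    slot_w <- element_length + background_gap
    cand <- seq(0L, seq_length - element_length, by = slot_w)
    if (nrow(blocks) > 0L) {
      near <- vapply(cand, function(s) {
        any(s + element_length + background_gap > blocks$start &
              s - background_gap < blocks$end)
      }, logical(1))
      cand <- cand[!near]
    }
    if (length(cand) < n_background) {
      abort("not enough free space for the requested background elements")
    }
    bg <- sort(sample(cand, n_background))
    el[[length(el) + 1L]] <- tibble(start = as.integer(bg),
                                    end = as.integer(bg + element_length),
                                    label = "background")
  }
  elements <- dplyr::bind_rows(el)
  elements$seq_id <- seq_id
  elements <- dplyr::arrange(
    dplyr::select(elements, "seq_id", "start", "end", "label"),
    .data$start)
  list(
    elements = elements,
    truth_clusters = dplyr::bind_rows(spans),
    seq_lengths = tibble(seq_id = seq_id, length = as.integer(seq_length))
  )
}

#' Write sequences to a FASTA file
#'
#' Companion to the simulator: writes a `seqs` tibble (`seq_id`, `sequence`)
#' as plain FASTA so simulated inputs can be fed to the command-line
#' interface or any external tool.
#'
#' @param seqs Tibble with columns `seq_id`, `sequence`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, the path written.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$seq_id[i]), con)
    s <- seqs$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(stringr::str_sub(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}
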