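#' Read genomic intervals from a BED file
#'
#' Accepts BED3 and wider (BED4/BED6+): the fourth column is kept as `label`,
#' fifth as `score`, sixth as `strand` when present; clustering itself only
#' uses the first three. Comment (`#`), `track` and `browser` lines are
#' skipped. Coordinates are 0-based half-open as on disk.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `seq_id`, `start`, `end` and, when present in
#'   the input, `label`, `score`, `strand`; rows grouped by `seq_id` and
#'   sorted by (`start`, `end`). A file containing no interval lines yields a
#'   zero-row tibble.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path))
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(seq_id = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(paste0("BED line ", lineno[which(nf < 3L)[1]],
                 ": fewer than 3 tab-separated fields"))
  }
  pull <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[[i]] else NA_character_
  }, character(1))
  start_chr <- pull(2L)
  end_chr <- pull(3L)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(paste0("BED line ", lineno[bad[1]], ": non-numeric coordinates '",
                 start_chr[bad[1]], "', '", end_chr[bad[1]], "'"))
  }
  rev <- which(start >= end)
  if (length(rev) > 0L) {
    abort(paste0("BED line ", lineno[rev[1]], ": start (", start[rev[1]],
                 ") must be < end (", end[rev[1]], ")"))
  }
  out <- tibble(seq_id = pull(1L), start = start, end = end)
  if (max(nf) >= 4L) out$label <- pull(4L)
  if (max(nf) >= 5L) out$score <- pull(5L)
  if (max(nf) >= 6L) out$strand <- pull(6L)
  dplyr::arrange(out, .data$seq_id, .data$start, .data$end)
}

#' Read per-sequence lengths from a two-column TSV
#'
#' The element-mode pipeline needs declared sequence lengths (as in a UCSC
#' `chrom.sizes` file) to compute success probabilities.
#'
#' @param path Path to a TSV with columns seq_id and length (no header).
#' @return A tibble with columns `seq_id` and `length`.
#' @export
read_seq_lengths <- function(path) {
  x <- readr::read_tsv(path, col_names = c("seq_id", "length"),
                       col_types = readr::cols(
                         seq_id = readr::col_character(),
                         length = readr::col_double()
                       ), comment = "#", progress = FALSE)
  if (nrow(x) == 0L || any(is.na(x$length)) || any(x$length <= 0)) {
    abort(paste0("invalid sequence-length table: ", path))
  }
  x$length <- as.integer(x$length)
  x
}

#' Write a BED-compatible cluster report
#'
#' Emits a tab-separated table (`seq_id`, `start`, `end`, `name`, `n`,
#' `p_value`) preceded by `#`-prefixed summary lines giving the number of
#' clusters, their mean length and the total genome coverage. The body is
#' valid BED: re-reading the file with [read_bed()] recovers the coordinates.
#' p-values are printed in scientific notation with two significant digits.
#'
#' @param clusters A cluster tibble (e.g. `tidy()` of a [word_cluster()]
#'   result) with columns `seq_id`, `start`, `end`, `n` and optionally
#'   `p_value`; or a `wordclust` result object, in which case the significant
#'   clusters are written.
#' @param path Output file path.
#' @param name Base name used for the BED name field (default `"cluster"`).
#' @return Invisibly, the path written.
#' @export
write_clusters <- function(clusters, path, name = "cluster") {
  if (inherits(clusters, "wordclust")) clusters <- clusters$significant
  stopifnot(is.data.frame(clusters))
  n_cl <- nrow(clusters)
  len <- if (n_cl > 0) clusters$end - clusters$start else integer()
  header <- c(
    paste0("# n_clusters=", n_cl),
    paste0("# mean_length=", if (n_cl > 0) round(mean(len), 1) else 0),
    paste0("# coverage_bp=", sum(len)),
    paste0("#seq_id\tstart\tend\tname\tn\tp_value")
  )
  body <- character(0)
  if (n_cl > 0) {
    pv <- if ("p_value" %in% names(clusters)) {
      formatC(clusters$p_value, format = "e", digits = 1)
    } else rep(".", n_cl)
    nn <- if ("n" %in% names(clusters)) clusters$n else rep(NA_integer_, n_cl)
    body <- paste(clusters$seq_id, clusters$start, clusters$end,
                  paste0(name, "_", seq_len(n_cl)), nn, pv, sep = "\t")
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read gene models from a refFlat-style table
#'
#' Accepts UCSC refFlat rows (geneName, name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) or the 10-column variant
#' without the second transcript-name column. Exon start/end lists are
#' comma-separated as exported by the UCSC table browser. Genes whose CDS is
#' not contained in the transcript span are dropped with a warning.
#'
#' @param path Path to a refFlat TSV (no header).
#' @return A tibble with columns `gene_id`, `seq_id`, `strand`, `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end`, `exon_starts`, `exon_ends` (the last
#'   two are list-columns of integer vectors).
#' @export
read_refflat <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(!nf %in% c(10L, 11L))) {
    abort(paste0("refFlat line ", which(!nf %in% c(10L, 11L))[1],
                 ": expected 10 or 11 tab-separated fields"))
  }
  parse_row <- function(f) {
    off <- length(f) - 10L  # 0 for 10-col, 1 for 11-col (extra name column)
    exon_starts <- as.integer(strsplit(f[[9L + off]], ",")[[1]])
    exon_ends <- as.integer(strsplit(f[[10L + off]], ",")[[1]])
    tibble(
      gene_id = f[[1L]],
      seq_id = f[[2L + off]],
      strand = f[[3L + off]],
      tx_start = as.integer(f[[4L + off]]),
      tx_end = as.integer(f[[5L + off]]),
      cds_start = as.integer(f[[6L + off]]),
      cds_end = as.integer(f[[7L + off]]),
      exon_starts = list(sort(exon_starts)),
      exon_ends = list(sort(exon_ends))
    )
  }
  genes <- purrr::map_dfr(fields, parse_row)
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("refFlat strand column must be '+' or '-'")
  }
  ok <- genes$cds_start >= genes$tx_start & genes$cds_end <= genes$tx_end &
    genes$cds_start <= genes$cds_end
  if (any(!ok)) {
    warn(paste0("dropping ", sum(!ok),
                " gene(s) whose CDS lies outside the transcript span"))
    genes <- genes[ok, ]
  }
  genes
}
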