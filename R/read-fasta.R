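#' Read a FASTA file into a tibble of sequences
#'
#' Sequences are uppercased; the sequence identifier is the first
#' whitespace-delimited token of the header line. Multi-line records and
#' mixed-case (soft-masked) input are handled; soft-masked bases are searched
#' like any other since repeat masking carries no meaning for word clustering.
#'
#' @param path Path to a FASTA file (plain text).
#' @return A tibble with one row per record and columns `seq_id`, `sequence`
#'   (uppercase character) and `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "acgTNNacg"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("no sequences found in FASTA file: ", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate sequence IDs in FASTA file: ",
                 paste(dup, collapse = ", ")))
  }
  tibble(
    seq_id = ids,
    sequence = unname(toupper(as.character(set))),
    length = Biostrings::width(set)
  )
}

#' Split sequences into N-free contigs
#'
#' Any character outside A/C/G/T — N or another IUPAC ambiguity code — breaks
#' the sequence: words and inter-copy distances are only ever measured inside
#' a contig, so no ambiguous base can lie between two clustered copies.
#'
#' @param seqs A tibble with columns `seq_id` and `sequence` (uppercase), as
#'   returned by [read_fasta()].
#' @return A tibble of contigs with columns `seq_id`, `start` (0-based
#'   inclusive), `end` (0-based exclusive) and `bases` (the A/C/G/T content).
#'   An all-ambiguous sequence contributes no rows.
#' @export
#' @examples
#' segment_contigs(tibble::tibble(seq_id = "s", sequence = "ACGTNNACG"))
segment_contigs <- function(seqs) {
  stopifnot(is.data.frame(seqs), all(c("seq_id", "sequence") %in% names(seqs)))
  purrr::map2_dfr(seqs$seq_id, seqs$sequence, function(seq_id, sequence) {
    loc <- stringr::str_locate_all(sequence, "[ACGT]+")[[1]]
    if (nrow(loc) == 0L) {
      return(tibble(seq_id = character(), start = integer(),
                    end = integer(), bases = character()))
    }
    tibble(
      seq_id = seq_id,
      start = as.integer(loc[, 1] - 1L),
      end = as.integer(loc[, 2]),
      bases = stringr::str_sub(sequence, loc[, 1], loc[, 2])
    )
  })
}
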