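#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames.  Frames
#' `+1,+2,+3` start at offsets 0/1/2 of the forward strand; `-1,-2,-3` at
#' offsets 0/1/2 of the reverse complement.  Any codon containing a non-ACGT
#' base translates to `X`; internal stop codons are kept as `*` (the
#' downstream profile-HMM engine tolerates both).  Sequences shorter than one
#' codon give six empty proteins.
#'
#' @param seq A [Biostrings::DNAString] or single nucleotide string.
#' @param genetic_code A genetic code table as returned by
#'   [Biostrings::getGeneticCode()]; default the standard code.
#' @param id Parent sequence id recorded in the output.
#' @return A data.frame with one row per frame: `parent_id`, `frame`
#'   (`+1..+3, -1..-3` as integers), `nt_offset` (0-based offset of the first
#'   codon base on the strand read), and `protein`.
#' @export
translate_six_frames <- function(seq, genetic_code = Biostrings::GENETIC_CODE,
                                 id = "seq") {
  set <- Biostrings::DNAStringSet(as(seq, "DNAString"))
  names(set) <- id
  translate_library(set, genetic_code = genetic_code)
}

## Translate one strand of a whole set at a given frame offset, in a single
## vectorized engine call (per-sequence calls are far slower because the
## fuzzy-codon machinery is set up per call).
translate_offset <- function(set, off, genetic_code) {
  len <- Biostrings::width(set) - off
  len <- pmax(len - (len %% 3L), 0L)
  sub <- Biostrings::subseq(set, start = off + 1L, width = len)
  out <- rep("", length(set))
  ok <- len > 0L
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      sub[ok], genetic.code = genetic_code, if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  out
}

#' Translate a whole library in six frames
#'
#' @param seqs A named [Biostrings::DNAStringSet] (e.g. from
#'   [read_te_fasta()]).
#' @inheritParams translate_six_frames
#' @return Row-bound frames for all records (see [translate_six_frames()]).
#' @export
translate_library <- function(seqs, genetic_code = Biostrings::GENETIC_CODE) {
  if (length(seqs) == 0L) {
    return(data.frame(parent_id = character(0), frame = integer(0),
                      nt_offset = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("translate_library() requires named sequences.", call. = FALSE)
  }
  seqs <- as(seqs, "DNAStringSet")
  rev <- Biostrings::reverseComplement(seqs)
  prot <- c(lapply(0:2, function(off) translate_offset(seqs, off, genetic_code)),
            lapply(0:2, function(off) translate_offset(rev, off, genetic_code)))
  n <- length(seqs)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  offsets <- c(0L, 1L, 2L, 0L, 1L, 2L)
  ## one row per (record, frame), grouped by record with frames in the
  ## order +1,+2,+3,-1,-2,-3
  out <- data.frame(
    parent_id = rep(ids, each = 6L),
    frame = rep(frames, times = n),
    nt_offset = rep(offsets, times = n),
    protein = as.vector(t(matrix(unlist(prot), nrow = n))),
    stringsAsFactors = FALSE
  )
  out
}

#' Map a protein-frame interval to forward-strand nucleotide coordinates
#'
#' Given a 1-based inclusive amino-acid interval on one of the six translated
#' frames, returns the corresponding 1-based inclusive nucleotide interval on
#' the forward strand, plus the strand.  For minus frames the interval is
#' reported in forward coordinates (GFF convention).
#'
#' @param frame Frame in `{+1,+2,+3,-1,-2,-3}`.
#' @param aa_start,aa_end 1-based inclusive amino-acid coordinates on the
#'   frame's protein.
#' @param seq_len Length of the parent nucleotide sequence.
#' @return A list with `nt_start`, `nt_end` (1-based inclusive, forward
#'   strand) and `strand` (`"+"` or `"-"`).  The interval always has length
#'   `3 * (aa_end - aa_start + 1)`.
#' @export
map_aa_to_nt <- function(frame, aa_start, aa_end, seq_len) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)) {
    stop("frame must be one of +1,+2,+3,-1,-2,-3", call. = FALSE)
  }
  if (aa_start < 1L || aa_end < aa_start) {
    stop("need 1 <= aa_start <= aa_end", call. = FALSE)
  }
  off <- abs(frame) - 1L
  s <- off + 3L * (aa_start - 1L) + 1L  # on the strand being read
  e <- off + 3L * aa_end
  if (e > seq_len) {
    stop("amino-acid interval [", aa_start, ",", aa_end, "] of frame ", frame,
         " extends beyond the sequence (length ", seq_len, ")",
         call. = FALSE)
  }
  if (frame > 0L) {
    list(nt_start = s, nt_end = e, strand = "+")
  } else {
    list(nt_start = seq_len - e + 1L, nt_end = seq_len - s + 1L,
         strand = "-")
  }
}
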