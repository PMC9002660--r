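#' Read a TE library FASTA
#'
#' Reads a nucleotide FASTA file of TE sequences.  Sequences may be
#' soft-masked (lowercase is uppercased) and may contain `N`; any other
#' character is rejected.  When `parse_labels = TRUE`, RepeatMasker-style
#' headers of the form `name#Order/Superfamily` are split: the part before the
#' first `#` becomes the record id, the part after it the truth label (used by
#' [score_classifications()]).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param parse_labels Parse `#Order/Superfamily` suffixes into truth labels?
#' @return A [Biostrings::DNAStringSet] named by record id, with metadata
#'   columns `description` and `truth_label` (`NA` when absent).  An empty
#'   file yields an empty set.
#' @export
read_te_fasta <- function(path, parse_labels = TRUE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("Malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(raw) == 0L) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      description = character(0), truth_label = character(0))
    return(out)
  }
  headers <- names(raw)
  if (any(!nzchar(headers))) {
    stop("FASTA entry ", which(!nzchar(headers))[1], " has an empty header.",
         call. = FALSE)
  }
  first_tok <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  truth <- rep(NA_character_, length(raw))
  ids <- first_tok
  if (parse_labels) {
    has_lab <- grepl("#", first_tok, fixed = TRUE)
    ids[has_lab] <- sub("#.*$", "", first_tok[has_lab])
    truth[has_lab] <- sub("^[^#]*#", "", first_tok[has_lab])
  }
  if (any(!nzchar(ids))) {
    stop("FASTA entry ", which(!nzchar(ids))[1], " has an empty id.",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("Duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  chars <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("Sequence '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N} (after uppercasing).",
         call. = FALSE)
  }
  if (any(nchar(chars) < 1L)) {
    stop("Sequence '", ids[which(nchar(chars) < 1L)[1]], "' is empty.",
         call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    description = desc, truth_label = truth)
  out
}

#' Write sequences to FASTA
#'
#' Thin deterministic wrapper around [Biostrings::writeXStringSet()]
#' (unwrapped lines, LF newlines).
#'
#' @param seqs An `XStringSet` (or named character vector of sequences).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = 20000L)
  invisible(path)
}

#' Split truth labels into lineage levels
#'
#' Turns `"LTR/Copia"`-style labels into order/superfamily/clade columns.
#'
#' @param labels Character vector of `Order[/Superfamily[/Clade]]` labels.
#' @return A data.frame with columns `order`, `superfamily`, `clade`
#'   (`NA` where the label stops short).
#' @export
parse_truth_labels <- function(labels) {
  parts <- strsplit(ifelse(is.na(labels), "", labels), "/", fixed = TRUE)
  get_part <- function(i) {
    vapply(parts, function(p) if (length(p) >= i && nzchar(p[i])) p[i]
           else NA_character_, character(1))
  }
  data.frame(order = get_part(1L), superfamily = get_part(2L),
             clade = get_part(3L), stringsAsFactors = FALSE)
}
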