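## Second-pass rescue: classify elements without usable domain evidence by
## nucleotide similarity to first-pass classified elements under the
## 80-80-80 rule, at superfamily level only.

rescue_submat <- function() {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  ## masked (N) positions must never re-match in later HSP rounds
  mat["N", ] <- -8
  mat[, "N"] <- -8
  mat
}

#' Local HSP alignments between one query and one subject
#'
#' Finds up to `max_rounds` high-scoring local alignments (HSPs) between a
#' query and a subject on both strands by iterative masking: the best local
#' alignment is recorded, its query interval masked, and the search
#' repeated until the score falls below `min_score`.  This lets a
#' fragmented derivative whose matching segments are interrupted in the
#' subject still be covered by the union of its HSPs.
#'
#' @param query,subject Nucleotide strings or `DNAString`s.
#' @param min_score Stop when the best remaining local score is below this.
#' @param max_rounds Maximum HSPs returned.
#' @return data.frame with one row per HSP: `q_start`, `q_end` (forward
#'   query coordinates), `strand`, `aln_len` (alignment columns), `identity`
#'   (percent over aligned columns, gaps counted), `score`.
#' @export
align_hsps <- function(query, subject, min_score = 40, max_rounds = 8L) {
  mat <- rescue_submat()
  qchars <- strsplit(toupper(as.character(query)), "")[[1]]
  qlen <- length(qchars)
  subj <- Biostrings::DNAString(toupper(as.character(subject)))
  out <- list()
  for (round in seq_len(max_rounds)) {
    qf <- Biostrings::DNAString(paste(qchars, collapse = ""))
    qr <- Biostrings::reverseComplement(qf)
    af <- Biostrings::pairwiseAlignment(qf, subj, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    ar <- Biostrings::pairwiseAlignment(qr, subj, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    use_rev <- Biostrings::score(ar) > Biostrings::score(af)
    a <- if (use_rev) ar else af
    sc <- Biostrings::score(a)
    if (sc < min_score) break
    ps <- Biostrings::start(Biostrings::pattern(a))
    pe <- Biostrings::end(Biostrings::pattern(a))
    if (use_rev) {
      tmp <- ps
      ps <- qlen - pe + 1L
      pe <- qlen - tmp + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      q_start = ps, q_end = pe,
      strand = if (use_rev) "-" else "+",
      aln_len = Biostrings::nchar(a),
      identity = 100 * Biostrings::nmatch(a) / Biostrings::nchar(a),
      score = sc, stringsAsFactors = FALSE)
    qchars[ps:pe] <- "N"
  }
  if (length(out) == 0L) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      strand = character(0), aln_len = integer(0),
                      identity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

empty_similarity_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             aln_len = integer(0), identity = numeric(0),
             query_coverage = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Similarity search of unclassified queries against classified subjects
#'
#' For each query/subject pair, local alignments are computed on both
#' strands.  The reported `identity` and `aln_len` come from the single
#' best HSP; `query_coverage` is the percentage of the query covered by
#' the union of all HSP query intervals against that subject (so
#' fragmented derivatives whose pieces match non-contiguous parts of the
#' subject are fully credited).  One hit row is reported per pair with at
#' least one HSP.
#'
#' The `"internal"` backend is a seeded-free exact local aligner adequate
#' for library-scale inputs; the `"external"` backend shells out to the
#' standard nucleotide similarity-search executable and parses its
#' 12-column tabular output via [parse_tabular_hits()].
#'
#' @param queries,subjects Named [Biostrings::DNAStringSet]s.
#' @param backend `"internal"` or `"external"`.
#' @param min_score Minimum HSP score retained (internal backend).
#' @return A similarity-hit data.frame: `query_id`, `subject_id`,
#'   `aln_len`, `identity`, `query_coverage`, `score`.  Empty subjects give
#'   an empty result.
#' @export
similarity_search <- function(queries, subjects,
                              backend = c("internal", "external"),
                              min_score = 40) {
  backend <- match.arg(backend)
  if (length(subjects) == 0L || length(queries) == 0L) {
    return(empty_similarity_hits())
  }
  if (backend == "external") {
    return(similarity_search_external(queries, subjects))
  }
  rows <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qlen <- length(queries[[qi]])
    for (si in seq_along(subjects)) {
      hsps <- align_hsps(queries[[qi]], subjects[[si]], min_score = min_score)
      if (nrow(hsps) == 0L) next
      best <- hsps[order(-hsps$score, -hsps$identity), , drop = FALSE][1, ]
      cov_bp <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(hsps$q_start, hsps$q_end))))
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, subject_id = names(subjects)[si],
        aln_len = best$aln_len, identity = best$identity,
        query_coverage = 100 * cov_bp / qlen, score = best$score,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_similarity_hits())
  do.call(rbind, rows)
}

similarity_search_external <- function(queries, subjects) {
  makeblastdb <- check_tool("makeblastdb")
  blastn <- check_tool("blastn")
  dir <- tempfile("blast")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  qfa <- file.path(dir, "q.fa")
  sfa <- file.path(dir, "s.fa")
  Biostrings::writeXStringSet(queries, qfa, width = 20000L)
  Biostrings::writeXStringSet(subjects, sfa, width = 20000L)
  status <- system2(makeblastdb, c("-in", sfa, "-dbtype", "nucl"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("makeblastdb failed", call. = FALSE)
  out <- file.path(dir, "hits.tsv")
  status <- system2(blastn, c("-query", qfa, "-db", sfa, "-outfmt", "6",
                              "-out", out, "-evalue", "1e-5"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blastn failed", call. = FALSE)
  parse_tabular_hits(out, stats::setNames(Biostrings::width(queries),
                                          names(queries)))
}

#' Parse 12-column tabular similarity hits
#'
#' Consumes the standard 12-column tabular alignment dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) and collapses HSPs per (query, subject) pair the same
#' way as the internal backend: identity and alignment length from the
#' best-bitscore HSP, query coverage from the union of HSP query intervals.
#'
#' @param x Path to a tabular file, or a character vector of lines.
#' @param query_lengths Named integer vector of query lengths.
#' @return A similarity-hit data.frame (see [similarity_search()]).
#' @export
parse_tabular_hits <- function(x, query_lengths) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_similarity_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("tabular hit row ", which(nf < 12L)[1], " has ", nf[which(nf < 12L)[1]],
         " columns (expected >= 12)", call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  hsp <- data.frame(
    query_id = get(1L), subject_id = get(2L),
    identity = as.numeric(get(3L)), aln_len = as.integer(get(4L)),
    q_start = as.integer(get(7L)), q_end = as.integer(get(8L)),
    score = as.numeric(get(12L)), stringsAsFactors = FALSE)
  ## minus-strand query coords can arrive reversed
  flip <- hsp$q_start > hsp$q_end
  tmp <- hsp$q_start[flip]
  hsp$q_start[flip] <- hsp$q_end[flip]
  hsp$q_end[flip] <- tmp
  parts <- split(seq_len(nrow(hsp)),
                 paste(hsp$query_id, hsp$subject_id, sep = "\r"))
  rows <- lapply(parts, function(ix) {
    h <- hsp[ix, , drop = FALSE]
    best <- h[order(-h$score, -h$identity), , drop = FALSE][1, ]
    qlen <- query_lengths[best$query_id]
    if (is.na(qlen)) {
      stop("no length known for query '", best$query_id, "'", call. = FALSE)
    }
    cov_bp <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(h$q_start, h$q_end))))
    data.frame(query_id = best$query_id, subject_id = best$subject_id,
               aln_len = best$aln_len, identity = best$identity,
               query_coverage = 100 * cov_bp / qlen, score = best$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

#' Classify rescue queries under the 80-80-80 rule
#'
#' A query is classified when its best surviving hit (highest score, ties
#' broken by higher identity, then lexicographic subject id) satisfies all
#' of: alignment length >= 80 bp, identity >= 80%, query coverage >= 80%
#' (boundaries inclusive).  The assigned lineage is the subject's lineage
#' truncated to superfamily depth — rescue never assigns a clade.  The
#' result carries `pass_no = 2`, no evidence hits, strand `"?"`, and
#' completeness `"unknown"`.
#'
#' @param hits Similarity hits from [similarity_search()].
#' @param pass1 Classification table (from [classification_table()]) of the
#'   first-pass subjects; every `subject_id` must appear in its
#'   `element_id` column.
#' @param min_aln_bp,min_identity,min_qcov The three rule thresholds.
#' @return A list of `te_classification` objects, one per rescued query.
#' @export
apply_80_80_80 <- function(hits, pass1, min_aln_bp = 80, min_identity = 80,
                           min_qcov = 80) {
  if (nrow(hits) == 0L) return(list())
  idx <- match(hits$subject_id, pass1$element_id)
  if (anyNA(idx)) {
    stop("subject(s) missing from pass-1 classifications: ",
         paste(unique(hits$subject_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (qid in sort(unique(hits$query_id))) {
    h <- hits[hits$query_id == qid, , drop = FALSE]
    h <- h[order(-h$score, -h$identity, h$subject_id), , drop = FALSE]
    best <- h[1, ]
    if (best$aln_len >= min_aln_bp && best$identity >= min_identity &&
        best$query_coverage >= min_qcov) {
      sub <- pass1[pass1$element_id == best$subject_id, ][1, ]
      if (is.na(sub$superfamily) || identical(sub$superfamily, "unknown")) {
        next  # subjects without a resolved superfamily cannot donate one
      }
      cls <- structure(list(element_id = qid, order = sub$order,
                            superfamily = sub$superfamily,
                            clade = NA_character_,
                            conflict_level = NA_character_, strand = "?",
                            domain_string = "", complete = "unknown",
                            pass_no = 2L, hits = empty_domain_hits()),
                       class = "te_classification")
      out[[length(out) + 1L]] <- cls
    }
  }
  out
}
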