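## Profile-HMM domain search over translated frames, per-domain table
## parsing, the coverage/E-value filter, and best-hit resolution.

## Query naming convention for frames written to the search engine:
## "<element_id>|aa<frame>", e.g. "el1|aa+2", "el1|aa-3".
frame_query_id <- function(element_id, frame) {
  sprintf("%s|aa%+d", element_id, frame)
}

parse_frame_query_id <- function(query_id) {
  m <- regexpr("\\|aa[+-][1-3]$", query_id)
  if (any(m < 0L)) {
    bad <- query_id[which(m < 0L)[1]]
    stop("query id '", bad, "' does not carry a |aa<frame> tag", call. = FALSE)
  }
  data.frame(
    element_id = substr(query_id, 1L, m - 1L),
    frame = as.integer(substring(query_id, m + 3L)),
    stringsAsFactors = FALSE
  )
}

#' Search translated frames against a profile database
#'
#' Writes the non-empty frame proteins to a temporary FASTA and runs
#' `hmmscan` with permissive reporting thresholds (`-E 10 --domE 10`); the
#' strict published filter is applied afterwards by [filter_hits()].  Results
#' do not depend on `threads` (the engine's parallelism does not change its
#' scores).
#'
#' @param frames A frames data.frame from [translate_library()].
#' @param db A `profile_db`.
#' @param threads Number of worker threads passed to the engine (`--cpu`).
#' @return A data.frame of raw per-domain hits: `query_id`, `profile_name`,
#'   `model_length`, `score` (domain bit score), `evalue` (per-domain
#'   independent E-value), `hmm_from`, `hmm_to`, `aa_from`, `aa_to`.
#' @export
search_frames <- function(frames, db, threads = 1L) {
  if (nrow(db$meta) == 0L) {
    stop("profile database is empty", call. = FALSE)
  }
  keep <- nzchar(frames$protein)
  if (nrow(frames) == 0L || !any(keep)) {
    return(empty_raw_hits())
  }
  hmmscan <- check_tool("hmmscan")
  ensure_pressed(db)
  frames <- frames[keep, , drop = FALSE]
  faa <- tempfile(fileext = ".faa")
  on.exit(unlink(faa), add = TRUE)
  prot <- Biostrings::AAStringSet(frames$protein)
  names(prot) <- frame_query_id(frames$parent_id, frames$frame)
  Biostrings::writeXStringSet(prot, faa, width = 20000L)
  tbl <- tempfile(fileext = ".domtbl")
  on.exit(unlink(tbl), add = TRUE)
  status <- system2(hmmscan,
                    c("--cpu", as.integer(threads), "--noali",
                      "-E", "10", "--domE", "10",
                      "--domtblout", tbl, db$hmm_path, faa),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) {
    stop("hmmscan failed (exit ", status, ") on database ", db$hmm_path,
         call. = FALSE)
  }
  parse_domtblout(tbl)
}

empty_raw_hits <- function() {
  data.frame(query_id = character(0), profile_name = character(0),
             model_length = integer(0), score = numeric(0),
             evalue = numeric(0), hmm_from = integer(0), hmm_to = integer(0),
             aa_from = integer(0), aa_to = integer(0),
             stringsAsFactors = FALSE)
}

#' Parse a per-domain tabular report (domtblout dialect)
#'
#' Parses the standard 23+-column per-domain table written by the
#' profile-HMM search suite (`--domtblout`).  The per-domain independent
#' E-value (column 13) and per-domain bit score (column 14) are retained;
#' comment lines are ignored.
#'
#' @param x Path to a table file, or a character vector of lines.
#' @return A raw-hit data.frame (see [search_frames()]).
#' @export
parse_domtblout <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_raw_hits())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 23L)) {
    stop("per-domain table row ", which(nf < 23L)[1],
         " has ", nf[which(nf < 23L)[1]], " columns (expected >= 23)",
         call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(
    query_id = get(4L),
    profile_name = get(1L),
    model_length = as.integer(get(3L)),
    score = as.numeric(get(14L)),
    evalue = as.numeric(get(13L)),
    hmm_from = as.integer(get(16L)),
    hmm_to = as.integer(get(17L)),
    aa_from = as.integer(get(18L)),
    aa_to = as.integer(get(19L)),
    stringsAsFactors = FALSE
  )
}

empty_domain_hits <- function() {
  data.frame(element_id = character(0), frame = integer(0),
             profile_name = character(0), domain_label = character(0),
             order = character(0), superfamily = character(0),
             clade = character(0), score = numeric(0), evalue = numeric(0),
             coverage = numeric(0), aa_from = integer(0), aa_to = integer(0),
             nt_start = integer(0), nt_end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Filter raw hits by model coverage and E-value
#'
#' Applies the published discard rule — hits with model coverage below 20%
#' or per-domain E-value above 1e-3 are dropped; boundary values are kept —
#' and decorates survivors with their lineage and forward-strand nucleotide
#' coordinates.  Coverage is `(hmm_to - hmm_from + 1) / model_length`, i.e.
#' the fraction of the profile's match states spanned by the hit.
#'
#' @param raw Raw hits from [search_frames()] / [parse_domtblout()].
#' @param db The `profile_db` searched (source of lineage and model length).
#' @param seq_lens Named integer vector of parent sequence lengths, needed to
#'   place minus-strand hits on forward coordinates.
#' @param min_coverage Minimum model coverage kept (default 0.20).
#' @param max_evalue Maximum E-value kept (default 1e-3).
#' @return A domain-hit data.frame, one row per surviving hit, with columns
#'   `element_id`, `frame`, `profile_name`, `domain_label`, `order`,
#'   `superfamily`, `clade`, `score`, `evalue`, `coverage`, `aa_from`,
#'   `aa_to`, `nt_start`, `nt_end`, `strand`.
#' @export
filter_hits <- function(raw, db, seq_lens, min_coverage = 0.20,
                        max_evalue = 1e-3) {
  if (nrow(raw) == 0L) return(empty_domain_hits())
  idx <- match(raw$profile_name, db$meta$profile_name)
  if (anyNA(idx)) {
    stop("hit(s) to profile(s) absent from the database metadata: ",
         paste(unique(raw$profile_name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  model_len <- db$meta$model_length[idx]
  coverage <- (raw$hmm_to - raw$hmm_from + 1L) / model_len
  keep <- coverage >= min_coverage & raw$evalue <= max_evalue
  raw <- raw[keep, , drop = FALSE]
  idx <- idx[keep]
  coverage <- coverage[keep]
  if (nrow(raw) == 0L) return(empty_domain_hits())
  qi <- parse_frame_query_id(raw$query_id)
  len <- seq_lens[qi$element_id]
  if (anyNA(len)) {
    stop("no sequence length known for element(s): ",
         paste(unique(qi$element_id[is.na(len)]), collapse = ", "),
         call. = FALSE)
  }
  nt <- mapply(function(fr, a, b, L) {
    m <- map_aa_to_nt(fr, a, b, L)
    c(m$nt_start, m$nt_end, if (m$strand == "+") 1L else -1L)
  }, qi$frame, raw$aa_from, raw$aa_to, len)
  out <- data.frame(
    element_id = qi$element_id,
    frame = qi$frame,
    profile_name = raw$profile_name,
    domain_label = db$meta$domain_label[idx],
    order = db$meta$order[idx],
    superfamily = db$meta$superfamily[idx],
    clade = db$meta$clade[idx],
    score = raw$score,
    evalue = raw$evalue,
    coverage = coverage,
    aa_from = raw$aa_from,
    aa_to = raw$aa_to,
    nt_start = as.integer(nt[1, ]),
    nt_end = as.integer(nt[2, ]),
    strand = ifelse(nt[3, ] > 0L, "+", "-"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

## TRUE when two forward-strand intervals overlap by more than half the
## shorter interval — the grouping rule under which "multiple hits to one
## domain" compete.
overlaps_majority <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  ov > 0L && ov > 0.5 * min(e1 - s1 + 1L, e2 - s2 + 1L)
}

#' Resolve competing domain hits to the best hit per locus
#'
#' Among hits whose nucleotide intervals mutually overlap by more than 50%
#' of the shorter interval, only the best hit — highest bit score, ties
#' broken by lower E-value then lexicographic profile name — is retained.
#' Non-overlapping hits (e.g. tandem domain copies) all survive.  Works
#' across elements: grouping never crosses element boundaries.
#'
#' @param hits A domain-hit data.frame from [filter_hits()].
#' @return The retained subset, ordered by element then `nt_start`.
#' @export
resolve_best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  parts <- split(seq_len(nrow(hits)), hits$element_id)
  kept <- unlist(lapply(parts, function(ix) {
    h <- hits[ix, , drop = FALSE]
    ord <- order(-h$score, h$evalue, h$profile_name)
    chosen <- integer(0)
    for (i in ord) {
      clash <- any(vapply(chosen, function(j) {
        overlaps_majority(h$nt_start[i], h$nt_end[i],
                          h$nt_start[j], h$nt_end[j])
      }, logical(1)))
      if (!clash) chosen <- c(chosen, i)
    }
    ix[chosen]
  }), use.names = FALSE)
  out <- hits[kept, , drop = FALSE]
  out <- out[order(out$element_id, out$nt_start, out$nt_end,
                   out$profile_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
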