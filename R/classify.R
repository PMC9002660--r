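## Per-element classification: score-weighted lineage aggregation, strand
## call, completeness from domain presence and order, and TSV/GFF3 output.

#' Canonical polyprotein domain orders
#'
#' The 5'→3' order of the five canonical domains expected in a complete
#' element, per superfamily: Copia elements carry integrase upstream of
#' reverse transcriptase, Gypsy elements downstream.  Exposed as data so a
#' database packager can extend it.
#'
#' @return Named list of character vectors of domain labels.
#' @export
canonical_domain_orders <- function() {
  list(Copia = c("GAG", "AP", "INT", "RT", "RH"),
       Gypsy = c("GAG", "AP", "RT", "RH", "INT"))
}

#' Classify one element from its resolved domain hits
#'
#' Aggregates the element's filtered, best-hit-resolved domain hits into a
#' lineage by score-weighted majority: at each level (order, then
#' superfamily, then clade) the value with the greatest summed bit score
#' wins, and the classification descends to that level only if the winner's
#' summed score exceeds 50% of the total summed score of the hits under
#' consideration.  On a tie (or an unclear majority) the classification
#' stops at the level above and the contested level is flagged as a
#' conflict.  The strand is that of the majority of hits by summed score
#' (`"?"` on an exact tie).  No hits yields the unclassified sentinel.
#'
#' @param hits Domain-hit data.frame rows for one element (may be empty).
#' @param element_id Element id; defaults to the one found in `hits`.
#' @return A `te_classification`: list with `element_id`, `order`,
#'   `superfamily`, `clade` (NA below the depth reached), `conflict_level`
#'   (NA, or the first level where evidence conflicted), `strand`,
#'   `domain_string`, `complete` (`"unknown"` until [call_completeness()]),
#'   `pass_no`, and the evidence `hits`.
#' @export
classify_element <- function(hits, element_id = NULL) {
  if (is.null(element_id)) {
    element_id <- if (nrow(hits) > 0L) hits$element_id[1] else NA_character_
  }
  if (nrow(hits) > 0L && length(unique(hits$element_id)) > 1L) {
    stop("classify_element() expects hits for a single element", call. = FALSE)
  }
  cls <- structure(list(element_id = element_id, order = NA_character_,
                        superfamily = NA_character_, clade = NA_character_,
                        conflict_level = NA_character_, strand = "?",
                        domain_string = "", complete = "unknown",
                        pass_no = NA_integer_, hits = hits),
                   class = "te_classification")
  if (nrow(hits) == 0L) return(cls)
  cls$pass_no <- 1L

  ## strand by summed score
  plus <- sum(hits$score[hits$strand == "+"])
  minus <- sum(hits$score[hits$strand == "-"])
  cls$strand <- if (plus > minus) "+" else if (minus > plus) "-" else "?"

  ## score-weighted majority descent through the lineage levels
  sub <- hits
  for (level in c("order", "superfamily", "clade")) {
    vals <- sub[[level]]
    if (all(is.na(vals))) break
    sums <- tapply(sub$score[!is.na(vals)], vals[!is.na(vals)], sum)
    total <- sum(sub$score)
    top <- max(sums)
    winners <- names(sums)[sums == top]
    if (length(winners) > 1L || top <= 0.5 * total) {
      cls$conflict_level <- level
      break
    }
    cls[[level]] <- winners[1]
    sub <- sub[!is.na(vals) & vals == winners[1], , drop = FALSE]
  }

  cls$domain_string <- domain_string(hits, cls$strand)
  cls
}

## Domains listed 5'->3' on the element's strand, each tagged with the
## deepest lineage name its profile carries, e.g. "GAG|Ale AP|Ale ...".
domain_string <- function(hits, strand) {
  if (nrow(hits) == 0L) return("")
  ord <- order(hits$nt_start)
  if (identical(strand, "-")) ord <- rev(ord)
  h <- hits[ord, , drop = FALSE]
  deepest <- ifelse(!is.na(h$clade), h$clade,
                    ifelse(!is.na(h$superfamily), h$superfamily, h$order))
  paste(paste0(h$domain_label, "|", deepest), collapse = " ")
}

#' @export
print.te_classification <- function(x, ...) {
  lin <- paste(stats::na.omit(c(x$order, x$superfamily, x$clade)),
               collapse = "/")
  if (!nzchar(lin)) lin <- "unclassified"
  cat("<classification> ", x$element_id, ": ", lin,
      " (strand ", x$strand, ", complete ", x$complete,
      ", pass ", x$pass_no, ")\n", sep = "")
  invisible(x)
}

#' Call element completeness from domain presence and order
#'
#' A Copia or Gypsy element is complete when, after best-hit resolution,
#' (a) each of GAG, AP, INT, RT, RH is present exactly once, (b) all five
#' lie on one strand, and (c) read 5'→3' along that strand they appear in
#' the superfamily's canonical order (see [canonical_domain_orders()]).
#' Hits with other domain labels are ignored.  Elements outside
#' Copia/Gypsy, or classified only in the rescue pass, stay `"unknown"`.
#'
#' @param cls A `te_classification` from [classify_element()].
#' @param canonical Canonical orders, see [canonical_domain_orders()].
#' @return `cls` with `complete` set to `"yes"`/`"no"` (or left
#'   `"unknown"`), plus attribute `"completeness_report"` giving the
#'   observed strand-normalized domain order.
#' @export
call_completeness <- function(cls, canonical = canonical_domain_orders()) {
  sf <- cls$superfamily
  if (is.na(sf) || !sf %in% names(canonical) || nrow(cls$hits) == 0L) {
    return(cls)
  }
  want <- canonical[[sf]]
  h <- cls$hits[cls$hits$domain_label %in% want, , drop = FALSE]
  observed <- character(0)
  ok <- FALSE
  counts <- table(h$domain_label)
  if (nrow(h) > 0L &&
      all(want %in% names(counts)) && all(counts == 1L) &&
      length(unique(h$strand)) == 1L) {
    ord <- order(h$nt_start)
    if (h$strand[1] == "-") ord <- rev(ord)
    observed <- h$domain_label[ord]
    ok <- identical(observed, want)
  }
  cls$complete <- if (ok) "yes" else "no"
  attr(cls, "completeness_report") <- paste(observed, collapse = ",")
  cls
}

#' Tabulate classifications
#'
#' @param cls_list List of `te_classification` objects.
#' @return A data.frame with one row per element: `element_id`, `order`,
#'   `superfamily`, `clade`, `complete`, `strand`, `domains`, `pass`.
#'   A level contested by conflicting evidence is rendered `"unknown"`;
#'   a level simply not reached is empty (`NA`).
#' @export
classification_table <- function(cls_list) {
  if (length(cls_list) == 0L) {
    return(data.frame(element_id = character(0), order = character(0),
                      superfamily = character(0), clade = character(0),
                      complete = character(0), strand = character(0),
                      domains = character(0), pass = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(cls_list, function(cls) {
    sf <- cls$superfamily
    cl <- cls$clade
    if (!is.na(cls$conflict_level)) {
      if (cls$conflict_level == "superfamily") sf <- "unknown"
      if (cls$conflict_level == "clade") cl <- "unknown"
    }
    data.frame(element_id = cls$element_id,
               order = cls$order %||% NA_character_,
               superfamily = sf, clade = cl,
               complete = cls$complete, strand = cls$strand,
               domains = cls$domain_string,
               pass = cls$pass_no, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write classification TSV and domain-feature GFF3
#'
#' Emits the per-element classification table as TSV and the retained
#' domain hits as GFF3 `protein_match` features with 1-based inclusive
#' forward-strand coordinates.  Output is byte-deterministic for identical
#' inputs (elements sorted by id).
#'
#' @param cls_list List of `te_classification` objects.
#' @param tsv_path,gff_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the classification table.
#' @export
write_classifications <- function(cls_list, tsv_path = NULL, gff_path = NULL) {
  ids <- vapply(cls_list, function(x) x$element_id, character(1))
  cls_list <- cls_list[order(ids)]
  tab <- classification_table(cls_list)
  if (!is.null(tsv_path)) write_tsv0(tab, tsv_path)
  if (!is.null(gff_path)) {
    con <- file(gff_path, open = "wb")
    on.exit(close(con))
    writeLines("##gff-version 3", con, sep = "\n")
    for (cls in cls_list) {
      h <- cls$hits
      if (is.null(h) || nrow(h) == 0L) next
      h <- h[order(h$nt_start, h$nt_end, h$profile_name), , drop = FALSE]
      attrs <- sprintf(
        "ID=%s.dom%d;Name=%s;profile=%s;lineage=%s;coverage=%.3f;evalue=%s",
        cls$element_id, seq_len(nrow(h)), h$domain_label, h$profile_name,
        ifelse(!is.na(h$clade), paste(h$order, h$superfamily, h$clade, sep = "/"),
               ifelse(!is.na(h$superfamily), paste(h$order, h$superfamily, sep = "/"),
                      h$order)),
        h$coverage, format(h$evalue))
      writeLines(sprintf("%s\tTEclade\tprotein_match\t%d\t%d\t%.1f\t%s\t.\t%s",
                         cls$element_id, h$nt_start, h$nt_end, h$score,
                         h$strand, attrs),
                 con, sep = "\n")
    }
  }
  invisible(tab)
}
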