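## Domain extraction for phylogenetics: per-domain protein/nucleotide FASTA
## and the concatenated RT-RH-INT set.

#' Extract domain sequences from classified elements
#'
#' For every retained domain hit with a requested label, extracts the
#' nucleotide interval (reverse-complemented for minus-strand hits) and its
#' translation.  By construction each record satisfies
#' `translate(oriented nt_seq) == aa_seq`.
#'
#' @param cls_list List of `te_classification` objects carrying evidence
#'   hits (pass-1 classifications).
#' @param seqs Named [Biostrings::DNAStringSet] of the element library.
#' @param labels Domain labels to extract.
#' @param genetic_code Genetic code table for the translation.
#' @return Named list (one entry per label present) of data.frames with
#'   columns `element_id`, `domain_label`, `lineage`, `clade`, `aa_seq`,
#'   `nt_seq`, `nt_start`, `nt_end`, `strand`.
#' @export
extract_domains <- function(cls_list, seqs, labels = DOMAIN_LABELS,
                            genetic_code = Biostrings::GENETIC_CODE) {
  rows <- list()
  for (cls in cls_list) {
    h <- cls$hits
    if (is.null(h) || nrow(h) == 0L) next
    h <- h[h$domain_label %in% labels, , drop = FALSE]
    if (nrow(h) == 0L) next
    if (!cls$element_id %in% names(seqs)) {
      stop("classified element '", cls$element_id,
           "' is absent from the library", call. = FALSE)
    }
    full <- seqs[[cls$element_id]]
    for (i in seq_len(nrow(h))) {
      if (h$nt_start[i] < 1L || h$nt_end[i] > length(full)) {
        stop("hit coordinates [", h$nt_start[i], ",", h$nt_end[i],
             "] outside element '", cls$element_id,
             "' (length ", length(full), ") — upstream coordinate bug",
             call. = FALSE)
      }
      nt <- as.character(Biostrings::subseq(full, h$nt_start[i],
                                            h$nt_end[i]))
      lin <- paste(stats::na.omit(c(h$order[i], h$superfamily[i],
                                    h$clade[i])), collapse = "/")
      rows[[length(rows) + 1L]] <- data.frame(
        element_id = cls$element_id, domain_label = h$domain_label[i],
        lineage = lin, clade = h$clade[i],
        aa_seq = NA_character_, nt_seq = nt,
        nt_start = h$nt_start[i], nt_end = h$nt_end[i],
        strand = h$strand[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(stats::setNames(list(), character(0)))
  all <- do.call(rbind, rows)
  ## translate all oriented intervals in one engine call
  oriented <- Biostrings::DNAStringSet(all$nt_seq)
  minus <- all$strand == "-"
  oriented[minus] <- Biostrings::reverseComplement(oriented[minus])
  all$aa_seq <- as.character(Biostrings::translate(
    oriented, genetic.code = genetic_code, if.fuzzy.codon = "X", no.init.codon = TRUE))
  all <- all[order(all$element_id, all$nt_start), , drop = FALSE]
  split(all, factor(all$domain_label, levels = intersect(labels,
                                                         all$domain_label)))
}

#' Concatenate domains across elements
#'
#' Builds the concatenated domain set (e.g. RT-RH-INT) used for
#' phylogenetics: only elements possessing exactly one retained copy of
#' every requested label are included, and sequences are joined in the
#' requested label order regardless of genomic order (which differs between
#' Copia and Gypsy).
#'
#' @param domains Output of [extract_domains()].
#' @param labels Ordered labels to concatenate; must be non-empty.
#' @return data.frame with `element_id`, `lineage`, `aa_seq`, `nt_seq`.
#' @export
concatenate_domains <- function(domains, labels = c("RT", "RH", "INT")) {
  if (length(labels) == 0L) {
    stop("concatenate_domains() needs at least one domain label",
         call. = FALSE)
  }
  per <- lapply(labels, function(lab) {
    d <- domains[[lab]]
    if (is.null(d)) d <- data.frame(element_id = character(0),
                                    aa_seq = character(0),
                                    nt_seq = character(0),
                                    lineage = character(0),
                                    stringsAsFactors = FALSE)
    d
  })
  ## elements with exactly one copy of every label
  single <- lapply(per, function(d) {
    counts <- table(d$element_id)
    names(counts)[counts == 1L]
  })
  elems <- sort(Reduce(intersect, single))
  if (length(elems) == 0L) {
    return(data.frame(element_id = character(0), lineage = character(0),
                      aa_seq = character(0), nt_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  aa <- nt <- rep("", length(elems))
  for (d in per) {
    idx <- match(elems, d$element_id)
    aa <- paste0(aa, d$aa_seq[idx])
    nt <- paste0(nt, d$nt_seq[idx])
  }
  lin <- per[[1]]$lineage[match(elems, per[[1]]$element_id)]
  data.frame(element_id = elems, lineage = lin, aa_seq = aa, nt_seq = nt,
             stringsAsFactors = FALSE)
}

#' Write per-domain and concatenated FASTA files
#'
#' Headers follow `elementID|lineage|domain`.  One protein (`.faa`) and one
#' nucleotide (`.fna`) file per label, plus a concatenated pair when
#' `concat_labels` is non-empty and any element qualifies.
#'
#' @param domains Output of [extract_domains()].
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @param concat_labels Labels for the concatenated set (default RT-RH-INT).
#' @return Character vector of files written, invisibly.
#' @export
write_domain_fastas <- function(domains, dir, prefix = "domains",
                                concat_labels = c("RT", "RH", "INT")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (lab in names(domains)) {
    d <- domains[[lab]]
    hdr <- paste(d$element_id, d$lineage, lab, sep = "|")
    faa <- file.path(dir, paste0(prefix, ".", lab, ".faa"))
    fna <- file.path(dir, paste0(prefix, ".", lab, ".fna"))
    write_fasta(stats::setNames(d$aa_seq, hdr), faa)
    write_fasta(stats::setNames(d$nt_seq, hdr), fna)
    written <- c(written, faa, fna)
  }
  if (length(concat_labels) > 0L) {
    cc <- concatenate_domains(domains, concat_labels)
    if (nrow(cc) > 0L) {
      tag <- paste(concat_labels, collapse = "-")
      hdr <- paste(cc$element_id, cc$lineage, tag, sep = "|")
      faa <- file.path(dir, paste0(prefix, ".", tag, ".faa"))
      fna <- file.path(dir, paste0(prefix, ".", tag, ".fna"))
      write_fasta(stats::setNames(cc$aa_seq, hdr), faa)
      write_fasta(stats::setNames(cc$nt_seq, hdr), fna)
      written <- c(written, faa, fna)
    }
  }
  invisible(written)
}
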