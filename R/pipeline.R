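## End-to-end pipeline: translate -> search -> filter -> resolve ->
## classify -> rescue -> extract, with deterministic outputs.

#' Pipeline configuration
#'
#' Bundles every tunable threshold with its published default: hits with
#' model coverage < 20% or E-value > 1e-3 are discarded, and the rescue
#' pass applies the 80-80-80 rule (>= 80 bp alignment, >= 80% identity,
#' >= 80% query coverage).
#'
#' @param min_coverage Minimum profile model coverage of a kept hit.
#' @param max_evalue Maximum per-domain E-value of a kept hit.
#' @param rule_min_aln_bp,rule_min_identity,rule_min_qcov The 80-80-80
#'   thresholds for the rescue pass.
#' @param pass2_enabled Run the similarity rescue pass?
#' @param rescue_backend `"internal"` or `"external"` (see
#'   [similarity_search()]).
#' @param threads Worker threads for the search engine (never changes any
#'   output byte).
#' @param seed Seed recorded in the config (the pipeline proper is
#'   deterministic; only fixture generation consumes randomness).
#' @param genetic_code Genetic code table (see
#'   [Biostrings::getGeneticCode()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_coverage = 0.20, max_evalue = 1e-3,
                            rule_min_aln_bp = 80, rule_min_identity = 80,
                            rule_min_qcov = 80, pass2_enabled = TRUE,
                            rescue_backend = "internal", threads = 1L,
                            seed = 1L,
                            genetic_code = Biostrings::GENETIC_CODE) {
  stopifnot(min_coverage >= 0, min_coverage <= 1, max_evalue >= 0,
            rule_min_aln_bp >= 0, rule_min_identity >= 0,
            rule_min_identity <= 100, rule_min_qcov >= 0,
            rule_min_qcov <= 100, threads >= 1)
  structure(list(min_coverage = min_coverage, max_evalue = max_evalue,
                 rule_min_aln_bp = rule_min_aln_bp,
                 rule_min_identity = rule_min_identity,
                 rule_min_qcov = rule_min_qcov,
                 pass2_enabled = isTRUE(pass2_enabled),
                 rescue_backend = rescue_backend,
                 threads = as.integer(threads), seed = as.integer(seed),
                 genetic_code = genetic_code),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Stages, in order: six-frame translation; profile-HMM search; the
#' coverage/E-value filter; best-hit resolution; per-element lineage and
#' completeness calling; similarity rescue of unclassified elements
#' (80-80-80 rule, superfamily level only, single round); domain
#' extraction.  Identical input and config give byte-identical outputs,
#' regardless of thread count.  Stage counts are logged via [message()].
#'
#' @param library A FASTA path or a named [Biostrings::DNAStringSet].
#' @param db A `profile_db`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `<prefix>.cls.tsv`, `<prefix>.dom.gff3`, and per-domain FASTA files.
#' @param prefix Output filename prefix.
#' @return List with `classifications` (list of `te_classification`,
#'   sorted by element id), `table` (the classification data.frame),
#'   `hits` (retained domain hits), `rescue_hits` (similarity hits of the
#'   rescue pass), `domains` (per-label extracted sequences), and `files`
#'   (paths written).
#' @export
run_pipeline <- function(library, db, config = pipeline_config(),
                         out_dir = NULL, prefix = "teclade") {
  t0 <- Sys.time()
  seqs <- if (is.character(library)) read_te_fasta(library) else library
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("library sequences must carry unique names", call. = FALSE)
  }
  seqs <- seqs[order(names(seqs))]
  ids <- names(seqs)
  message("[translate] ", length(seqs), " elements")
  frames <- translate_library(seqs, genetic_code = config$genetic_code)

  message("[search] database '", db$db_name, "' (", nrow(db$meta),
          " profiles), threads=", config$threads)
  raw <- search_frames(frames, db, threads = config$threads)
  message("[search] ", nrow(raw), " raw domain hits")

  seq_lens <- stats::setNames(Biostrings::width(seqs), ids)
  hits <- filter_hits(raw, db, seq_lens,
                      min_coverage = config$min_coverage,
                      max_evalue = config$max_evalue)
  message("[filter] ", nrow(hits), " hits pass coverage >= ",
          config$min_coverage, ", E-value <= ", config$max_evalue)
  hits <- resolve_best_hits(hits)
  message("[resolve] ", nrow(hits), " hits after best-hit resolution")

  cls_list <- lapply(ids, function(id) {
    h <- hits[hits$element_id == id, , drop = FALSE]
    call_completeness(classify_element(h, element_id = id))
  })
  names(cls_list) <- ids
  classified <- vapply(cls_list, function(x) !is.na(x$order), logical(1))
  message("[classify] pass 1: ", sum(classified), "/", length(ids),
          " elements classified")

  rescue_hits <- empty_similarity_hits()
  if (config$pass2_enabled && any(!classified)) {
    tab1 <- classification_table(cls_list[classified])
    subj_ok <- !is.na(tab1$superfamily) & tab1$superfamily != "unknown"
    subjects <- seqs[tab1$element_id[subj_ok]]
    queries <- seqs[!classified]
    if (length(subjects) > 0L && length(queries) > 0L) {
      rescue_hits <- similarity_search(queries, subjects,
                                       backend = config$rescue_backend)
      rescued <- apply_80_80_80(rescue_hits, tab1[subj_ok, , drop = FALSE],
                                min_aln_bp = config$rule_min_aln_bp,
                                min_identity = config$rule_min_identity,
                                min_qcov = config$rule_min_qcov)
      for (cls in rescued) cls_list[[cls$element_id]] <- cls
      message("[rescue] ", length(rescued), "/", length(queries),
              " unclassified elements rescued (superfamily level)")
    } else {
      message("[rescue] skipped (no queries or no subjects)")
    }
  }
  ## invariant: rescue never assigns a clade
  stopifnot(all(vapply(cls_list, function(x) {
    is.na(x$pass_no) || x$pass_no != 2L || is.na(x$clade)
  }, logical(1))))

  cls_list <- cls_list[order(names(cls_list))]
  tab <- classification_table(cls_list)
  domains <- extract_domains(cls_list, seqs,
                             genetic_code = config$genetic_code)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(out_dir, paste0(prefix, ".cls.tsv"))
    gff <- file.path(out_dir, paste0(prefix, ".dom.gff3"))
    write_classifications(cls_list, tsv_path = tsv, gff_path = gff)
    dom_files <- write_domain_fastas(domains, out_dir, prefix = prefix)
    files <- c(tsv, gff, dom_files)
  }
  message(sprintf("[done] %.1fs", as.numeric(Sys.time() - t0, units = "secs")))
  list(classifications = cls_list, table = tab, hits = hits,
       rescue_hits = rescue_hits, domains = domains, files = files)
}
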