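## Profile-HMM domain database: an HMMER3 text file plus a sidecar metadata
## table (profile_name, te_class, order, superfamily, clade, domain_label,
## model_length).  The metadata table is the authoritative lineage source;
## name parsing in the "path" dialect is the fallback, so REXdb- or
## GyDB-style databases only need a metadata TSV, not a renamed HMM file.

PROFILE_META_COLS <- c("profile_name", "te_class", "order", "superfamily",
                       "clade", "domain_label", "model_length")

new_profile_db <- function(hmm_path, meta, db_name = "db",
                           source = "fixture") {
  stopifnot(all(PROFILE_META_COLS %in% colnames(meta)))
  if (anyDuplicated(meta$profile_name)) {
    stop("duplicate profile names in database metadata", call. = FALSE)
  }
  structure(list(hmm_path = hmm_path, meta = meta, db_name = db_name,
                 source = source),
            class = "profile_db")
}

#' @export
print.profile_db <- function(x, ...) {
  cat("<profile_db> ", x$db_name, " (", x$source, "): ",
      nrow(x$meta), " profiles\n  hmm: ", x$hmm_path, "\n", sep = "")
  invisible(x)
}

#' Load a profile-HMM domain database
#'
#' Reads an HMMER3 text-format database together with its lineage metadata.
#' If `meta_path` is `NULL`, the sidecar `<hmm_path>.meta.tsv` is used when
#' present; otherwise each profile name is parsed with
#' [parse_profile_name()].
#'
#' @param hmm_path Path to the HMMER3 text database.
#' @param meta_path Optional metadata TSV with columns `profile_name`,
#'   `te_class`, `order`, `superfamily`, `clade`, `domain_label`
#'   (`model_length` is always taken from the HMM file).
#' @param db_name Display name.
#' @param source One of `"REXdb-style"`, `"GyDB-style"`, `"fixture"`.
#' @return A `profile_db` object.
#' @export
read_profile_db <- function(hmm_path, meta_path = NULL, db_name = basename(hmm_path),
                            source = "REXdb-style") {
  if (!file.exists(hmm_path)) {
    stop("HMM database not found: ", hmm_path, call. = FALSE)
  }
  lens <- scan_hmm_lengths(hmm_path)
  if (is.null(meta_path)) {
    cand <- paste0(hmm_path, ".meta.tsv")
    if (file.exists(cand)) meta_path <- cand
  }
  if (!is.null(meta_path)) {
    meta <- read_tsv0(meta_path)
    need <- setdiff(PROFILE_META_COLS, c(colnames(meta), "model_length"))
    if (length(need)) {
      stop("metadata TSV is missing column(s): ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(names(lens), meta$profile_name)
    if (length(missing)) {
      stop("profile(s) in HMM file absent from metadata: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    meta <- meta[meta$profile_name %in% names(lens), , drop = FALSE]
    meta$model_length <- unname(lens[meta$profile_name])
  } else {
    parsed <- lapply(names(lens), parse_profile_name)
    meta <- data.frame(
      profile_name = names(lens),
      te_class = vapply(parsed, function(p) p$lineage$te_class, character(1)),
      order = vapply(parsed, function(p) p$lineage$order, character(1)),
      superfamily = vapply(parsed, function(p) p$lineage$superfamily,
                           character(1)),
      clade = vapply(parsed, function(p) p$lineage$clade, character(1)),
      domain_label = vapply(parsed, function(p) p$domain_label, character(1)),
      model_length = unname(lens),
      stringsAsFactors = FALSE
    )
  }
  meta$domain_label <- normalize_domain_label(meta$domain_label)
  new_profile_db(hmm_path, meta, db_name = db_name, source = source)
}

## Parse NAME/LENG pairs out of an HMMER3 text file.
scan_hmm_lengths <- function(hmm_path) {
  lines <- readLines(hmm_path)
  names_ <- sub("^NAME\\s+", "", grep("^NAME\\s", lines, value = TRUE))
  lens <- as.integer(sub("^LENG\\s+", "", grep("^LENG\\s", lines, value = TRUE)))
  if (length(names_) == 0L || length(names_) != length(lens)) {
    stop("'", hmm_path, "' does not look like an HMMER3 text database",
         call. = FALSE)
  }
  stats::setNames(lens, names_)
}

#' Build a profile database from per-clade domain alignments
#'
#' Runs `hmmbuild` on each protein multiple alignment and concatenates the
#' models into one HMMER3 text database with a sidecar metadata TSV.  Profile
#' names must follow the `"path"` dialect (see [parse_profile_name()]) so the
#' lineage can be recorded.  The number of match states per model
#' (`model_length`) is whatever the engine assigns; for ungapped alignments
#' it equals the alignment length.
#'
#' The `DATE` header each model carries is rewritten to a fixed epoch string
#' so that databases rebuilt from identical alignments are byte-identical.
#'
#' @param alignments Named list: profile name -> character vector of aligned
#'   protein rows (equal lengths, `-` for gaps, at least 2 rows).
#' @param out_dir Directory for the database files (created if needed).
#' @param db_name Basename of the database (`<db_name>.hmm`).
#' @return A `profile_db`.  An empty alignment list yields an empty database
#'   (no HMM file rows, empty metadata).
#' @export
build_profiles_from_alignments <- function(alignments, out_dir = tempfile("db"),
                                           db_name = "fixture_db") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hmm_path <- file.path(out_dir, paste0(db_name, ".hmm"))
  if (length(alignments) == 0L) {
    file.create(hmm_path)
    meta <- data.frame(profile_name = character(0), te_class = character(0),
                       order = character(0), superfamily = character(0),
                       clade = character(0), domain_label = character(0),
                       model_length = integer(0), stringsAsFactors = FALSE)
    write_tsv0(meta, paste0(hmm_path, ".meta.tsv"))
    return(new_profile_db(hmm_path, meta, db_name = db_name,
                          source = "fixture"))
  }
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    stop("alignments must be a named list (names are profile names)",
         call. = FALSE)
  }
  hmmbuild <- check_tool("hmmbuild")
  work <- file.path(out_dir, "hmmbuild_work")
  dir.create(work, showWarnings = FALSE)
  pieces <- character(0)
  for (name in names(alignments)) {
    rows <- alignments[[name]]
    if (length(rows) < 2L) {
      stop("alignment '", name, "' has fewer than 2 rows", call. = FALSE)
    }
    if (length(unique(nchar(rows))) != 1L) {
      stop("alignment '", name, "' is ragged (unequal row lengths)",
           call. = FALSE)
    }
    parse_profile_name(name)  # validates the grammar early
    safe <- gsub("[^A-Za-z0-9]", "_", name)
    afa <- file.path(work, paste0(safe, ".afa"))
    writeLines(c(rbind(paste0(">row", seq_along(rows)), rows)), afa)
    one <- file.path(work, paste0(safe, ".hmm"))
    status <- system2(hmmbuild, c("--amino", "-n", shQuote(name), one, afa),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) {
      stop("hmmbuild failed for alignment '", name, "'", call. = FALSE)
    }
    pieces <- c(pieces, one)
  }
  txt <- unlist(lapply(pieces, readLines), use.names = FALSE)
  txt <- sub("^DATE .*$", "DATE  Thu Jan  1 00:00:00 1970", txt)
  writeLines(txt, hmm_path)
  unlink(work, recursive = TRUE)
  lens <- scan_hmm_lengths(hmm_path)
  parsed <- lapply(names(lens), parse_profile_name)
  meta <- data.frame(
    profile_name = names(lens),
    te_class = vapply(parsed, function(p) p$lineage$te_class, character(1)),
    order = vapply(parsed, function(p) p$lineage$order, character(1)),
    superfamily = vapply(parsed, function(p) p$lineage$superfamily,
                         character(1)),
    clade = vapply(parsed, function(p) p$lineage$clade, character(1)),
    domain_label = vapply(parsed, function(p) p$domain_label, character(1)),
    model_length = unname(lens),
    stringsAsFactors = FALSE
  )
  write_tsv0(meta, paste0(hmm_path, ".meta.tsv"))
  new_profile_db(hmm_path, meta, db_name = db_name, source = "fixture")
}

## hmmscan needs the pressed binary index; (re)press when absent or stale.
ensure_pressed <- function(db) {
  idx <- paste0(db$hmm_path, ".h3i")
  if (!file.exists(idx) ||
      file.mtime(idx) < file.mtime(db$hmm_path)) {
    hmmpress <- check_tool("hmmpress")
    status <- system2(hmmpress, c("-f", db$hmm_path),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) {
      stop("hmmpress failed on ", db$hmm_path, call. = FALSE)
    }
  }
  invisible(db)
}
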