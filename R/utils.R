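## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a required external tool
#'
#' @param tool Executable name, e.g. `"hmmscan"`.
#' @return Absolute path to the executable.
#' @keywords internal
check_tool <- function(tool) {
  path <- Sys.which(tool)
  if (!nzchar(path)) {
    stop("External tool '", tool, "' is required but was not found on PATH. ",
         "Install HMMER/BLAST+ or adjust PATH.", call. = FALSE)
  }
  unname(path)
}

## Byte-stable TSV writer: LF newlines, no quoting, NA rendered empty.
write_tsv0 <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0L) {
    cols <- lapply(df, function(col) {
      x <- as.character(col)
      x[is.na(x)] <- ""
      x
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

read_tsv0 <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    na.strings = "")
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Deterministic random DNA / protein draws (uniform alphabet).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}
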