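# Shared fixtures, cached per test session (profile databases are built by
# the external engine once and reused).

.fx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fx_cache, inherits = FALSE)) {
    assign(key, build(), envir = .fx_cache)
  }
  get(key, envir = .fx_cache, inherits = FALSE)
}

# Two-clade spec (one Copia, one Gypsy clade, 3 elements each): fast unit
# fixture.
tiny_spec <- function(...) {
  fixture_spec(clades = data.frame(superfamily = c("Copia", "Gypsy"),
                                   clade = c("Ale", "CRM"),
                                   stringsAsFactors = FALSE),
               n_elements_per_clade = 3L, ...)
}

tiny_fixture <- function() {
  cache_get("tiny", function() {
    spec <- tiny_spec()
    gen <- generate_database(spec, out_dir = file.path(tempdir(), "tinydb"))
    lib <- generate_library(spec, gen$ancestors)
    list(spec = spec, db = gen$db, ancestors = gen$ancestors,
         seqs = lib$seqs, truth = lib$truth)
  })
}

# The reference study conditions: fixture_spec() defaults (seed 42, eight
# clades, ten elements each, zero mutation).
full_fixture <- function() {
  cache_get("full", function() {
    spec <- fixture_spec()
    gen <- generate_database(spec, out_dir = file.path(tempdir(), "fulldb"))
    lib <- generate_library(spec, gen$ancestors)
    list(spec = spec, db = gen$db, ancestors = gen$ancestors,
         seqs = lib$seqs, truth = lib$truth)
  })
}

full_run <- function() {
  cache_get("full_run", function() {
    fx <- full_fixture()
    out <- file.path(tempdir(), "full_run1")
    res <- suppressMessages(
      run_pipeline(fx$seqs, fx$db, pipeline_config(threads = 1L),
                   out_dir = out, prefix = "acc"))
    list(res = res, out_dir = out)
  })
}

# ---- independent oracles -------------------------------------------------

# Brute-force codon-loop translation (independent of the Biostrings path):
# walks the string codon by codon against the standard code table.
oracle_translate <- function(ntseq, offset = 0) {
  code <- Biostrings::GENETIC_CODE  # lookup table only; the loop is ours
  n <- nchar(ntseq)
  aa <- character(0)
  i <- offset + 1
  while (i + 2 <= n) {
    codon <- substr(ntseq, i, i + 2)
    aa <- c(aa, if (grepl("[^ACGT]", codon)) "X"
            else unname(code[codon]))
    i <- i + 3
  }
  paste(aa, collapse = "")
}

oracle_revcomp <- function(ntseq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(ntseq, "")[[1]]]), collapse = "")
}

oracle_six_frames <- function(ntseq) {
  rc <- oracle_revcomp(ntseq)
  data.frame(frame = c(1L, 2L, 3L, -1L, -2L, -3L),
             protein = c(oracle_translate(ntseq, 0),
                         oracle_translate(ntseq, 1),
                         oracle_translate(ntseq, 2),
                         oracle_translate(rc, 0),
                         oracle_translate(rc, 1),
                         oracle_translate(rc, 2)),
             stringsAsFactors = FALSE)
}

# Brute-force best-hit resolver: repeatedly extract the globally best
# remaining hit and delete everything conflicting with it.  (Independent
# loop structure from the greedy implementation, same contract.)
oracle_resolve <- function(hits) {
  kept <- hits[0, , drop = FALSE]
  pool <- hits
  overlap_frac <- function(s1, e1, s2, e2) {
    ov <- min(e1, e2) - max(s1, s2) + 1
    if (ov <= 0) return(0)
    ov / min(e1 - s1 + 1, e2 - s2 + 1)
  }
  while (nrow(pool) > 0L) {
    rank <- order(-pool$score, pool$evalue, pool$profile_name)
    best <- pool[rank[1], , drop = FALSE]
    kept <- rbind(kept, best)
    drop <- vapply(seq_len(nrow(pool)), function(i) {
      overlap_frac(pool$nt_start[i], pool$nt_end[i],
                   best$nt_start, best$nt_end) > 0.5
    }, logical(1))
    drop[rank[1]] <- TRUE
    pool <- pool[!drop, , drop = FALSE]
  }
  kept[order(kept$nt_start, kept$nt_end, kept$profile_name), , drop = FALSE]
}

# Ungapped percent identity between equal-length strings.
oracle_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  100 * mean(va == vb)
}

# Construct a resolved domain-hit data.frame row by hand (for classify /
# completeness tests that bypass the search engine).
make_hit <- function(element_id = "el", domain_label = "RT",
                     superfamily = "Copia", clade = "Ale", order = "LTR",
                     score = 100, evalue = 1e-10, nt_start = 1L,
                     nt_end = 300L, strand = "+", frame = 1L,
                     profile_name = NULL, coverage = 0.9) {
  if (is.null(profile_name)) {
    profile_name <- paste0(order,
                           if (!is.na(superfamily)) paste0("/", superfamily),
                           if (!is.na(clade)) paste0("/", clade),
                           ":", domain_label)
  }
  data.frame(element_id = element_id, frame = frame,
             profile_name = profile_name, domain_label = domain_label,
             order = order, superfamily = superfamily, clade = clade,
             score = score, evalue = evalue, coverage = coverage,
             aa_from = 1L, aa_to = as.integer((nt_end - nt_start + 1) / 3),
             nt_start = as.integer(nt_start), nt_end = as.integer(nt_end),
             strand = strand, stringsAsFactors = FALSE)
}

# Random hit set generator for resolution property tests.
random_hit_set <- function(n) {
  starts <- sample.int(2000L, n, replace = TRUE)
  widths <- sample(30:600, n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_hit(score = round(runif(1, 10, 300), 1),
             evalue = 10^-runif(1, 4, 30),
             nt_start = starts[i], nt_end = starts[i] + widths[i] - 1L,
             profile_name = sprintf("LTR/Copia/C%02d:RT", sample.int(20, 1)))
  }))
}
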