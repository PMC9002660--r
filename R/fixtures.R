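## Synthetic fixtures: a seeded mini profile database plus a labelled TE
## library with planted domains, so the whole pipeline is testable without
## any downloads.  The generator emulates a curated LTR-retrotransposon
## library (planted polyprotein domains in superfamily-canonical order,
## optional substitutions, frameshifts, domain losses, and non-autonomous
## derivatives); it does not simulate LTRs, PBS or TSDs.

## One fixed codon per amino acid (common plant-biased codons).  Using a
## single codon keeps nucleotide identity between sibling elements high, so
## the similarity rescue pass is exercised deterministically.
REVTRANS_CODON <- c(
  A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG")

reverse_translate <- function(protein) {
  paste(REVTRANS_CODON[strsplit(protein, "")[[1]]], collapse = "")
}

default_fixture_clades <- function() {
  data.frame(
    superfamily = c(rep("Copia", 4), rep("Gypsy", 4)),
    clade = c("Ale", "Angela", "SIRE", "Tork", "CRM", "Reina", "Tekay",
              "Athila"),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic fixture
#'
#' Parameters of the planted-domain generator.  The defaults define the
#' package's reference study conditions: eight clades (four Copia, four
#' Gypsy), ten elements per clade, and no mutational corruption.
#'
#' @param seed Integer seed; a fixed seed makes every output byte-identical
#'   across runs.
#' @param clades data.frame with columns `superfamily`, `clade`.
#' @param domain_length_aa Named lengths (aa) of the five planted domains.
#' @param n_elements_per_clade Elements generated per clade.
#' @param substitution_rate Per-base nucleotide substitution probability
#'   applied to each element.
#' @param domain_loss_prob Per-domain whole-domain deletion probability;
#'   either a scalar or a vector named by domain label (unnamed labels
#'   default to 0), e.g. `c(RH = 1)` to delete every RNase H.
#' @param frameshift_prob Per-domain probability of a single-base indel.
#' @param nonautonomous_fraction Fraction of each clade's elements emitted
#'   as non-autonomous derivatives: all domains removed, backbone
#'   (pads/linkers) copied from an autonomous sibling — the rescue targets.
#' @param intergenic_pad_bp Random pad length at each element end.
#' @param linker_bp Random linker length between adjacent domains.
#' @param clade_divergence Per-site amino-acid divergence of each clade
#'   ancestor from its superfamily root (0.2 keeps clades >= 60% identical
#'   to the root while still separable by their profiles).
#' @param within_clade_noise Per-site noise of each alignment row around the
#'   clade ancestor.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L,
                         clades = default_fixture_clades(),
                         domain_length_aa = c(GAG = 150L, AP = 120L,
                                              INT = 280L, RT = 250L,
                                              RH = 150L),
                         n_elements_per_clade = 10L,
                         substitution_rate = 0,
                         domain_loss_prob = 0,
                         frameshift_prob = 0,
                         nonautonomous_fraction = 0,
                         intergenic_pad_bp = 150L,
                         linker_bp = 30L,
                         clade_divergence = 0.20,
                         within_clade_noise = 0.03) {
  if (!is.null(names(domain_loss_prob))) {
    full <- stats::setNames(rep(0, length(DOMAIN_LABELS)), DOMAIN_LABELS)
    full[names(domain_loss_prob)] <- domain_loss_prob
    domain_loss_prob <- full
  } else if (length(domain_loss_prob) == 1L) {
    domain_loss_prob <- stats::setNames(rep(domain_loss_prob,
                                            length(DOMAIN_LABELS)),
                                        DOMAIN_LABELS)
  } else {
    stop("domain_loss_prob must be a scalar or a named vector",
         call. = FALSE)
  }
  rates <- c(substitution_rate, domain_loss_prob, frameshift_prob,
             nonautonomous_fraction, clade_divergence, within_clade_noise)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(clades) < 2L) {
    stop("a fixture needs at least 2 clades", call. = FALSE)
  }
  if (!all(DOMAIN_LABELS %in% names(domain_length_aa))) {
    stop("domain_length_aa must name all of ",
         paste(DOMAIN_LABELS, collapse = ", "), call. = FALSE)
  }
  structure(list(seed = as.integer(seed), clades = clades,
                 domain_length_aa = domain_length_aa,
                 n_elements_per_clade = as.integer(n_elements_per_clade),
                 substitution_rate = substitution_rate,
                 domain_loss_prob = domain_loss_prob,
                 frameshift_prob = frameshift_prob,
                 nonautonomous_fraction = nonautonomous_fraction,
                 intergenic_pad_bp = as.integer(intergenic_pad_bp),
                 linker_bp = as.integer(linker_bp),
                 clade_divergence = clade_divergence,
                 within_clade_noise = within_clade_noise),
            class = "fixture_spec")
}

mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  v <- strsplit(protein, "")[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(a) sample(setdiff(AA20, a), 1L),
                     character(1))
  }
  paste(v, collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  paste(v, collapse = "")
}

## Single-base insertion or deletion at a random internal position.
frameshift_dna <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), 1L)
  if (runif(1) < 0.5) {
    v <- v[-pos]
  } else {
    v <- append(v, sample(c("A", "C", "G", "T"), 1L), after = pos)
  }
  paste(v, collapse = "")
}

#' Generate a fixture profile database
#'
#' Draws, under the spec's seed, one random ancestor protein per
#' (superfamily, domain) root; derives each clade's ancestor by per-site
#' divergence from its superfamily root (so clades of one superfamily stay
#' mutually similar while different superfamilies are unrelated random
#' proteins); builds a 6-row noised alignment per (clade, domain); and runs
#' the profile builder over all alignments.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Directory for the database files.
#' @return List with `db` (a `profile_db`) and `ancestors` (nested list
#'   `superfamily -> clade -> domain -> protein`, plus a `.roots` entry per
#'   superfamily).
#' @export
generate_database <- function(spec, out_dir = tempfile("fixdb")) {
  alignments <- list()
  ancestors <- list()
  with_seed(spec$seed, {
    for (sf in unique(spec$clades$superfamily)) {
      roots <- lapply(spec$domain_length_aa[DOMAIN_LABELS], random_protein)
      ancestors[[sf]] <- list(.roots = roots)
      for (cl in spec$clades$clade[spec$clades$superfamily == sf]) {
        ancestors[[sf]][[cl]] <- list()
        for (dom in DOMAIN_LABELS) {
          anc <- mutate_protein(roots[[dom]], spec$clade_divergence)
          ancestors[[sf]][[cl]][[dom]] <- anc
          name <- render_profile_name(
            lineage("LTR", superfamily = sf, clade = cl), dom)
          alignments[[name]] <- vapply(1:6, function(i) {
            mutate_protein(anc, spec$within_clade_noise)
          }, character(1))
        }
      }
    }
  })
  db <- build_profiles_from_alignments(alignments, out_dir = out_dir,
                                       db_name = "fixture_db")
  list(db = db, ancestors = ancestors)
}

#' Generate a labelled fixture TE library
#'
#' Each autonomous element is built as pad + reverse-translated clade
#' domains in the superfamily's canonical order (with random linkers) +
#' pad, placed on a random strand, then corrupted at the spec's rates:
#' per-base substitutions, per-domain single-base frameshifts, and
#' per-domain whole-domain losses.  A `nonautonomous_fraction` of each
#' clade's elements instead carry only the backbone (pads and linkers)
#' copied from an autonomous sibling — elements classifiable only by
#' sequence similarity.  Uses the RNG stream seeded with `spec$seed + 1`
#' (offset from the database stream so the two stages are independently
#' reproducible).
#'
#' @param spec A [fixture_spec()].
#' @param ancestors Ancestor proteins from [generate_database()].
#' @return List with `seqs` (a named [Biostrings::DNAStringSet], names
#'   `id#LTR/Superfamily`-labelled on read/write) and `truth` (data.frame:
#'   `element_id`, `order`, `superfamily`, `clade`, `complete`, `strand`,
#'   `autonomous`).
#' @export
generate_library <- function(spec, ancestors) {
  canonical <- canonical_domain_orders()
  seqs <- character(0)
  truth <- list()
  with_seed(spec$seed + 1L, {
    for (k in seq_len(nrow(spec$clades))) {
      sf <- spec$clades$superfamily[k]
      cl <- spec$clades$clade[k]
      doms <- canonical[[sf]]
      if (is.null(doms)) doms <- DOMAIN_LABELS
      n <- spec$n_elements_per_clade
      n_nonauto <- min(round(n * spec$nonautonomous_fraction), n - 1L)
      sibling_backbone <- NULL
      for (i in seq_len(n)) {
        id <- sprintf("%s_%s_%02d", sf, cl, i)
        nonauto <- i > n - n_nonauto
        if (!nonauto) {
          backbone <- list(pad5 = random_dna(spec$intergenic_pad_bp))
          parts <- backbone$pad5
          kept_domains <- character(0)
          for (dom in doms) {
            if (runif(1) < spec$domain_loss_prob[[dom]]) next
            nt <- reverse_translate(ancestors[[sf]][[cl]][[dom]])
            if (runif(1) < spec$frameshift_prob) nt <- frameshift_dna(nt)
            link <- random_dna(spec$linker_bp)
            backbone[[paste0("link_", dom)]] <- link
            parts <- paste0(parts, nt, link)
            kept_domains <- c(kept_domains, dom)
          }
          backbone$pad3 <- random_dna(spec$intergenic_pad_bp)
          parts <- paste0(parts, backbone$pad3)
          if (is.null(sibling_backbone)) sibling_backbone <- backbone
          seq <- mutate_dna(parts, spec$substitution_rate)
          complete <- identical(kept_domains, doms)
        } else {
          seq <- paste(unlist(sibling_backbone), collapse = "")
          seq <- mutate_dna(seq, spec$substitution_rate)
          complete <- FALSE
        }
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") {
          seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
        }
        seqs[id] <- seq
        truth[[length(truth) + 1L]] <- data.frame(
          element_id = id, order = "LTR", superfamily = sf, clade = cl,
          complete = if (complete) "yes" else "no", strand = strand,
          autonomous = !nonauto, stringsAsFactors = FALSE)
      }
    }
  })
  out <- Biostrings::DNAStringSet(seqs)
  truth <- do.call(rbind, truth)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    description = "", truth_label = paste(truth$order, truth$superfamily,
                                          sep = "/"))
  list(seqs = out, truth = truth)
}

#' Write fixture files to a directory
#'
#' Builds the database and the library and writes: `fixture_db.hmm` (+
#' `.meta.tsv`), `library.fa` (headers `id#LTR/Superfamily`), and
#' `truth.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Invisibly, a list with `db`, `ancestors`, `seqs`, `truth` and
#'   the file paths.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_database(spec, out_dir = dir)
  lib <- generate_library(spec, gen$ancestors)
  fa <- file.path(dir, "library.fa")
  labelled <- lib$seqs
  names(labelled) <- paste0(names(lib$seqs), "#",
                            S4Vectors::mcols(lib$seqs)$truth_label)
  write_fasta(labelled, fa)
  truth_path <- file.path(dir, "truth.tsv")
  write_tsv0(lib$truth, truth_path)
  invisible(list(db = gen$db, ancestors = gen$ancestors, seqs = lib$seqs,
                 truth = lib$truth, library_path = fa,
                 truth_path = truth_path))
}
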