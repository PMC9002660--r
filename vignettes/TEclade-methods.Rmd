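---
title: "Classifying transposable elements from protein-domain evidence"
author: "TEclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transposable elements from protein-domain evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transposable elements (TEs) dominate many plant genomes, and long terminal
repeat retrotransposons (LTR-RTs) dominate among them.  Most classifiers
stop at the superfamily level (Copia vs Gypsy); yet the internal
polyprotein domains of LTR-RTs — capsid protein (GAG), aspartic proteinase
(AP), integrase (INT), reverse transcriptase (RT) and RNase H (RH) — carry
enough phylogenetic signal to place elements into *clades* (Ale, Tork,
SIRE, CRM, Tekay, Athila, ...).  TEclade classifies a nucleotide TE
library against a profile-HMM database of such domains, whose profile
names (or a sidecar metadata table) encode a lineage path
`order/superfamily/clade`, and emits per-element classifications,
completeness calls, domain features (GFF3), and alignment-ready domain
FASTA for tree building.

## The procedure and its assumptions

1. **Six-frame translation.**  Each element is translated in all six
   frames.  Any codon containing a non-ACGT base becomes `X` (profile-HMM
   engines score `X` neutrally) and internal stops are kept as `*`; no
   initiator-codon special-casing is applied, since these are arbitrary
   windows, not genes.  The genetic code defaults to the standard table
   and is configurable.
2. **Domain search.**  Translated frames are searched with `hmmscan`
   (HMMER 3) against the database, with permissive reporting thresholds so
   that the published filter is applied by our own code: hits with
   **model coverage < 20% or per-domain E-value > 1e-3 are discarded**.
   Coverage is measured against the profile's match states
   (`(hmm_to − hmm_from + 1)/model_length`) — the convention under which
   coverage speaks to domain completeness — and the per-domain
   *independent* E-value is used, since filtering operates on domains.
   Both discards are phrased as strict inequalities, so boundary values
   (coverage exactly 0.20, E-value exactly 1e-3) are kept.
3. **Best-hit resolution.**  Where several profiles explain the same
   locus, only the best hit survives.  "Same locus" is an overlap group
   in nucleotide space: two hits compete when their forward-strand
   intervals overlap by more than 50% of the shorter one.  This is
   deliberately *not* per-domain-label deduplication: tandemly duplicated
   domains at distinct loci all survive.  Ranking is bit score, then
   lower E-value, then lexicographic profile name (a total order, for
   determinism).
4. **Classification.**  An element's lineage is aggregated from its
   resolved hits by score-weighted majority, level by level: at each of
   order → superfamily → clade, the value with the greatest summed bit
   score wins, and the classification descends only if that winner
   exceeds 50% of the total summed score under consideration.  Ties and
   weak majorities stop the descent and are reported as `unknown` at the
   contested level.  This >50% descent rule is this package's own design
   choice: the evidence aggregation had to be defined somewhere, and a
   score-weighted majority degrades gracefully to shallower (but safe)
   levels under conflicting evidence.  Strand is likewise the
   summed-score majority strand.
5. **Completeness.**  A Copia or Gypsy element is *complete* when all
   five canonical domains are present exactly once, on one strand, in the
   superfamily's canonical 5'→3' order — Copia: GAG, AP, INT, RT, RH;
   Gypsy: GAG, AP, RT, RH, INT (after Wicker's hierarchy; stored as
   configuration data in `canonical_domain_orders()`, not hard-coded
   logic).
6. **Similarity rescue (pass 2).**  Elements with no usable domain
   evidence — typically non-autonomous derivatives that lost their coding
   regions — are compared at the nucleotide level with the pass-1
   classified elements and accepted under the **80-80-80 rule**: best hit
   with ≥ 80 bp alignment, ≥ 80% identity, ≥ 80% sequence coverage (all
   inclusive).  Coverage is read as coverage of the *query* (the unknown
   element should be substantially explained by a known one) and is
   computed from the union of all HSP query intervals against the best
   subject, so a derivative whose matching segments are interrupted in
   the donor is fully credited; identity and alignment length come from
   the single best HSP.  Rescue assigns lineage only to superfamily depth
   — never a clade — and runs a single round: rescued elements are not
   reused as subjects, because transitive rescue risks label drift.
7. **Domain extraction.**  Per-domain protein and nucleotide FASTA are
   emitted for the retained hits, plus a concatenated set (default
   RT–RH–INT, in that label order regardless of genomic order, which
   differs between Copia and Gypsy).  Elements with duplicated copies of
   a requested domain are excluded from concatenation (ambiguous
   orthology) but stay in the per-domain files.  Every emitted record
   satisfies `translate(oriented nt) == aa`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_coverage` | 0.20 | minimum fraction of profile match states spanned |
| `max_evalue` | 1e-3 | maximum per-domain independent E-value |
| `rule_min_aln_bp` | 80 | rescue: minimum best-HSP alignment length (bp) |
| `rule_min_identity` | 80 | rescue: minimum best-HSP percent identity |
| `rule_min_qcov` | 80 | rescue: minimum percent of query covered (HSP union) |
| `pass2_enabled` | TRUE | run the rescue pass |
| `threads` | 1 | hmmscan workers; provably no effect on outputs |

The filter and rule defaults are the published values; the overlap
threshold (50% of the shorter interval) and the majority-descent
threshold (50% of summed score) are package choices, fixed and
documented here.

## Engine backends

Profile-HMM model building and search are not reimplemented: `hmmbuild`
/`hmmpress`/`hmmscan` (HMMER 3) do that work behind
`build_profiles_from_alignments()` and `search_frames()`, which parse the
standard per-domain table (`--domtblout`).  `hmmbuild` stamps a build
date into each model; we rewrite that header to a fixed epoch string so
databases rebuilt from identical alignments are byte-identical.  The
rescue aligner defaults to an exact local aligner
(`Biostrings::pairwiseAlignment`, match 2 / mismatch −3 / gap open 5 /
gap extend 2) with iterative query masking to recover multiple HSPs; an
external BLAST+ backend (`makeblastdb`/`blastn`, tabular output) is
available via `rescue_backend = "external"` and both backends are
collapsed through the same HSP-union code path.

## The synthetic fixture generator

`fixture_spec()` / `generate_database()` / `generate_library()` build a
fully self-contained test world: per (superfamily, domain) a random root
protein; per clade an ancestor derived from the root at 20% per-site
divergence (clades stay ≥ 60% identical to their root, superfamilies are
unrelated random sequences, so profiles separate cleanly); per (clade,
domain) a 6-row alignment of 3%-noised copies, compiled into profiles.
Elements are pads + reverse-translated domains in the canonical order +
pads, on a random strand, then corrupted at configurable rates:
per-base substitutions, per-domain single-base frameshifts, per-domain
losses, and a fraction of non-autonomous derivatives that keep only the
backbone (pads/linkers) of an autonomous sibling — the rescue targets.
Reverse translation uses a fixed one-codon-per-amino-acid table so
sibling elements are near-identical at the nucleotide level and the
80-80-80 arithmetic is exercised deterministically.

The generator's reference conditions (its defaults) are seed 42, four
Copia clades + four Gypsy clades, ten elements per clade, zero
corruption.  All randomness flows from the single seed (the library
stream is offset by +1 from the database stream so each stage is
independently reproducible), and output is byte-identical across runs at
a fixed seed.

What the fixtures do **not** emulate: real LTR structure (no LTRs, PBS,
or TSDs), biological codon usage, alignment-worthy indel processes, or
the curation noise of real TE libraries.  Perfect recovery on the clean
fixture therefore demonstrates the correctness of the plumbing —
coordinate mapping, filtering, aggregation, rescue arithmetic — not
field performance on real libraries, which depends on the quality of the
user-supplied domain database.

## Benchmarking conventions

`score_classifications()` computes per-category precision
(`tp/(tp+fp)`) and sensitivity (`tp/(tp+fn)`) at a chosen level.
Unclassified predictions (including those stopping above the requested
level) count as false negatives only, never false positives — the usual
treatment of abstentions in classifier comparisons.  Elements whose
truth label does not reach the level (or is `unknown`) are excluded.

## Numerical and degenerate-input choices

* Coordinates in every report are 1-based inclusive on the forward
  strand (GFF convention); minus-frame hits are flipped via
  `map_aa_to_nt()`.
* Sequences shorter than one codon translate to six empty proteins, not
  an error; empty libraries and empty databases yield empty, typed
  results.
* All output files are byte-deterministic: elements are sorted by id,
  ties in every ranking are broken by a total order, and thread count
  affects only wall time.
* Test and acceptance problem sizes (80-element reference library; a
  4-clade, 20-element library across a 0–0.3 substitution sweep with 5
  seeds per rate, rescue disabled since it cannot affect clade-level
  scores) are the package's own choices, sized so the whole suite runs
  comfortably on a laptop.

## Known limitations

* Clade assignment quality is bounded by the profile database; the
  shipped generator is for testing, and real analyses should point
  `read_profile_db()` at a curated domain database plus metadata TSV.
* The rescue pass propagates whatever pass-1 says: a systematic pass-1
  error can be amplified by similarity transfer (mitigated, but not
  removed, by the single-round design).
* Elements with genuinely chimeric domain content are reported at the
  deepest consistent level with `unknown` below it, not split.
* No structural detection: the package classifies sequences it is
  given; it does not find elements or their boundaries in a genome.
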