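# TEclade

Classify transposable-element (TE) library sequences by protein-domain
evidence: order and superfamily for any TE, and **clade-level**
assignments for LTR retrotransposons (Copia and Gypsy), the repeat class
that dominates plant genomes.

Most TE classifiers stop at Copia-vs-Gypsy.  TEclade searches all six
translation frames of each element against a profile-HMM database of the
canonical polyprotein domains — capsid protein (GAG), aspartic proteinase
(AP), integrase (INT), reverse transcriptase (RT), RNase H (RH) — whose
profile names encode a lineage path such as `LTR/Gypsy/CRM:RT`.  From the
filtered hits it derives:

* a per-element classification (deepest consistent of
  order → superfamily → clade, by score-weighted majority with a >50%
  descent rule);
* a **completeness** call: all five domains present once, on one strand,
  in the superfamily's canonical 5'→3' order (Copia GAG-AP-INT-RT-RH,
  Gypsy GAG-AP-RT-RH-INT);
* a second-pass **rescue** of elements without domain evidence (e.g.
  non-autonomous derivatives) by nucleotide similarity to first-pass
  classified elements under the 80-80-80 rule (≥ 80 bp alignment, ≥ 80%
  identity, ≥ 80% query coverage), at superfamily level only;
* per-domain and concatenated RT–RH–INT FASTA, alignment-ready for
  phylogenetics.

Hits are kept when profile model coverage ≥ 20% and per-domain
E-value ≤ 1e-3; overlapping hits are resolved to the highest-scoring one
per locus.  Everything is deterministic: identical inputs give
byte-identical TSV/GFF3/FASTA outputs regardless of thread count.

## Requirements and installation

R (≥ 4.1) with Bioconductor `Biostrings`/`IRanges`, and HMMER 3
(`hmmbuild`, `hmmpress`, `hmmscan`) on `PATH`.  NCBI BLAST+ is optional
(external rescue backend).

```sh
R CMD INSTALL .
# test suite
Rscript -e 'testthat::test_dir("tests/testthat", package = "TEclade", load_package = "installed")'
```

## Worked example

The package ships a seeded fixture generator (a mini domain database plus
a labelled planted-domain library), so the whole pipeline runs with no
downloads:

```r
library(TEclade)

spec <- fixture_spec()                      # seed 42, 8 clades, 10 elements each
gen  <- generate_database(spec, out_dir = tempfile())
lib  <- generate_library(spec, gen$ancestors)

res <- run_pipeline(lib$seqs, gen$db, pipeline_config(threads = 2),
                    out_dir = "out")
#> [translate] 80 elements
#> [search] database 'fixture_db' (40 profiles), threads=2
#> [search] 2481 raw domain hits
#> [filter] 1600 hits pass coverage >= 0.2, E-value <= 0.001
#> [resolve] 400 hits after best-hit resolution
#> [classify] pass 1: 80/80 elements classified

head(res$table, 3)
#>     element_id order superfamily clade complete strand                              domains pass
#> 1 Copia_Ale_01   LTR       Copia   Ale      yes      - GAG|Ale AP|Ale INT|Ale RT|Ale RH|Ale    1
#> 2 Copia_Ale_02   LTR       Copia   Ale      yes      - GAG|Ale AP|Ale INT|Ale RT|Ale RH|Ale    1
#> 3 Copia_Ale_03   LTR       Copia   Ale      yes      - GAG|Ale AP|Ale INT|Ale RT|Ale RH|Ale    1

score_classifications(res$table, lib$truth, "superfamily")
#>    category tp fp fn precision sensitivity
#> 1 LTR/Copia 40  0  0         1           1
#> 2 LTR/Gypsy 40  0  0         1           1
```

Every element of the clean fixture is recovered at its planted clade,
called complete, and each 400-hit resolution keeps exactly one hit per
domain locus.  `out/` receives the classification TSV, a GFF3 of domain
features, and per-domain plus RT–RH–INT FASTA files.

For real libraries, point `read_profile_db()` at a curated TE
protein-domain HMM database (REXdb- or GyDB-style) with a metadata TSV
(`profile_name, te_class, order, superfamily, clade, domain_label`)
mapping its naming scheme onto the lineage, and pass RepeatMasker-style
`name#Order/Superfamily` headers to benchmark against `truth` labels.

A command-line wrapper with `classify`, `extract`, `bench` and
`fixtures make` subcommands is installed under `inst/cli/teclade`.

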