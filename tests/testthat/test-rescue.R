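test_that("similarity search reports identity, length and union coverage", {
  set.seed(5)
  s <- TEclade:::with_seed(1, TEclade:::random_dna(600))
  subjects <- Biostrings::DNAStringSet(c(sub1 = s))

  # identical query: full-identity, full-coverage hit
  hit <- similarity_search(Biostrings::DNAStringSet(c(q = s)), subjects)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity, 100)
  expect_equal(hit$query_coverage, 100)
  expect_gte(hit$aln_len, 600L)

  # reverse-complement query still matches (both strands searched)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  hit_rc <- similarity_search(Biostrings::DNAStringSet(c(q = rc)), subjects)
  expect_equal(hit_rc$query_coverage, 100)

  # unrelated query: no hit
  other <- TEclade:::with_seed(99, TEclade:::random_dna(600))
  expect_equal(nrow(similarity_search(
    Biostrings::DNAStringSet(c(q = other)), subjects)), 0L)

  # 10% seeded substitutions: identity close to 90
  q10 <- TEclade:::with_seed(7, TEclade:::mutate_dna(s, 0.10))
  hit10 <- similarity_search(Biostrings::DNAStringSet(c(q = q10)), subjects)
  expect_gte(hit10$identity, 87)
  expect_lte(hit10$identity, 93)

  # empty subjects give an empty result
  expect_equal(nrow(similarity_search(Biostrings::DNAStringSet(c(q = s)),
                                      Biostrings::DNAStringSet())), 0L)
})

test_that("fragmented queries are covered by the union of their HSPs", {
  # subject = A + spacer + B; query = A + B (a derivative that lost the
  # middle).  One HSP cannot cover the query; the union of two must.
  a <- TEclade:::with_seed(11, TEclade:::random_dna(200))
  b <- TEclade:::with_seed(12, TEclade:::random_dna(200))
  spacer <- TEclade:::with_seed(13, TEclade:::random_dna(900))
  subjects <- Biostrings::DNAStringSet(c(s = paste0(a, spacer, b)))
  hit <- similarity_search(Biostrings::DNAStringSet(c(q = paste0(a, b))),
                           subjects)
  expect_equal(nrow(hit), 1L)
  expect_lte(hit$aln_len, 250L)       # best single HSP is one fragment
  expect_gte(hit$query_coverage, 99)  # union covers the whole query
})

test_that("the 80-80-80 rule is inclusive on every boundary, superfamily only", {
  pass1 <- data.frame(element_id = "sub", order = "LTR",
                      superfamily = "Copia", clade = "Ale",
                      stringsAsFactors = FALSE)
  mk <- function(aln, id, cov) {
    data.frame(query_id = "q", subject_id = "sub", aln_len = aln,
               identity = id, query_coverage = cov, score = 100,
               stringsAsFactors = FALSE)
  }
  for (aln in c(79, 80, 81)) for (idn in c(79, 80, 81))
    for (cov in c(79, 80, 81)) {
      rescued <- apply_80_80_80(mk(aln, idn, cov), pass1)
      should <- aln >= 80 && idn >= 80 && cov >= 80
      expect_equal(length(rescued) == 1L, should,
                   info = sprintf("aln=%d id=%d cov=%d", aln, idn, cov))
      if (should) {
        cls <- rescued[[1]]
        expect_equal(cls$superfamily, "Copia")
        expect_true(is.na(cls$clade))    # never a clade in pass 2
        expect_equal(cls$pass_no, 2L)
        expect_equal(cls$complete, "unknown")
      }
    }
})

test_that("the best rescue hit wins by score, then identity, then subject id", {
  pass1 <- data.frame(element_id = c("cop", "gyp", "aaa"), order = "LTR",
                      superfamily = c("Copia", "Gypsy", "Gypsy"),
                      clade = NA_character_, stringsAsFactors = FALSE)
  hits <- data.frame(query_id = "q",
                     subject_id = c("cop", "gyp"),
                     aln_len = 200L, identity = c(90, 95),
                     query_coverage = 95, score = c(300, 200),
                     stringsAsFactors = FALSE)
  # higher score beats higher identity
  expect_equal(apply_80_80_80(hits, pass1)[[1]]$superfamily, "Copia")
  # score tie -> higher identity
  hits$score <- 300
  expect_equal(apply_80_80_80(hits, pass1)[[1]]$superfamily, "Gypsy")
  # full tie -> lexicographic subject id
  hits2 <- data.frame(query_id = "q", subject_id = c("gyp", "aaa"),
                      aln_len = 200L, identity = 90, query_coverage = 95,
                      score = 300, stringsAsFactors = FALSE)
  expect_equal(apply_80_80_80(hits2, pass1)[[1]]$element_id, "q")
  expect_equal(apply_80_80_80(hits2, pass1)[[1]]$superfamily, "Gypsy")

  expect_error(apply_80_80_80(
    data.frame(query_id = "q", subject_id = "nope", aln_len = 200L,
               identity = 90, query_coverage = 95, score = 1,
               stringsAsFactors = FALSE), pass1), "missing")
})

test_that("tightening any threshold never increases the rescued count", {
  set.seed(17)
  pass1 <- data.frame(element_id = paste0("s", 1:5), order = "LTR",
                      superfamily = "Copia", clade = NA_character_,
                      stringsAsFactors = FALSE)
  hits <- data.frame(query_id = paste0("q", sample.int(30, 60, TRUE)),
                     subject_id = paste0("s", sample.int(5, 60, TRUE)),
                     aln_len = sample(40:300, 60, TRUE),
                     identity = runif(60, 60, 100),
                     query_coverage = runif(60, 60, 100),
                     score = runif(60, 50, 400), stringsAsFactors = FALSE)
  base <- length(apply_80_80_80(hits, pass1))
  for (i in 1:20) {
    tighter <- apply_80_80_80(hits, pass1,
                              min_aln_bp = 80 + sample(0:40, 1),
                              min_identity = 80 + runif(1, 0, 15),
                              min_qcov = 80 + runif(1, 0, 15))
    expect_lte(length(tighter), base)
  }
})

test_that("tabular hits parse and collapse HSPs like the internal backend", {
  lines <- c(
    "q1\ts1\t95.0\t120\t6\t0\t1\t120\t1\t120\t1e-50\t200",
    "q1\ts1\t90.0\t100\t10\t0\t200\t299\t300\t399\t1e-30\t150",
    "q1\ts2\t99.0\t80\t1\t0\t10\t89\t5\t84\t1e-20\t140")
  hits <- parse_tabular_hits(lines, c(q1 = 300L))
  expect_equal(nrow(hits), 2L)
  s1 <- hits[hits$subject_id == "s1", ]
  expect_equal(s1$identity, 95)     # best HSP by bitscore
  expect_equal(s1$aln_len, 120L)
  expect_equal(s1$query_coverage, 100 * 220 / 300)  # union of both HSPs
  expect_error(parse_tabular_hits("q1\ts1\tonly-three", c(q1 = 10L)),
               "columns")
})

test_that("internal and external rescue backends agree on a planted pair", {
  s <- TEclade:::with_seed(3, TEclade:::random_dna(500))
  q <- TEclade:::with_seed(4, TEclade:::mutate_dna(s, 0.05))
  queries <- Biostrings::DNAStringSet(c(q = q))
  subjects <- Biostrings::DNAStringSet(c(s = s))
  int <- similarity_search(queries, subjects, backend = "internal")
  ext <- similarity_search(queries, subjects, backend = "external")
  expect_equal(nrow(int), 1L)
  expect_equal(nrow(ext), 1L)
  expect_lt(abs(int$identity - ext$identity), 3)
  expect_gte(min(int$query_coverage, ext$query_coverage), 95)
})
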