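test_that("unanimous evidence classifies to clade with majority strand", {
  h <- do.call(rbind, lapply(
    list(c("GAG", 100, 900), c("AP", 1000, 1300), c("INT", 1400, 2200),
         c("RT", 2300, 3000), c("RH", 3100, 3500)),
    function(x) make_hit(domain_label = x[1], nt_start = as.integer(x[2]),
                         nt_end = as.integer(x[3]), score = 100)))
  cls <- classify_element(h)
  expect_equal(cls$order, "LTR")
  expect_equal(cls$superfamily, "Copia")
  expect_equal(cls$clade, "Ale")
  expect_equal(cls$strand, "+")
  expect_equal(cls$pass_no, 1L)
  expect_match(cls$domain_string, "^GAG\\|Ale AP\\|Ale")
})

test_that("score-weighted majority descends only past 50% of summed score", {
  # RT|Ale 100 + RH|Ale 80 vs INT|Tork 60: Ale wins 180/240
  h <- rbind(make_hit(domain_label = "RT", clade = "Ale", score = 100,
                      nt_start = 1, nt_end = 300),
             make_hit(domain_label = "RH", clade = "Ale", score = 80,
                      nt_start = 400, nt_end = 700),
             make_hit(domain_label = "INT", clade = "Tork", score = 60,
                      nt_start = 800, nt_end = 1100))
  cls <- classify_element(h)
  expect_equal(cls$clade, "Ale")

  # an exact superfamily tie stops at order and flags the conflict
  h2 <- rbind(make_hit(superfamily = "Copia", clade = "Ale", score = 100,
                       nt_start = 1, nt_end = 300),
              make_hit(superfamily = "Gypsy", clade = "CRM", score = 100,
                       nt_start = 400, nt_end = 700))
  cls2 <- classify_element(h2)
  expect_equal(cls2$order, "LTR")
  expect_true(is.na(cls2$superfamily))
  expect_equal(cls2$conflict_level, "superfamily")
  tab <- classification_table(list(cls2))
  expect_equal(tab$superfamily, "unknown")

  # a bare majority below 50% does not descend either
  h3 <- rbind(make_hit(clade = "Ale", score = 40, nt_start = 1, nt_end = 300),
              make_hit(clade = "Tork", score = 35, nt_start = 400,
                       nt_end = 700),
              make_hit(clade = "SIRE", score = 30, nt_start = 800,
                       nt_end = 1100))
  expect_true(is.na(classify_element(h3)$clade))

  # no hits -> unclassified sentinel
  cls0 <- classify_element(TEclade:::empty_domain_hits(), element_id = "e0")
  expect_true(is.na(cls0$order))
  expect_equal(cls0$strand, "?")
  expect_true(is.na(cls0$pass_no))
})

test_that("completeness requires the five domains once, one strand, canonical order", {
  copia_hits <- function(order_labels, strand = "+") {
    starts <- seq(100, by = 1000, length.out = length(order_labels))
    do.call(rbind, lapply(seq_along(order_labels), function(i) {
      make_hit(domain_label = order_labels[i], nt_start = starts[i],
               nt_end = starts[i] + 299, strand = strand)
    }))
  }
  ok <- call_completeness(classify_element(
    copia_hits(c("GAG", "AP", "INT", "RT", "RH"))))
  expect_equal(ok$complete, "yes")

  # INT after RH violates the Copia order
  bad <- call_completeness(classify_element(
    copia_hits(c("GAG", "AP", "RT", "RH", "INT"))))
  expect_equal(bad$complete, "no")

  # the same genomic order on the minus strand is canonical Gypsy when
  # read 5'->3' along that strand
  h <- do.call(rbind, lapply(seq_along(c("INT", "RH", "RT", "AP", "GAG")),
    function(i) {
      lab <- c("INT", "RH", "RT", "AP", "GAG")[i]
      make_hit(domain_label = lab, superfamily = "Gypsy", clade = "CRM",
               nt_start = i * 1000, nt_end = i * 1000 + 299, strand = "-")
    }))
  gok <- call_completeness(classify_element(h))
  expect_equal(gok$superfamily, "Gypsy")
  expect_equal(gok$complete, "yes")

  # missing or duplicated domains are incomplete
  expect_equal(call_completeness(classify_element(
    copia_hits(c("GAG", "AP", "INT", "RT"))))$complete, "no")
  expect_equal(call_completeness(classify_element(
    copia_hits(c("GAG", "AP", "INT", "RT", "RH", "RH"))))$complete, "no")
})

test_that("classification TSV and GFF3 are written deterministically", {
  h <- rbind(make_hit(domain_label = "RT", nt_start = 100, nt_end = 399),
             make_hit(domain_label = "RH", nt_start = 500, nt_end = 799))
  cls1 <- call_completeness(classify_element(h))
  cls2 <- structure(list(element_id = "zz_rescued", order = "LTR",
                         superfamily = "Copia", clade = NA_character_,
                         conflict_level = NA_character_, strand = "?",
                         domain_string = "", complete = "unknown",
                         pass_no = 2L, hits = TEclade:::empty_domain_hits()),
                    class = "te_classification")
  tsv <- tempfile(fileext = ".tsv")
  gff <- tempfile(fileext = ".gff3")
  write_classifications(list(cls2, cls1), tsv_path = tsv, gff_path = gff)
  tab <- read.delim(tsv, na.strings = "")
  expect_equal(colnames(tab), c("element_id", "order", "superfamily",
                                "clade", "complete", "strand", "domains",
                                "pass"))
  # sorted by element id; pass-2 rows have an empty clade
  expect_equal(tab$element_id, c("el", "zz_rescued"))
  expect_true(is.na(tab$clade[2]))
  expect_equal(tab$pass[2], 2L)

  g <- readLines(gff)
  expect_equal(g[1], "##gff-version 3")
  expect_equal(length(g), 3L)  # header + 2 domain features
  expect_match(g[2], "^el\tTEclade\tprotein_match\t100\t399\t")

  # byte determinism, independent of input order
  tsv2 <- tempfile(); gff2 <- tempfile()
  write_classifications(list(cls1, cls2), tsv_path = tsv2, gff_path = gff2)
  expect_identical(readLines(tsv), readLines(tsv2))
  expect_identical(readLines(gff), readLines(gff2))

  # empty input -> header-only TSV
  tsv3 <- tempfile()
  write_classifications(list(), tsv_path = tsv3)
  expect_equal(length(readLines(tsv3)), 1L)
})
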