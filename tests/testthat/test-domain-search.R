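test_that("per-domain tables parse field-for-field", {
  row <- paste("LTR/Copia/Ale:RT - 100 el1|aa+1 - 1100 1.5e-52 161.9 8.8",
               "1 1 1.7e-52 2.5e-40 161.7 8.8 10 50 301 341 299 343 0.99 -")
  raw <- parse_domtblout(row)
  expect_equal(nrow(raw), 1L)
  expect_equal(raw$profile_name, "LTR/Copia/Ale:RT")
  expect_equal(raw$model_length, 100L)
  expect_equal(raw$evalue, 2.5e-40)  # per-domain independent E-value
  expect_equal(raw$score, 161.7)     # per-domain bit score
  expect_equal(raw$hmm_from, 10L)
  expect_equal(raw$hmm_to, 50L)
  expect_equal(raw$aa_from, 301L)

  expect_equal(nrow(parse_domtblout(c("# comment", "# another"))), 0L)
  expect_error(parse_domtblout("a b c"), "row 1")
})

test_that("the coverage/E-value filter keeps boundaries and attaches coordinates", {
  db <- TEclade:::new_profile_db(
    hmm_path = "unused",
    meta = data.frame(profile_name = "LTR/Copia/Ale:RT",
                      te_class = NA_character_, order = "LTR",
                      superfamily = "Copia", clade = "Ale",
                      domain_label = "RT", model_length = 100L,
                      stringsAsFactors = FALSE))
  mk <- function(hmm_from, hmm_to, evalue, frame = 1L) {
    data.frame(query_id = sprintf("el1|aa%+d", frame),
               profile_name = "LTR/Copia/Ale:RT", model_length = 100L,
               score = 50, evalue = evalue,
               hmm_from = hmm_from, hmm_to = hmm_to,
               aa_from = 11L, aa_to = 30L, stringsAsFactors = FALSE)
  }
  lens <- c(el1 = 3000L)

  # hmm span 10..50 on 100 states -> coverage 0.41
  kept <- filter_hits(mk(10L, 50L, 1e-10), db, lens)
  expect_equal(kept$coverage, 0.41)
  expect_equal(kept$nt_start, 31L)  # aa 11..30 on frame +1
  expect_equal(kept$nt_end, 90L)
  expect_equal(kept$strand, "+")

  # minus frame coordinates land on the forward strand
  kept_m <- filter_hits(mk(10L, 50L, 1e-10, frame = -2L), db, lens)
  expect_equal(kept_m$strand, "-")
  expect_equal(kept_m$nt_end - kept_m$nt_start + 1L, 60L)
  expect_equal(kept_m$nt_end, 3000L - 1L - 30L)  # offset 1, aa_from 11

  # boundary values are kept; strictly worse values are discarded
  expect_equal(nrow(filter_hits(mk(1L, 20L, 1e-3), db, lens)), 1L)
  expect_equal(nrow(filter_hits(mk(1L, 19L, 1e-10), db, lens)), 0L)
  expect_equal(nrow(filter_hits(mk(1L, 50L, 2e-3), db, lens)), 0L)

  expect_error(filter_hits(
    within(mk(1L, 50L, 1e-10), profile_name <- "LTR/Gypsy/CRM:RT"),
    db, lens), "absent")
})

test_that("filter is subset-idempotent and monotone in its thresholds", {
  set.seed(21)
  db <- TEclade:::new_profile_db(
    hmm_path = "unused",
    meta = data.frame(profile_name = "LTR/Copia/Ale:RT",
                      te_class = NA_character_, order = "LTR",
                      superfamily = "Copia", clade = "Ale",
                      domain_label = "RT", model_length = 100L,
                      stringsAsFactors = FALSE))
  n <- 200L
  froms <- sample.int(80L, n, replace = TRUE)
  raw <- data.frame(query_id = "el1|aa+1",
                    profile_name = "LTR/Copia/Ale:RT", model_length = 100L,
                    score = runif(n, 5, 200),
                    evalue = 10^runif(n, -20, 1),
                    hmm_from = froms,
                    hmm_to = froms + sample.int(99L, n, replace = TRUE),
                    aa_from = 1L, aa_to = 10L, stringsAsFactors = FALSE)
  raw$hmm_to <- pmin(raw$hmm_to, 100L)
  raw <- raw[raw$hmm_to >= raw$hmm_from, ]
  lens <- c(el1 = 1000L)

  kept <- filter_hits(raw, db, lens)
  expect_lte(nrow(kept), nrow(raw))
  # relaxing either threshold never removes a kept hit
  looser_e <- filter_hits(raw, db, lens, max_evalue = 1e-2)
  looser_c <- filter_hits(raw, db, lens, min_coverage = 0.10)
  key <- function(h) paste(h$evalue, h$coverage, h$score)
  expect_true(all(key(kept) %in% key(looser_e)))
  expect_true(all(key(kept) %in% key(looser_c)))
})

test_that("best-hit resolution keeps the top scorer of each overlap group", {
  h <- rbind(make_hit(score = 120, nt_start = 100, nt_end = 700,
                      profile_name = "LTR/Copia/Ale:RT"),
             make_hit(score = 90, nt_start = 150, nt_end = 720,
                      profile_name = "LTR/Copia/Tork:RT"))
  r <- resolve_best_hits(h)
  expect_equal(nrow(r), 1L)
  expect_equal(r$score, 120)

  # non-overlapping copies of the same domain both survive
  h2 <- rbind(make_hit(score = 120, nt_start = 100, nt_end = 700),
              make_hit(score = 90, nt_start = 1000, nt_end = 1600))
  expect_equal(nrow(resolve_best_hits(h2)), 2L)

  # a single hit is unchanged
  h3 <- make_hit(score = 50)
  expect_equal(resolve_best_hits(h3)$score, 50)

  # ties break by lower E-value then profile name
  h4 <- rbind(make_hit(score = 100, evalue = 1e-5, nt_start = 1,
                       nt_end = 300, profile_name = "LTR/Copia/B:RT"),
              make_hit(score = 100, evalue = 1e-9, nt_start = 1,
                       nt_end = 300, profile_name = "LTR/Copia/A:RT"))
  expect_equal(resolve_best_hits(h4)$profile_name, "LTR/Copia/A:RT")
})

test_that("resolution matches a brute-force extractor on random hit sets", {
  set.seed(33)
  for (rep in 1:60) {
    h <- random_hit_set(sample(2:15, 1))
    got <- resolve_best_hits(h)
    want <- oracle_resolve(h)
    expect_equal(got$score, want$score, info = paste("rep", rep))
    expect_equal(got$nt_start, want$nt_start, info = paste("rep", rep))
    # retained scores are a sub-multiset of the input
    expect_true(all(got$score %in% h$score))
    # no two retained hits overlap by >50% of the shorter
    if (nrow(got) > 1L) {
      for (i in 1:(nrow(got) - 1L)) for (j in (i + 1L):nrow(got)) {
        expect_false(TEclade:::overlaps_majority(
          got$nt_start[i], got$nt_end[i], got$nt_start[j], got$nt_end[j]))
      }
    }
  }
})

test_that("the search engine finds planted consensus domains and ignores X frames", {
  fx <- tiny_fixture()
  anc <- fx$ancestors$Copia$Ale$RT
  frames <- data.frame(parent_id = "probe", frame = 1L, nt_offset = 0L,
                       protein = anc, stringsAsFactors = FALSE)
  raw <- search_frames(frames, fx$db, threads = 1L)
  own <- raw[raw$profile_name == "LTR/Copia/Ale:RT", ]
  expect_gte(nrow(own), 1L)
  span <- max(own$hmm_to) - min(own$hmm_from) + 1L
  expect_gte(span / own$model_length[1], 0.95)

  xframe <- data.frame(parent_id = "probe", frame = 1L, nt_offset = 0L,
                       protein = strrep("X", 200), stringsAsFactors = FALSE)
  expect_equal(nrow(search_frames(xframe, fx$db)), 0L)

  none <- frames[0, , drop = FALSE]
  expect_equal(nrow(search_frames(none, fx$db)), 0L)
})
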