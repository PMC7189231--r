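test_that("vocabulary collects observed codes, sorted, plus five specials", {
  corp <- corpus_of(
    make_patient("p1", list(list(30, c("D2")), list(31, c("D1", "D2")))),
    make_patient("p2", list(list(40, c("D1"))))
  )
  v <- build_vocab(corp)
  expect_equal(v$codes, c("D1", "D2"))
  expect_equal(v$n_total, 7L)
  expect_equal(unname(v$specials), 0:4)
  # ids contiguous and disjoint from specials
  expect_equal(sort(c(unname(v$specials), unname(v$code_ids))), 0:6)
  # determinism
  expect_identical(build_vocab(corp), build_vocab(corp))
  expect_error(build_vocab(corp[0, ]), "empty")
})

test_that("vocabulary size tracks the generator configuration", {
  gen <- generate_corpus(sim_config(n_patients = 300, n_codes = 60, seed = 4))
  v <- build_vocab(gen$corpus)
  expect_equal(length(v$codes), 60L)
  expect_equal(v$n_total, 65L)
  expect_equal(unname(code_to_id(v, v$codes)), 5:64)
})

test_that("id mapping is a bijection with UNK fallback and round-trips", {
  v <- build_vocab(corpus_of(make_patient("p", list(list(30, c("A", "B", "C"))))))
  ids <- code_to_id(v, c("A", "B", "C"))
  expect_equal(id_to_code(v, ids), c("A", "B", "C"))
  expect_equal(code_to_id(v, "NOPE"), unname(v$specials[["UNK"]]))
  expect_equal(id_to_code(v, 0:4), c("PAD", "CLS", "SEP", "MASK", "UNK"))
  tmp <- withr::local_tempfile()
  write_vocab(v, tmp)
  expect_identical(read_vocab(tmp), v)
})

test_that("inclusion filter keeps exactly the patients with enough visits", {
  visits4 <- lapply(30:33, function(a) list(a, "A"))
  visits5 <- lapply(30:34, function(a) list(a, "A"))
  corp <- corpus_of(make_patient("short", visits4), make_patient("long", visits5))
  expect_equal(filter_inclusion(corp)$patient_id, "long")
  expect_identical(filter_inclusion(corp, min_visits = 0L), corp)

  # order preserved and count matches a brute-force loop on 1000 patients
  set.seed(42)
  n_vis <- pmax(1L, stats::rgeom(1000, 0.2))
  corp2 <- ehr_corpus(lapply(seq_len(1000), function(i) {
    make_patient(sprintf("g%04d", i),
                 lapply(seq_len(n_vis[i]) + 29L, function(a) list(a, "A")))
  }))
  kept <- filter_inclusion(corp2)
  brute <- 0L
  for (i in seq_len(1000)) if (n_vis[i] >= 5L) brute <- brute + 1L
  expect_equal(nrow(kept), brute)
  expect_equal(kept$patient_id, corp2$patient_id[n_vis >= 5])
})

test_that("tokenization follows the CLS/SEP layout with per-visit channels", {
  corp <- corpus_of(make_patient("p", list(list(30, "A"), list(31, c("B", "C")))))
  v <- build_vocab(corp)
  s <- encode_patient(corp[1, ], v, max_len = 10L)
  # CLS=1, A=5, SEP=2, B=6, C=7, PAD=0
  expect_equal(s$token_ids, c(1L, 5L, 2L, 6L, 7L, 2L, 0L, 0L, 0L, 0L))
  expect_equal(s$position_ids[1:6], c(0L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(s$segment_ids[1:6], c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(s$age_ids[1:6], c(30L, 30L, 30L, 31L, 31L, 31L))
  expect_equal(s$padding_mask, rep(c(TRUE, FALSE), c(6, 4)))
})

test_that("single-visit single-code patient yields three real tokens", {
  corp <- corpus_of(make_patient("p", list(list(50, "A"))))
  s <- encode_patient(corp[1, ], build_vocab(corp), max_len = 8L)
  expect_equal(sum(s$padding_mask), 3L)
})

test_that("permuting codes within a visit only permutes that token span", {
  corp1 <- corpus_of(make_patient("p", list(list(30, c("A", "B")), list(31, c("C", "D")))))
  corp2 <- corpus_of(make_patient("p", list(list(30, c("A", "B")), list(31, c("D", "C")))))
  v <- build_vocab(corp1)
  s1 <- encode_patient(corp1[1, ], v, 12L)
  s2 <- encode_patient(corp2[1, ], v, 12L)
  # layout: CLS A B SEP | C D SEP ... -> visit-2 codes sit at tokens 5:6
  expect_equal(sort(s1$token_ids[5:6]), sort(s2$token_ids[5:6]))
  expect_equal(s1$token_ids[-(5:6)], s2$token_ids[-(5:6)])
  expect_equal(s1$age_ids, s2$age_ids)
  expect_equal(s1$segment_ids, s2$segment_ids)
  expect_equal(s1$position_ids, s2$position_ids)
})

test_that("truncation drops whole oldest visits and keeps CLS", {
  corp <- corpus_of(make_patient("p", list(
    list(30, c("A", "B", "C")), list(31, c("D", "E")), list(32, "F"))))
  v <- build_vocab(corp)
  # full length would be 1 + 4 + 3 + 2 = 10; cap at 6 forces dropping visit 1
  s <- encode_patient(corp[1, ], v, max_len = 6L)
  expect_equal(s$token_ids[1], 1L)  # CLS
  expect_equal(id_to_code(v, s$token_ids[s$padding_mask]),
               c("CLS", "D", "E", "SEP", "F", "SEP"))
  # SEP count equals retained visit count; position restarts at 1
  expect_equal(sum(s$token_ids == 2L), 2L)
  expect_equal(max(s$position_ids), 2L)
  expect_error(encode_patient(corp[1, ], v, max_len = 3L), "too long")
})

test_that("tokenized sequences satisfy their invariants on random corpora", {
  gen <- small_sim(n = 40, seed = 9)
  v <- build_vocab(gen$corpus)
  seqs <- encode_corpus(gen$corpus, v)
  for (s in seqs) {
    real <- which(s$padding_mask)
    expect_equal(s$token_ids[real[1]], 1L)  # CLS first
    n_sep <- sum(s$token_ids[real] == 2L)
    expect_equal(n_sep, nrow(gen$corpus$visits[[match(s$patient_id, gen$corpus$patient_id)]]))
    expect_true(all(diff(s$position_ids[real]) >= 0))
    # channels constant within each visit span (split by position id)
    for (pos in unique(s$position_ids[real])) {
      span <- real[s$position_ids[real] == pos]
      expect_length(unique(s$age_ids[span]), 1L)
      expect_length(unique(s$segment_ids[span]), 1L)
    }
    # segments alternate between consecutive visits
    seg_by_visit <- vapply(seq_len(max(s$position_ids)), function(pos)
      unique(s$segment_ids[real[s$position_ids[real] == pos]]), integer(1))
    expect_equal(seg_by_visit, (seq_along(seg_by_visit) - 1L) %% 2L)
  }
  # determinism
  expect_identical(seqs, encode_corpus(gen$corpus, v))
})

test_that("corpus JSONL round-trips and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), tmp)
  expect_equal(nrow(read_corpus(tmp)), 0L)

  gen <- small_sim(n = 100, seed = 2)
  write_corpus(gen$corpus, tmp)
  back <- read_corpus(tmp)
  expect_equal(back$patient_id, gen$corpus$patient_id)
  expect_equal(back$observation_end_age_months, gen$corpus$observation_end_age_months)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$visits[[i]]$age_months, gen$corpus$visits[[i]]$age_months)
    expect_equal(back$visits[[i]]$codes, gen$corpus$visits[[i]]$codes)
    expect_equal(back$attributes[[i]]$attribute, gen$corpus$attributes[[i]]$attribute)
  }

  writeLines(c("{\"patient_id\": \"x\"", "{}"), tmp)
  expect_error(read_corpus(tmp), "line 1")

  bad <- make_patient("pbad", list(list(40, "A"), list(30, "B")))
  expect_error(ehr_corpus(list(bad)), "pbad")
})

test_that("corpus summary matches a brute-force recount", {
  corp <- corpus_of(make_patient("solo", lapply(30:34, function(a) list(a, "A"))))
  s <- summarize_corpus(corp)
  expect_equal(s$visits_per_patient$mean, 5)
  expect_equal(s$codes_per_visit$mean, 1)

  gen <- small_sim(n = 60, seed = 5)
  s2 <- summarize_corpus(gen$corpus)
  for (k in sample(nrow(s2$prevalence), 5)) {
    code <- s2$prevalence$code[k]
    carry <- 0L
    for (i in seq_len(nrow(gen$corpus))) {
      if (code %in% unlist(gen$corpus$visits[[i]]$codes)) carry <- carry + 1L
    }
    expect_equal(s2$prevalence$n_patients[k], carry)
    expect_equal(s2$prevalence$prevalence[k], carry / nrow(gen$corpus))
  }

  # an attribute-exclusive code can be at most as prevalent as its level
  gt <- gen$ground_truth
  excl <- names(gt$allowed_attribute)[gt$allowed_attribute != "both"]
  attr_of <- vapply(gen$corpus$attributes, function(a) a$attribute, numeric(1))
  for (code in excl[1:3]) {
    lvl <- as.numeric(gt$allowed_attribute[[code]])
    p_code <- s2$prevalence$prevalence[match(code, s2$prevalence$code)]
    if (!is.na(p_code)) expect_lte(p_code, mean(attr_of == lvl))
  }
})
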