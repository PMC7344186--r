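test_that("JSONL corpus reading handles fixtures, duplicates and errors", {
  path <- withr::local_tempfile(fileext = ".jsonl")

  # empty file -> empty list
  writeLines(character(0), path)
  expect_identical(read_corpus(path), list())

  # one patient, 2 visits of 3 codes each; duplicates preserved at read
  write_corpus(list(patient_record("p1", list(
    visit_event(0L, c("a", "b", "c"),
                c("symptom", "medication", "lab_test")),
    visit_event(10L, c("a", "a", "d"),
                c("symptom", "symptom", "diagnosis"))))), path)
  recs <- read_corpus(path)
  expect_length(recs, 1L)
  expect_length(recs[[1]]$visits, 2L)
  expect_identical(recs[[1]]$visits[[1]]$codes, c("a", "b", "c"))
  expect_identical(recs[[1]]$visits[[2]]$codes, c("a", "a", "d"))

  # malformed line names the line number
  writeLines(c('{"patient_id": "p1", "visits": []}', "{oops"), path)
  expect_error(read_corpus(path), "line 2")

  # unknown category names the code
  writeLines(paste0('{"patient_id":"p1","visits":[{"timestamp":0,',
                    '"entities":[{"code":"xyz","category":"procedure"}]}]}'),
             path)
  expect_error(read_corpus(path), "xyz")
})

test_that("write_corpus / read_corpus round-trips the in-memory corpus", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  recs <- tiny_corpus()
  write_corpus(recs, path)
  expect_equal(read_corpus(path), recs)
  # byte-level idempotence of a second write
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(read_corpus(path), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("patient exclusion drops single-visit and missing-date patients", {
  ok <- function(id) patient_record(id, list(
    visit_event(0L, "a", "symptom"), visit_event(5L, "b", "medication")))
  one_visit <- function(id) patient_record(id, list(
    visit_event(0L, "a", "symptom")))
  recs <- list(ok("p1"), one_visit("p2"), ok("p3"), one_visit("p4"), ok("p5"))
  expect_message(out <- filter_patients(recs), "2 patient")
  expect_identical(vapply(out, `[[`, "", "patient_id"), c("p1", "p3", "p5"))

  # no-op when every patient qualifies
  clean <- list(ok("q1"), ok("q2"))
  expect_identical(filter_patients(clean), clean)

  # 2 visits but unparseable first timestamp -> removed
  bad_date <- patient_record("p6", list(
    visit_event("not-a-date", "a", "symptom"),
    visit_event(9L, "b", "medication")))
  expect_message(out2 <- filter_patients(list(ok("p7"), bad_date)),
                 "missing first-visit date")
  expect_identical(vapply(out2, `[[`, "", "patient_id"), "p7")
})

test_that("temporal sort is correct, stable and idempotent", {
  rec <- patient_record("p1", list(
    visit_event(30L, "a", "symptom"),
    visit_event(0L, "b", "medication"),
    visit_event(400L, "c", "diagnosis")))
  sorted <- sort_visits_temporally(rec)
  expect_identical(vapply(sorted$visits, `[[`, integer(1), "timestamp"),
                   c(0L, 30L, 400L))
  expect_identical(sort_visits_temporally(sorted), sorted)

  # ties keep input order (stable); mixed int / ISO timestamps compare by day
  tied <- patient_record("p2", list(
    visit_event(7L, "A", "symptom"), visit_event(7L, "B", "symptom")))
  expect_identical(vapply(sort_visits_temporally(tied)$visits,
                          function(v) v$codes, ""), c("A", "B"))

  # missing timestamp names the patient
  bad <- patient_record("pX", list(
    visit_event("n/a", "a", "symptom"), visit_event(1L, "b", "medication")))
  expect_error(sort_visits_temporally(bad), "pX")

  # sorting is a permutation of the visits
  expect_setequal(vapply(sorted$visits, function(v) v$codes, ""),
                  vapply(rec$visits, function(v) v$codes, ""))
})

test_that("vocabulary build indexes by first appearance with min_count", {
  recs <- tiny_corpus()  # 6 distinct codes
  vocab <- build_vocabulary(recs, min_count = 1L)
  expect_length(vocab$codes, 6L)
  expect_identical(vocab$codes[1:3], c("fever", "hcq", "ana_test"))
  # lookup and code_of are mutual inverses
  idx <- vocab_index(vocab, vocab$codes)
  expect_identical(idx, seq_along(vocab$codes))
  expect_identical(vocab$codes[idx], vocab$codes)
  # counts: fever appears in 2 visits, ana_test in 2, nephritis in 1
  expect_identical(vocab$counts[vocab$codes == "fever"], 2L)
  expect_identical(vocab$counts[vocab$codes == "nephritis"], 1L)

  # min_count above all frequencies -> empty vocabulary, training refuses
  empty <- build_vocabulary(recs, min_count = 99L)
  expect_length(empty$codes, 0L)
  expect_error(train_ehr2vec(list(tiny_indexed_record()), empty,
                             train_config(dim = 2L, n_heads = 1L)),
               "at least 2")

  # category conflict errors with the offending code
  bad <- list(patient_record("p1", list(
    visit_event(0L, "x", "symptom"), visit_event(1L, "x", "diagnosis"))))
  expect_error(build_vocabulary(bad), "'x'")
})

test_that("vocabulary TSV export round-trips", {
  vocab <- build_vocabulary(tiny_corpus())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(vocab, path)
  expect_equal(read_vocabulary(path), vocab)
})

test_that("index_corpus dedups, drops OOV, and never grows the corpus", {
  recs <- list(patient_record("p1", list(
    visit_event(0L, c("a", "b", "a"), rep("symptom", 3)),
    visit_event(5L, c("zzz"), "diagnosis"),
    visit_event(9L, c("b", "c"), c("symptom", "medication")))))
  vocab <- ehrvec:::new_vocabulary(c("a", "b", "c"),
                                   c("symptom", "symptom", "medication"),
                                   c(2L, 2L, 1L))
  expect_message(out <- index_corpus(recs, vocab), "out-of-vocabulary")
  # visit [a, b, a] -> [idx(a), idx(b)]; all-OOV visit removed
  expect_identical(out[[1]]$visits[[1]]$entities, c(1L, 2L))
  expect_length(out[[1]]$visits, 2L)

  # patients reduced below 2 visits are removed entirely
  short <- list(patient_record("p2", list(
    visit_event(0L, "zzz", "diagnosis"), visit_event(1L, "a", "symptom"))))
  expect_message(out2 <- index_corpus(short, vocab))
  expect_length(out2, 0L)

  # no-op case: full coverage, no duplicates
  clean <- list(patient_record("p3", list(
    visit_event(0L, c("a", "b"), c("symptom", "symptom")),
    visit_event(2L, "c", "medication"))))
  out3 <- index_corpus(clean, vocab)
  expect_identical(out3[[1]]$visits[[1]]$entities, c(1L, 2L))
  expect_identical(out3[[1]]$visits[[2]]$entities, 3L)

  # monotonicity: never more patients/visits/entities than the input
  d <- default_sim()
  n_vis <- function(rs) sum(vapply(rs, function(r) length(r$visits), 0L))
  expect_lte(length(d$indexed), length(d$records))
  expect_lte(n_vis(d$indexed), n_vis(d$records))
})
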