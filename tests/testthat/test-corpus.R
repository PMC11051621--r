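test_that("SemEval XML parsing recovers counts, offsets and labels", {
  sents <- dplyr::bind_rows(
    worked_example_sentence(),
    make_sentence("Aspirin has no annotated pairs here.", "Aspirin",
                  sid = "d0.s1", did = "d0")
  )
  tmp <- withr::local_tempfile(fileext = ".xml")
  write_semeval(sents, tmp)
  got <- parse_semeval(tmp)

  expect_equal(nrow(got), 2L)
  expect_equal(nrow(got$entities[[1]]), 3L)
  expect_equal(nrow(got$pairs[[1]]), 1L)
  expect_equal(got$pairs[[1]]$label, "Advise")
  # a sentence without pairs yields an empty gold-pair table
  expect_equal(nrow(got$pairs[[2]]), 0L)

  # round trip: re-serializing preserves every charOffset byte for byte
  tmp2 <- withr::local_tempfile(fileext = ".xml")
  write_semeval(got, tmp2)
  off <- function(p) xml2::xml_attr(
    xml2::xml_find_all(xml2::read_xml(p), "//entity"), "charOffset")
  expect_identical(off(tmp2), off(tmp))

  # entity spans match the surface strings
  e <- got$entities[[1]]
  expect_equal(substring(got$text[1], e$start + 1, e$end), e$text)
})

test_that("parsing rejects bad offsets and dangling pair references", {
  s <- worked_example_sentence()
  bad <- s
  bad$entities[[1]]$end[1] <- 999L
  tmp <- withr::local_tempfile(fileext = ".xml")
  write_semeval(bad, tmp)
  expect_error(parse_semeval(tmp), "offset")

  bad2 <- s
  bad2$pairs[[1]]$e1 <- "d0.s0.e9"
  write_semeval(bad2, tmp)
  expect_error(parse_semeval(tmp), "unknown entity")
})

test_that("candidate generation reproduces the worked preprocessing example", {
  cand <- generate_candidates(worked_example_sentence())
  expect_equal(nrow(cand), 3L)

  expect_equal(cand$label, c("Advise", "Negative", "Negative"))
  expect_equal(cand$text[1], paste0(
    "If in certain cases, an DRUG1 is considered necessary, it may be ",
    "advisable to replace DRUG2 with anastrozole."))
  expect_equal(cand$text[2], paste0(
    "If in certain cases, an DRUG1 is considered necessary, it may be ",
    "advisable to replace tamoxifen with DRUG2."))
  expect_equal(cand$text[3], paste0(
    "If in certain cases, an antidepressant is considered necessary, ",
    "it may be advisable to replace DRUG1 with DRUG2."))

  # placeholder spans point at the placeholders
  for (i in 1:3) {
    expect_equal(substr(cand$text[i], cand$d1_start[i] + 1,
                        cand$d1_end[i]), "DRUG1")
    expect_equal(substr(cand$text[i], cand$d2_start[i] + 1,
                        cand$d2_end[i]), "DRUG2")
  }
})

test_that("candidate counts follow the pair-combinatorics contract", {
  one <- make_sentence("Only warfarin is mentioned.", "warfarin")
  expect_equal(nrow(generate_candidates(one)), 0L)

  four <- make_sentence("a1 with b2 and c3 plus d4 end.",
                        c("a1", "b2", "c3", "d4"))
  expect_equal(nrow(generate_candidates(four)), 6L)

  # total = sum of C(n_s, 2) over sentences
  sents <- dplyr::bind_rows(worked_example_sentence(), four,
                            rule_example_sentences())
  ns <- vapply(sents$entities, nrow, 1L)
  expect_equal(nrow(generate_candidates(sents)), sum(choose(ns, 2)))

  # anonymization changes length only by the two replacements
  cand <- generate_candidates(sents)
  expect_equal(
    nchar(cand$text),
    nchar(cand$text_orig) - (cand$e1_end - cand$e1_start) -
      (cand$e2_end - cand$e2_start) + 10L
  )
})

test_that("the three filtering rules remove their example pairs", {
  cand <- generate_candidates(rule_example_sentences())
  kept <- filter_negatives(cand)
  removed <- attr(kept, "removed")

  r1 <- removed[removed$drug1_name == "coumaphos" &
                  removed$drug2_name == "coumaphos", ]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$rule, "same_name")

  r2 <- removed[removed$drug1_name == "itraconazole" &
                  removed$drug2_name == "clarithromycin", ]
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$rule, "coordinate")

  r3 <- removed[removed$drug1_name == "penthrane" &
                  removed$drug2_name == "methoxyflurane", ]
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$rule, "special_case")

  # survivors + removed = generated, and per-rule counts add up
  expect_equal(nrow(kept) + nrow(removed), nrow(cand))
  expect_equal(sum(attr(kept, "removals")$n), nrow(removed))
})

test_that("filtering never removes gold-positive instances", {
  cand <- generate_candidates(rule_example_sentences())
  cand$label[cand$drug1_name == "coumaphos" &
               cand$drug2_name == "coumaphos"] <- "Mechanism"
  kept <- filter_negatives(cand)
  expect_true(any(kept$drug1_name == "coumaphos" &
                    kept$drug2_name == "coumaphos"))
  # rules can be toggled off individually
  kept2 <- filter_negatives(cand, rules = c(same_name = TRUE,
                                            coordinate = FALSE,
                                            special_case = FALSE))
  expect_equal(attr(kept2, "removals")$n[2:3], c(0L, 0L))
})

test_that("DrugBank mapping keeps only fully mapped pairs", {
  cand <- generate_candidates(worked_example_sentence())
  mapping <- tibble::tibble(
    name = c("Antidepressant ", "TAMOXIFEN"),
    drugbank_id = c("DB00001", "DB00675")
  )
  got <- map_to_drugbank(cand, mapping)
  # only the (antidepressant, tamoxifen) pair has both ids
  expect_equal(nrow(got), 1L)
  expect_equal(got$db1, "DB00001")
  expect_equal(got$db2, "DB00675")
  expect_equal(attr(got, "n_unmapped"), 2L)

  # empty mapping drops everything
  none <- map_to_drugbank(cand, tibble::tibble(name = character(),
                                               drugbank_id = character()))
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_unmapped"), 3L)

  # conflicting duplicate rows are an error
  expect_error(
    map_to_drugbank(cand, tibble::tibble(
      name = c("tamoxifen", "tamoxifen"),
      drugbank_id = c("DB00675", "DB99999"))),
    "conflicting")
})
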