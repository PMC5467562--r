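# curation snippets: construction, status, summaries, export round-trips

annotated_example <- function() {
  lex <- mini_lexicon()
  sentences <- tibble::tibble(
    doc_id = "d1", index = 0:1,
    text = c("miR-185 is increased in IPF.",
             "An increase in miR-21 targets Smad7 in IPF."))
  mentions <- annotate_corpus(sentences, lex)
  list(sentences = sentences, mentions = mentions)
}

test_that("snippets are built one per structure match with AUTO status", {
  ex <- annotated_example()
  m1 <- match_structure(
    ex$mentions[ex$mentions$sentence_index == 0L, ], "S1")
  sn <- snippets_from_matches(m1, ex$sentences)
  expect_identical(nrow(sn), nrow(m1))
  expect_identical(sn$mirna_key, "mir-185")
  expect_identical(sn$effect_polarity, "positive")
  expect_identical(sn$disease, "IPF")
  expect_identical(sn$status, "AUTO")
  expect_identical(sn$sentence_text, ex$sentences$text[1L])
  expect_identical(nrow(snippets_from_matches(
    mircurate:::empty_structure_matches())), 0L)
})

test_that("snippet ids are deterministic in the corpus content", {
  ex <- annotated_example()
  matches <- match_structure_corpus(ex$mentions, "S1")
  a <- snippets_from_matches(matches, ex$sentences)
  b <- snippets_from_matches(matches, ex$sentences)
  expect_identical(a, b)
  expect_identical(anyDuplicated(a$snippet_id), 0L)
})

test_that("status transitions preserve count and forbid revisiting", {
  ex <- annotated_example()
  sn <- curate_corpus(ex$sentences, ex$mentions)
  n0 <- nrow(sn)
  sn2 <- set_snippet_status(sn, sn$snippet_id[1L], "CONFIRMED")
  expect_identical(nrow(sn2), n0)
  expect_identical(sn2$status[1L], "CONFIRMED")
  expect_error(set_snippet_status(sn2, sn2$snippet_id[1L], "REJECTED"),
               "AUTO")
})

test_that("summaries report snippet and distinct-miRNA counts", {
  gc <- generate_corpus(9, corpus_params(n_docs = 3L))
  s <- summarize_snippets(gc$gold_snippets)
  expect_identical(s$n_snippets, nrow(gc$gold_snippets))
  expect_identical(s$n_mirnas, length(unique(gc$gold_snippets$mirna_key)))
  expect_lte(s$n_mirnas, s$n_snippets)
  # invariant under reordering
  shuffled <- gc$gold_snippets[sample(nrow(gc$gold_snippets)), ]
  expect_identical(summarize_snippets(shuffled)$n_mirnas, s$n_mirnas)
  # rejected snippets drop out of the default summary
  rej <- set_snippet_status(gc$gold_snippets,
                            gc$gold_snippets$snippet_id[1L], "REJECTED")
  expect_identical(summarize_snippets(rej)$n_snippets, s$n_snippets - 1L)
  # empty input gives zeros
  empty <- summarize_snippets(mircurate:::empty_snippets())
  expect_identical(empty$n_snippets, 0L)
  expect_identical(empty$n_mirnas, 0L)
})

test_that("TSV and JSON exports round-trip field-for-field", {
  gc <- generate_corpus(13, corpus_params(n_docs = 2L))
  sn <- gc$gold_snippets
  for (ext in c(".tsv", ".json")) {
    tf <- tempfile(fileext = ext)
    export_snippets(sn, tf)
    back <- import_snippets(tf)
    expect_identical(as.data.frame(back), as.data.frame(sn),
                     info = ext)
  }
  expect_error(export_snippets(sn, "/no/such/dir/x.tsv"), "directory")
})

test_that("JSON export carries the schema's required fields", {
  gc <- generate_corpus(14, corpus_params(n_docs = 1L))
  tf <- tempfile(fileext = ".json")
  export_snippets(gc$gold_snippets, tf)
  objs <- jsonlite::fromJSON(tf, simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(
    system.file("extdata", "snippet_schema.json", package = "mircurate"),
    simplifyVector = FALSE)
  required <- unlist(schema$items$required)
  for (o in objs) {
    expect_true(all(required %in% names(o)))
    expect_true(o$status %in% c("AUTO", "CONFIRMED", "REJECTED"))
    expect_true(o$structure_id %in% c("S1", "S2", "S3"))
  }
  # imports reject structurally invalid tables
  bad <- gc$gold_snippets
  bad$mirna_key[1L] <- ""
  tf2 <- tempfile(fileext = ".tsv")
  expect_error({
    export_snippets(bad, tf2)
    import_snippets(tf2)
  }, "mirna_key")
})

test_that("effect polarity classification follows the shipped mapping", {
  expect_identical(effect_polarity(c("increase", "Repressed", "constant",
                                     "mysteriously")),
                   c("positive", "negative", "none", "none"))
})
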