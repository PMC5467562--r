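# dictionary building: term lists, variant generation, curator additions

test_that("load_term_list parses one term per line with optional identifier", {
  tf <- write_term_file(c("# comment", "hsa-mir-21-5p", "",
                          "SMAD7\tHGNC:6773", "bad\tline\textra"))
  expect_warning(entries <- load_term_list(tf, "MICRORNA"), "malformed")
  expect_identical(nrow(entries), 2L)
  expect_identical(entries$surface[1L], "hsa-mir-21-5p")
  expect_identical(entries$canonical_id[2L], "HGNC:6773")
  expect_true(all(!entries$is_variant))
})

test_that("duplicate surfaces within a file are deduplicated with a warning", {
  tf <- write_term_file(c("miR-21", "miR-185", "miR-21"))
  expect_warning(entries <- load_term_list(tf, "MICRORNA"), "duplicate")
  # entry count equals distinct non-blank lines (brute-force recount)
  lines <- readLines(tf)
  expect_identical(nrow(entries), length(unique(lines[nzchar(lines)])))
})

test_that("missing file is a fatal error naming the path; empty file is empty", {
  expect_error(load_term_list("/no/such/terms.txt", "GENE"),
               "/no/such/terms.txt")
  tf <- write_term_file(character())
  expect_identical(nrow(load_term_list(tf, "GENE")), 0L)
})

test_that("miRNA variant generation covers case, hyphen and pre-/pri- forms", {
  e <- term_entry("miR-21", "MICRORNA")
  v <- generate_variants(e)
  expect_true(all(c("MIR21", "mir-21", "miR21", "pre-miR-21", "pri-miR-21")
                  %in% v$surface))
  expect_false(e$surface %in% v$surface)
  expect_identical(v$category[v$surface == "pre-miR-21"], "PRE_MIRNA")
  expect_identical(v$category[v$surface == "pri-miR-21"], "PRI_MIRNA")
  expect_identical(unique(v$canonical_id), e$canonical_id)
  expect_true(all(v$is_variant))
})

test_that("non-miRNA categories yield no variants unless the policy asks", {
  e <- term_entry("IPF", "DISEASE")
  expect_identical(nrow(generate_variants(e)), 0L)
  v <- generate_variants(e, variant_policy(other_case_variants = TRUE))
  expect_setequal(v$surface, "ipf")
})

test_that("variant closure: every generated surface normalizes to the original key", {
  set.seed(31)
  fixture <- c(reference_mirna_names(),
               replicate(9, sample_grammar_name()))
  fixture <- fixture[mirna_matches(fixture)][1:20]
  for (name in fixture) {
    e <- term_entry(name, "MICRORNA")
    v <- generate_variants(e)
    expect_identical(unique(normalize_mirna_name(v$surface)),
                     normalize_mirna_name(name))
  }
})

test_that("build_lexicon assembles categories and resolves variant lookups", {
  mir_file <- write_term_file("miR-21")
  dis_file <- write_term_file(c("IPF", "asthma"))
  lex <- build_lexicon(list(
    list(path = mir_file, category = "MICRORNA", source = "mirbase-like"),
    list(path = dis_file, category = "DISEASE", source = "expert")
  ))
  expect_setequal(unique(lex$entries$category),
                  c("MICRORNA", "PRE_MIRNA", "PRI_MIRNA", "DISEASE"))
  # the HGNC-style spelling resolves through a generated variant
  hit <- lexicon_lookup(lex, "MIR21")
  expect_identical(hit$canonical_id, "mir-21")
  # independent recount: originals + variants - dedupe
  originals <- rbind(load_term_list(mir_file, "MICRORNA"),
                     load_term_list(dis_file, "DISEASE"))
  expected <- originals
  for (i in seq_len(nrow(originals))) {
    expected <- rbind(expected, generate_variants(originals[i, ]))
  }
  expected <- expected[!duplicated(expected[, c("surface", "category")]), ]
  expect_identical(nrow(lex$entries), nrow(expected))
  expect_error(build_lexicon(list()), "no term lists")
})

test_that("build_lexicon is idempotent and leaks no category entries", {
  tf <- write_term_file(c("miR-21", "miR-185"))
  spec <- list(list(path = tf, category = "MICRORNA"))
  lex1 <- build_lexicon(spec)
  lex2 <- build_lexicon(spec)
  expect_identical(lex1$entries, lex2$entries)
  # filtering by category and unioning reproduces the entry set exactly
  parts <- lapply(unique(lex1$entries$category),
                  function(cat) lex1$entries[lex1$entries$category == cat, ])
  rebuilt <- do.call(rbind, parts)
  expect_identical(nrow(rebuilt), nrow(lex1$entries))
  expect_setequal(paste(rebuilt$surface, rebuilt$category),
                  paste(lex1$entries$surface, lex1$entries$category))
})

test_that("add_term is idempotent and keeps the index consistent", {
  lex <- mini_lexicon()
  n0 <- nrow(lex$entries)
  e <- term_entry("miR-4242", "MICRORNA")
  lex1 <- add_term(lex, e)
  expect_gt(nrow(lex1$entries), n0)
  lex2 <- add_term(lex1, e)
  expect_identical(lex1$entries, lex2$entries)
  # a sentence containing the new name is now recognized via the dictionary
  m <- annotate_sentence("MIR4242 is increased in IPF.", lex1)
  expect_true("mir-4242" %in% m$canonical_key)
  # category index covers exactly the entries present
  indexed <- sum(vapply(lex1$index, function(slot)
    length(ls(envir = slot$env)), integer(1L)))
  keys <- unique(paste(
    vapply(seq_len(nrow(lex1$entries)), function(i) {
      toks <- tokenize(lex1$entries$surface[i])$token
      key <- paste(toks, collapse = " ")
      if (lex1$entries$category[i] %in% lex1$ci_categories) key <- tolower(key)
      key
    }, character(1L)),
    lex1$entries$category))
  expect_identical(indexed, length(keys))
})

test_that("lexicon round-trips through its TSV serialization", {
  lex <- mini_lexicon()
  tf <- tempfile(fileext = ".tsv")
  write_lexicon(lex, tf)
  lex2 <- read_lexicon(tf)
  expect_identical(as.data.frame(lex2$entries), as.data.frame(lex$entries))
  expect_identical(nrow(lexicon_lookup(lex2, "IPF", "DISEASE")), 1L)
})

test_that("ambiguous surfaces are retained in both categories", {
  f1 <- write_term_file("ZEB1\tZEB1")
  lex <- build_lexicon(list(
    list(path = f1, category = "GENE"),
    list(path = f1, category = "TRANSCRIPTION_FACTOR")
  ))
  hit <- lexicon_lookup(lex, "ZEB1")
  expect_setequal(hit$category, c("GENE", "TRANSCRIPTION_FACTOR"))
  # annotation keeps overlapping spans across categories
  m <- annotate_sentence("ZEB1 is increased.", lex)
  expect_setequal(m$category, c("GENE", "TRANSCRIPTION_FACTOR"))
})
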