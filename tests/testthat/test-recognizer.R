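# miRNA grammar matching, token-bounded mention finding, normalization

test_that("the pattern set fully matches nomenclature-conformant names", {
  pats <- compile_mirna_patterns()
  expect_true(all(mirna_matches(reference_mirna_names(), pats)))
  # let-family forms come from the extension set
  expect_true(all(mirna_matches(
    c("let-7a", "hsa-let-7a-5p", "LET7", "pre-let-7"), pats)))
  # a core token without a digit is never a name
  expect_false(any(mirna_matches(
    c("mir", "miR", "MIRLET", "mirage", "admire", "lethal"), pats)))
})

test_that("grammar-built names are all matched (component enumeration)", {
  pats <- compile_mirna_patterns()
  set.seed(11)
  names <- replicate(500, sample_grammar_name())
  ok <- mirna_matches(names, pats)
  expect_true(all(ok), info = paste("unmatched:",
                                    paste(head(names[!ok]), collapse = " ")))
})

test_that("regex matching agrees with the brute-force grammar oracle", {
  pats <- compile_mirna_patterns()
  set.seed(12)
  pool <- replicate(600, sample_grammar_name())
  perturbed <- vapply(pool, perturb_name, character(1L))
  cand <- c(pool, perturbed)
  got <- mirna_matches(cand, pats)
  want <- vapply(cand, in_grammar, logical(1L))
  expect_identical(unname(got), unname(want))
})

test_that("malformed extension patterns are rejected by name", {
  bad <- tempfile()
  writeLines("([unclosed", bad)
  expect_error(compile_mirna_patterns(extension_file = bad), "\\[unclosed")
})

test_that("find_mirna_mentions returns token-bounded leftmost-longest spans", {
  m <- find_mirna_mentions("An increase in miR-21 targets Smad7 in IPF.")
  expect_identical(nrow(m), 1L)
  expect_identical(m$surface, "miR-21")
  expect_identical(m$category, "MICRORNA")
  expect_identical(m$provenance, "REGEX")
  # offsets are 0-based half-open into the sentence
  s <- "An increase in miR-21 targets Smad7 in IPF."
  expect_identical(substr(s, m$start + 1L, m$end), m$surface)

  # hyphen flanks are allowed; alphanumeric flanks are not
  anti <- find_mirna_mentions("Treatment with anti-miR-21 improved outcome.")
  expect_identical(anti$surface, "miR-21")
  expect_identical(nrow(find_mirna_mentions("the word XmiR-21x is not a name")),
                   0L)

  # arm suffix is part of the leftmost-longest span
  arm <- find_mirna_mentions("levels of hsa-mir-21-5p rose")
  expect_identical(arm$surface, "hsa-mir-21-5p")

  expect_identical(nrow(find_mirna_mentions("")), 0L)
})

test_that("pre-/pri- modifiers set the mention category", {
  m <- find_mirna_mentions("pre-miR-21 and pri-miR-21 were detected")
  expect_setequal(m$category, c("PRE_MIRNA", "PRI_MIRNA"))
  expect_identical(unique(m$canonical_key), "mir-21")
})

test_that("plain English paragraphs yield no miRNA mentions", {
  doc <- generate_nonbio_text(3, 500)
  expect_identical(nrow(find_mirna_mentions(doc$text)), 0L)
})

test_that("normalization collapses variant spellings to one family key", {
  expect_identical(unique(normalize_mirna_name(
    c("MIR21", "miR-21", "MiR-21", "hsa-mir-21", "hsa-mir-21-5p",
      "pre-miR-21", "MIRN21"))), "mir-21")
  expect_identical(normalize_mirna_name("MIRLET7A"),
                   normalize_mirna_name("let-7a"))
  # let-7a and miR-7a are different families
  expect_false(normalize_mirna_name("let-7a") ==
                 normalize_mirna_name("miR-7a"))
  # idempotence: a key normalizes to itself
  keys <- normalize_mirna_name(reference_mirna_names())
  expect_identical(normalize_mirna_name(keys), keys)
  expect_error(normalize_mirna_name("SMAD7"), "not a miRNA name")
})

test_that("grammar-generated variant clusters map to one key per cluster", {
  set.seed(21)
  combos <- expand.grid(num = c("1", "21", "155", "4999"),
                        value = c("", "a", "b"),
                        suf1 = c("", "-1", "-2"),
                        stringsAsFactors = FALSE)
  combos <- combos[sample(nrow(combos), 30L), ]
  keys_by_cluster <- apply(combos, 1L, function(row) {
    variants <- c(
      paste0("miR-", row[["num"]], row[["value"]], row[["suf1"]]),
      paste0("mir", row[["num"]], row[["value"]], row[["suf1"]]),
      paste0("hsa-MiR-", row[["num"]], row[["value"]], row[["suf1"]]),
      paste0("MIR-", row[["num"]], row[["value"]], row[["suf1"]], "-5p")
    )
    unique(normalize_mirna_name(variants))
  })
  expect_true(all(lengths(keys_by_cluster) == 1L))
  expect_identical(anyDuplicated(unlist(keys_by_cluster)), 0L)
})

test_that("parse_mirna_name exposes species, modifier and arm facets", {
  p <- parse_mirna_name("pre-hsa-mir-21-5p")
  expect_identical(p$key, "mir-21")
  expect_identical(p$species, "hsa")
  expect_identical(p$modifier, "pre")
  expect_identical(p$arm, "5p")
})
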