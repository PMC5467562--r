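# Boolean filters and conceptual-structure matching

test_that("filter expressions parse into the expected trees", {
  f <- parse_filter("MICRORNA AND EFFECT='induced or repressed' AND DISEASE='IPF'")
  expect_identical(f$op, "AND")
  expect_length(f$children, 3L)
  expect_identical(f$children[[2L]]$category, "EFFECT")
  expect_setequal(f$children[[2L]]$values, c("induced", "repressed"))
  leaf <- parse_filter("MICRORNA")
  expect_identical(leaf$op, "LEAF")
  # AND binds tighter than OR
  g <- parse_filter("MICRORNA OR GENE AND DISEASE")
  expect_identical(g$op, "OR")
  expect_identical(g$children[[2L]]$op, "AND")
})

test_that("parse errors report a position", {
  expect_error(parse_filter("MICRORNA AND"), "position")
  expect_error(parse_filter("NOTACATEGORY"), "unknown category")
  expect_error(parse_filter("MICRORNA AND (GENE"), "position")
  expect_error(parse_filter("EFFECT='unterminated"), "unterminated")
})

test_that("parse/render round-trips are stable for random expressions", {
  set.seed(51)
  for (i in 1:200) {
    e <- random_filter_expr(depth = 3L)
    p1 <- parse_filter(e)
    p2 <- parse_filter(render_filter(p1))
    expect_identical(p2, p1)
  }
})

test_that("apply_filter retains sentences per leaf semantics and reports stats", {
  lex <- mini_lexicon()
  sentences <- tibble::tibble(
    doc_id = "d", index = 0:2,
    text = c("miR-185 is increased in IPF.",
             "SMAD7 was unchanged.",
             "Nothing relevant here."))
  mentions <- annotate_corpus(sentences, lex)
  r <- apply_filter(sentences, mentions, "MICRORNA")
  expect_identical(r$retained$index, 0L)
  expect_identical(r$stats$retained, 1L)
  r2 <- apply_filter(sentences, mentions, "GENE OR MICRORNA")
  expect_identical(r2$retained$index, 0:1)
  # value constraints match surfaces or canonical keys case-insensitively
  r3 <- apply_filter(sentences, mentions, "DISEASE='ipf'")
  expect_identical(r3$retained$index, 0L)
  # no-hit category yields zero retained, 0.00 percent
  r4 <- apply_filter(sentences, mentions, "ORGANISM")
  expect_identical(r4$stats$retained, 0L)
  expect_identical(r4$stats$percent_retained, 0)
})

test_that("EFFECT value constraints expand through polarity synonym groups", {
  lex <- mini_lexicon()
  sentences <- tibble::tibble(doc_id = "d", index = 0L,
                              text = "miR-185 is increased in IPF.")
  mentions <- annotate_corpus(sentences, lex)
  hit <- apply_filter(sentences, mentions, "EFFECT='induced or repressed'")
  expect_identical(hit$stats$retained, 1L)
  miss <- apply_filter(sentences, mentions, "EFFECT='repressed'")
  expect_identical(miss$stats$retained, 0L)
  literal <- apply_filter(sentences, mentions, "EFFECT='induced'",
                          effect_synonyms = FALSE)
  expect_identical(literal$stats$retained, 0L)
})

test_that("percent retained uses half-up rounding to 2 decimals", {
  s <- filter_stats(26347, 2799)
  expect_identical(s$percent_retained, 10.62)
  expect_identical(filter_stats(0, 0)$percent_retained, 0)
  expect_identical(filter_stats(800, 1)$percent_retained, 0.13)  # 0.125 up
  expect_error(filter_stats(10, 11))
})

test_that("filter algebra: AND is intersection, OR is union, both monotone", {
  set.seed(52)
  cats <- mircurate_categories()
  for (rep in 1:25) {
    corp <- random_annotated_corpus(15L)
    x <- sample(cats, 1L)
    y <- sample(cats, 1L)
    rx <- apply_filter(corp$sentences, corp$mentions, x)$retained$index
    ry <- apply_filter(corp$sentences, corp$mentions, y)$retained$index
    rand <- apply_filter(corp$sentences, corp$mentions,
                         paste(x, "AND", y))$retained$index
    ror <- apply_filter(corp$sentences, corp$mentions,
                        paste(x, "OR", y))$retained$index
    expect_identical(rand, intersect(rx, ry))
    expect_identical(sort(ror), sort(union(rx, ry)))
    expect_lte(length(rand), length(rx))   # AND-monotone
    expect_gte(length(ror), length(rx))    # OR-monotone
  }
})

test_that("conceptual structures bind the worked example sentences", {
  lex <- mini_lexicon()
  m1 <- annotate_sentence("miR-185 is increased in IPF.", lex)
  s1 <- match_structure(m1, "S1")
  expect_identical(nrow(s1), 1L)
  expect_identical(s1$mirna_surface, "miR-185")
  expect_identical(s1$effect_surface, "increased")
  expect_identical(s1$disease_surface, "IPF")

  m2 <- annotate_sentence("An increase in miR-21 targets Smad7 in IPF.", lex)
  s2 <- match_structure(m2, "S2")
  expect_identical(nrow(s2), 1L)
  expect_identical(s2$target_gene_surface, "Smad7")
  expect_identical(s2$target_gene_key, "SMAD7")
  expect_identical(s2$mirna_key, "mir-21")

  m3 <- annotate_sentence(
    "There is an increase in COL1A2 (A MIR-29b target) in lung biopsies from IPF patients.",
    lex)
  s3 <- match_structure(m3, "S3")
  expect_identical(nrow(s3), 1L)
  expect_identical(s3$mirna_key, "mir-29b")
  expect_identical(s3$effect_surface, "increase")
  expect_identical(s3$target_gene_key, "COL1A2")
  expect_identical(s3$sample_surface, "lung biopsies")
  expect_identical(s3$disease_surface, "IPF")
})

test_that("slot binding enumerates combinations and requires required slots", {
  lex <- mini_lexicon()
  m <- annotate_sentence("miR-21 and miR-185 both target Smad7.", lex)
  s2 <- match_structure(m, "S2")
  expect_identical(nrow(s2), 2L)  # 2 miRNAs x 1 gene
  expect_setequal(s2$mirna_key, c("mir-21", "mir-185"))
  # without a gene, S2 cannot match
  m_nogene <- annotate_sentence("miR-21 is increased in IPF.", lex)
  expect_identical(nrow(match_structure(m_nogene, "S2")), 0L)
  # enumeration cap
  capped <- match_structure(m, "S2", max_matches = 1L)
  expect_identical(nrow(capped), 1L)
  # transcription factors are admissible target genes
  m_tf <- annotate_sentence("miR-200c represses ZEB1 in fibroblasts.",
                            lex)
  s_tf <- match_structure(m_tf, "S3")
  expect_true(all(s_tf$target_gene_key == "ZEB1"))
})

test_that("every S1 structure match implies retention by the MICRORNA filter", {
  lex <- mini_lexicon()
  gc <- generate_corpus(5, corpus_params(n_docs = 2L))
  mentions <- annotate_corpus(gc$sentences, lex)
  retained <- apply_filter(gc$sentences, mentions, "MICRORNA")$retained
  matches <- match_structure_corpus(mentions, "S1")
  keys_matched <- unique(paste(matches$doc_id, matches$sentence_index))
  keys_retained <- paste(retained$doc_id, retained$index)
  expect_true(all(keys_matched %in% keys_retained))
})

test_that("trigger-term ranking counts category mentions with conservation", {
  surfaces <- rep(c("increased", "repressed"), c(10L, 3L))
  mentions <- tibble::tibble(
    doc_id = "d", sentence_index = rep(c(0L, 1L), c(10L, 3L)),
    start = 0L, end = 9L, surface = surfaces, category = "EFFECT",
    canonical_key = surfaces, provenance = "DICTIONARY")
  ranked <- rank_trigger_terms(mentions, "EFFECT")
  expect_identical(ranked$term[1L], "increased")
  expect_identical(ranked$count[1L], 10L)
  expect_identical(sum(ranked$count), sum(mentions$category == "EFFECT"))
  empty <- rank_trigger_terms(mircurate:::empty_mentions(), "EFFECT")
  expect_identical(nrow(empty), 0L)
})
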