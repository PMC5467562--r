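# shared fixtures for the test suite

reference_mirna_names <- function() {
  c("hsa-mir-21-5p", "hsa-mir-213", "hsa-mir-21", "miR-21", "MIR21",
    "miR-185", "miR-338-5p", "miR-323", "miR-200a", "miR-200c", "miR-200")
}

write_term_file <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  writeLines(lines, tf, useBytes = TRUE)
  tf
}

# a small annotated corpus built directly as tables (fast path for
# filter-algebra properties): random mentions over random sentences
random_annotated_corpus <- function(n_sentences = 20L) {
  cats <- mircurate_categories()
  sentences <- tibble::tibble(
    doc_id = "rnd", index = seq_len(n_sentences) - 1L,
    text = replicate(n_sentences, paste(sample(letters, 5L), collapse = " "))
  )
  rows <- list()
  for (i in seq_len(n_sentences)) {
    k <- sample(0:4, 1L)
    if (!k) next
    for (j in seq_len(k)) {
      cat_j <- sample(cats, 1L)
      surf <- sample(c("increased", "repressed", "IPF", "SMAD7", "miR-21",
                       "lung tissue", "mice", "constant"), 1L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        doc_id = "rnd", sentence_index = i - 1L,
        start = 0L, end = nchar(surf), surface = surf,
        category = cat_j, canonical_key = tolower(surf),
        provenance = "DICTIONARY")
    }
  }
  mentions <- if (length(rows)) do.call(rbind, rows) else
    mircurate:::empty_mentions()
  list(sentences = sentences, mentions = mentions)
}

random_filter_expr <- function(depth = 2L) {
  cats <- mircurate_categories()
  leaf <- function() {
    cat_x <- sample(cats, 1L)
    if (runif(1) < 0.3) {
      vals <- sample(c("increased", "repressed", "ipf", "smad7", "mir-21"),
                     sample(1:2, 1L))
      paste0(cat_x, "='", paste(vals, collapse = " or "), "'")
    } else cat_x
  }
  build <- function(d) {
    if (d <= 0L || runif(1) < 0.4) return(leaf())
    op <- sample(c(" AND ", " OR "), 1L)
    paste0("(", build(d - 1L), op, build(d - 1L), ")")
  }
  build(depth)
}
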