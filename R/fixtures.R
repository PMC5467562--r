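# Synthetic gold-corpus generation: template-built articles with seeded,
# offset-exact mentions and snippets, plus a non-biomedical text generator
# for false-positive testing of the miRNA recognizer.

#' The bundled mini-lexicon
#'
#' A small multi-category annotation dictionary shipped with the package:
#' regulatory-effect vocabulary, disease terms (idiopathic pulmonary
#' fibrosis and related), target genes, transcription factors, organisms and
#' sample descriptors. It powers the worked examples, the synthetic-corpus
#' generator and the test suite; real curation projects supply their own
#' term lists via \code{\link{build_lexicon}}.
#'
#' @param policy A \code{\link{variant_policy}}.
#' @return A \code{mircurate_lexicon}.
#' @export
mini_lexicon <- function(policy = variant_policy()) {
  files <- list(
    list(path = extdata_path("minilex", "effects.tsv"), category = "EFFECT",
         source = "minilex"),
    list(path = extdata_path("minilex", "diseases.tsv"),
         category = "DISEASE", source = "minilex"),
    list(path = extdata_path("minilex", "genes.tsv"), category = "GENE",
         source = "minilex"),
    list(path = extdata_path("minilex", "transcription_factors.tsv"),
         category = "TRANSCRIPTION_FACTOR", source = "minilex"),
    list(path = extdata_path("minilex", "organisms.tsv"),
         category = "ORGANISM", source = "minilex"),
    list(path = extdata_path("minilex", "samples.tsv"), category = "SAMPLE",
         source = "minilex")
  )
  build_lexicon(files, policy = policy)
}

nonbio_vocabulary <- function() {
  readLines(extdata_path("nonbio_vocab.txt"), encoding = "UTF-8")
}

# read a minilex table as surface/id pairs
minilex_terms <- function(file) {
  lines <- readLines(extdata_path("minilex", file), encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    surface = vapply(parts, `[`, character(1L), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else
      tolower(p[1L]), character(1L))
  )
}

#' Default generation parameters for the synthetic gold corpus
#'
#' The defaults emulate a small full-text curation corpus: a minority of
#' sentences carry curatable miRNA statements (the three conceptual
#' structures, together about 12 percent of sentences, mirroring the roughly
#' one-in-ten miRNA-sentence share seen when filtering real full texts) and
#' the rest is filler English. miRNA names are sampled from the
#' nomenclature grammar and rendered in randomized variant spellings (core
#' casing, hyphenation, species prefix, arm suffix, occasional pre-/pri-
#' modifier) while the gold annotations record the family canonical key.
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Sentences per document.
#' @param rates Named numeric: probabilities for sentence kinds \code{s1},
#'   \code{s2}, \code{s3}; the remainder is filler.
#' @param p_species,p_arm,p_premod,p_no_hyphen Variant-rendering
#'   probabilities for seeded miRNA names.
#' @return Parameter list for \code{\link{generate_corpus}}.
#' @export
corpus_params <- function(n_docs = 5L, sentences_per_doc = 40L,
                          rates = c(s1 = 0.05, s2 = 0.04, s3 = 0.03),
                          p_species = 0.3, p_arm = 0.25, p_premod = 0.1,
                          p_no_hyphen = 0.25) {
  stopifnot(all(rates >= 0), sum(rates) <= 1, n_docs >= 1L,
            sentences_per_doc >= 1L)
  list(n_docs = as.integer(n_docs),
       sentences_per_doc = as.integer(sentences_per_doc),
       rates = rates, p_species = p_species, p_arm = p_arm,
       p_premod = p_premod, p_no_hyphen = p_no_hyphen)
}

# sample a miRNA identity and render one variant surface of it
sample_mirna <- function(params) {
  number <- sample(1:499, 1L)
  value <- sample(c("", "a", "b", "c"), 1L, prob = c(0.6, 0.15, 0.15, 0.1))
  core <- sample(c("mir", "miR", "MiR", "MIR"), 1L,
                 prob = c(0.2, 0.5, 0.1, 0.2))
  hyphen <- stats::runif(1) > params$p_no_hyphen
  prefix <- if (stats::runif(1) < params$p_species)
    sample(c("hsa", "mmu", "rno"), 1L) else ""
  arm <- if (stats::runif(1) < params$p_arm) sample(c("-3p", "-5p"), 1L)
         else ""
  premod <- if (stats::runif(1) < params$p_premod) sample(c("pre-", "pri-"), 1L)
            else ""
  surface <- paste0(
    premod,
    if (nzchar(prefix)) paste0(prefix, "-") else "",
    core, if (hyphen) "-" else "", number, value, arm
  )
  list(surface = surface,
       key = paste0("mir-", number, value),
       category = switch(premod, "pre-" = "PRE_MIRNA", "pri-" = "PRI_MIRNA",
                         "MICRORNA"))
}

# assemble a sentence from parts; parts with a category become gold mentions
compose_sentence <- function(parts) {
  text <- ""
  mentions <- list()
  for (p in parts) {
    start <- nchar(text)
    text <- paste0(text, p$text)
    if (!is.null(p$category)) {
      mentions[[length(mentions) + 1L]] <- list(
        start = start, end = start + nchar(p$text), surface = p$text,
        category = p$category, key = p$key)
    }
  }
  list(text = text, mentions = mentions)
}

piece <- function(text, category = NULL, key = NULL) {
  list(text = text, category = category, key = key)
}

#' Generate a synthetic gold-annotated corpus
#'
#' Builds documents from sentence templates mirroring the three conceptual
#' structures plus filler English, recording gold mentions (offset-exact by
#' construction) and gold snippets for every seeded structure instance.
#' Regenerating with the same seed and parameters is deterministic.
#'
#' @param seed Integer RNG seed.
#' @param params Parameter list from \code{\link{corpus_params}}.
#' @return A \code{gold_corpus}: list with \code{documents} (list of
#'   \code{mircurate_document}), \code{sentences} (sentence tibble),
#'   \code{gold_mentions} (mention tibble, provenance \code{"GOLD"}),
#'   \code{gold_snippets} (snippet tibble) and \code{params}.
#' @export
#' @examples
#' gc <- generate_corpus(1, corpus_params(n_docs = 2, sentences_per_doc = 10))
#' summarize_snippets(gc$gold_snippets)
generate_corpus <- function(seed, params = corpus_params()) {
  if (sum(params$rates) > 1) stop("structure rates exceed 1", call. = FALSE)
  vocab <- nonbio_vocabulary()
  if (!length(vocab)) stop("empty filler vocabulary", call. = FALSE)
  effects <- minilex_terms("effects.tsv")
  diseases <- minilex_terms("diseases.tsv")
  genes <- minilex_terms("genes.tsv")
  tfs <- minilex_terms("transcription_factors.tsv")
  organisms <- minilex_terms("organisms.tsv")
  samples <- minilex_terms("samples.tsv")
  adj_effects <- effects$surface[effects$surface %in% c(
    "increased", "decreased", "induced", "repressed", "upregulated",
    "downregulated", "up-regulated", "down-regulated", "overexpressed",
    "reduced", "diminished", "elevated")]
  noun_effects <- effects$surface[effects$surface %in% c(
    "increase", "decrease", "induction", "repression")]
  pol_map <- effect_polarity_map()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  pick <- function(df) {
    i <- sample(nrow(df), 1L)
    df[i, ]
  }
  kinds <- c(names(params$rates), "filler")
  probs <- c(params$rates, filler = 1 - sum(params$rates))
  documents <- list()
  sent_rows <- list()
  mention_rows <- list()
  snippet_rows <- list()
  for (d in seq_len(params$n_docs)) {
    doc_id <- sprintf("synth-%03d", d)
    doc_text <- ""
    for (si in seq_len(params$sentences_per_doc)) {
      kind <- sample(kinds, 1L, prob = probs)
      gene_pool <- if (stats::runif(1) < 0.2) tfs else genes
      if (kind == "s1") {
        m <- sample_mirna(params)
        eff <- pick(effects[effects$surface %in% adj_effects, ])
        dis <- pick(diseases)
        with_org <- stats::runif(1) < 0.3
        parts <- list(
          piece(m$surface, m$category, m$key),
          piece(" is "),
          piece(eff$surface, "EFFECT", eff$id),
          piece(" in ")
        )
        if (with_org) {
          org <- pick(organisms)
          parts <- c(parts, list(piece(org$surface, "ORGANISM", org$id),
                                 piece(" with ")))
        }
        parts <- c(parts, list(piece(dis$surface, "DISEASE", dis$id),
                               piece(".")))
        snip <- list(mirna_key = m$key, effect = eff$surface,
                     target_gene = NA_character_, sample = NA_character_,
                     disease = dis$surface, structure_id = "S1")
      } else if (kind == "s2") {
        m <- sample_mirna(params)
        eff <- pick(effects[effects$surface %in% noun_effects, ])
        gene <- pick(gene_pool)
        dis <- pick(diseases)
        parts <- list(
          piece("An "), piece(eff$surface, "EFFECT", eff$id),
          piece(" in "), piece(m$surface, m$category, m$key),
          piece(" targets "),
          piece(gene$surface,
                if (identical(gene_pool, tfs)) "TRANSCRIPTION_FACTOR"
                else "GENE", gene$id),
          piece(" in "), piece(dis$surface, "DISEASE", dis$id), piece(".")
        )
        snip <- list(mirna_key = m$key, effect = eff$surface,
                     target_gene = gene$id, sample = NA_character_,
                     disease = dis$surface, structure_id = "S2")
      } else if (kind == "s3") {
        m <- sample_mirna(params)
        eff <- pick(effects[effects$surface %in% noun_effects, ])
        gene <- pick(gene_pool)
        dis <- pick(diseases)
        smp <- pick(samples)
        parts <- list(
          piece("There is an "), piece(eff$surface, "EFFECT", eff$id),
          piece(" in "),
          piece(gene$surface,
                if (identical(gene_pool, tfs)) "TRANSCRIPTION_FACTOR"
                else "GENE", gene$id),
          piece(" (a "), piece(m$surface, m$category, m$key),
          piece(" target) in "), piece(smp$surface, "SAMPLE", smp$id),
          piece(" from "), piece(dis$surface, "DISEASE", dis$id),
          piece(" patients.")
        )
        snip <- list(mirna_key = m$key, effect = eff$surface,
                     target_gene = gene$id, sample = smp$surface,
                     disease = dis$surface, structure_id = "S3")
      } else {
        nw <- sample(8:14, 1L)
        words <- sample(vocab, nw, replace = TRUE)
        words[1L] <- paste0(toupper(substr(words[1L], 1L, 1L)),
                            substr(words[1L], 2L, nchar(words[1L])))
        parts <- list(piece(paste0(paste(words, collapse = " "), ".")))
        snip <- NULL
      }
      built <- compose_sentence(parts)
      sent_start <- nchar(doc_text) + if (nzchar(doc_text)) 1L else 0L
      doc_text <- if (nzchar(doc_text)) paste0(doc_text, " ", built$text)
                  else built$text
      sent_index <- si - 1L
      sent_rows[[length(sent_rows) + 1L]] <- tibble::tibble(
        doc_id = doc_id, index = sent_index,
        start = sent_start, end = sent_start + nchar(built$text),
        text = built$text)
      for (gm in built$mentions) {
        mention_rows[[length(mention_rows) + 1L]] <- tibble::tibble(
          doc_id = doc_id, sentence_index = sent_index,
          start = as.integer(gm$start), end = as.integer(gm$end),
          surface = gm$surface, category = gm$category,
          canonical_key = gm$key, provenance = "GOLD")
      }
      if (!is.null(snip)) {
        snippet_rows[[length(snippet_rows) + 1L]] <- tibble::tibble(
          snippet_id = sprintf("gold:%s:%d", doc_id, sent_index),
          doc_id = doc_id, sentence_index = sent_index,
          sentence_text = built$text,
          mirna_key = snip$mirna_key, effect = snip$effect,
          effect_polarity = effect_polarity(snip$effect, pol_map),
          target_gene = snip$target_gene, sample = snip$sample,
          disease = snip$disease, structure_id = snip$structure_id,
          status = "AUTO")
      }
    }
    documents[[doc_id]] <- structure(
      list(doc_id = doc_id, source_path = NA_character_, text = doc_text,
           cleaning_log = "generated"),
      class = "mircurate_document")
  }
  structure(
    list(
      documents = documents,
      sentences = do.call(rbind, sent_rows),
      gold_mentions = if (length(mention_rows)) do.call(rbind, mention_rows)
                      else empty_mentions(),
      gold_snippets = if (length(snippet_rows)) do.call(rbind, snippet_rows)
                      else empty_snippets(),
      params = c(list(seed = seed), params)
    ),
    class = "gold_corpus"
  )
}

#' @export
print.gold_corpus <- function(x, ...) {
  cat("<gold_corpus> ", length(x$documents), " documents, ",
      nrow(x$sentences), " sentences, ", nrow(x$gold_mentions),
      " gold mentions, ", nrow(x$gold_snippets), " gold snippets\n",
      sep = "")
  invisible(x)
}

#' Write a gold corpus to disk
#'
#' Documents as one \code{.txt} per article plus gold annotation and snippet
#' tables in the package's TSV exchange formats.
#'
#' @param corpus A \code{gold_corpus}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_gold_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus$documents) {
    writeLines(doc$text, file.path(dir, paste0(doc$doc_id, ".txt")),
               useBytes = TRUE)
  }
  write_sentences(corpus$sentences, file.path(dir, "sentences.tsv"))
  write_mentions(corpus$gold_mentions, file.path(dir, "gold_mentions.tsv"))
  export_snippets(corpus$gold_snippets, file.path(dir, "gold_snippets.tsv"))
  invisible(dir)
}

#' Generate non-biomedical English text
#'
#' Plain filler English drawn from a bundled non-biomedical vocabulary that
#' contains no digits and no miRNA core tokens, so by construction it can
#' contain no string matching the miRNA grammar (which requires a core
#' token followed by at least one digit). Used as the false-positive test
#' bed for the recognizer.
#'
#' @param seed Integer RNG seed.
#' @param n_words Number of words to generate.
#' @return A \code{mircurate_document}.
#' @export
#' @examples
#' doc <- generate_nonbio_text(1, 50)
#' nrow(find_mirna_mentions(doc$text))  # 0
generate_nonbio_text <- function(seed, n_words) {
  stopifnot(n_words > 0)
  vocab <- nonbio_vocabulary()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  words <- sample(vocab, n_words, replace = TRUE)
  sentences <- character()
  i <- 1L
  while (i <= n_words) {
    len <- min(sample(8:15, 1L), n_words - i + 1L)
    chunk <- words[i:(i + len - 1L)]
    chunk[1L] <- paste0(toupper(substr(chunk[1L], 1L, 1L)),
                        substr(chunk[1L], 2L, nchar(chunk[1L])))
    sentences <- c(sentences, paste0(paste(chunk, collapse = " "), "."))
    i <- i + len
  }
  structure(
    list(doc_id = sprintf("nonbio-seed%d", seed), source_path = NA_character_,
         text = paste(sentences, collapse = " "),
         cleaning_log = "generated"),
    class = "mircurate_document")
}
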