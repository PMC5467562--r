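# Candidate-term mining: the n-gram pipeline that produced the effect and
# sample vocabularies (tokenize -> lowercase -> stopword filter -> length
# filter -> n-grams, n = 1..5 -> frequency ranking).

#' The bundled English stopword list
#'
#' A compact common-English stopword list shipped with the package and used
#' by default in \code{\link{extract_candidate_terms}}; fully overridable.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  readLines(extdata_path("stopwords_en.txt"), encoding = "UTF-8")
}

#' Mine candidate terms from a corpus by n-gram extraction
#'
#' Reproduces the candidate-vocabulary pipeline, in order: tokenize each
#' sentence (hyphen-preserving), lowercase, drop stopwords, drop tokens
#' whose length falls outside \code{[min_len, max_len]}, then form n-grams
#' (n = 1..\code{max_n}) over the surviving \emph{consecutive} tokens.
#' N-grams never cross sentence boundaries. Terms are counted by total
#' corpus occurrences and by the number of documents containing them, and
#' ranked by corpus frequency, then document frequency, then
#' lexicographically.
#'
#' @param docs A list of \code{mircurate_document}s (or character vector of
#'   document texts).
#' @param stopwords Lowercase words removed before n-gram formation.
#' @param min_len,max_len Token length band kept after stopword removal.
#' @param max_n Largest n-gram size (default 5).
#' @return Tibble with columns \code{ngram}, \code{n}, \code{doc_freq},
#'   \code{corpus_freq}, ranked as above.
#' @export
#' @examples
#' extract_candidate_terms(list(as_document("mir-21 is increased in ipf lungs")),
#'                         stopwords = c("is", "in"))
extract_candidate_terms <- function(docs, stopwords = default_stopwords(),
                                    min_len = 2L, max_len = 40L,
                                    max_n = 5L) {
  stopifnot(min_len <= max_len, max_n >= 1L)
  if (is.character(docs)) docs <- lapply(docs, as_document)
  if (inherits(docs, "mircurate_document")) docs <- list(docs)
  if (!length(docs)) stop("no documents supplied", call. = FALSE)
  stopwords <- tolower(stopwords)
  counts <- new.env(parent = emptyenv())
  docsets <- new.env(parent = emptyenv())
  any_tokens <- FALSE
  for (d in seq_along(docs)) {
    doc <- docs[[d]]
    sentences <- split_sentences(doc)
    for (si in seq_len(nrow(sentences))) {
      toks <- tolower(tokenize(sentences$text[si])$token)
      toks <- toks[!toks %in% stopwords]
      lens <- nchar(toks)
      toks <- toks[lens >= min_len & lens <= max_len]
      m <- length(toks)
      if (!m) next
      any_tokens <- TRUE
      for (n in seq_len(min(max_n, m))) {
        for (i in seq_len(m - n + 1L)) {
          g <- paste(toks[i:(i + n - 1L)], collapse = " ")
          key <- paste0(n, "|", g)
          prev <- if (exists(key, envir = counts, inherits = FALSE))
            get(key, envir = counts) else 0L
          assign(key, prev + 1L, envir = counts)
          dset <- if (exists(key, envir = docsets, inherits = FALSE))
            get(key, envir = docsets) else integer()
          if (!d %in% dset) assign(key, c(dset, d), envir = docsets)
        }
      }
    }
  }
  keys <- ls(envir = counts)
  if (!length(keys)) {
    if (!any_tokens) warning("no tokens survived filtering", call. = FALSE)
    return(tibble::tibble(ngram = character(), n = integer(),
                          doc_freq = integer(), corpus_freq = integer()))
  }
  n <- as.integer(sub("\\|.*$", "", keys))
  ngram <- sub("^[0-9]+\\|", "", keys)
  corpus_freq <- unname(vapply(keys, function(k) get(k, envir = counts),
                               integer(1L)))
  doc_freq <- unname(vapply(keys, function(k)
    length(get(k, envir = docsets)), integer(1L)))
  res <- tibble::tibble(ngram = ngram, n = n, doc_freq = doc_freq,
                        corpus_freq = corpus_freq)
  res[order(-res$corpus_freq, -res$doc_freq, res$ngram), ]
}

#' Write a ranked candidate-term table
#'
#' Tab-separated columns: ngram, n, doc_freq, corpus_freq — the table handed
#' to expert review for dictionary expansion.
#'
#' @param terms Tibble from \code{\link{extract_candidate_terms}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_candidate_terms <- function(terms, path) {
  utils::write.table(terms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
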