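# Sentence annotation: union of grammar-based miRNA recognition and
# dictionary longest-match scanning, with per-category overlap resolution.

# dictionary longest-match scan over the sentence's tokens, one category at
# a time; returns a mention tibble
dictionary_mentions <- function(sentence, lexicon, doc_id = "doc",
                                sentence_index = 0L) {
  toks <- tokenize(sentence)
  if (!nrow(toks)) return(empty_mentions())
  out <- list()
  for (cat in names(lexicon$index)) {
    slot <- lexicon$index[[cat]]
    ci <- cat %in% lexicon$ci_categories
    i <- 1L
    n <- nrow(toks)
    while (i <= n) {
      matched <- FALSE
      for (len in seq(min(slot$max_tokens, n - i + 1L), 1L)) {
        j <- i + len - 1L
        # multi-token terms must be separated by whitespace only
        if (len > 1L) {
          gaps_ok <- TRUE
          for (g in i:(j - 1L)) {
            gap <- substr(sentence, toks$end[g] + 1L, toks$start[g + 1L])
            if (!stringi::stri_detect_regex(gap, "^\\s*$")) {
              gaps_ok <- FALSE
              break
            }
          }
          if (!gaps_ok) next
        }
        key <- paste(toks$token[i:j], collapse = " ")
        if (ci) key <- tolower(key)
        if (exists(key, envir = slot$env, inherits = FALSE)) {
          row <- get(key, envir = slot$env)
          start0 <- toks$start[i]
          end0 <- toks$end[j]
          out[[length(out) + 1L]] <- tibble::tibble(
            doc_id = doc_id, sentence_index = as.integer(sentence_index),
            start = start0, end = end0,
            surface = substr(sentence, start0 + 1L, end0),
            category = cat,
            canonical_key = lexicon$entries$canonical_id[row],
            provenance = "DICTIONARY"
          )
          i <- j + 1L
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
  }
  if (!length(out)) return(empty_mentions())
  do.call(rbind, out)
}

# within one category keep the longer of two overlapping spans; on identical
# spans prefer the dictionary mention (it carries a database identifier)
resolve_overlaps <- function(mentions) {
  if (nrow(mentions) < 2L) return(mentions)
  keep <- rep(TRUE, nrow(mentions))
  ord <- order(mentions$category,
               -(mentions$end - mentions$start),
               mentions$provenance != "DICTIONARY",
               mentions$start)
  for (cat in unique(mentions$category)) {
    rows <- ord[mentions$category[ord] == cat]
    taken_start <- integer()
    taken_end <- integer()
    for (r in rows) {
      s <- mentions$start[r]
      e <- mentions$end[r]
      if (any(s < taken_end & e > taken_start)) {
        keep[r] <- FALSE
      } else {
        taken_start <- c(taken_start, s)
        taken_end <- c(taken_end, e)
      }
    }
  }
  res <- mentions[keep, ]
  res[order(res$start, res$end, res$category), ]
}

#' Annotate a sentence with entity mentions
#'
#' Combines grammar-based miRNA recognition
#' (\code{\link{find_mirna_mentions}}) with dictionary longest-match
#' scanning over every lexicon category. Within one category, overlapping
#' spans are resolved in favor of the longer one (identical spans in favor
#' of the dictionary mention, which carries a database identifier);
#' overlapping spans in \emph{different} categories are all kept — a surface
#' may legitimately be both a gene and a transcription factor. The result is
#' a pure function of (sentence, lexicon, pattern set).
#'
#' @param sentence Character scalar (one segmented sentence).
#' @param lexicon A \code{mircurate_lexicon}, or \code{NULL} for regex-only
#'   annotation.
#' @param doc_id,sentence_index Identifiers stamped onto the mentions.
#' @param patterns A \code{mirna_patterns} object.
#' @return Mention tibble; offsets are 0-based, half-open into the sentence,
#'   and slicing the sentence at them reproduces each surface.
#' @export
#' @examples
#' lex <- mini_lexicon()
#' annotate_sentence("miR-185 is increased in IPF.", lex)
annotate_sentence <- function(sentence, lexicon = NULL, doc_id = "doc",
                              sentence_index = 0L,
                              patterns = compile_mirna_patterns()) {
  rx <- find_mirna_mentions(sentence, patterns, doc_id, sentence_index)
  dict <- if (is.null(lexicon)) empty_mentions()
          else dictionary_mentions(sentence, lexicon, doc_id, sentence_index)
  resolve_overlaps(rbind(rx, dict))
}

#' Annotate a sentence table
#'
#' Applies \code{\link{annotate_sentence}} to every row of a sentence table
#' (as produced by \code{\link{split_sentences}}).
#'
#' @param sentences Tibble with columns \code{doc_id}, \code{index},
#'   \code{text}.
#' @param lexicon A \code{mircurate_lexicon} (or \code{NULL}).
#' @param patterns A \code{mirna_patterns} object.
#' @return Mention tibble over all sentences.
#' @export
annotate_corpus <- function(sentences, lexicon = NULL,
                            patterns = compile_mirna_patterns()) {
  out <- lapply(seq_len(nrow(sentences)), function(i) {
    annotate_sentence(sentences$text[i], lexicon,
                      doc_id = sentences$doc_id[i],
                      sentence_index = sentences$index[i],
                      patterns = patterns)
  })
  res <- do.call(rbind, c(list(empty_mentions()), out))
  res
}

#' Write mentions as a tab-separated annotation file
#'
#' One record per mention: doc_id, sentence_index, start, end, surface,
#' category, canonical_key, provenance. Offsets are 0-based and half-open —
#' this layout is the package's exchange contract. \code{format = "json"}
#' writes an equivalent JSON array.
#'
#' @param mentions Mention tibble.
#' @param path Output path.
#' @param format \code{"tsv"} (default) or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_mentions <- function(mentions, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(mentions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(mentions, path, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a mention table written by \code{\link{write_mentions}}
#'
#' @param path Path to a TSV or JSON mention file.
#' @return Mention tibble.
#' @export
read_mentions <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.delim(path, sep = "\t", quote = "", as.is = TRUE,
                            encoding = "UTF-8")
  }
  df <- tibble::as_tibble(df)
  df$sentence_index <- as.integer(df$sentence_index)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}
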