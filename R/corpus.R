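# Document ingestion, sentence segmentation and tokenization: the stable,
# offset-faithful units over which annotation and filtering operate.

# abbreviations after which a period never ends a sentence
sentence_abbreviations <- function() {
  c("al", "et al", "Fig", "Figs", "fig", "e.g", "i.e", "vs", "cf", "etc",
    "Dr", "Prof", "No", "ca", "approx", "resp", "Suppl", "Ref", "Refs")
}

#' Read and clean a plain-text or XML document
#'
#' Reads an article as UTF-8 (with a Latin-1 fallback), strips control
#' characters, rejoins words hyphenated across line breaks and collapses
#' whitespace runs. The line-break hyphen is \emph{kept} when rejoining
#' (\code{"miR-\\n21"} becomes \code{"miR-21"}): miRNA names carry meaningful
#' hyphens, and losing them would break both regex and dictionary matching.
#' The occasional false join of an ordinary end-of-line hyphenation is the
#' accepted trade-off. Files ending in \code{.xml} or \code{.nxml} are parsed
#' with \pkg{xml2} and reduced to their body text (all tags discarded).
#'
#' @param path Path to a \code{.txt} (or \code{.xml}/\code{.nxml}) file.
#' @param doc_id Document identifier; defaults to the file name sans extension.
#' @return An object of class \code{mircurate_document}: a list with
#'   \code{doc_id}, \code{source_path}, \code{text} and \code{cleaning_log}.
#' @export
read_document <- function(path, doc_id = NULL) {
  if (!file.exists(path)) stop("cannot read document: ", path, call. = FALSE)
  if (is.null(doc_id)) {
    doc_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  }
  is_xml <- grepl("\\.(xml|nxml)$", path, ignore.case = TRUE)
  if (is_xml) {
    doc <- xml2::read_xml(path)
    body <- xml2::xml_find_first(doc, ".//body")
    node <- if (inherits(body, "xml_node")) body else doc
    raw <- xml2::xml_text(node)
  } else {
    raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (any(is.na(nchar(raw, allowNA = TRUE)))) {
      raw <- readLines(path, encoding = "latin1", warn = FALSE)
      raw <- enc2utf8(raw)
    }
    raw <- paste(raw, collapse = "\n")
  }
  log <- character()
  text <- raw
  if (stringi::stri_detect_regex(text, "[\\x00-\\x08\\x0b-\\x1f\\x7f]")) {
    text <- stringi::stri_replace_all_regex(
      text, "[\\x00-\\x08\\x0b-\\x1f\\x7f]", " ")
    log <- c(log, "stripped control characters")
  }
  if (stringi::stri_detect_regex(text, "-\\n\\s*[A-Za-z0-9]")) {
    text <- stringi::stri_replace_all_regex(
      text, "-\\n\\s*(?=[A-Za-z0-9])", "-")
    log <- c(log, "rejoined line-break hyphenation (hyphen kept)")
  }
  if (stringi::stri_detect_regex(text, "\\s{2,}|\\n|\\t")) {
    text <- stringi::stri_replace_all_regex(text, "\\s+", " ")
    log <- c(log, "collapsed whitespace runs")
  }
  text <- trimws(text)
  if (!nzchar(text)) warning("document is empty: ", path, call. = FALSE)
  if (is_xml) log <- c("extracted XML body text", log)
  structure(
    list(doc_id = doc_id, source_path = path, text = text,
         cleaning_log = log),
    class = "mircurate_document"
  )
}

#' Construct a document object from in-memory text
#'
#' Convenience constructor applying the same cleaning as
#' \code{\link{read_document}} but starting from a character scalar.
#'
#' @param text Document text.
#' @param doc_id Document identifier.
#' @return A \code{mircurate_document}.
#' @export
as_document <- function(text, doc_id = "doc") {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(text, tf, useBytes = FALSE)
  doc <- suppressWarnings(read_document(tf, doc_id = doc_id))
  doc$source_path <- NA_character_
  doc
}

#' @export
print.mircurate_document <- function(x, ...) {
  cat("<mircurate_document> ", x$doc_id, ": ", nchar(x$text), " chars\n",
      sep = "")
  invisible(x)
}

#' Split a document into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at \code{.},
#' \code{!} or \code{?} followed by whitespace and an uppercase letter, digit
#' or opening quote/parenthesis, unless the period terminates a known
#' abbreviation (\code{et al.}, \code{Fig.}, \code{e.g.}, \code{i.e.},
#' \code{vs.}, ...) or a single-letter initial. Offsets are 0-based,
#' half-open into the document text, and slicing the document at a
#' sentence's offsets reproduces its text exactly.
#'
#' @param doc A \code{mircurate_document} (or character scalar).
#' @return Tibble with columns \code{doc_id}, \code{index} (0-based),
#'   \code{start}, \code{end}, \code{text}.
#' @export
#' @examples
#' doc <- as_document("miR-185 is increased in IPF. miR-21 targets Smad7.")
#' split_sentences(doc)
split_sentences <- function(doc) {
  if (is.character(doc)) doc <- as_document(doc)
  text <- doc$text
  n <- nchar(text)
  empty <- tibble::tibble(doc_id = character(), index = integer(),
                          start = integer(), end = integer(),
                          text = character())
  if (n == 0L) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  abbrevs <- tolower(sentence_abbreviations())
  breaks <- integer()  # positions (1-based) of sentence-final characters
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      # absorb a closing quote/paren following the terminator
      j <- i
      while (j < n && chars[j + 1L] %in% c("\"", "'", ")", "]")) j <- j + 1L
      nxt <- if (j < n) chars[j + 1L] else ""
      after_ok <- j == n ||
        (nxt == " " && j + 1L < n &&
           grepl("[A-Za-z0-9\"'(\\[]", chars[j + 2L]))
      split_here <- after_ok
      if (split_here && ch == ".") {
        prev <- substr(text, max(1L, i - 12L), i - 1L)
        word <- stringi::stri_extract_last_regex(prev, "[A-Za-z][A-Za-z.]*$")
        if (!is.na(word)) {
          if (tolower(word) %in% abbrevs) split_here <- FALSE
          # single uppercase initial, e.g. "J. Smith"
          if (nchar(word) == 1L && grepl("[A-Z]", word)) split_here <- FALSE
        }
        # "et al." — two-word abbreviation
        if (split_here &&
            stringi::stri_detect_regex(prev, "(?i)\\bet\\s+al$")) {
          split_here <- FALSE
        }
      }
      if (split_here) {
        breaks <- c(breaks, j)
        i <- j
      }
    }
    i <- i + 1L
  }
  if (!length(breaks) || breaks[length(breaks)] < n) breaks <- c(breaks, n)
  starts1 <- c(1L, head(breaks, -1L) + 1L)
  rows <- list()
  idx <- 0L
  for (k in seq_along(breaks)) {
    s <- starts1[k]
    e <- breaks[k]
    # trim whitespace into the separator, keeping offsets faithful
    while (s <= e && chars[s] == " ") s <- s + 1L
    while (e >= s && chars[e] == " ") e <- e - 1L
    if (s > e) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      doc_id = doc$doc_id, index = idx,
      start = s - 1L, end = e,
      text = substr(text, s, e)
    )
    idx <- idx + 1L
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Tokenize a sentence, preserving internal hyphens
#'
#' Tokens are maximal runs of alphanumerics in which internal hyphens between
#' alphanumeric characters are kept, so \code{hsa-mir-21-5p} is one token.
#' All other punctuation and whitespace separates tokens. Offsets are
#' 0-based, half-open into the sentence.
#'
#' @param sentence Character scalar.
#' @return Tibble with columns \code{token}, \code{start}, \code{end}.
#' @export
#' @examples
#' tokenize("miR-21 targets Smad7")
tokenize <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  empty <- tibble::tibble(token = character(), start = integer(),
                          end = integer())
  if (!nzchar(sentence)) return(empty)
  loc <- stringi::stri_locate_all_regex(
    sentence, "[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*")[[1L]]
  if (all(is.na(loc[, 1L]))) return(empty)
  tibble::tibble(
    token = stringi::stri_sub(sentence, loc[, 1L], loc[, 2L]),
    start = as.integer(loc[, 1L] - 1L),
    end = as.integer(loc[, 2L])
  )
}

#' Write a sentence table to a tab-separated file
#'
#' Columns: doc_id, index, start, end, text; offsets 0-based, half-open.
#'
#' @param sentences Tibble from \code{\link{split_sentences}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sentences <- function(sentences, path) {
  utils::write.table(sentences, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
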