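# Curation snippets: the exportable unit binding a miRNA to optional
# effect, target gene, sample and disease, plus corpus-level summaries.

#' Effect-term polarity mapping
#'
#' Maps regulatory-effect vocabulary to a polarity: \code{positive}
#' (induction/activation: increase, induced, up-regulated, overexpressed,
#' higher, ...), \code{negative} (repression: decrease, repressed,
#' down-regulated, reduced, diminished, deleted, ...) or \code{none}
#' (no-change wording such as "constant" / "unchanged", which carries
#' curatable information but no direction). Shipped as an editable
#' tab-separated file (term, polarity) in \code{extdata}.
#'
#' @return Named character vector: lowercase effect term -> polarity.
#' @export
effect_polarity_map <- function() {
  df <- utils::read.delim(extdata_path("effect_polarity.tsv"), sep = "\t",
                          quote = "", as.is = TRUE, encoding = "UTF-8")
  stats::setNames(df$polarity, tolower(df$term))
}

#' Classify an effect term's polarity
#'
#' @param term Character vector of effect surfaces.
#' @param map Polarity map, by default \code{\link{effect_polarity_map}}.
#' @return Character vector: \code{"positive"}, \code{"negative"} or
#'   \code{"none"} (unknown terms map to \code{"none"}).
#' @export
effect_polarity <- function(term, map = effect_polarity_map()) {
  out <- unname(map[tolower(term)])
  out[is.na(out)] <- "none"
  out[is.na(term)] <- NA_character_
  out
}

snippet_columns <- function() {
  c("snippet_id", "doc_id", "sentence_index", "sentence_text", "mirna_key",
    "effect", "effect_polarity", "target_gene", "sample", "disease",
    "structure_id", "status")
}

empty_snippets <- function() {
  tibble::tibble(
    snippet_id = character(), doc_id = character(),
    sentence_index = integer(), sentence_text = character(),
    mirna_key = character(), effect = character(),
    effect_polarity = character(), target_gene = character(),
    sample = character(), disease = character(),
    structure_id = character(), status = character()
  )
}

#' Build curation snippets from structure matches
#'
#' One snippet per structure match, status \code{AUTO}; the snippet id is a
#' deterministic function of (doc_id, sentence_index, bound mention
#' offsets), so regenerating from the same corpus yields the same ids.
#'
#' @param matches Structure-match tibble from \code{\link{match_structure}}
#'   or \code{\link{match_structure_corpus}}.
#' @param sentences Optional sentence tibble used to attach sentence text.
#' @param polarity_map Effect-polarity map.
#' @return Snippet tibble (columns \code{snippet_id}, \code{doc_id},
#'   \code{sentence_index}, \code{sentence_text}, \code{mirna_key},
#'   \code{effect}, \code{effect_polarity}, \code{target_gene},
#'   \code{sample}, \code{disease}, \code{structure_id}, \code{status}).
#' @export
snippets_from_matches <- function(matches, sentences = NULL,
                                  polarity_map = effect_polarity_map()) {
  if (!nrow(matches)) return(empty_snippets())
  sent_text <- function(doc_id, idx) {
    if (is.null(sentences)) return(NA_character_)
    hit <- which(sentences$doc_id == doc_id & sentences$index == idx)
    if (length(hit)) sentences$text[hit[1L]] else NA_character_
  }
  rows <- lapply(seq_len(nrow(matches)), function(i) {
    m <- matches[i, ]
    offs <- c(m$mirna_start, m$effect_start, m$target_gene_start,
              m$sample_start, m$disease_start)
    sid <- paste0(m$doc_id, ":", m$sentence_index, ":",
                  paste(ifelse(is.na(offs), "x", offs), collapse = "-"))
    tibble::tibble(
      snippet_id = sid, doc_id = m$doc_id,
      sentence_index = m$sentence_index,
      sentence_text = sent_text(m$doc_id, m$sentence_index),
      mirna_key = m$mirna_key,
      effect = m$effect_surface,
      effect_polarity = if (is.na(m$effect_surface)) NA_character_
                        else effect_polarity(m$effect_surface, polarity_map),
      target_gene = m$target_gene_key,
      sample = m$sample_surface,
      disease = m$disease_surface,
      structure_id = m$structure_id,
      status = "AUTO"
    )
  })
  do.call(rbind, rows)
}

#' Confirm or reject curation snippets
#'
#' Status moves only \code{AUTO -> CONFIRMED} or \code{AUTO -> REJECTED};
#' revisiting an already-decided snippet is an error. The snippet count is
#' never changed, only the status column.
#'
#' @param snippets Snippet tibble.
#' @param snippet_ids Ids to update.
#' @param status \code{"CONFIRMED"} or \code{"REJECTED"}.
#' @return Updated snippet tibble.
#' @export
set_snippet_status <- function(snippets, snippet_ids,
                               status = c("CONFIRMED", "REJECTED")) {
  status <- match.arg(status)
  rows <- snippets$snippet_id %in% snippet_ids
  if (any(snippets$status[rows] != "AUTO")) {
    stop("status transitions are AUTO -> CONFIRMED/REJECTED only",
         call. = FALSE)
  }
  snippets$status[rows] <- status
  snippets
}

#' Summarize a snippet collection
#'
#' Reports the snippet count, the distinct-miRNA count (family-level
#' canonical keys, so \code{miR-21} and \code{hsa-mir-21-5p} count once),
#' per-miRNA snippet counts and per-effect-polarity counts.
#'
#' @param snippets Snippet tibble.
#' @param include_status Statuses counted; by default \code{AUTO} and
#'   \code{CONFIRMED} (rejected snippets are excluded).
#' @return A \code{snippet_summary} list: \code{n_snippets},
#'   \code{n_mirnas}, \code{per_mirna} (tibble), \code{per_polarity}
#'   (tibble).
#' @export
summarize_snippets <- function(snippets,
                               include_status = c("AUTO", "CONFIRMED")) {
  sub <- snippets[snippets$status %in% include_status, ]
  per_mirna <- if (nrow(sub)) {
    tab <- table(sub$mirna_key)
    res <- tibble::tibble(mirna_key = names(tab), n = as.integer(tab))
    res[order(-res$n, res$mirna_key), ]
  } else tibble::tibble(mirna_key = character(), n = integer())
  pol <- sub$effect_polarity[!is.na(sub$effect_polarity)]
  per_polarity <- if (length(pol)) {
    tab <- table(pol)
    tibble::tibble(polarity = names(tab), n = as.integer(tab))
  } else tibble::tibble(polarity = character(), n = integer())
  structure(
    list(n_snippets = nrow(sub),
         n_mirnas = length(unique(sub$mirna_key)),
         per_mirna = per_mirna,
         per_polarity = per_polarity),
    class = "snippet_summary"
  )
}

#' @export
print.snippet_summary <- function(x, ...) {
  cat("<snippet_summary> ", x$n_snippets, " snippets across ",
      x$n_mirnas, " distinct miRNAs\n", sep = "")
  if (nrow(x$per_polarity)) {
    cat("  effect polarity: ",
        paste(x$per_polarity$polarity, x$per_polarity$n,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export / import curation snippets
#'
#' TSV export writes the fixed snippet columns with a header; JSON export
#' writes an array of objects conforming to the schema shipped at
#' \code{system.file("extdata", "snippet_schema.json", package =
#' "mircurate")}. The round-trip \code{import_snippets(export_snippets(x))}
#' reproduces the collection field-for-field.
#'
#' @param snippets Snippet tibble.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"} (inferred from the extension
#'   when omitted).
#' @return \code{path}, invisibly (export); a snippet tibble (import).
#' @export
export_snippets <- function(snippets, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write snippets: directory does not exist: ",
                    dirname(path), call. = FALSE)
  snippets <- snippets[, snippet_columns()]
  if (format == "tsv") {
    out <- snippets
    for (col in names(out)) {
      if (is.character(out[[col]])) out[[col]][is.na(out[[col]])] <- ""
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(snippets, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname export_snippets
#' @export
import_snippets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (!length(df)) return(empty_snippets())
    df <- tibble::as_tibble(df)
  } else {
    df <- utils::read.delim(path, sep = "\t", quote = "", as.is = TRUE,
                            encoding = "UTF-8",
                            colClasses = "character")
    df <- tibble::as_tibble(df)
    for (col in names(df)) {
      df[[col]][df[[col]] == ""] <- NA_character_
    }
  }
  df$sentence_index <- as.integer(df$sentence_index)
  validate_snippets(df)
  df[, snippet_columns()]
}

# light schema validation mirroring extdata/snippet_schema.json
validate_snippets <- function(snippets) {
  missing <- setdiff(snippet_columns(), names(snippets))
  if (length(missing)) {
    stop("snippet table is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(snippets$mirna_key) | !nzchar(snippets$mirna_key))) {
    stop("snippet with empty mirna_key", call. = FALSE)
  }
  bad <- !snippets$status %in% c("AUTO", "CONFIRMED", "REJECTED")
  if (any(bad)) stop("invalid snippet status: ",
                     paste(unique(snippets$status[bad]), collapse = ", "),
                     call. = FALSE)
  invisible(snippets)
}

#' Run the full curation pipeline over an annotated corpus
#'
#' For each sentence with at least one miRNA mention, matches the most
#' specific conceptual structure the sentence supports — S3 when a target
#' gene and a sample co-occur, S2 when a target gene does, S1 otherwise —
#' and materializes the matches as curation snippets. The three structures
#' overlap (dropping optional slots reduces S3 to S2 to S1), so a
#' deterministic specificity rule is needed for a well-defined snippet
#' count.
#'
#' @param sentences Sentence tibble.
#' @param mentions Mention tibble over those sentences.
#' @param max_matches Per-sentence combination cap.
#' @param polarity_map Effect-polarity map.
#' @return Snippet tibble.
#' @export
curate_corpus <- function(sentences, mentions, max_matches = 50L,
                          polarity_map = effect_polarity_map()) {
  if (!nrow(mentions)) return(empty_snippets())
  key <- paste(mentions$doc_id, mentions$sentence_index, sep = "\r")
  parts <- lapply(split(seq_len(nrow(mentions)), key), function(rows) {
    sub <- mentions[rows, ]
    has_gene <- any(sub$category %in% c("GENE", "TRANSCRIPTION_FACTOR"))
    has_sample <- any(sub$category == "SAMPLE")
    sid <- if (has_gene && has_sample) "S3" else if (has_gene) "S2" else "S1"
    match_structure(sub, sid, max_matches)
  })
  matches <- do.call(rbind, c(list(empty_structure_matches()),
                              unname(parts)))
  snippets_from_matches(matches, sentences, polarity_map)
}
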