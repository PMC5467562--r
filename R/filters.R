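# Boolean category filters over annotated sentences, and the typed
# conceptual structures (miRNA / effect / target gene / sample / disease)
# used to select curatable sentences.

# ---------------------------------------------------------------------------
# filter-expression grammar:
#   expr   := term ('OR' term)*
#   term   := factor ('AND' factor)*
#   factor := leaf | '(' expr ')'
#   leaf   := CATEGORY ("=" "'v1 or v2 or ...'")?
# AND binds tighter than OR.

filter_leaf <- function(category, values = NULL) {
  structure(list(op = "LEAF", category = category, values = values),
            class = "filter_expr")
}

filter_node <- function(op, children) {
  # flatten same-op children so associativity-equivalent expressions parse
  # to one canonical tree (render/parse round-trips are then stable)
  flat <- list()
  for (ch in children) {
    if (inherits(ch, "filter_expr") && identical(ch$op, op)) {
      flat <- c(flat, ch$children)
    } else {
      flat <- c(flat, list(ch))
    }
  }
  structure(list(op = op, children = flat), class = "filter_expr")
}

tokenize_filter <- function(expression) {
  toks <- list()
  i <- 1L
  n <- nchar(expression)
  while (i <= n) {
    ch <- substr(expression, i, i)
    if (ch == " ") { i <- i + 1L; next }
    if (ch %in% c("(", ")", "=")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
      next
    }
    if (ch == "'") {
      j <- i + 1L
      while (j <= n && substr(expression, j, j) != "'") j <- j + 1L
      if (j > n) stop("unterminated quoted value at position ", i,
                      call. = FALSE)
      toks[[length(toks) + 1L]] <- list(
        type = "STRING", value = substr(expression, i + 1L, j - 1L), pos = i)
      i <- j + 1L
      next
    }
    m <- stringi::stri_match_first_regex(
      substr(expression, i, n), "^[A-Za-z_][A-Za-z0-9_]*")[1L, 1L]
    if (is.na(m)) stop("syntax error at position ", i, ": unexpected '",
                       ch, "'", call. = FALSE)
    type <- switch(toupper(m), AND = "AND", OR = "OR", "WORD")
    toks[[length(toks) + 1L]] <- list(type = type, value = m, pos = i)
    i <- i + nchar(m)
  }
  toks
}

#' Parse a Boolean category filter expression
#'
#' The grammar accepts category names, optional value constraints
#' (\code{CATEGORY='v1 or v2'}), \code{AND} / \code{OR} and parentheses;
#' \code{AND} binds tighter than \code{OR}. Example:
#' \code{"MICRORNA AND EFFECT='induced or repressed' AND DISEASE='IPF'"}.
#'
#' @param expression Filter expression string.
#' @return A \code{filter_expr} tree.
#' @export
#' @examples
#' parse_filter("MICRORNA AND EFFECT='induced or repressed' AND DISEASE='IPF'")
parse_filter <- function(expression) {
  toks <- tokenize_filter(expression)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() {
    t <- toks[[pos]]
    pos <<- pos + 1L
    t
  }
  fail <- function(t, what) {
    at <- if (is.null(t)) nchar(expression) + 1L else t$pos
    stop("syntax error at position ", at, ": ", what, call. = FALSE)
  }
  parse_leaf <- function() {
    t <- peek()
    if (is.null(t)) fail(t, "expected a category")
    if (t$type == "(") {
      advance()
      e <- parse_expr()
      t2 <- peek()
      if (is.null(t2) || t2$type != ")") fail(t2, "expected ')'")
      advance()
      return(e)
    }
    if (t$type != "WORD") fail(t, paste0("expected a category, got '",
                                         t$value, "'"))
    advance()
    category <- toupper(t$value)
    if (!category %in% mircurate_categories()) {
      stop("unknown category at position ", t$pos, ": ", t$value,
           call. = FALSE)
    }
    values <- NULL
    t2 <- peek()
    if (!is.null(t2) && t2$type == "=") {
      advance()
      t3 <- peek()
      if (is.null(t3) || t3$type != "STRING") {
        fail(t3, "expected a quoted value after '='")
      }
      advance()
      values <- trimws(strsplit(t3$value, "\\s+or\\s+")[[1L]])
      values <- values[nzchar(values)]
      if (!length(values)) fail(t3, "empty value constraint")
    }
    filter_leaf(category, values)
  }
  parse_term <- function() {
    children <- list(parse_leaf())
    while (!is.null(peek()) && peek()$type == "AND") {
      advance()
      children[[length(children) + 1L]] <- parse_leaf()
    }
    if (length(children) == 1L) children[[1L]] else filter_node("AND", children)
  }
  parse_expr <- function() {
    children <- list(parse_term())
    while (!is.null(peek()) && peek()$type == "OR") {
      advance()
      children[[length(children) + 1L]] <- parse_term()
    }
    if (length(children) == 1L) children[[1L]] else filter_node("OR", children)
  }
  e <- parse_expr()
  t <- peek()
  if (!is.null(t)) fail(t, paste0("unexpected '", t$value, "'"))
  e
}

#' Render a filter tree back to its expression string
#'
#' \code{parse_filter(render_filter(x))} reproduces an equivalent tree.
#'
#' @param x A \code{filter_expr}.
#' @return Character scalar.
#' @export
render_filter <- function(x) {
  stopifnot(inherits(x, "filter_expr"))
  if (x$op == "LEAF") {
    if (is.null(x$values)) return(x$category)
    return(paste0(x$category, "='", paste(x$values, collapse = " or "), "'"))
  }
  parts <- vapply(x$children, function(ch) {
    s <- render_filter(ch)
    if (x$op == "AND" && ch$op == "OR") paste0("(", s, ")") else s
  }, character(1L))
  paste(parts, collapse = paste0(" ", x$op, " "))
}

#' @export
print.filter_expr <- function(x, ...) {
  cat("<filter_expr> ", render_filter(x), "\n", sep = "")
  invisible(x)
}

# expand EFFECT constraint values through the polarity synonym groups:
# "induced" also admits "increase", "upregulated", ... (same group). Terms
# not in the map, and the directionless "none" group, expand to themselves.
expand_effect_values <- function(values, map) {
  vals <- tolower(values)
  extra <- unlist(lapply(vals, function(v) {
    g <- unname(map[v])
    if (is.na(g) || g == "none") return(character())
    names(map)[map == g]
  }))
  unique(c(vals, extra))
}

# evaluate a filter tree for one sentence's mention subset
eval_filter <- function(x, mentions, effect_map = NULL) {
  if (x$op == "LEAF") {
    # the MicroRNA concept covers precursor and primary-transcript forms
    cats <- if (x$category == "MICRORNA")
      c("MICRORNA", "PRE_MIRNA", "PRI_MIRNA") else x$category
    rows <- mentions$category %in% cats
    if (!any(rows)) return(FALSE)
    if (is.null(x$values)) return(TRUE)
    vals <- tolower(x$values)
    if (x$category == "EFFECT" && !is.null(effect_map)) {
      vals <- expand_effect_values(vals, effect_map)
    }
    return(any(tolower(mentions$surface[rows]) %in% vals |
                 tolower(mentions$canonical_key[rows]) %in% vals))
  }
  results <- vapply(x$children, eval_filter, logical(1L), mentions,
                    effect_map)
  if (x$op == "AND") all(results) else any(results)
}

#' Sentence-retention statistics for a filter
#'
#' @param total_sentences Total sentence count.
#' @param retained Retained sentence count.
#' @return A \code{filter_stats} list: \code{total_sentences},
#'   \code{retained}, \code{percent_retained} (100 * retained / total,
#'   rounded half-up to 2 decimals).
#' @export
#' @examples
#' filter_stats(26347, 2799)  # 10.62 percent retained
filter_stats <- function(total_sentences, retained) {
  stopifnot(retained >= 0L, retained <= total_sentences)
  pct <- if (total_sentences == 0L) 0
         else floor(100 * retained / total_sentences * 100 + 0.5) / 100
  structure(list(total_sentences = as.integer(total_sentences),
                 retained = as.integer(retained),
                 percent_retained = pct),
            class = "filter_stats")
}

#' @export
print.filter_stats <- function(x, ...) {
  cat(x$retained, " of ", x$total_sentences, " sentences retained (",
      sprintf("%.2f", x$percent_retained), "%)\n", sep = "")
  invisible(x)
}

#' Filter annotated sentences with a Boolean category expression
#'
#' A sentence is retained iff the filter tree evaluates true over its
#' mentions: a leaf is true iff the sentence carries at least one mention of
#' that category and, when a value constraint is present, at least one such
#' mention whose surface or canonical key equals (case-insensitively) one of
#' the listed values. A \code{MICRORNA} leaf selects everything annotated as
#' a miRNA, including \code{PRE_MIRNA} / \code{PRI_MIRNA} forms; name the
#' precursor categories explicitly to filter on them alone.
#'
#' Value constraints on the \code{EFFECT} category are expanded through the
#' polarity synonym groups of \code{\link{effect_polarity_map}} (so
#' \code{EFFECT='induced or repressed'} also retains sentences saying
#' "increased" or "downregulated"); pass \code{effect_synonyms = FALSE} for
#' literal matching.
#'
#' @param sentences Sentence tibble (\code{doc_id}, \code{index},
#'   \code{text}, ...).
#' @param mentions Mention tibble over those sentences.
#' @param filter A \code{filter_expr}, or an expression string.
#' @param effect_synonyms Expand EFFECT values through synonym groups?
#' @return List with \code{retained} (sentence tibble subset) and
#'   \code{stats} (a \code{filter_stats}).
#' @export
apply_filter <- function(sentences, mentions, filter,
                         effect_synonyms = TRUE) {
  if (is.character(filter)) filter <- parse_filter(filter)
  stopifnot(inherits(filter, "filter_expr"))
  effect_map <- if (isTRUE(effect_synonyms)) effect_polarity_map() else NULL
  keep <- vapply(seq_len(nrow(sentences)), function(i) {
    sub <- mentions[mentions$doc_id == sentences$doc_id[i] &
                      mentions$sentence_index == sentences$index[i], ]
    eval_filter(filter, sub, effect_map)
  }, logical(1L))
  list(retained = sentences[keep, ],
       stats = filter_stats(nrow(sentences), sum(keep)))
}

# ---------------------------------------------------------------------------
# conceptual structures

#' The three conceptual structures for miRNA curation
#'
#' Typed co-occurrence patterns over annotated categories, used to select
#' curatable sentences:
#' \describe{
#'   \item{S1}{MicroRNA (Effect)? (AND Disease)? — e.g. "miR-185 is
#'     increased in IPF."}
#'   \item{S2}{MicroRNA (Effect)? AND TargetGene (AND Disease)? — e.g. "An
#'     increase in miR-21 targets Smad7 in IPF."}
#'   \item{S3}{MicroRNA (Effect)? AND TargetGene (AND Sample)? (AND
#'     Disease)? — e.g. "There is an increase in COL1A2 (A MIR-29b target)
#'     in lung biopsies from IPF patients."}
#' }
#' The MicroRNA slot is always required and binds \code{MICRORNA},
#' \code{PRE_MIRNA} or \code{PRI_MIRNA} mentions; TargetGene binds
#' \code{GENE} or \code{TRANSCRIPTION_FACTOR} (transcription factors are
#' regulatory genes and legitimate miRNA targets).
#'
#' @param id One of \code{"S1"}, \code{"S2"}, \code{"S3"}.
#' @return A \code{conceptual_structure}: slot specification with
#'   required/optional flags.
#' @export
conceptual_structure <- function(id = c("S1", "S2", "S3")) {
  id <- match.arg(id)
  slots <- switch(id,
    S1 = list(mirna = TRUE, effect = FALSE, target_gene = NA,
              sample = NA, disease = FALSE),
    S2 = list(mirna = TRUE, effect = FALSE, target_gene = TRUE,
              sample = NA, disease = FALSE),
    S3 = list(mirna = TRUE, effect = FALSE, target_gene = TRUE,
              sample = FALSE, disease = FALSE)
  )
  # TRUE = required, FALSE = optional, NA = not part of the structure
  structure(list(id = id, slots = slots), class = "conceptual_structure")
}

#' @export
print.conceptual_structure <- function(x, ...) {
  lab <- vapply(names(x$slots), function(s) {
    if (is.na(x$slots[[s]])) return(NA_character_)
    if (x$slots[[s]]) s else paste0("(", s, ")?")
  }, character(1L))
  cat("<conceptual_structure ", x$id, "> ",
      paste(lab[!is.na(lab)], collapse = " AND "), "\n", sep = "")
  invisible(x)
}

slot_categories <- function(slot) {
  switch(slot,
    mirna = c("MICRORNA", "PRE_MIRNA", "PRI_MIRNA"),
    effect = "EFFECT",
    target_gene = c("GENE", "TRANSCRIPTION_FACTOR"),
    sample = "SAMPLE",
    disease = "DISEASE"
  )
}

empty_structure_matches <- function() {
  cols <- c("doc_id", "sentence_index", "structure_id")
  slots <- c("mirna", "effect", "target_gene", "sample", "disease")
  out <- c(
    list(doc_id = character(), sentence_index = integer(),
         structure_id = character()),
    setNames(rep(list(character()), length(slots)),
             paste0(slots, "_surface")),
    setNames(rep(list(character()), length(slots)),
             paste0(slots, "_key")),
    setNames(rep(list(integer()), length(slots)), paste0(slots, "_start")),
    setNames(rep(list(integer()), length(slots)), paste0(slots, "_end"))
  )
  do.call(tibble::tibble, out)
}

#' Match a conceptual structure against an annotated sentence
#'
#' Binding is sentence-level typed co-occurrence: a slot binds any mention
#' of its categories in the sentence, with no linguistic parsing. Required
#' slots must bind; an optional slot binds when candidates exist and is left
#' unbound otherwise. When several mentions are candidates for a slot, all
#' combinations are enumerated, up to \code{max_matches}.
#'
#' @param mentions Mention tibble for \emph{one} sentence.
#' @param structure A \code{conceptual_structure} (or its id string).
#' @param max_matches Cap on enumerated combinations per sentence.
#' @return Tibble of structure matches: one row per admissible binding,
#'   with surface/key/offset columns per slot (\code{NA} when unbound).
#' @export
#' @examples
#' m <- annotate_sentence("miR-185 is increased in IPF.", mini_lexicon())
#' match_structure(m, "S1")
match_structure <- function(mentions, structure, max_matches = 50L) {
  if (is.character(structure)) structure <- conceptual_structure(structure)
  stopifnot(inherits(structure, "conceptual_structure"))
  if (!nrow(mentions)) return(empty_structure_matches())
  doc_id <- mentions$doc_id[1L]
  sentence_index <- mentions$sentence_index[1L]
  slot_rows <- list()
  for (slot in names(structure$slots)) {
    req <- structure$slots[[slot]]
    if (is.na(req)) {
      slot_rows[[slot]] <- NA_integer_  # not part of the structure
      next
    }
    rows <- which(mentions$category %in% slot_categories(slot))
    if (!length(rows)) {
      if (isTRUE(req)) return(empty_structure_matches())
      slot_rows[[slot]] <- NA_integer_
    } else {
      slot_rows[[slot]] <- rows
    }
  }
  combos <- expand.grid(slot_rows, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(combos) > max_matches) combos <- combos[seq_len(max_matches), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    vals <- list(doc_id = doc_id,
                 sentence_index = as.integer(sentence_index),
                 structure_id = structure$id)
    for (slot in names(slot_rows)) {
      r <- combos[[slot]][i]
      if (is.na(r)) {
        vals[[paste0(slot, "_surface")]] <- NA_character_
        vals[[paste0(slot, "_key")]] <- NA_character_
        vals[[paste0(slot, "_start")]] <- NA_integer_
        vals[[paste0(slot, "_end")]] <- NA_integer_
      } else {
        vals[[paste0(slot, "_surface")]] <- mentions$surface[r]
        vals[[paste0(slot, "_key")]] <- mentions$canonical_key[r]
        vals[[paste0(slot, "_start")]] <- mentions$start[r]
        vals[[paste0(slot, "_end")]] <- mentions$end[r]
      }
    }
    do.call(tibble::tibble, vals)
  })
  out <- do.call(rbind, rows)
  out[, names(empty_structure_matches())]
}

#' Match a conceptual structure across an annotated corpus
#'
#' @param mentions Mention tibble over many sentences.
#' @param structure A \code{conceptual_structure} or id string.
#' @param max_matches Per-sentence combination cap.
#' @return Tibble of structure matches over all sentences.
#' @export
match_structure_corpus <- function(mentions, structure, max_matches = 50L) {
  if (!nrow(mentions)) return(empty_structure_matches())
  key <- paste(mentions$doc_id, mentions$sentence_index, sep = "\r")
  parts <- lapply(split(seq_len(nrow(mentions)), key), function(rows) {
    match_structure(mentions[rows, ], structure, max_matches)
  })
  do.call(rbind, c(list(empty_structure_matches()), unname(parts)))
}

#' Rank trigger terms of a category by mention frequency
#'
#' Counts, per distinct (lowercased) surface, the mentions of one category
#' across an annotated corpus — the summary used to see which effect or
#' target-signaling words dominate a corpus.
#'
#' @param mentions Mention tibble.
#' @param category Category to summarize.
#' @return Tibble with columns \code{term}, \code{count}, sorted by
#'   descending count then term.
#' @export
rank_trigger_terms <- function(mentions, category) {
  assert_category(category)
  sub <- mentions[mentions$category == category, ]
  if (!nrow(sub)) return(tibble::tibble(term = character(),
                                        count = integer()))
  tab <- table(tolower(sub$surface))
  res <- tibble::tibble(term = names(tab), count = as.integer(tab))
  res[order(-res$count, res$term), ]
}
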