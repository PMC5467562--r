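# The multi-category annotation dictionary: term lists per category,
# automatic surface-variant generation for miRNA names, curator additions.

#' Variant-generation policy for the annotation dictionary
#'
#' Controls which surface variants are generated for dictionary entries.
#' For miRNA names the generator is bounded to case permutations of the core
#' token (\code{mir}/\code{miR}/\code{MiR}/\code{MIR}), single-edit hyphen
#' insertion/removal between core and number, and \code{pre-}/\code{pri-}
#' prefixed forms (emitted under the \code{PRE_MIRNA}/\code{PRI_MIRNA}
#' categories); this keeps the dictionary linear in the input while covering
#' the variation actually seen in articles (\code{miR-21} vs \code{MIR21} vs
#' \code{hsa-mir-21}).
#'
#' @param mirna_variants Generate variants for \code{MICRORNA} entries?
#' @param pre_pri Also emit \code{pre-}/\code{pri-} prefixed forms?
#' @param other_case_variants Generate lower/upper-case variants for
#'   non-miRNA, case-sensitively matched categories? Off by default.
#' @return An object of class \code{variant_policy}.
#' @export
variant_policy <- function(mirna_variants = TRUE, pre_pri = TRUE,
                           other_case_variants = FALSE) {
  structure(
    list(mirna_variants = isTRUE(mirna_variants),
         pre_pri = isTRUE(pre_pri),
         other_case_variants = isTRUE(other_case_variants)),
    class = "variant_policy"
  )
}

#' Create a dictionary term entry
#'
#' @param surface Surface form as it should be matched in documents.
#' @param category One of \code{\link{mircurate_categories}}.
#' @param canonical_id Database-style identifier; defaults to the normalized
#'   surface (family key for miRNA names, the surface itself otherwise).
#' @param source Provenance tag for the term list.
#' @param is_variant Is this a generated variant of another entry?
#' @return One-row tibble with the entry fields.
#' @export
term_entry <- function(surface, category, canonical_id = NULL,
                       source = "user", is_variant = FALSE) {
  surface <- stringi::stri_replace_all_regex(trimws(surface), "\\s+", " ")
  if (!nzchar(surface)) stop("term surface is empty", call. = FALSE)
  assert_category(category)
  if (is.null(canonical_id) || is.na(canonical_id) || !nzchar(canonical_id)) {
    canonical_id <- default_canonical_id(surface, category)
  }
  tibble::tibble(surface = surface, canonical_id = canonical_id,
                 category = category, source = source,
                 is_variant = isTRUE(is_variant))
}

default_canonical_id <- function(surface, category) {
  if (category %in% c("MICRORNA", "PRE_MIRNA", "PRI_MIRNA")) {
    key <- tryCatch(normalize_mirna_name(surface), error = function(e) NULL)
    if (!is.null(key)) return(key)
  }
  if (category %in% ci_categories_default()) tolower(surface) else surface
}

#' Load a term list file for one category
#'
#' One term per line, optionally a tab-separated identifier column; lines
#' beginning with \code{#} are comments; blank lines are skipped. Duplicate
#' surfaces within a file are deduplicated with a warning; a line with more
#' than one embedded tab is malformed and skipped with a warning.
#'
#' @param path Path to a UTF-8 term-list file.
#' @param category Category assigned to every term in the file.
#' @param source Provenance tag; defaults to the file name.
#' @return Tibble of term entries (zero rows for an empty file).
#' @export
load_term_list <- function(path, category, source = basename(path)) {
  assert_category(category)
  if (!file.exists(path)) {
    stop("term list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  entries <- list()
  seen <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) > 2L) {
      warning("malformed term-list line skipped (", length(parts) - 1L,
              " tabs): ", ln, call. = FALSE)
      next
    }
    surface <- stringi::stri_replace_all_regex(trimws(parts[1L]), "\\s+", " ")
    if (!nzchar(surface)) next
    if (surface %in% seen) {
      warning("duplicate term deduplicated: ", surface, call. = FALSE)
      next
    }
    seen <- c(seen, surface)
    id <- if (length(parts) == 2L && nzchar(trimws(parts[2L])))
      trimws(parts[2L]) else NULL
    entries[[length(entries) + 1L]] <-
      term_entry(surface, category, canonical_id = id, source = source)
  }
  if (!length(entries)) {
    return(term_entry("x", category)[0L, ])
  }
  do.call(rbind, entries)
}

# render one parsed miRNA name back to a surface with the requested core
# casing and hyphenation between core and number
render_mirna_surface <- function(p, core, hyphen, premod = "") {
  paste0(
    premod,
    p$prefix_raw,
    core,
    if (hyphen) "-" else "",
    p$iab, p$number, p$value, p$suf1, p$suf2
  )
}

#' Generate surface variants for a dictionary entry
#'
#' For miRNA entries, produces the bounded variant set: core-token case
#' permutations (\code{mir}, \code{miR}, \code{MiR}, \code{MIR}), hyphen
#' inserted/removed between core and number, and (policy permitting)
#' \code{pre-}/\code{pri-} prefixed forms carrying the \code{PRE_MIRNA} /
#' \code{PRI_MIRNA} categories. Every variant shares the original's
#' \code{canonical_id}; the original itself is not returned. Non-miRNA
#' entries yield case variants only when the policy enables them, otherwise
#' an empty set.
#'
#' @param entry A one-row term-entry tibble (an original, not a variant).
#' @param policy A \code{\link{variant_policy}}.
#' @return Tibble of variant entries (possibly zero rows).
#' @export
#' @examples
#' e <- term_entry("miR-21", "MICRORNA")
#' generate_variants(e)$surface
generate_variants <- function(entry, policy = variant_policy()) {
  stopifnot(nrow(entry) == 1L)
  if (isTRUE(entry$is_variant)) {
    stop("variants are generated from originals only", call. = FALSE)
  }
  out <- list()
  if (entry$category %in% c("MICRORNA", "PRE_MIRNA", "PRI_MIRNA") &&
      policy$mirna_variants) {
    comp <- parse_mirna_components(entry$surface)
    if (!is.null(comp)) {
      is_let <- toupper(comp$core) %in% c("LET", "MIRLET")
      cores <- if (is_let) c("let", "Let", "LET")
               else c("mir", "miR", "MiR", "MIR")
      p <- list(
        prefix_raw = if (nzchar(comp$prefix)) paste0(comp$prefix, "-") else "",
        iab = comp$iab, number = comp$number, value = comp$value,
        suf1 = comp$suf1, suf2 = comp$suf2
      )
      base_pm <- if (nzchar(comp$premod)) paste0(comp$premod, "-") else ""
      premods <- base_pm
      if (entry$category == "MICRORNA" && policy$pre_pri) {
        premods <- c(base_pm, "pre-", "pri-")
      }
      for (pm in premods) {
        cat_pm <- switch(pm, "pre-" = "PRE_MIRNA", "pri-" = "PRI_MIRNA",
                         entry$category)
        for (core in cores) {
          for (hyph in c(TRUE, FALSE)) {
            surf <- render_mirna_surface(p, core, hyph, premod = pm)
            if (surf == entry$surface) next
            out[[length(out) + 1L]] <- term_entry(
              surf, cat_pm, canonical_id = entry$canonical_id,
              source = entry$source, is_variant = TRUE)
          }
        }
      }
    }
  } else if (policy$other_case_variants) {
    for (surf in unique(c(tolower(entry$surface), toupper(entry$surface)))) {
      if (surf == entry$surface) next
      out[[length(out) + 1L]] <- term_entry(
        surf, entry$category, canonical_id = entry$canonical_id,
        source = entry$source, is_variant = TRUE)
    }
  }
  if (!length(out)) return(entry[0L, ])
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("surface", "category")]), ]
}

#' Build the annotation dictionary from category term lists
#'
#' Loads each term list, generates variants under the policy, and assembles
#' a lexicon. A surface occurring in two categories is retained in both
#' (ambiguity is resolved at annotation time by longest-match within each
#' category); within one category, \code{(surface, category)} is unique, the
#' first occurrence winning.
#'
#' @param term_lists A list of specs, each a list/vector with elements
#'   \code{path}, \code{category} and optionally \code{source}.
#' @param policy A \code{\link{variant_policy}}.
#' @param case_sensitive_genes Match \code{GENE} and
#'   \code{TRANSCRIPTION_FACTOR} surfaces case-sensitively? Short uppercase
#'   gene symbols otherwise collide with ordinary words. Default \code{TRUE}.
#' @return An object of class \code{mircurate_lexicon}.
#' @export
build_lexicon <- function(term_lists, policy = variant_policy(),
                          case_sensitive_genes = TRUE) {
  if (!length(term_lists)) stop("no term lists supplied", call. = FALSE)
  parts <- lapply(term_lists, function(tl) {
    tl <- as.list(tl)
    src <- if (!is.null(tl$source)) tl$source else basename(tl$path)
    load_term_list(tl$path, tl$category, source = src)
  })
  originals <- do.call(rbind, parts)
  if (is.null(originals) || !nrow(originals)) {
    stop("no usable dictionary entries in the supplied term lists",
         call. = FALSE)
  }
  lexicon_from_entries(originals, policy = policy,
                       case_sensitive_genes = case_sensitive_genes,
                       inputs = vapply(term_lists, function(tl)
                         paste0(as.list(tl)$path, ":", as.list(tl)$category),
                         character(1L)))
}

lexicon_from_entries <- function(originals, policy, case_sensitive_genes,
                                 inputs = character()) {
  variants <- lapply(seq_len(nrow(originals)), function(i) {
    generate_variants(originals[i, ], policy)
  })
  entries <- do.call(rbind, c(list(originals), variants))
  entries <- entries[!duplicated(entries[, c("surface", "category")]), ]
  ci <- ci_categories_default()
  if (!case_sensitive_genes) {
    ci <- unique(c(ci, "GENE", "TRANSCRIPTION_FACTOR"))
  }
  structure(
    list(
      entries = entries,
      policy = policy,
      ci_categories = ci,
      build_metadata = list(inputs = inputs,
                            built = format(Sys.time(), tz = "UTC")),
      index = build_lexicon_index(entries, ci)
    ),
    class = "mircurate_lexicon"
  )
}

# per-category hash: token-joined match key -> row index into entries
build_lexicon_index <- function(entries, ci_categories) {
  idx <- list()
  for (cat in unique(entries$category)) {
    rows <- which(entries$category == cat)
    env <- new.env(parent = emptyenv(), size = max(2L * length(rows), 16L))
    maxlen <- 1L
    for (r in rows) {
      toks <- tokenize(entries$surface[r])$token
      if (!length(toks)) next
      key <- paste(toks, collapse = " ")
      if (cat %in% ci_categories) key <- tolower(key)
      if (!exists(key, envir = env, inherits = FALSE)) {
        assign(key, r, envir = env)
      }
      maxlen <- max(maxlen, length(toks))
    }
    idx[[cat]] <- list(env = env, max_tokens = maxlen)
  }
  idx
}

#' @export
print.mircurate_lexicon <- function(x, ...) {
  tab <- table(x$entries$category)
  cat("<mircurate_lexicon> ", nrow(x$entries), " entries (",
      sum(x$entries$is_variant), " generated variants)\n", sep = "")
  for (cat_name in names(tab)) {
    cat("  ", format(cat_name, width = 22), tab[[cat_name]], "\n", sep = "")
  }
  invisible(x)
}

#' Look up a surface form in the lexicon
#'
#' @param lexicon A \code{mircurate_lexicon}.
#' @param surface Surface form to look up.
#' @param category Optional category to restrict the lookup.
#' @return Tibble of matching entries (zero rows if absent).
#' @export
lexicon_lookup <- function(lexicon, surface, category = NULL) {
  cats <- if (is.null(category)) names(lexicon$index) else category
  toks <- tokenize(surface)$token
  key0 <- paste(toks, collapse = " ")
  hits <- integer()
  for (cat in cats) {
    slot <- lexicon$index[[cat]]
    if (is.null(slot)) next
    key <- if (cat %in% lexicon$ci_categories) tolower(key0) else key0
    if (exists(key, envir = slot$env, inherits = FALSE)) {
      hits <- c(hits, get(key, envir = slot$env))
    }
  }
  lexicon$entries[hits, ]
}

#' Add a term to the lexicon (curator addition)
#'
#' Adds an entry plus its variants under the lexicon's policy. Idempotent:
#' adding an already-present \code{(surface, category)} leaves the lexicon
#' unchanged.
#'
#' @param lexicon A \code{mircurate_lexicon}.
#' @param entry A one-row entry from \code{\link{term_entry}}.
#' @return The updated lexicon.
#' @export
add_term <- function(lexicon, entry) {
  stopifnot(inherits(lexicon, "mircurate_lexicon"), nrow(entry) == 1L)
  present <- any(lexicon$entries$surface == entry$surface &
                   lexicon$entries$category == entry$category)
  if (present) return(lexicon)
  add <- rbind(entry, generate_variants(entry, lexicon$policy))
  entries <- rbind(lexicon$entries, add)
  entries <- entries[!duplicated(entries[, c("surface", "category")]), ]
  lexicon$entries <- entries
  lexicon$index <- build_lexicon_index(entries, lexicon$ci_categories)
  lexicon
}

#' Write / read a lexicon as a tab-separated table
#'
#' Columns: surface, canonical_id, category, source, is_variant. The
#' round-trip preserves the entry set; the variant policy recorded at build
#' time is not re-applied on reload.
#'
#' @param lexicon A \code{mircurate_lexicon}.
#' @param path Output path.
#' @return \code{path} (write) or a \code{mircurate_lexicon} (read).
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(lexicon$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lexicon
#' @param case_sensitive_genes See \code{\link{build_lexicon}}.
#' @export
read_lexicon <- function(path, case_sensitive_genes = TRUE) {
  df <- utils::read.delim(path, sep = "\t", quote = "", as.is = TRUE,
                          encoding = "UTF-8")
  entries <- tibble::as_tibble(df)
  entries$is_variant <- as.logical(entries$is_variant)
  ci <- ci_categories_default()
  if (!case_sensitive_genes) ci <- unique(c(ci, "GENE", "TRANSCRIPTION_FACTOR"))
  structure(
    list(entries = entries, policy = variant_policy(),
         ci_categories = ci,
         build_metadata = list(inputs = path,
                               built = format(Sys.time(), tz = "UTC")),
         index = build_lexicon_index(entries, ci)),
    class = "mircurate_lexicon"
  )
}
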