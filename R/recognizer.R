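# miRNA name recognition: a nomenclature grammar compiled to regular
# expressions, plus token-bounded scanning and canonical-key normalization.

#' Components of the miRNA nomenclature grammar
#'
#' The grammar captures names of the shape
#' \code{((pre|pri)-)? prefix? core -? (iab-)? digits value? paralog? arm?}:
#' an optional precursor/primary-transcript modifier, an optional species
#' prefix (\code{hsa-}, \code{mmu-}, ...), one of the core tokens
#' (\code{mir}, \code{miR}, \code{MiR}, \code{MIR}, \code{MIRN},
#' \code{MIRLET}), a mandatory 1-4 digit number, an optional alphanumeric
#' value tail (family letter, host-gene \code{HG} marker), an optional
#' paralog suffix (\code{-1}, \code{-2}, ...) and an optional arm suffix
#' (\code{-3p} / \code{-5p}). Requiring a core token followed by at least one
#' digit is what keeps the pattern from firing on ordinary English.
#'
#' @return Named list of regex fragments (character scalars):
#'   \code{premod}, \code{prefix}, \code{core}, \code{iab}, \code{number},
#'   \code{value}, \code{suf1} (paralog), \code{suf2} (arm).
#' @export
mirna_grammar_components <- function() {
  list(
    premod = "(?:pre|pri)-",
    prefix = paste0(
      "(?:ath|bmo|bta|cel|cfa|dme|dre|ebv|gga|hcmv|hsa|hsv1|hsv2|mml|mmu|",
      "ola|ptr|rno|ssc|tgu|xla|xtr)-"),
    core   = "(?:mir|miR|MiR|MIR|MIRN|MIRLET)",
    iab    = "iab-",
    number = "[0-9]{1,4}",
    value  = "[A-Za-z]?[0-9A-Za-z]?[0-9]?(?:HG)?",
    suf1   = "(?:-[1-9][0-9]?|-[123]HG)",
    suf2   = "(?:-3p|-5p)"
  )
}

# core pattern with named captures, used both for matching and for parsing
mirna_core_regex <- function() {
  g <- mirna_grammar_components()
  paste0(
    "(?:(?<premod>pre|pri)-)?",
    "(?:(?<prefix>", sub("^\\(\\?:", "", sub("\\)-$", "", g$prefix)), ")-)?",
    "(?<core>mir|miR|MiR|MIR|MIRN|MIRLET)",
    "-?",
    "(?<iab>iab-)?",
    "(?<num>[0-9]{1,4})",
    "(?<value>[A-Za-z]?[0-9A-Za-z]?[0-9]?(?:HG)?)",
    "(?<suf1>-[1-9][0-9]?|-[123]HG)?",
    "(?<suf2>-3p|-5p)?"
  )
}

# let-family analogue of the core pattern (extension set), with captures
mirna_let_regex <- function() {
  g <- mirna_grammar_components()
  paste0(
    "(?:(?<premod>pre|pri)-)?",
    "(?:(?<prefix>", sub("^\\(\\?:", "", sub("\\)-$", "", g$prefix)), ")-)?",
    "(?<core>let|Let|LET)",
    "-?",
    "(?<num>[0-9]{1,4})",
    "(?<value>[A-Za-z]?[0-9A-Za-z]?[0-9]?)",
    "(?<suf1>-[1-9][0-9]?)?",
    "(?<suf2>-3p|-5p)?"
  )
}

#' Built-in extension patterns for specialized miRNA name forms
#'
#' A small starter set of additional patterns for names the core grammar does
#' not cover, currently the \code{let-7} family written with the bare
#' \code{let} core (\code{let-7a}, \code{hsa-let-7a-5p}, ...). The set is a
#' curated approximation of the larger specialized-pattern collections used
#' in production dictionaries; users can extend it via a one-pattern-per-line
#' file (\code{#} comments allowed) passed to \code{\link{compile_mirna_patterns}}.
#'
#' @return Character vector of regular expressions.
#' @export
mirna_extension_patterns <- function() {
  path <- extdata_path("mirna_extension_patterns.txt")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Compile the miRNA recognition pattern set
#'
#' Assembles the core nomenclature pattern (see
#' \code{\link{mirna_grammar_components}}) and an extension slot of
#' specialized patterns, and returns them compiled for full-string matching.
#'
#' @param extension_file Optional path to a file of additional patterns, one
#'   per line, \code{#} comments allowed. Appended to the built-in starter
#'   set. Each pattern must be a valid regular expression; a malformed
#'   pattern is a fatal error naming the offending pattern.
#' @return An object of class \code{mirna_patterns}: a list with elements
#'   \code{core} (the core pattern), \code{extensions} (character vector) and
#'   \code{anchored} (all patterns wrapped in \code{^...$}, core first).
#' @export
#' @examples
#' pats <- compile_mirna_patterns()
#' mirna_matches(c("hsa-mir-21-5p", "mir", "let-7a"), pats)
compile_mirna_patterns <- function(extension_file = NULL) {
  extensions <- mirna_extension_patterns()
  if (!is.null(extension_file)) {
    lines <- trimws(readLines(extension_file, encoding = "UTF-8"))
    extensions <- c(extensions, lines[nzchar(lines) & !startsWith(lines, "#")])
  }
  core <- mirna_core_regex()
  for (p in extensions) {
    ok <- tryCatch({
      stringi::stri_detect_regex("x", p)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("malformed extension pattern: ", p, call. = FALSE)
  }
  structure(
    list(
      core = core,
      extensions = extensions,
      anchored = paste0("^(?:", c(core, extensions), ")$")
    ),
    class = "mirna_patterns"
  )
}

#' @export
print.mirna_patterns <- function(x, ...) {
  cat("<mirna_patterns> core grammar + ", length(x$extensions),
      " extension pattern(s)\n", sep = "")
  invisible(x)
}

#' Test strings for full-match against the miRNA pattern set
#'
#' @param x Character vector of candidate surface forms.
#' @param patterns A \code{mirna_patterns} object; compiled fresh if omitted.
#' @return Logical vector: does the entire string match the grammar?
#' @export
mirna_matches <- function(x, patterns = compile_mirna_patterns()) {
  out <- rep(FALSE, length(x))
  for (p in patterns$anchored) {
    rest <- !out
    if (!any(rest)) break
    out[rest] <- stringi::stri_detect_regex(x[rest], p)
  }
  out
}

# parse a full surface form into its grammar components; NULL if no parse.
# tries the core grammar first, then the let-family extension grammar.
parse_mirna_components <- function(surface) {
  for (pat in c(mirna_core_regex(), mirna_let_regex())) {
    m <- regexpr(paste0("^(?:", pat, ")$"), surface, perl = TRUE)
    if (m == 1L) {
      cs <- attr(m, "capture.start")[1L, ]
      cl <- attr(m, "capture.length")[1L, ]
      grab <- function(name) {
        if (is.na(cs[name]) || cs[name] <= 0L || cl[name] == 0L) ""
        else substr(surface, cs[name], cs[name] + cl[name] - 1L)
      }
      return(list(
        premod = grab("premod"), prefix = grab("prefix"),
        core = grab("core"),
        iab = if ("iab" %in% names(cs)) grab("iab") else "",
        number = grab("num"), value = grab("value"),
        suf1 = grab("suf1"), suf2 = grab("suf2")
      ))
    }
  }
  NULL
}

#' Parse miRNA surface forms into nomenclature facets
#'
#' @param x Character vector of surface forms (each must match the grammar).
#' @return A tibble with one row per input: \code{surface}, \code{key} (the
#'   family-level canonical key), \code{species} (prefix or \code{NA}),
#'   \code{modifier} (\code{pre}/\code{pri} or \code{NA}), \code{arm}
#'   (\code{3p}/\code{5p} or \code{NA}), plus the raw \code{core},
#'   \code{number}, \code{value} and \code{paralog} components.
#' @export
#' @examples
#' parse_mirna_name(c("hsa-mir-21-5p", "MIR21", "pre-miR-21", "let-7a"))
parse_mirna_name <- function(x) {
  rows <- lapply(x, function(s) {
    p <- parse_mirna_components(s)
    if (is.null(p)) stop("not a miRNA name: ", s, call. = FALSE)
    family_core <- if (toupper(p$core) %in% c("MIRLET", "LET")) "let" else "mir"
    key <- paste0(family_core, "-", p$iab, p$number,
                  tolower(p$value), tolower(p$suf1))
    tibble::tibble(
      surface = s, key = key,
      species = if (nzchar(p$prefix)) p$prefix else NA_character_,
      modifier = if (nzchar(p$premod)) p$premod else NA_character_,
      arm = if (nzchar(p$suf2)) sub("^-", "", p$suf2) else NA_character_,
      core = p$core, number = p$number, value = p$value,
      paralog = if (nzchar(p$suf1)) sub("^-", "", p$suf1) else NA_character_
    )
  })
  do.call(rbind, rows)
}

#' Normalize a miRNA surface form to its family-level canonical key
#'
#' Variant spellings of one miRNA (\code{miR-21}, \code{MIR21},
#' \code{hsa-mir-21}, \code{hsa-mir-21-5p}, \code{pre-miR-21}) share one
#' canonical key: lowercase, core token rewritten to \code{mir} (or
#' \code{let} for let-family names), a single hyphen between core and number.
#' The species prefix, pre-/pri- modifier and arm suffix are recorded as
#' facets by \code{\link{parse_mirna_name}} but excluded from the key, so the
#' key identifies the miRNA family. Normalization is idempotent: a key
#' normalizes to itself.
#'
#' @param x Character vector of miRNA surface forms.
#' @return Character vector of canonical keys.
#' @export
#' @examples
#' normalize_mirna_name(c("MIR21", "miR-21", "hsa-mir-21-5p"))
normalize_mirna_name <- function(x) {
  parse_mirna_name(x)$key
}

# boundary positions within a token run at which a grammar match may start
# (run start or just after a hyphen) and end (run end or just before one)
run_substring_candidates <- function(run) {
  chars <- strsplit(run, "", fixed = TRUE)[[1L]]
  hyph <- which(chars == "-")
  starts <- sort(unique(c(1L, hyph + 1L)))
  ends <- sort(unique(c(length(chars), hyph - 1L)), decreasing = TRUE)
  list(starts = starts[starts <= length(chars)], ends = ends[ends >= 1L])
}

#' Find miRNA name mentions in a sentence
#'
#' Scans a sentence for token-bounded matches of the miRNA pattern set.
#' Matches are leftmost-longest and non-overlapping, and must not be embedded
#' inside a longer alphanumeric word; hyphens are permitted flanks, so
#' \code{anti-miR-21} yields the mention \code{miR-21}. A match whose
#' pre-/pri- modifier group fired is categorized \code{PRE_MIRNA} /
#' \code{PRI_MIRNA}; all others are \code{MICRORNA}.
#'
#' @param sentence A single sentence (character scalar).
#' @param patterns A \code{mirna_patterns} object.
#' @param doc_id,sentence_index Identifiers stamped onto the mentions.
#' @return A mention tibble (possibly empty) with columns \code{doc_id},
#'   \code{sentence_index}, \code{start}, \code{end} (0-based, half-open
#'   character offsets into the sentence), \code{surface}, \code{category},
#'   \code{canonical_key}, \code{provenance} (\code{"REGEX"}).
#' @export
#' @examples
#' find_mirna_mentions("An increase in miR-21 targets Smad7 in IPF.")
find_mirna_mentions <- function(sentence, patterns = compile_mirna_patterns(),
                                doc_id = "doc", sentence_index = 0L) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  if (!nzchar(sentence)) return(empty_mentions())
  runs <- stringi::stri_locate_all_regex(
    sentence, "[A-Za-z0-9][A-Za-z0-9-]*")[[1L]]
  if (all(is.na(runs[, 1L]))) return(empty_mentions())
  run_texts <- stringi::stri_sub(sentence, runs[, 1L], runs[, 2L])
  # every pattern in the set requires a digit after the core token
  candidates <- which(stringi::stri_detect_regex(run_texts, "[0-9]"))
  out <- list()
  for (r in candidates) {
    run_start <- runs[r, 1L]
    run_text <- run_texts[r]
    cand <- run_substring_candidates(run_text)
    pos <- 1L
    for (s in cand$starts) {
      if (s < pos) next
      hit <- NULL
      for (e in cand$ends) {
        if (e < s) break
        piece <- substr(run_text, s, e)
        if (mirna_matches(piece, patterns)) {
          hit <- c(s, e)
          break
        }
      }
      if (!is.null(hit)) {
        piece <- substr(run_text, hit[1L], hit[2L])
        comp <- parse_mirna_components(piece)
        category <- "MICRORNA"
        if (!is.null(comp) && comp$premod == "pre") category <- "PRE_MIRNA"
        if (!is.null(comp) && comp$premod == "pri") category <- "PRI_MIRNA"
        key <- if (is.null(comp)) tolower(piece) else parse_mirna_name(piece)$key
        abs_start <- run_start + hit[1L] - 2L  # 0-based
        out[[length(out) + 1L]] <- tibble::tibble(
          doc_id = doc_id, sentence_index = as.integer(sentence_index),
          start = as.integer(abs_start),
          end = as.integer(abs_start + nchar(piece)),
          surface = piece, category = category, canonical_key = key,
          provenance = "REGEX"
        )
        pos <- hit[2L] + 1L
      }
    }
  }
  if (!length(out)) return(empty_mentions())
  do.call(rbind, out)
}
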