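# Independent grammar-membership oracle for the miRNA nomenclature.
#
# Decides membership by brute-force state-set propagation over the grammar's
# components, one component at a time, never touching a regular expression —
# so it is an independent cross-check of the compiled pattern set.

grammar_species_prefixes <- function() {
  c("ath", "bmo", "bta", "cel", "cfa", "dme", "dre", "ebv", "gga", "hcmv",
    "hsa", "hsv1", "hsv2", "mml", "mmu", "ola", "ptr", "rno", "ssc", "tgu",
    "xla", "xtr")
}

# consume one literal alternative (options may include "" for an optional
# component); a state set is the set of possible remaining suffixes
consume_literals <- function(states, options) {
  unique(unlist(lapply(states, function(s) {
    keep <- options[startsWith(s, options) | options == ""]
    vapply(keep, function(o) substring(s, nchar(o) + 1L), character(1L))
  })))
}

# consume zero or one character from a class
consume_class1 <- function(states, class_regex, optional = TRUE) {
  unique(unlist(lapply(states, function(s) {
    res <- if (optional) s else character()
    if (nzchar(s) && grepl(class_regex, substr(s, 1L, 1L))) {
      res <- c(res, substring(s, 2L))
    }
    res
  })))
}

consume_digits_1_to_4 <- function(states) {
  unique(unlist(lapply(states, function(s) {
    res <- character()
    for (k in 1:4) {
      d <- substr(s, 1L, k)
      if (nchar(d) == k && grepl(sprintf("^[0-9]{%d}$", k), d)) {
        res <- c(res, substring(s, k + 1L))
      }
    }
    res
  })))
}

grammar_suf1_options <- function() c("", paste0("-", 1:99),
                                     paste0("-", 1:3, "HG"))

# membership in the core grammar:
# ((pre|pri)-)? prefix? core -? (iab-)? [0-9]{1,4} value? suf1? suf2?
in_core_grammar <- function(s) {
  states <- consume_literals(s, c("", "pre-", "pri-"))
  states <- consume_literals(states,
                             c("", paste0(grammar_species_prefixes(), "-")))
  states <- consume_literals(states,
                             c("mir", "miR", "MiR", "MIR", "MIRN", "MIRLET"))
  if (!length(states)) return(FALSE)
  states <- consume_literals(states, c("", "-"))
  states <- consume_literals(states, c("", "iab-"))
  states <- consume_digits_1_to_4(states)
  if (!length(states)) return(FALSE)
  # value = [A-Za-z]? [0-9A-Za-z]? [0-9]? (HG)?
  states <- consume_class1(states, "[A-Za-z]")
  states <- consume_class1(states, "[0-9A-Za-z]")
  states <- consume_class1(states, "[0-9]")
  states <- consume_literals(states, c("", "HG"))
  states <- consume_literals(states, grammar_suf1_options())
  states <- consume_literals(states, c("", "-3p", "-5p"))
  "" %in% states
}

# membership in the shipped let-family extension:
# ((pre|pri)-)? prefix? (let|Let|LET) -? [0-9]{1,4} [A-Za-z]? suf1? suf2?
in_let_grammar <- function(s) {
  states <- consume_literals(s, c("", "pre-", "pri-"))
  states <- consume_literals(states,
                             c("", paste0(grammar_species_prefixes(), "-")))
  states <- consume_literals(states, c("let", "Let", "LET"))
  if (!length(states)) return(FALSE)
  states <- consume_literals(states, c("", "-"))
  states <- consume_digits_1_to_4(states)
  if (!length(states)) return(FALSE)
  states <- consume_class1(states, "[A-Za-z]")
  states <- consume_literals(states, c("", paste0("-", 1:99)))
  states <- consume_literals(states, c("", "-3p", "-5p"))
  "" %in% states
}

in_grammar <- function(s) in_core_grammar(s) || in_let_grammar(s)

# sample a name by choosing grammar components directly
sample_grammar_name <- function() {
  premod <- sample(c("", "pre-", "pri-"), 1L, prob = c(0.8, 0.1, 0.1))
  prefix <- if (runif(1) < 0.4)
    paste0(sample(grammar_species_prefixes(), 1L), "-") else ""
  core <- sample(c("mir", "miR", "MiR", "MIR", "MIRN", "MIRLET"), 1L)
  hyph <- sample(c("", "-"), 1L)
  iab <- if (runif(1) < 0.05) "iab-" else ""
  num <- as.character(sample(c(1:9, 10:999, 1000:2999), 1L,
                             prob = c(rep(4, 9), rep(0.05, 990),
                                      rep(0.002, 2000))))
  value <- if (runif(1) < 0.4)
    sample(c(letters[1:6], "a1", "b2", "aHG", "HG"), 1L) else ""
  suf1 <- if (runif(1) < 0.25) sample(grammar_suf1_options()[-1L], 1L) else ""
  suf2 <- if (runif(1) < 0.25) sample(c("-3p", "-5p"), 1L) else ""
  paste0(premod, prefix, core, hyph, iab, num, value, suf1, suf2)
}

# random single-character perturbation; may or may not leave the grammar
perturb_name <- function(s) {
  n <- nchar(s)
  mode <- sample(3L, 1L)
  pos <- sample(n, 1L)
  alphabet <- c(letters, LETTERS, 0:9, "-", "p", "q", "_")
  if (mode == 1L) {  # substitute
    paste0(substr(s, 1L, pos - 1L), sample(alphabet, 1L),
           substring(s, pos + 1L))
  } else if (mode == 2L) {  # delete
    paste0(substr(s, 1L, pos - 1L), substring(s, pos + 1L))
  } else {  # insert
    paste0(substr(s, 1L, pos), sample(alphabet, 1L), substring(s, pos + 1L))
  }
}
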