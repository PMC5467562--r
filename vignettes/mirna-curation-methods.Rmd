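---
title: "Methods: assisted curation of miRNA-disease statements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assisted curation of miRNA-disease statements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircurate)
```

## The problem

Databases of miRNA-disease associations lag far behind the literature,
and respiratory diseases in particular are thinly covered. Manual
biocuration — reading full texts and transcribing every statement that links
a miRNA to an expression change, a target gene, a sample type or a
disease — is the bottleneck. `mircurate` implements the automatic half of a
semiautomatic workflow: it annotates entity mentions in article sentences,
lets the curator cut the corpus down to the small fraction of sentences that
can contain curatable facts, and materializes those sentences as structured
snippet records for human confirmation. The human judgment is out of scope
by design; the package's job is to make sure the curator reads tens of
sentences instead of thousands.

## miRNA name recognition

miRNA nomenclature is regular enough to capture with a grammar:

```
((pre|pri)-)? prefix? core -? (iab-)? [0-9]{1,4} value? paralog? arm?
```

where `prefix` is a closed set of species codes (`hsa-`, `mmu-`, `rno-`,
...), `core` is one of `mir | miR | MiR | MIR | MIRN | MIRLET`, `value` is a
short alphanumeric tail (`[A-Za-z]?[0-9A-Za-z]?[0-9]?(HG)?`, covering family
letters like `-200a` and host-gene `HG` markers), `paralog` is
`-[1-9][0-9]?` or `-[123]HG`, and `arm` is `-3p | -5p`. Requiring a core
token *followed by at least one digit* is what keeps the pattern silent on
ordinary English: `admire`, `mirage` and bare `mir` never match.

Names that use the bare `let` core (the let-7 family) fall outside this
core pattern; they are handled by an extension slot, a file of additional
anchored patterns shipped in `extdata/mirna_extension_patterns.txt` and
extendable by the user. The shipped set is a deliberately small, curated
starter list; production dictionaries use larger specialized collections,
and ours is documented as an approximation of that tier.

Scanning is token-bounded: a match may not be flanked by alphanumerics, but
hyphens are legal flanks, so `anti-miR-21` yields the mention `miR-21` while
`XmiR-21x` yields nothing. Within a sentence matches are leftmost-longest
and non-overlapping; candidate spans inside a hyphenated token are tried
from each post-hyphen boundary, longest end first, which is what makes
`hsa-mir-21-5p` come out whole instead of as `hsa-mir-21-5`.

Normalization maps every variant spelling of a name to a family-level
canonical key: lowercase, core rewritten to `mir` (or `let`), one hyphen
before the number. The species prefix, `pre-`/`pri-` modifier and arm
suffix are parsed as facets (`parse_mirna_name()`) but excluded from the
key, so `miR-21`, `MIR21`, `hsa-mir-21` and `hsa-mir-21-5p` share the key
`mir-21`. This granularity is a design choice: the variant
examples all concern one miRNA family, and family-level keys are what a
distinct-miRNA summary should count. Arm-level counting remains possible
through the facets.

The test suite checks the recognizer two independent ways: a brute-force
grammar-membership oracle (state-set propagation over the components, no
regular expressions) must agree with the compiled pattern on ten thousand
generated strings and single-character perturbations of them; and generated
non-biomedical English — built from a vocabulary containing no digits, so by
construction no grammar match can occur — must produce zero mentions.
Passing the second check shows the pattern does not fire on digit-free
English; it cannot show what happens on adversarial technical text with
dense alphanumerics, which is the honest limit of the protocol it mirrors.

## The annotation dictionary

Everything that is not a miRNA name is matched from a categorized term
dictionary: genes, transcription factors (kept separate so regulatory
targets can be distinguished from structural ones), organisms, diseases,
regulatory-effect vocabulary and sample descriptors. Term lists are plain
text, one surface per line with an optional tab-separated identifier.

Variant generation is bounded on purpose: core-token case permutations,
one hyphen inserted or removed between core and number, and `pre-`/`pri-`
prefixed forms that are emitted under the precursor categories. This covers
the variation the nomenclature actually produces (`miR-21` vs `MIR21` vs
`hsa-mir-21`) while keeping the dictionary linear in its input; full
combinatorial case variation would explode the lexicon for no recall gain.

Two policies are configurable because the underlying convention is genuinely
unsettled:

* **Case.** miRNA, organism, disease, effect and sample matching is
  case-insensitive; gene and transcription-factor matching is
  case-sensitive by default (`build_lexicon(case_sensitive_genes = )`).
  Short uppercase gene symbols collide with English words too easily
  (`MIR21` the gene symbol vs `mir` the Persian title), and the cost of the
  strict default is mitigated by listing common mixed-case spellings
  (`Smad7`) in the term list, as the bundled mini-lexicon does.
* **Ambiguity.** A surface listed under two categories is kept in both and
  annotated in both; overlap resolution applies only *within* a category
  (longest span wins; on identical spans the dictionary mention beats the
  regex mention because it carries a database identifier). Cross-category
  disambiguation is deliberately not attempted — a ZEB1 mention really is
  both a gene and a transcription factor.

## Corpus units

Articles are consumed as cleaned plain text (or PMC-style XML reduced to
body text). Cleaning strips control characters, collapses whitespace and
rejoins words hyphenated across line breaks *keeping the hyphen*: miRNA
names carry meaningful hyphens, and restoring `miR-\n21` to `miR-21` matters
more than the occasional ordinary word that ends up with a spurious hyphen.
That trade-off is logged per document.

Sentence segmentation is rule-based — terminator punctuation followed by
whitespace and a plausible sentence opener, with a fixed abbreviation list
(`et al.`, `Fig.`, `e.g.`, `i.e.`, `vs.`, ...) and single-initial
protection — rather than statistical, so that offsets are deterministic and
auditable. One consequence of supporting miRNA-initial sentences (which
begin lowercase, `miR-185 is ...`) is that the splitter accepts lowercase
sentence openers; the abbreviation list is what keeps that from
over-splitting. Tokenization keeps internal hyphens inside
alphanumeric-hyphen runs so `hsa-mir-21-5p` survives as one token; both the
dictionary scan and the n-gram miner depend on that.

All offsets in the package are 0-based and half-open, and every table that
leaves the package (sentences, mentions, snippets) carries offsets under
that contract; slicing the source at the offsets always reproduces the
surface, and the tests enforce this everywhere.

## Candidate-term mining

The vocabulary-building pipeline is frequency mining, in a fixed order:
tokenize, lowercase, remove stopwords, remove tokens outside a length band,
then n-grams for n = 1..5 over the surviving consecutive tokens. Choices
the method itself leaves open:

* the length band defaults to 2–40 characters (dropping single-character
  noise and extraction artifacts) and is configurable;
* the stopword list is a compact common-English list shipped as an editable
  file; any list can be substituted;
* n-grams do not cross sentence boundaries — windows spanning a sentence
  break are not meaningful term candidates.

Ranking is corpus frequency, then document frequency, then lexicographic,
and the per-n counts conserve exactly the number of n-windows in the
filtered token stream (a tested invariant). The output table is an input to
expert review, not an end product.

## Filters and conceptual structures

Curators narrow the corpus with Boolean expressions over categories:
`MICRORNA AND EFFECT='induced or repressed' AND DISEASE='IPF'`. The grammar
supports value constraints (quoted, `or`-separated), `AND`/`OR` with `AND`
binding tighter, and parentheses; parsing flattens associative nests so
render/parse round-trips are canonical. A `MICRORNA` leaf selects all
miRNA-annotated material including `pre-`/`pri-` forms, matching how a
curator uses the concept; the precursor categories can still be named
explicitly. `EFFECT` value constraints expand through polarity synonym
groups (asking for `induced` also admits `increase`, `upregulated`, ...),
shipped as an editable mapping; no-change wording (`constant`, `unchanged`)
forms a directionless group of its own, an interpretation noted as such.

Retention statistics report `100 * retained / total`, rounded half-up to
two decimals.

Beyond flat filters, three conceptual structures describe curatable
sentences as typed co-occurrence patterns:

| id | pattern |
|----|---------|
| S1 | MicroRNA (Effect)? (AND Disease)? |
| S2 | MicroRNA (Effect)? AND TargetGene (AND Disease)? |
| S3 | MicroRNA (Effect)? AND TargetGene (AND Sample)? (AND Disease)? |

Binding is deliberately *not* parsing: a slot binds any mention of its
categories in the sentence, optional slots bind when candidates exist, and
multiple candidates enumerate combinations up to a cap (default 50 per
sentence, ties resolved by mention order, which is document order). This
realizes the structures exactly as the worked examples use them and keeps
the matcher transparent; the price is that a sentence with two miRNAs and
one gene yields two matches whether or not the syntax supports both
readings. Negation, coordination ellipsis (`miR-200a, -b, and -c`) and
anaphora are out of scope, and the ellipsis non-expansion is a documented
recognizer decision.

## Curation snippets

A snippet is one structure match in one sentence — the finest unit a curator
can confirm or reject independently. Ids are deterministic in
(document, sentence, bound offsets). Status moves only `AUTO → CONFIRMED`
or `AUTO → REJECTED`; counts are conserved under status changes, and
summaries count family-level distinct miRNAs by default.

Because the three structures nest (dropping optional slots reduces S3 to S2
to S1), an end-to-end pipeline needs a rule for which structure a sentence
reports. `curate_corpus()` picks the most specific structure the mention
set supports: target gene and sample present → S3; target gene → S2;
otherwise S1. Any other deterministic rule would work; this one maximizes
the information captured per snippet.

## The synthetic gold corpus

`generate_corpus()` builds documents from sentence templates that
instantiate the three structures plus filler English, recording every
seeded mention and snippet with exact offsets — template construction, not
language-model text, precisely so the gold standard is correct by
construction. Defaults: 5 documents of 40 sentences; structure rates
`s1 = 0.05`, `s2 = 0.04`, `s3 = 0.03` (so roughly one sentence in eight
carries a miRNA statement, mirroring the order of magnitude seen when
filtering real full-text corpora for miRNA content); miRNA names sampled
from the grammar's own components and rendered in randomized variant
spellings (species prefix 0.3, arm suffix 0.25, pre-/pri- 0.1, hyphen
dropped 0.25) while gold records the family key. The filler vocabulary is
screened against the mini-lexicon and contains no digits, so filler can
produce neither dictionary nor regex mentions and gold precision/recall are
well-defined.

What the generator does *not* emulate — and therefore what passing tests do
not show about real articles: PDF-extraction noise beyond optional line-break
hyphenation, tables and figure captions, coordination ellipsis, anaphora,
sentences mentioning multiple competing facts, and vocabulary outside the
mini-lexicon. A perfect score on the gold corpus validates the machinery
(offsets, matching, counting), not real-world recall, which depends on the
user's dictionaries. Corpus-scale reference figures from real curation projects (tens of thousands of
sentences, hundreds of curated miRNAs) depend on external full texts and
database releases and are intentionally not reproduced here; the test suite
instead verifies the corpus-independent arithmetic (e.g. the retention
percentage formula) and scaled-down analogs of the recognizer validation
(recall over a reference set of example names; precision over 100,000 generated
non-biomedical words).

## Numerical and degenerate-input choices

* Percentages: half-up rounding to 2 decimals (`floor(x * 100 + 0.5) / 100`
  on the percentage scale).
* Empty documents warn and produce empty sentence tables; empty filter
  results report 0.00%.
* Duplicate term-list lines deduplicate with a warning; malformed lines
  (more than one tab) are skipped with a warning; a fully unusable term-list
  set is a fatal error.
* Combination caps truncate deterministically (document order) rather than
  sampling.
* Problem sizes in the test suite are chosen to exercise each property at
  desk scale: 10,000-string grammar-oracle comparisons, a 100,000-word
  precision corpus, 100 random corpora for the filter-algebra suite,
  gold corpora of 3-5 documents elsewhere.

## Limitations

Sentence-level co-occurrence cannot tell *which* miRNA regulates which gene
in a multi-entity sentence, cannot see negation, and cannot recover
relations split across sentences. Dictionary recall is bounded by the term
lists supplied; the bundled mini-lexicon exists for examples and testing,
not production curation. The extension-pattern starter set covers the
let-family but not every specialized name form in circulation. These are
the points where the human curator — who this package assists rather than
replaces — remains essential.
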