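# mircurate

Assisted biocuration of miRNA–disease statements from the scientific
literature.

Databases linking microRNAs to diseases are chronically behind the
literature: every statement of the form *"miR-21 is upregulated in
idiopathic pulmonary fibrosis and targets SMAD7 in lung fibroblasts"* has
to be found, read and transcribed by a human curator. `mircurate`
implements the automatic half of a semiautomatic curation workflow for
exactly this kind of statement. It is aimed at biocurators and text-mining
practitioners who want a transparent, auditable pipeline rather than a
black-box extractor: every stage is rule-based, offset-faithful and
individually testable.

## What it does

1. **miRNA name recognition.** Names are matched with a nomenclature
   grammar compiled to regular expressions:

   ```
   ((pre|pri)-)? prefix? core -? (iab-)? [0-9]{1,4} value? paralog? arm?
   ```

   with `core ∈ {mir, miR, MiR, MIR, MIRN, MIRLET}`, a closed species-prefix
   set (`hsa-`, `mmu-`, ...), optional family letter / host-gene tail,
   paralog suffix (`-1`, `-2`) and arm suffix (`-3p`/`-5p`). A core token
   followed by at least one digit is mandatory, which keeps the pattern
   from firing on plain English; let-7-family forms come from an editable
   extension-pattern file. Variant spellings normalize to one family key:
   `miR-21`, `MIR21`, `hsa-mir-21-5p` → `mir-21`.
2. **Dictionary annotation.** All other entities (genes, transcription
   factors, organisms, diseases, regulatory-effect words, sample
   descriptors) are tagged by longest-match against a categorized term
   dictionary with automatic surface-variant generation and curator
   additions (`build_lexicon()`, `add_term()`).
3. **Candidate-term mining.** An n-gram pipeline (tokenize → lowercase →
   stopwords → length filter → n = 1..5) ranks corpus vocabulary for expert
   review when building effect/sample term lists.
4. **Sentence filtering.** Boolean category filters
   (`MICRORNA AND EFFECT='induced or repressed' AND DISEASE='IPF'`) and
   three typed co-occurrence structures — MicroRNA (+Effect) (+TargetGene)
   (+Sample) (+Disease) — reduce a corpus to its curatable sentences, with
   retention statistics.
5. **Curation snippets.** Structure matches become structured records
   (miRNA key, effect + polarity, target gene, sample, disease, status)
   with TSV/JSON export, import and summaries.
6. **Synthetic gold corpora.** `generate_corpus()` builds articles with
   seeded, offset-exact annotations so the whole pipeline is testable with
   known ground truth; `generate_nonbio_text()` builds miRNA-free English
   for false-positive testing.

## Worked example

```r
library(mircurate)

lex <- mini_lexicon()  # bundled demo dictionary; real projects load their own
doc <- as_document(paste(
  "miR-185 is increased in IPF.",
  "An increase in miR-21 targets Smad7 in IPF.",
  "The weather was pleasant and the garden quiet."), doc_id = "example")

sentences <- split_sentences(doc)
mentions  <- annotate_corpus(sentences, lex)
mentions
#> # A tibble: 7 × 8
#>   doc_id  sentence_index start   end surface   category canonical_key provenance
#>   <chr>            <int> <int> <int> <chr>     <chr>    <chr>         <chr>
#> 1 example              0     0     7 miR-185   MICRORNA mir-185       REGEX
#> 2 example              0    11    20 increased EFFECT   increased     DICTIONARY
#> 3 example              0    24    27 IPF       DISEASE  ipf           DICTIONARY
#> 4 example              1     3    11 increase  EFFECT   increase      DICTIONARY
#> 5 example              1    15    21 miR-21    MICRORNA mir-21        REGEX
#> 6 example              1    30    35 Smad7     GENE     SMAD7         DICTIONARY
#> 7 example              1    39    42 IPF       DISEASE  ipf           DICTIONARY
```

Each row is one entity mention: 0-based half-open offsets into the
sentence, the matched surface, its category, a canonical key (family key
for miRNAs, database identifier for dictionary terms) and whether the
recognizer was the grammar (`REGEX`) or the dictionary. Filtering and
curation then run over these tables:

```r
apply_filter(sentences, mentions, "MICRORNA AND DISEASE='IPF'")$stats
#> 2 of 3 sentences retained (66.67%)

snippets <- curate_corpus(sentences, mentions)
snippets[, c("mirna_key", "effect", "effect_polarity", "target_gene",
             "disease", "structure_id")]
#>   mirna_key    effect effect_polarity target_gene disease structure_id
#> 1   mir-185 increased        positive        <NA>     IPF           S1
#> 2    mir-21  increase        positive       SMAD7     IPF           S2

summarize_snippets(snippets)
#> <snippet_summary> 2 snippets across 2 distinct miRNAs
#>   effect polarity: positive=2
```

The filler sentence is annotated with nothing, retained by nothing and
curated into nothing — which is the point: the curator confirms or rejects
two structured records instead of reading three sentences (or, at corpus
scale, thousands).

A thin CLI over the same functions ships in `inst/scripts/mircurate`
(`annotate`, `filter`, `curate`, `terms`, `simulate`).

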