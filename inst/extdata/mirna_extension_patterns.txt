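# Specialized miRNA name forms not covered by the core nomenclature grammar.
# One regular expression per line; each is compiled anchored (^...$) and
# scanned token-bounded. This starter set covers the let-7 family written
# with the bare "let" core (let-7, let-7a, hsa-let-7a-5p, LET7, ...); it is
# a curated approximation of the larger specialized-pattern collections
# used in production dictionaries and can be extended freely.
(?:(?:pre|pri)-)?(?:(?:ath|bmo|bta|cel|cfa|dme|dre|ebv|gga|hcmv|hsa|hsv1|hsv2|mml|mmu|ola|ptr|rno|ssc|tgu|xla|xtr)-)?(?:let|Let|LET)-?[0-9]{1,4}[A-Za-z]?(?:-[1-9][0-9]?)?(?:-3p|-5p)?
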