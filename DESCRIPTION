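Package: exocascade
Title: Multistep Variant Prioritization for Exome Cohorts Under a Dominant Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a multistep whole-exome variant-prioritization cascade
    for cohorts of unrelated patients analysed under an autosomal-dominant
    hypothesis: reliable-heterozygote screening by allele balance and depth,
    rarity and functional-class filtering, multi-predictor pathogenicity
    consensus, a joint CADD/REVEL gate, and keyword-gene-set functional
    selection, with per-stage accounting, cohort summaries, a synthetic
    annotated-VCF cohort simulator with ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
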