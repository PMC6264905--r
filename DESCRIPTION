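Package: hubevolve
Title: Analysis of Hub-Gene Replacement Experimental Evolution in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the computational backbone of a yeast
    experimental-evolution study in which an essential network hub (Hsp90)
    is replaced by a distant ortholog: maximal growth rates from plate-reader
    OD time series via sliding-window regression, fitness improvements and
    their group comparisons, two-color competition fixation calls and serial
    transfer generation accounting, normalization, clustering, PCA and
    Pearson correlation-distance divergence statistics for strain-by-condition
    fitness matrices, pooled-segregant (bulk segregant) mapping with a
    Monte-Carlo binomial-mixture null and strong-effect mutation criteria,
    evolved-mutation filtering, gene copy-number calls and mutation-rate
    estimation, hypergeometric GO-category enrichment, and a synthetic-data
    module that generates every input the pipeline consumes so all stages run
    end-to-end with no external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    vcfR
Config/testthat/edition: 3
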