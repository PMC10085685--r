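Package: ftlmap
Title: Crossover Frequency Estimation from Fluorescent-Tagged-Line Seed Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring meiotic crossover frequency with fluorescent
    tagged lines (FTLs) carrying two dominant, cis-linked seed-expressed
    fluorescent markers. Classifies seeds into four fluorescence classes from
    two-channel intensity tables, estimates genetic distance (cM) with the
    design-specific F2 and backcross formulas together with delta-method
    uncertainty, compares genotypes by chi-square or Fisher's exact test on the
    proportion of recombinant seeds, and summarises meiotic cytology (bivalent
    counts, chromosome fragmentation) and fertility (seeds per fruit) with the
    matching tests. A meiotic segregation and measurement simulator generates
    every input the pipeline consumes, so all stages can be exercised and
    calibrated without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
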