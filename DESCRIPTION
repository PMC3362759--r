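Package: episplice
Title: Epigenomic Signal Association with Alternative Splicing Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates alternative-splicing events (exon skipping, mutually
    exclusive exons, alternative 3'/5' splice sites, intron retention) and
    constitutive internal exons from transcript models, aggregates epigenomic
    signal (CpG density, CpG methylation, ChIP-seq style read tracks) in
    100-bp exonic/intronic bins around acceptor and donor splice sites,
    tests per-feature level differences between alternatively and
    constitutively spliced exons with one-tailed Welch t-tests under
    Bonferroni correction, optionally corrects for ChIP input and nucleosome
    occupancy, builds a direction-signed log p-value association matrix, and
    clusters epigenetic features and splicing-event types by k-means. A
    synthetic-data module generates toy genomes, gene models with planted
    events, methylomes and read tracks with known effect sizes for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
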