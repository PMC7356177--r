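Package: lncnet
Title: Prioritizing Long Non-Coding RNAs by Differential Expression and
    Network Module Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative transcriptomics pipeline that goes from a
    normalized log2 expression matrix to a short list of candidate regulatory
    long non-coding RNAs (lncRNAs). Differentially expressed features are
    called with Welch's t-test and Benjamini-Hochberg correction, a
    protein-protein interaction network is induced on the coding DEGs, dense
    gene modules are detected with an MCODE-style seeded clustering
    (neighborhood k-core vertex weighting, cutoff-bounded expansion, haircut
    and core filtering), gene lists are tested for over-representation with
    the hypergeometric distribution, and modulated lncRNAs are prioritized by
    resolving lncRNA-miRNA-gene regulatory chains against the DEG set and
    requiring coverage of every detected module. A seeded synthetic-data
    generator with planted ground truth makes every stage testable by
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
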