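Package: lenqc
Title: Length-Based Quality Control of Chloroplast Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the distributions of complete chloroplast (plastome)
    genome lengths within plant families and genera using Tukey boxplot
    descriptors, flags taxa whose distributions are anomalously wide by the
    IQR/median ratio, detects per-genus outlier sequences, and checks whether
    alternative GenBank records of the same species lie closer to the genus
    median than the flagged RefSeq record -- a metadata-only heuristic for
    spotting suspect assemblies. Includes a synthetic fixture generator with
    ground-truth labels, a multi-worksheet report writer, diagnostic figures,
    and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
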