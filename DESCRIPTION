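Package: redigest
Title: In Silico Restriction Digestion and Genome Coverage for
    Genotyping-by-Sequencing Enzyme Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates restriction digestion of sequenced genomes with single
    enzymes or enzyme pairs, using IUPAC-degenerate recognition sites and
    top-strand cut offsets. Computes fragment metrics and the in-silico genome
    coverage (IgC) statistic under GBS-style size selection (100-600 bp by
    default) and the different-ends rule for double digests, windowed
    fragment-density profiles along chromosomes, and batch rankings of enzymes
    and enzyme pairs across genomes against a reference pair. Includes a
    seeded synthetic-genome generator with planted recognition sites and
    assembly-gap runs so every pipeline stage can be tested without genome
    downloads, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
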