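Package: pcpascreen
Title: Screening Promoter-Proximal Intronic Polyadenylation and Cryptic 3' Splice Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for finding genes prone to premature cleavage
    and polyadenylation (PCPA) in promoter-proximal introns. Scans intronic
    sequence for poly(A) signal hexamers, applies transcript-relative positional
    filters (distance from the transcription start site, intron ordinal and
    length, distance from the 5' splice site), scores candidate branch-site
    7-mers and 3'-splice-site 14-mers with Shapiro-Senapathy consensus values,
    and ranks cryptic acceptors upstream of each passing signal. Downstream
    tools build the isoform models the screen predicts (mRNA, PCPA, cryptically
    spliced PCPA, read-through), construct minigene/reporter variants with
    targeted splice-site and poly(A)-signal mutations, and simulate 3' RACE
    with nested PCR to predict which amplicons discriminate the isoforms.
    A seeded synthetic-genome generator with a ground-truth manifest makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
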