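Package: corekit
Title: Core Collection Construction from SSR Genotypes and Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing genetic diversity of germplasm panels typed
    at codominant microsatellite (SSR) loci and for constructing nested core
    collections by least-distance stepwise sampling (LDSS) guided by
    metabolite content. Provides readers for GenAlEx-style and simple
    tab-separated genotype tables, per-locus diversity statistics (Na, Ne,
    Ho, He, Shannon's I, Nei's gene diversity, PIC) and allele retention
    rates, genetic-structure analyses (simple-matching and band-based
    distances, UPGMA clustering, principal coordinates analysis, AMOVA with
    Phi-statistics and permutation tests), MISA-style microsatellite mining
    of transcript sequences, quality evaluation of candidate core
    collections against the full panel, and a Balding-Nichols simulator of
    multi-population SSR germplasm with population-structured metabolite
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
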