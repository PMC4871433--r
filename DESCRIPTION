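Package: chipscan
Title: Windowed ChIP-Seq Enrichment Scoring, Peak Annotation, Motif
    Discovery and qPCR Quantification
Version: 0.1.0
Authors@R: person("chipscan", "developers", email = "chipscan@example.org",
    role = c("aut", "cre"))
Description: A small, deterministic pipeline for transcription-factor
    binding-site discovery from chromatin immunoprecipitation sequencing
    (ChIP-seq) with a pre-immune serum control. Reads are counted in
    overlapping fixed-width windows, depth-normalized with pseudocounts,
    and scored as IP/control ratios; enriched windows are merged into
    peaks, ranked, and annotated with the nearest catalog feature within
    100 kb using a five-class location scheme and long noncoding RNA
    proximity tiers. Includes greedy information-content consensus motif
    discovery over top peak sequences, delta-delta-Ct and percent-input
    qPCR arithmetic, and a seeded synthetic-data generator with truth
    tables for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
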