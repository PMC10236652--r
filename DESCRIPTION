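Package: tandemdup
Title: Tandem Gene Duplication Detection and Gene Family Amplification
    Analysis for Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects tandemly duplicated genes (TDG) in annotated genome
    assemblies from all-vs-all protein similarity and gene order, groups
    them by single-linkage clustering, and validates pairs and whole
    clusters with spanning long reads. Includes the tandem-array-aware
    annotation refinements (recursive splitting of chimeric spliced
    alignments across long introns, mapping-noise and gene-candidate
    filters), Nei-Gojobori (1986) synonymous substitution rate estimation
    with Jukes-Cantor correction for duplicate-pair ageing, exon/intron
    structure comparison, orthogroup consensus construction with outlier
    removal and unspecific-region masking, read-depth gene copy-number
    estimation normalised on single-copy orthogroups, a binomial
    gene-family amplification screen with Benjamini-Hochberg FDR control,
    synteny block chaining between annotated genomes, and interstitial
    telomeric sequence (ITS) detection. A synthetic-data generator plants
    tandem arrays, reads, orthogroup count matrices and telomeric repeat
    arrays with full ground truth so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
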