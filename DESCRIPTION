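Package: ESTsplice
Title: EST-Based Discovery and Classification of Alternative Splicing Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genome-wide discovery of alternative splicing
    from expressed sequence tag (EST) evidence. ESTs are spliced-aligned to a
    genome (or ingested from BLAT PSL files), filtered for best hit, percent
    identity and canonical GT/AG splice sites, clustered by genomic overlap
    into loci, and assembled into per-locus splice graphs of exonic segments
    and EST-supported introns. Graphs are pattern-matched into classified
    alternative splicing events (intron retention, exon skipping, alternative
    5' and 3' splice sites, mutually exclusive exons, complex), quality
    filtered by a support-ratio rule, and localized relative to the longest
    open reading frame (coding region, 5' UTR, 3' UTR). Includes a synthetic
    genome/EST simulator with planted events of known coordinates for
    validation, and a splice-variant toolkit: merged intron lengths, protein
    length changes, premature stop detection, in-silico RT-PCR amplicon
    prediction, and relative expression by the 2^-ddCt method.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
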