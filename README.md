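# ESTsplice

Genome-wide discovery and classification of alternative splicing from EST
evidence, with a splice-variant verification toolkit.

## The problem

Expressed sequence tags (ESTs) — single-pass, partial cDNA reads — remain
the canonical evidence for annotating alternative splicing in organisms
without deep RNA-seq, such as the multicellular green alga *Volvox carteri*
(~14,500 protein-coding genes, mean intron length ~491 bp, genomic GC
~56%). Turning a pile of ESTs into a catalogue of splicing events takes a
chain of well-defined steps, each with filters that decide what counts as
evidence:

1. **Spliced alignment** of each EST to the genome; only the best alignment
   per EST is used (avoiding double counting of paralogs), alignments under
   95% identity are removed, and every inferred intron must carry the
   canonical splice dinucleotides (GT at the 5' end, AG at the 3' end, read
   on the transcribed strand).
2. **Clustering** of surviving alignments by genomic overlap into loci, and
   construction of a per-locus **splice graph**: nodes are exonic segments,
   edges are EST-supported introns, and observed intron chains define
   isoforms (alternative transcription starts/ends are not events).
3. **Event classification** by pattern matching: intron retention (IR),
   exon skipping (ES, including multi-exon skips as one event),
   alternative 5'/3' splice sites (labels are transcript-orientation
   aware), mutually exclusive exons, and complex events; followed by a
   quality filter keeping only events whose two alternatives have EST
   support within 10x of each other.
4. **Localization** of each event relative to the longest ATG-initiated
   open reading frame of the locus's reference isoform: coding region,
   5' UTR or 3' UTR.
5. **Reporting** of type and region distributions, exons per locus, and
   the fraction of genes with alternative splicing.

ESTsplice implements this pipeline end to end, plus a synthetic-data module
that generates genomes with planted events of known type and coordinates —
so every stage is testable offline, without the original 132,038-EST
dataset — and per-gene verification arithmetic: merged intron lengths,
protein-length deltas, premature-stop detection, in-silico RT-PCR amplicon
prediction, and relative expression by the 2^-ddCt method
(ddCt = [Ct_target − Ct_reference]_sample − [Ct_target − Ct_reference]_calibrator).

## Worked example

```r
library(ESTsplice)

cfg   <- sim_config(seed = 11, n_genes = 3, est_count_per_gene = 8,
                    est_error_rate = 0, est_partial_fraction = 0)
sim   <- simulate_genome(cfg)        # genome + gene models + planted events
reads <- simulate_ests(sim)          # reads with per-EST ground truth
res   <- run_as_pipeline(sim$genome, reads$ests, verbose = FALSE)

sim$truth[, 1:6]
#>   gene_id event_type chrom start  end strand
#> 1   g0001       Alt3  chr1   935  977      -
#> 2   g0003         IR  chr1  7127 7600      +

res$report
#> 2 events at 2 of 3 loci (66.7% of genes); 12 exons, 4.0 exons/locus
#> Event types:
#>               type count percent
#> 1 intron_retention     1      50
#> 2    exon_skipping     0       0
#> 3             alt5     0       0
#> 4             alt3     1      50
#> 5            other     0       0
#> Localization (over 2 localized of 2 events):
#>        region count percent
#> coding coding     2     100
#> utr5     utr5     0       0
#> utr3     utr3     0       0
```

Both planted events are recovered with their exact coordinates: the 473 bp
retained intron is called as intron retention, and the 42 bp acceptor-side
shift on the minus strand as an alternative 3' event. Localizations say
both fall inside the reference isoform's longest open reading frame.

The variant toolkit reproduces per-gene arithmetic directly. Skipping a
56 bp exon flanked by introns of 7,996 and 8,313 bp splices out one merged
intron of

```r
merged_intron_length(7996, 56, integer(0), 8313)
#> [1] 16365
```

and an in-frame loss of a 135 bp exon shortens a 284-residue protein to

```r
protein_length_change(284, 135)$new_length
#> [1] 239
```

Relative expression of a splice variant against a reference gene within one
sample (no calibrator) uses 2^-dCt:

```r
t <- ct_measurement("s", "v1",    c(24.1, 24.3, 24.2))
r <- ct_measurement("s", "actin", c(20.0, 20.1, 19.9))
delta_delta_ct(t, r)
#> 2^-dCt vs reference: fold change 0.05441 (dCt 4.200)
```

A thin command-line front-end over the same functions lives at
`inst/cli/altsplice.R` (subcommands `simulate`, `run`, `ddct`).

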