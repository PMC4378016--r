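---
title: "EST-based alternative splicing discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EST-based alternative splicing discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ESTsplice)
```

ESTsplice turns spliced EST-to-genome alignments into a classified
catalogue of alternative splicing events. This vignette documents the
models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data validation does and does not
demonstrate.

## Pipeline model and assumptions

The pipeline assumes that (i) mature transcripts are contiguous substrings
of spliced isoforms, so an EST maps to the genome as a chain of blocks
separated by intron-sized gaps; (ii) real introns carry GT at their 5' end
and AG at their 3' end on the transcribed strand (the 1–2% of genuinely
non-canonical introns are deliberately sacrificed, as the canonical filter
is what keeps alignment artefacts out of the event catalogue); and (iii)
EST coverage is deep enough that both alternatives of a true event are
observed — the support-ratio filter makes this explicit.

Coordinates are 0-based half-open everywhere inside the package and are
converted only at I/O boundaries: PSL is already 0-based half-open, GFF3 is
1-based inclusive.

## The spliced aligner

`spliced_align()` is a minimal seed-and-extend aligner built for
substitution-only reads; it is exact on the simulator's output and is not a
general-purpose replacement for BLAT or minimap2 on real data with indels.

* **Seeding.** Exact k-mers (`k = 16`, one seed every `stride = 4` bases,
  both read orientations) matched with `Biostrings::matchPDict`. With 1%
  substitution errors the mean error-free stretch is ~100 bp, so a 16-mer
  grid at stride 4 retains seeds in essentially every exon fragment longer
  than ~20 bp; terminal exon fragments shorter than that may go unseeded,
  costing a junction on that read but not the locus.
* **Chaining.** Seeds merge on common diagonals into gapless candidate
  blocks; dynamic programming selects the chain with maximal seeded length
  under the constraints that query positions increase and diagonal jumps
  lie in `[min_intron, max_intron]` (defaults 40 bp and 25 kb).
* **Junction refinement.** The true splice point lies in the unseeded
  window between chained blocks. Every candidate split is scored by its
  match count plus a bonus of 3 for canonical dinucleotides (GT..AG
  forward, CT..AC reverse) at the implied intron boundaries; ties prefer
  the canonical, then the 5'-most split. The bonus outweighs one
  substitution adjacent to the junction but never two, so splice sites are
  snapped to GT/AG without overriding strong sequence evidence.
* **Scoring and identity.** Score is `matches − 2 × mismatches`; percent
  identity is computed over aligned read bases with intron gaps excluded,
  matching PSL matches/misMatches semantics. Genomic gaps shorter than
  `min_intron` invalidate an alignment rather than being scored as
  deletions, because the aligner cannot distinguish a small deletion from
  a misplaced block.

`select_best_alignment()` keeps one alignment per EST (ties broken by
chromosome then start, so results are invariant to input order), and
`call_introns()` infers the transcription strand from splice-site
dinucleotides, overriding the sequencing orientation — single-pass cDNA
reads come from either end.

## Splice graphs and isoforms

Loci are single-linkage clusters of alignments by genomic overlap.
Segments are the union of aligned blocks split at every observed
donor/acceptor position; each distinct canonical intron is one edge whose
support is the number of member ESTs containing exactly that junction.

Isoforms are the *observed* intron chains, never exhaustive graph paths: a
graph with n independent bubbles admits 2^n paths, almost all of which no
EST ever witnessed. Chains that are consecutive sub-runs of a longer
observed chain merge into it when none of their reads exonically covers an
intron of the longer chain — without this, every truncated read would
found a spurious isoform. A read compatible with several maximal chains is
assigned to the one with the most exact-chain support (ties by genomic
order); this mis-allocates some fragment support between similar isoforms
but never invents a chain. Clusters whose spliced reads imply both
transcription strands are flagged and excluded from event calling;
unspliced reads inherit the cluster strand since they carry no strand
signal of their own.

## Event classification

Detectors run in the precedence order mutually-exclusive > exon skipping >
intron retention > alternative 5'/3' > complex, so each discordance yields
exactly one typed event:

* **IR** — an intron edge plus at least one read covering the complete
  intron *and at least one base of both flanking exons* exonically; the
  flank requirement guards against genomic-DNA-like fragments that merely
  start or end inside the intron.
* **ES** — an intron edge (D, A) coexisting with an observed chain of two
  or more introns whose outer boundaries are exactly D and A; all exons
  between are skipped in one event, matching how a six-exon skip is
  narrated as a single splice choice.
* **Alt 5'/3'** — two introns sharing one genomic end. Labels are resolved
  on the transcribed strand: a varying genomic-left boundary is
  alternative 5' on '+' and alternative 3' on '−'. With unknown strand the
  event keeps the '+' reading and `strand = NA` marks it ambiguous.
* **MXE** — two or more inclusion chains sharing both flanks with pairwise
  disjoint cassettes, no chain containing two cassettes, and no direct
  D–A skip; a skip or a joint path demotes the pattern to ES events.
* **Complex** — any remaining pair of overlapping, incompatible introns
  not explained by an event above; overlapping discordant regions merge
  into one event.

Support of an alternative is the number of ESTs whose block structure
contains **all** of its defining introns (for IR's retention side,
uninterrupted exonic coverage as above). When fragmentation leaves no
single read spanning a multi-intron alternative, the count falls back to
reads containing at least one defining intron and none of the rival's.
The quality filter keeps an event iff
`max(support) / min(support) <= 10`, boundary inclusive — the permissive
reading of "within ten times", exposed as `max_ratio`.

## ORF localization

`find_longest_orf()` scans the three sense frames for the longest
ATG-initiated ORF, stop codon included in the interval; ties go to the
5'-most start, and ORFs running off the transcript end are kept but
flagged incomplete because ESTs truncate 3' ends. The reference isoform of
a locus is the isoform with the longest ORF — the natural anchor when no
annotation dictates which variant defines the UTR boundaries. An event
overlapping the ORF by at least one nucleotide counts as coding (so
boundary-straddling events are coding, keeping the three labels
exclusive); a purely intronic variable region is localized by its
insertion point in the spliced reference. Region percentages are
denominated over localized events only, and both denominators (all events
vs localized events) are reported, since the two totals genuinely differ.

## The synthetic-data generator

`sim_config()` defaults encode the gene architecture the analysis assumes:
~4.6 exons per locus (shifted Poisson), intron lengths log-normal with
arithmetic mean 491 bp truncated to [60 bp, 20 kb] (sdlog 0.8 — a long
right tail that still allows desk-scale genomes), genomic GC 0.56, exons
uniform 80–300 bp, intergenic spacers >= 500 bp so loci never merge by
construction. One event of a configurable type mix is planted per selected
gene; every intron of every isoform gets canonical dinucleotides on the
transcribed strand, and alternative-site shifts are drawn from 6–45 bp.
EST simulation draws a configurable mixture of full-length and partial
reads (partials uniform 400–800 bp — the field's typical single-pass read
lengths; the source never states these, so they are configuration, not
claims), from both orientations, with per-base substitution errors
(default 1%). Errors are substitutions only: the built-in aligner is
substitution-exact, and an indel rate would break its gap model. Terminal
exons are extended where needed so every isoform can host the shortest
configured read.

What passing tests on this generator demonstrate: the graph, classifier
and localization logic are exact on reads satisfying the aligner's
assumptions, and degrade gracefully under substitution noise and
fragmentation. What they do not demonstrate: robustness to indels,
chimeric clones, vector contamination, paralogous gene families with
near-identical copies, or non-canonical splice sites — all real phenomena
the simulator deliberately omits.

## Validation problem sizes

The test suite validates end-to-end recovery on a 50-gene simulation
(~200 kb genome, 1,500 ESTs at 30 per gene, minor-variant frequency 0.5):
with error-free full-length reads every planted event is recovered with
exact coordinates and type (precision = recall = 1.0); with 1%
substitutions and 60% partial reads the suite asserts recall >= 0.9 and
precision >= 0.95. Statistical properties of the generator (GC within
±0.01, intron mean within 10%) are checked on a 280-gene simulation
(>500 kb, >1,000 introns). Oracle equivalences run against quadratic
union-find (clustering), an all-(start, frame) scan (ORFs), and direct
string search (amplicons).

## Known limitations

* The aligner requires a seedable exact match per exon; exons shorter than
  ~20 bp, or reads whose errors cluster inside a junction window, can lose
  a junction (support loss, occasionally a missed event at low coverage).
* Complex events report the supports of their two most-supported
  incompatible introns; a full decomposition of multi-way tangles is out
  of scope.
* Fragment support allocation between near-identical isoforms is
  heuristic (most-supported compatible chain), which can bias the support
  ratio at loci with many partial reads.
* Relative-expression arithmetic assumes perfect (2-fold per cycle)
  amplification efficiency, as the 2^-ddCt formula does.
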