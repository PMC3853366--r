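---
title: "Methods: nanoCAGE tag processing, artifact filtering and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoCAGE tag processing, artifact filtering and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

nanoCAGE reads are 5′-anchored: a template-switching (TS) oligonucleotide
added to the reverse-transcription reaction attaches the 5′ adapter, so a
single read per cDNA reports a transcription start site (TSS) and tag
counts give digital expression. Three artifact channels contaminate the
signal and must be removed before counting:

1. **Tag dust** — empty constructs and oligo concatemers that contain no
   cDNA.
2. **rRNA carry-over** — highly abundant ribosomal sequence that survives
   library preparation.
3. **Strand invasion** — the TS oligo hybridises to a complementary
   stretch of the nascent first-strand cDNA instead of waiting for the cap
   site, truncating reverse transcription. The resulting tag looks like a
   genuine 5′ end but starts wherever the oligo invaded.

Strand invasion is detectable genomically: the sequence immediately
upstream of an invaded tag's 5′ end, read on the tag's strand, resembles
the oligo 3′ end (`TATAGGG`), because that is the sequence the oligo
base-paired with. Capped tags have no such bias.

## Read model and preprocessing

A read is `barcode(6) + UMI(8) + TATA + G-run(≥3) + insert`. The constant
24-nt oligo head is covered by the sequencing primer and not sequenced
(`head_included = TRUE` handles layouts that retain it). Parsing:

* **Barcode**: exact match against the sample sheet by default
  (`barcode_max_mismatch = 0`); at 1 mismatch, ambiguity (two barcodes at
  the same distance) sends the read to the *unassigned* stream rather than
  guessing. The fifteen published barcodes are three per chemistry (R3,
  D3, L1, L2, L3).
* **UMI**: stored but never used for deduplication — the analysis counts
  tags, and deduplication is a separate concern.
* **Linker**: literal `TATA`, then the *entire* run of G's is stripped.
  Capped templates make the reverse transcriptase append extra cytosines
  (read as G's), geometric in number, so stopping at exactly three G's
  would leave cap-derived G's on the insert. The cost is ambiguity when a
  transcript itself starts with G — see the simulator notes below.
* **Trimming**: inserts are cut to `trim_length = 31` nt, the length at
  which a tag is long enough to map essentially uniquely in a mammalian
  genome yet short enough for inexpensive sequencing.

Reads whose linker cannot be parsed are counted as artifacts: with a
per-base error rate of order 10⁻³ this mislays a percent or so of genuine
reads, which the stage counts make visible.

The tag-dust screen is a deterministic coverage criterion (the established
screening tools wrap a similar decision in an FDR machinery that is not
reproducible from published settings): windows of `artifact_window = 12`
nt slide along the insert at step 1; a window "hits" when it matches any
artifact-library sequence within `artifact_k = 1` edit; the read is an
artifact when hits cover ≥ `artifact_fraction = 0.8` of the insert. The
default library holds the oligo head, head–linker junctions and linker
concatemers — the parts every tag-dust read is built from — and excludes
the UMI (random in real artifacts).

## Approximate matching

All screens run on one primitive: the semi-global edit distance of a whole
pattern against any substring of a text (both text ends free), unit costs.
Patterns up to 64 nt use the Myers bit-parallel column update — one
machine word per text character — and longer patterns fall back to a plain
dynamic-programming scan. Conventions chosen where the field is silent:

* `N` matches nothing, including another `N` (conservative for
  contaminant screens).
* Case is normalised on ingest; costs are uniform Levenshtein.
* Reported hits are the *best-match* end offsets (0-based, 1-past-end);
  `myers_search(k)` returns them only when the best distance is ≤ k.

The implementation is validated against an independent, pure-R
Wagner–Fischer oracle on a thousand random instances per run (patterns
4–64 nt, texts up to 500 nt, k ≤ 5) in the test suite.

The rRNA screen flags an insert when it (or its reverse complement —
contamination appears on both strands in practice) matches any contaminant
record within `k = floor(0.1 × length)` edits; `k` scales with read length
rather than being a constant so the tolerance is constant per base.
Inserts under 12 nt carry too little information and are never flagged
(counted separately).

## Alignment

External alignments are imported from SAM/BAM (via Rsamtools; unmapped and
secondary records skipped) or BED6; everything is converted to 0-based
half-open coordinates with `five_prime_pos = start` (+) or `end − 1` (−).
For synthetic genomes the built-in aligner is exhaustive and exact: an
Aho–Corasick pass (`Biostrings::PDict`) locates exact hits for all reads
at once, and only reads without an exact hit are rescanned with the
bit-parallel matcher up to `max_errors = 3` (about one error per 10 nt of
a 31-nt tag). Ties — co-optimal hits at distinct loci — make a read
unmapped with the tie multiplicity recorded, because CTSS counting needs
unique 5′ positions; co-optimal end offsets within one pattern length are
collapsed to one locus first, and the leftmost co-optimal span is reported
for determinism. The aligner refuses genomes over 10 Mb: it is a testing
instrument, not a mapper.

## Strand-invasion filter

For each alignment the filter reads the `w = 7` genomic bases immediately
upstream of the 5′ end on the tag's strand (for minus tags: reverse
complement of the bases genomically after the 5′ end) and counts Hamming
mismatches against `TATAGGG`; tags at ≤ 2 mismatches are flagged. The
window content, length and threshold are configuration
(`invasion_motif`, `invasion_max_mm`) because the upstream tooling defines
only the two-mismatch threshold; the 7-nt terminal motif with Hamming
distance is this package's declared interpretation. Tags too close to a
contig edge cannot be tested, are never flagged, and are counted.

On an i.i.d. uniform genome a genuine tag false-flags with probability
$\sum_{i=0}^{2} \binom{7}{i} 3^i / 4^7 = 211/16384 \approx 0.0129$
(`invasion_false_flag_prob()`), the unavoidable background loss.
`invasion_rate()` reports the raw flagged fraction with its binomial
standard error — the convention used for per-library invasion percentages
— plus, optionally, a background-corrected estimate
$(\hat f - q)/(1 - q)$ for real libraries where genuine tags are assumed
to false-flag at the analytic rate. The filter operates per alignment;
cluster-level removal (drop a cluster only when *all* its tags are
flagged) is available through `split_strand_invasion()` on clustered
calls, but per-tag filtering composes better with downstream stages and
keeps a per-read record.

Filtering at Hamming (not edit) distance is deliberate: the invasion
hybrid is an ungapped duplex, and an ungapped comparison makes the
closed-form background exact.

## Clustering, annotation, quantification

Tag 5′ ends are tallied per (position, strand, sample) into CTSS, then
clustered by single linkage: consecutive CTSS on one chromosome and strand
join a cluster while gaps are ≤ `cluster_gap = 20` nt, with *no*
expression threshold. Twenty nucleotides merges the micro-heterogeneity of
one promoter without bridging independent promoters; the parameter is
exposed because the literature uses a range of values. Clustering is
idempotent and order-independent; the cluster peak is the CTSS with the
largest pooled count, ties broken toward the smaller coordinate so output
is deterministic.

Clusters are annotated against gene models (GTF or BED12) by same-strand
overlap of the **peak position** with precedence
promoter > exon > intron > other. The promoter is ±100 nt around every
transcript start (width 201); "intron" is any peak inside a gene span that
hits no exon or promoter. Peak-based classification avoids multi-basket
ambiguity for clusters spanning a boundary; `--annotate-by hull` semantics
are available (`by = "hull"`) with the same precedence, and an unstranded
mode supports antisense-signal exploration. When a peak overlaps features
of several genes within one precedence level, the lexicographically first
gene id wins — declared, deterministic, and irrelevant on non-overlapping
synthetic annotation.

Quantification: gene counts pool all same-strand clusters assigned to a
gene (promoter, exon and intron baskets). Pearson correlations are
computed on TPM (each library scaled by its own total), optionally on
log10(TPM + 1); both scales are provided because published figures are
log-scale while the correlation scale is rarely stated. Rarefaction draws
exactly *n* tags without replacement (multivariate hypergeometric,
delegated to `vegan::rrarefy`, seeded); depth 30,000 is the conventional
comparison depth for benchtop-scale CAGE. The resampling null for
common-loci counts replaces comparison pools by seeded subsamples of one
reference library at matched depths: with scale-free expression most
detected loci are low-count, so even samples identical by construction
miss each other's loci, and the null quantifies how much overlap depth
alone destroys.

## The simulator: what it emulates, and what not

`simulate_reference()` builds an i.i.d. uniform A/C/G/T genome (one
contig), places non-overlapping genes (1–5 exons of 80–300 nt, introns
60–400 nt, intergenic gaps 200–1,500 nt, both strands), draws a separate
2-kb contaminant record, and plants strand-invasion sites in intergenic
space. Sites are written into the *genome*, not the reads: the filter
tests flank sequence, so the artifact signal must live in the flank.
Planted motifs carry 0–2 mismatches from `TATAGGG` (probabilities
0.5/0.3/0.2), all within the filter threshold, so planted sensitivity is
100% by construction. Expression follows a Zipf law (exponent 1) because
digital expression levels are scale-free; ranks are assigned to genes at
random.

`simulate_library()` emits reads of the exact oligo layout with per-base
substitution errors (default 10⁻³) and a per-read truth record. Classes:

* **tss** — insert starts at a gene's transcript start; 0–5 extra G's
  (geometric, mean 0.5) model cap-derived additions.
* **internal** — uncapped: insert starts uniformly within the mature
  transcript (no extra G's).
* **invasion** — insert starts immediately downstream of a planted site.
* **rrna** — substring of the contaminant, either strand.
* **artifact** — substring of head–linker concatemers.

Two ground-truth guarantees are enforced at generation time. First, the
genomic base at every read start is never G on the read's strand
(rewritten at reference build for TSS and planted sites, resampled for
internal positions): linker G-run stripping would otherwise consume
genomic G's and shift the recovered 5′ end by construction — the known
one-base ambiguity of template switching at G-initiated transcripts, which
the simulator excludes so that position recovery is exactly testable.
Second, a read is never *labelled* tss or internal when its upstream flank
lies inside the filter's Hamming ball (TSS flanks are pushed out of the
ball at reference build; internal positions are resampled): such a read
would be indistinguishable from strand invasion, so the label would be
meaningless and the planted invasion rate would not be identifiable. The
coincidental false-flag background is instead measured where it is
well-defined — on uniform positions of an i.i.d. genome, against the
closed form.

Chemistry presets set the invasion class rate to the published per-library
invasion percentages (R3 9.1%, L3 35.9%, D3 73.6%, L1 48.6%, L2 38.6%)
and split the remaining mass between tss and internal at 2:1 for the
cap-specific R3 and 1:2 otherwise; rRNA and artifact rates are 0 in the
presets so the invasion rate among aligned tags equals the preset. The
generic default mix (55/25/10/5/5) represents a reasonably clean library.

The simulator does **not** emulate: realistic quality scores, indel
sequencing errors, spliced alignment of junction-crossing inserts (inserts
are genomic sequence, so gene-body reads align contiguously), polyA
selection, paired ends, chromatin- or sequence-dependent TSS usage, or
overlapping gene models. Tests passing on these data therefore demonstrate
the correctness of the *computational* chain — parsing, matching,
filtering arithmetic, clustering, counting — not robustness to every
failure mode of real libraries.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one CPU while keeping every statistical
check well-powered: 1,000 random instances for matcher–oracle equivalence;
12,000 uniform tags for the false-flag background (3 binomial SE ≈ 0.3
percentage points); 20,000 reads per chemistry preset for rate recovery;
three 4,000-read libraries on a 200-kb genome for the end-to-end ordering;
100 random CTSS sets × 4 gap values for the clustering oracle; 1,200 genes
at 60,000 tags, rarefied to 30,000, for detection stability. Binomial and
hypergeometric checks use 3-standard-error bands throughout.

Degenerate inputs are defined, not accidental: empty text gives distance =
pattern length with end offset 0; empty alignment sets give empty CTSS and
cluster tables; zero exon tags give an infinite promoter/exon ratio (NaN
when the promoter is also empty); rarefaction below the requested depth is
an error naming the shortfall; a zero library total is an error rather
than silent NaN TPM.

## Known limitations

* The tag-dust criterion is a stated stand-in for FDR-based screening
  tools; absolute artifact counts are not comparable across the two.
* The built-in aligner is exhaustive and therefore bounded to ≤ 10 Mb
  genomes; real libraries should be aligned externally and imported.
* The strand-invasion window definition (7-nt terminal motif, Hamming
  distance) is one of several defensible readings of the two-mismatch
  rule; the motif and threshold are configuration for that reason.
* Basket fractions depend on annotation completeness; on sparse synthetic
  annotation the "other" basket absorbs everything intergenic, including
  all planted invasion sites.
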