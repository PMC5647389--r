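---
title: "peaktargets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peaktargets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaktargets)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the geometry of the synthetic-data
generators, and the design decisions taken where more than one reasonable
choice existed.

## Coordinates

Every interval in the package is 0-based half-open, `[start, end)`. The
two file conventions the field uses are converted at the I/O boundary and
nowhere else: GTF is 1-based inclusive (`parse_gtf()` subtracts one from
starts; `write_gtf()` adds it back), BED/narrowPeak is already 0-based
half-open, and MACS14 tables carry 1-based starts with an absolute
1-based summit. Keeping a single internal convention removes the
off-by-one class of bugs from every downstream comparison; the format
round-trip tests pin the conversions at the boundary records
(a one-base exon at position 1, a summit on the first base of a
chromosome).

## Summit classification

A peak is reduced to its summit — the single base of maximal signal
reported by the peak caller — and compared against every transcript.
The TSS is the first transcribed base: locus start on `+`, `end − 1` on
`−`. The signed upstream distance of a summit *s* from a TSS *t* is
*d = t − s* on `+` and *d = s − t* on `−`, so *d* ≥ 0 always means "the
summit sits on the 5′ side of the TSS along the direction of
transcription". The per-transcript relation is proximal when
0 ≤ *d* ≤ `proximal_max`, distal when `proximal_max` < *d* ≤
`distal_max`, and — independently — exonic or intronic when the summit
falls inside the transcript locus. Defaults are `proximal_max` = 2000 bp
and `distal_max` = 50000 bp, the conventional promoter windows for this
kind of survey; both are plain arguments (`classifier_config()`).

Decisions embedded in the classifier, all exercised by tests:

- **Boundaries are inclusive.** *d* = 2000 is proximal, *d* = 50000 is
  distal, and *d* = 0 (summit exactly on the TSS base) is proximal even
  though that base is also exonic.
- **A summit past the TSS has no promoter relation** (*d* < 0): inside a
  gene it is exonic/intronic, and promoter status can only come from a
  *different* transcript's TSS.
- **Precedence.** Peak classes must be mutually exclusive to report a
  distribution that sums to 100%, so the class is the highest-precedence
  relation over all transcripts: proximal > distal > exonic > intronic,
  with intergenic reserved for peaks with no relation at all (no TSS
  within `distal_max`, inside no locus). The promoter-before-genic order
  mirrors the order in which the tests are usually described; it is a
  decision, not a law of nature, and all contributing associations are
  retained in the output so a different precedence can be recomputed from
  the association table.
- **All transcripts, not one per gene.** No representative-transcript
  selection is applied; gene-level deduplication happens at the
  integration step. A position exonic in any containing transcript is
  exonic, which is deterministic and isoform-agnostic.
- **Ties** between equally ranked associations are broken by smaller
  absolute distance, then transcript id, so annotation is a pure function
  of its inputs regardless of input order.

The implementation indexes TSS windows and loci per chromosome with
IRanges; a brute-force per-(peak, transcript) scan lives in the test
suite as the oracle, and the two agree on random summits as well as on
5000 constructed peaks over a 1000-gene genome.

## Blacklist filtering

Artifact ("blacklist") regions are consumed as BED, merged on load, and
applied to *peak intervals*: a peak is removed when it overlaps a
blacklist interval by ≥ 1 bp (half-open semantics; touching never
overlaps). The conventional place for blacklist filtering is on reads,
before peak calling; since this pipeline starts from called peaks, the
interval-level filter is the standard post-hoc equivalent, and `run_all()`
records the substitution in its report. A summit-only mode
(`blacklist_mode = "summit"`) is available for a stricter reading.

## Integration with differential expression

Significance is taken from the upstream caller's `significant` column
rather than re-thresholding q-values: the DE caller already made an
FDR-controlled decision, and re-deciding with different assumptions would
silently change the gene universe. Direction is the sign of the log2
fold change; infinite fold changes (one condition at zero) survive the
round-trip as ±Inf.

A DEG is peak-associated when any association (promoter, exonic,
intronic) lists its gene id. Intergenic peaks associate with no gene:
assigning them to a nearest gene would contradict the definition of
intergenic used by the classifier (no TSS within 50 kb). An
`include_intergenic_nearest` escape hatch exists for annotations produced
under a narrower window. The Venn decomposition satisfies
`deg_only + intersection = n_deg` by construction and is tested as a set
identity.

Replicate QC computes Pearson r on log2(FPKM+1) — the +1 pseudocount
keeps zeros finite and is negligible at realistic FPKM — and discards a
replicate when the *median* of its correlations with same-condition
replicates falls below `min_corr` (default 0.9; no universal value
exists, so it is a visible parameter). Zero-variance replicates have
undefined correlations and are discarded with a warning rather than
propagating NAs.

## Enrichment statistics

Over-representation uses the upper-tail hypergeometric probability
P(X ≥ k) with X ~ Hypergeom(N, K, n), evaluated through `phyper()`'s
log-space machinery; an exhaustive enumeration over all C(N, n) draws
serves as the test oracle for every configuration with N ≤ 12 at 1e-12.
Multiple testing uses Benjamini–Hochberg by default (with Bonferroni and
none as options) — the FDR idiom of RNA-seq analyses. Two rankings are
returned because they answer different questions: by p-value (strength of
evidence, dominated by large terms) and by fold enrichment
(effect size, dominated by small terms). The background defaults to the
DE-tested gene universe, not the mapping's gene set: genes never tested
for expression cannot enter the study set, and using the mapping universe
would overstate enrichment. Terms with k = 0 are dropped as
uninformative. The mapping is a flat pre-propagated gene↔term table plus
an optional slim list; ontology-graph propagation is out of scope by
design, which keeps the module agnostic to the ontology's format and
version.

## Motif scanning and clusters

Scanning is exact-word matching (Biostrings) of the motif and its
reverse complement, with the reverse-complement hits reported at their
forward-strand offsets; overlapping occurrences are all reported, and `N`
never matches. GGCCGG's reverse complement CCGGCC is a distinct word, so
a GC-rich stretch can legitimately produce interleaved +/− hits — these
are kept, as exact-word semantics demand. For a truly palindromic motif
the − strand scan would duplicate the + strand hits and is skipped.

No formal definition of a motif "cluster" exists in this context, so the
package uses positional chaining: a maximal run of hits in which
consecutive starts differ by ≤ `window_bp` (default 200 bp), reported
when it holds ≥ `min_hits` (default 2). Both parameters are exposed; the
defaults are conservative for a 6-mer in promoter-sized windows. The
chaining equals the transitive closure of the pairwise within-window
relation on a line, which is what the brute-force oracle in the tests
computes.

Promoter windows are cut strand-aware around the TSS
(`upstream_bp` before, `downstream_bp` after) and minus-strand windows
are reverse-complemented, so offset 0 is always the most upstream base
and the TSS sits at offset `upstream_bp` in every returned sequence.
Windows are truncated at contig edges and flagged.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed, not tuned per run.

**Geometry.** Genes are laid out one per fixed-width slot:
`[clearance C | gene | clearance C | intergenic zone]`, with
C = `distal_max` + 5 kb. Because C exceeds every classification window, a
summit placed relative to one gene can never acquire an unintended
relation to a neighbour, which makes the planted class labels
unambiguous under the classifier's precedence — the property the central
oracle test (100% label agreement on 5000 peaks) depends on. Class
counts follow the configured mix by largest-remainder apportionment, so
distribution assertions are exact rather than multinomially noisy. The
default mix (4.3 / 29.7 / 0.9 / 17.9 / 47.2 percent) and the default DE
composition (2233 down, 2206 up, 33,613 unchanged among 38,052; 344 of
the 4439 significant genes hosting peaks) reproduce the shapes of the
study this pipeline was built around. The first two proximal and distal
peaks are pinned to the boundary distances (*d* = 2000/0 and
*d* = 50000/2001) so the inclusive boundaries are always exercised.

**Sequences.** Chromosome sequences are uniform random DNA scrubbed of
accidental motif occurrences by bounded rejection resampling, then
motif copies are planted at fixed upstream offsets (default 3 copies
within 200 bp centred 1.5 kb upstream of each TSS, strand-aware). Plants
are protected from subsequent scrubbing, so extraction + scanning must
recover exactly the planted set — the basis of the motif recovery tests.
Sequence simulation is intended for small genomes (tens of genes); the
geometry-only generators scale to the 1000-gene/5000-peak configuration
without generating sequence.

**Replicate matrices.** Gene-level log2 expression has sd 2 across
genes, each replicate adds N(0, 0.15) log2 noise, and a 10% subset of
genes carries a ±1 condition effect. Corrupted wild-type replicates
receive additional independent N(0, 1.2) log2 noise. The 1.2 figure is a
designed calibration, not an arbitrary "heavy" value: with 2 corrupted
replicates among 5, an intact replicate's median same-condition
correlation is the mean of one intact-intact and one intact-corrupted
correlation, so noise heavy enough to push the corrupted replicates'
correlations toward zero would drag intact replicates below any
reasonable threshold too. At sd 1.2 the intact-corrupted correlation
sits near 0.85, leaving corrupted medians below the 0.9 default and
intact medians above it with margin on both sides; the recovery tests
run this over 20 seeds.

**What the generators do not emulate:** read-level noise, peak-shape or
signal profiles, realistic base composition or repeat structure, isoform
complexity (one transcript per gene), correlated DE effect sizes, or
ontology term overlap structure (null terms are drawn independently).
Passing tests therefore demonstrate the correctness of the pipeline's
logic and arithmetic under clean, known ground truth — not robustness to
the pathologies of real sequencing data.

## Problem sizes and determinism

The test suite and the acceptance script run at: 1000 genes / 5000 peaks
for classification, a 38,052-row DE table, 2000 genes × 10 replicates
for QC (20 seeds), 50-term mappings at a 200-of-5000 study/background
scale for enrichment (20 repetitions), and ~10-gene sequenced genomes
for motif recovery — sizes at which every check completes in seconds
while leaving the constructions non-trivial. All generator randomness
derives from a single integer seed (per-generator offsets keep the
streams independent); a fixed seed reproduces every emitted file
byte-identically, which the determinism tests assert.

## Known limitations

- Peak-to-gene assignment is distance-based only; no chromatin-contact
  or enhancer-activity evidence is consulted.
- The classifier's precedence order is a modelling choice; alternative
  orders can be derived from the retained association table but are not
  built in.
- GFF3, broadPeak and bigWig inputs are unsupported; mappings must be
  pre-propagated; no PWM scanning — the motif module is exact-word by
  design.
- `read_cuffdiff()` trusts the upstream caller's significance decision;
  no DE model is fitted here.
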