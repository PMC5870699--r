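---
title: "Predicting miRNA loci from small RNA sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA loci from small RNA sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRPeaks)
```

## The problem

Mature microRNAs are ~21-22 nt RNAs excised by Drosha/Dicer (animals) or
DCL1 (plants) from a hairpin precursor. In a small RNA sequencing
library mapped to a genome, a genuine miRNA locus shows a characteristic
signature: one or two sharp stacks of reads (the miRNA and the miRNA*)
with homogeneous 5' ends, sitting on a sequence that folds into a stable
stem-loop. At modern sequencing depths this signature is buried under
RNA degradation products that cover much of the transcriptome at low,
diffuse abundance, which inflates both false positive and false negative
rates of proximity-clustering locus finders.

miRPeaks addresses this with an entropy-based peak caller followed by
rule-based alignment-pattern filters and a hairpin test. Every stage is
exposed as an exported function, so each can be exercised and audited
independently; `runPredict()` chains them.

## Peak detection

The genome is tiled per strand into windows of `lW` nt overlapping by
`lO` nt, each split into subwindows of `lSw` nt. Reads are assigned to
subwindows by their 5' end — the Dicer-defined coordinate at which
genuine miRNA stacks are most homogeneous. With raw subwindow abundances
r(i) and a pseudo-count `offset` added to every subwindow, the window's
distribution P is compared against the uniform distribution Q(i) = 1/n
with an absolute-log divergence

$$D(P\|Q) = \sum_i \left|\ln \frac{P(i)}{Q(i)}\right| P(i),$$

which is zero exactly for a uniform profile and, unlike the standard
Kullback-Leibler divergence, accumulates positive contributions from
subwindows below as well as above the uniform level. While the
divergence exceeds the threshold `rudVal`, the most abundant read of the
highest subwindow is taken; a local window of `plateauRange` nt centred
on it is re-tested with the same statistic, so that broad plateaus of
uniformly high coverage (repeat-derived or highly transcribed regions)
are rejected while true spikes pass. The selected read's abundance is
then removed and the loop continues, which is what lets one window emit
both the miRNA and the miRNA* peak.

Two interpretation choices deserve note. First, "the sRNA is removed
from the distribution" is implemented literally: only the selected
read's abundance is subtracted, not the whole subwindow. Second, the
pseudo-count doubles as the assumed background level: a read whose
abundance does not exceed `offset` is never emitted as a peak, which is
the stated purpose of the offset (keeping low-expression reads out of
the candidate set). Candidates surfacing in two overlapping windows are
deduplicated by identity of the read placement.

Defaults: `lW` 200, `lO` 100, `lSw` 25, `rudVal` 0.35, `plateauRange`
75, `offset` 1. `lSw` is close to one miRNA length, so a genuine stack
occupies roughly one subwindow — the configuration the statistic is
designed to detect. These are package defaults, all configurable.

## Alignment-pattern filters

Three predicates exclude false positives, applied in a fixed order with
the first failing reason recorded per candidate:

1. **Repetitive locus** (`repeatFilter`): candidates whose sequence has
   strictly more than `repeats` (20) exact genome placements, both
   strands counted, are discarded. Multi-mapping reads below that bound
   keep their full abundance at every placement; no fractional
   allocation is attempted.
2. **Size class** (`sizeClassFilter`): the abundance histogram of all
   reads incident to the prospective folding window, over lengths 16-28
   nt with a +1 pseudo-count per class, must diverge from uniform by
   more than `rudVal` *and* peak inside the expected mature range
   `[minLen, maxLen]` = [21, 23]. Degradation shows either a flat
   length profile or a dominant class outside that range (e.g. the
   24 nt heterochromatic siRNA class in plants).
3. **Precise processing** (`preciseProcessingFilter`): reads are grouped
   into clusters — greedy single pass over reads sorted by start, a read
   joining the open cluster when both ends lie within `clearCut` (3) nt
   of the cluster seed's. The candidate is kept only if (i) coordinate
   variants of the candidate (both ends within `clearCut`) hold at least
   `clearCutPercent`% (75, read inclusively) of its cluster's abundance,
   and (ii) reads of *other* clusters overlapping it by more than
   `clearCut` nt hold less than `overlapPercent`% (50). Together these
   demand the sharp excision boundaries of Drosha/Dicer products and
   reject smeared degradation stacks.

## Hairpin analysis

A window of `maxFoldLen` nt on each side of the candidate is folded and
*all* locally stable structures are enumerated, rather than folding one
arbitrary flank length; structures of different lengths are compared by
the adjusted minimum free energy

$$\mathrm{aMFE} = \frac{\mathrm{MFE}}{\mathrm{fold\ length}} \times 100,$$

in kcal/mol per 100 nt. Structures containing the mature span are pushed
through six checks: minimum hairpin length; aMFE at most `maxAmfe`;
mature not spanning the terminal loop; at least `minPairedInMature`
paired mature bases; no unpaired run in the mature longer than
`maxUnpairedRun`; and at most `maxLoops` hairpin loops. The lowest-aMFE
survivor is the precursor (ties: shorter fold, then leftmost — a
deterministic-output requirement). The miRNA* is then inferred from the
pair table by projecting the mature through the duplex with a
`starOverhang` (2 nt) 3' overhang on each end, clipped and flagged at
the hairpin boundary, and suppressed when more than half of the mature
is unpaired.

Two parameter profiles reflect precursor biology: `animalParams()`
(`maxFoldLen` 100, `minHairpinLen` 50, `maxLoops` 1) for the compact
~70 nt animal pre-miRNA, and `plantParams()` (`maxFoldLen` 300,
`minHairpinLen` 60, `maxLoops` 3) for the longer, occasionally
multi-branched plant precursors. Both use `maxAmfe` -20,
`minPairedInMature` 14 and `maxUnpairedRun` 5.

### Folding backends

Folding is a pluggable interface with two implementations. The
`"rnalfold"` backend shells out to ViennaRNA's `RNALfold` when the
executable is on the PATH and parses its locally stable structure list.
The `"internal"` backend (the default) is a self-contained
dynamic-programming folder: minimum-energy base pairing with pair
energies GC -3, AU -2, GU -1 kcal/mol, a -1 helix-stacking bonus and a
3 nt minimum hairpin loop, reporting every closed span that is not
dominated by a one-step extension of its closing pair (a locality rule
in the spirit of `RNALfold`). Its energies are on a simplified scale and
it over-pairs random sequence relative to the nearest-neighbour model,
so its absolute MFEs are not comparable to ViennaRNA's; what the
pipeline consumes — the *ranking* of subspans by aMFE, pairedness of the
mature, loop counts — is robust to this. The internal backend keeps the
whole test-suite free of external binaries and bit-reproducible. Result
files record which backend ran (`config.yml`).

## Scoring

A structure randomization p-value is computed by folding
dinucleotide-preserving shuffles (Altschul-Erickson Eulerian-walk
construction, exact dinucleotide counts) of the precursor:
p = (1 + #\{MFE_shuffle ≤ MFE_obs\}) / (n + 1), with n = 99 by default
(resolution 0.01) and a fixed seed. The prediction score is an explicit
three-term log-odds sum: log2((1-p)/p) clamped to ±10; +3/+1/0 for star
evidence (observed star reads with abundance ≥ 2 / any / none); and the
clamped log-odds of the signature fraction, the share of precursor-span
abundance within `clearCut` of the mature or star coordinates. The score
ranks predictions and is reported per component so users can re-rank; it
never gates the output (a below-everything `minScore` provably returns
the identical set, and `minScore` is off by default). The score scale is
specific to this breakdown and is not interchangeable with other tools'
score cut-offs.

## Wild-type versus mutant validation

Biogenesis-pathway mutants (Dicer/DCL1, Drosha, DGCR8) deplete genuine
miRNAs but not degradation products or Pol III transcripts, giving an
annotation-free accuracy signal. Abundances are normalized by
library-size scaling to the *median* total genome-mapped count of the
experiment (value / librarySize × median), fold changes are
log2((wt + pseudo)/(mut + pseudo)) with a pseudo-count of 1 normalized
unit to absorb zeros, and a locus counts as downregulated at log2FC ≥ 1
("at least 2-fold", boundary inclusive). `runValidate()` reports the
downregulated fraction, the per-locus fold changes and a cumulative
table for plotting, and processes an optional control locus set (tRNA/
snoRNA-like) identically. Against a GFF3 annotation,
`evaluateAgainstAnnotation()` defines a match as ≥ 1 nt same-strand
overlap of the predicted mature with an annotated mature; specificity is
the matched share of predictions, sensitivity the detected share of
*expressed* precursors, expressed meaning at least one incident read.

## The simulator and what passing means

`simulateGenome()`/`simulateReads()`/`simulateFixture()` build the test
surface: i.i.d. uniform background sequence; implanted stem-loops
(25 bp stem, 10 nt loop by default) whose 3' arm carries two non-pairing
mismatches, because real duplexes are imperfect — and because a perfect
inverted repeat would let mature reads map exactly to the opposite
strand, an artifact no real locus shows; mature (hairpin positions 3-23
of either arm) and star stacks at abundance 100 and 30 with ±1 nt jitter
at probability 0.1 per end (isomiR raggedness); uniform degradation
reads of 16-28 nt on both strands at 20 reads/kb; optional hairpin-free
control stacks and tandem-repeat blocks; and paired wild-type/mutant
sets in which ablated loci drop to 10% in the mutant. All randomness
sits behind one seed, and every artifact is bit-reproducible from
(spec, seed).

The default conditions used in the end-to-end checks are 10 implanted
loci in a 50 kb genome across 5 seeds — sizes chosen so the whole suite
folds and shuffles in minutes on one core while every stage still sees
realistic contrasts. The simulator emulates peak shape, duplex geometry,
size-class structure and depth asymmetries; it does not emulate
transcriptome-scale expression gradients, sequencing error, isomiR
families beyond ±1 nt, or genomic repeat landscapes. Recovery of
implanted loci therefore demonstrates internal correctness of the
statistic-filter-fold chain under its own assumptions, not field
accuracy on real libraries; hairpin-free sharp stacks (the control loci)
can still be called when flanking random sequence happens to fold, which
is precisely the false-positive mode the mutant validation is designed
to expose.

## Numerical and degenerate-input choices

Probability vectors are kept strictly positive by the pseudo-counts, so
the divergence is always finite and `D = 0 ⇔ P = Q` holds exactly — an
empty window is uniform by construction. Coordinates are 1-based
inclusive GRanges throughout, converted only at the PatMaN boundary
(also 1-based inclusive). Ties anywhere in the pipeline (equal subwindow
peaks, equal-abundance reads, equal aMFE) break deterministically
(lowest index, leftmost 5' end, shortest fold), so reruns are
byte-identical. An unmappable read set produces an empty prediction set
with a warning, not an error; a zero-library validation sample is an
error. Candidates are processed in descending abundance order, and a
candidate falling inside an already-accepted precursor span on the same
strand is absorbed into that prediction — this reports each locus once,
through its dominant (mature) read, with the star carried as metadata.

## Known limitations

The internal folder's energies are heuristic; for publication-grade MFE
values run the `"rnalfold"` backend. The score is a ranking aid whose
scale is package-specific. No replicate-aware differential testing is
attempted (single WT/mutant pairs only). Phased siRNA loci, isomiR
annotation and mismatched/gapped mapping are out of scope; the mapper is
exact and full-length by contract.
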