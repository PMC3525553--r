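---
title: "Methods: miRNAome discovery and four-stage expression analysis"
author: "mirnaome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNAome discovery and four-stage expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnaome)
```

# Scope

`mirnaome` implements, as a tested and reusable pipeline, the two halves of
a small-RNA study of developing tooth germ in the miniature pig: (i)
discovery of the tissue miRNAome from deep-sequencing reads — read
cleaning, six-group novelty classification with stem-loop (hairpin)
prediction — and (ii) the downstream expression analysis over the four
developmental stages bud (E35), cap (E45), early bell (E50) and late bell
(E60): array normalization and differential testing, short time-series
(STC) profile clustering with permutation significance, seed-match target
prediction, GO/pathway enrichment, a bipartite miRNA–gene network ranked
by degree, key-miRNA selection, and ΔΔCT qPCR concordance. A synthetic-data
module generates every input with known ground truth, so each stage can be
tested for exact recovery.

# Read cleaning

Raw reads carry a 3′ sequencing adapter. `stripAdapter()` removes it by
locating the leftmost adapter occurrence allowing at most one substitution
(configurable) over the aligned adapter prefix, with a minimum overlap of
6 nt at the read's 3′ end; reads without an adapter hit (unligated
molecules) and empty inserts (adapter dimers) are rejected.
`collapseUnique()` collapses identical inserts into unique tags carrying
their copy number — the unit of all downstream analysis — ordered by
descending count and then lexicographically so outputs are
order-independent. `filterTags()` applies the clean-read window of
**15–26 nt** and the high-copy cut-off **count ≥ 3**; both are parameters
of `filterParams()`. `removeContaminants()` drops any tag occurring as an
exact substring of an mRNA, Rfam-style ncRNA, or Repbase-style repeat
record on either strand, attributing each removal to the first matching
category in that order. Exact matching was chosen because it is fully
reproducible and oracle-checkable; no mismatch policy is defined for
contaminant screening.

# Six-group classification

Clean tags are mapped with `mapTags()` (substitution-only matching,
default 0 mismatches, configurable up to 2) against the same-species (ssc)
precursor/mature sets, the 22-mammal other-species sets, the genome (both
strands), and ESTs. Tags without a miRNA-set annotation have their genomic
neighbourhood extended **60 nt on each side** and folded. Groups are
assigned by the first matching rule, in order:

| group | evidence | label |
|-------|----------|-------|
| gp1a | ssc miRNA hit and a genome or EST locus | known |
| gp1b | other-species hit whose precursor maps to the genome, locus distinct from gp1a | known |
| gp1c | no miRNA-set hit; EST-supported locus distinct from gp1a/gp1b; window folds to a hairpin | PC |
| gp2 | other-species hit, precursor absent from the genome, tag itself genome-mapped | PC |
| gp3 | other-species hit, precursor absent, tag not genome-mapped | PN |
| gp4 | no miRNA-set hit; genome-only hairpin locus not claimed by earlier groups | PC |

"Distinct location" is a 0-based half-open interval overlap test against
the loci claimed by *strictly earlier* groups; several sequence variants
of one mature may therefore share a locus within a group, which mirrors
how groups in this kind of screen count more tags than precursors. The
gp1b rule conditions on the *precursor* being genome-mapped (and gp2/gp3
on it not being mapped): this is what makes the six rules a decision tree
rather than an ordered list in which gp2 could never fire. gp1c and gp4
are separated by EST support, the only distinguishing evidence available.

## Hairpin folding

`foldHairpin()` computes a maximum weighted base-pairing secondary
structure without pseudoknots (Nussinov-style dynamic program in C++,
minimum loop 3 nt, pairs GC/AU/GU weighted 3/2/1). The window is accepted
as a pre-miRNA-like hairpin iff

1. the dominant helix — the longest run of pairs allowing single-nt
   bulges — has ≥ 18 pairs (`stemMin`),
2. its terminal loop is 4–20 nt (`loopMin`, `loopMax`),
3. the mature arm lies entirely on one side of that helix, and
4. the weighted score is ≥ 35 (`scoreMin`).

The four thresholds are package defaults, not published constants: the
original screen used criteria derived from thermodynamic folding software
that were never printed. They are deliberately strict enough that random
60-nt windows essentially never pass while the generator's planted stems
(perfect-complement, ≥ 26 bp) pass with margin. Thermodynamic free-energy
folding is out of scope; the weighted pairing score is a transparent,
exactly testable proxy.

# Array expression analysis

The signal matrix is a `SummarizedExperiment` of 4 stages × 3 replicates.
`normalizeSignal()` floors at 1, log2-transforms, quantile-normalizes the
12 columns (via limma) and returns to the linear scale. Quantile
normalization assumes most probes do not change; when a large fraction of
probes carries real temporal signal it compresses that signal, which is
why `runProfiling()` exposes `normalize` as a switch and the zero-noise
recovery tests run on the generated (already scale-consistent) matrix.

Detectability (`callDetectable()`) requires a stage-mean intensity of at
least 32 (a package default — the original study reports per-stage counts
but no rule). Differential expression uses one-way fixed-effects ANOVA on
log2 intensities across the four stages and Welch t-tests for pairwise
stage contrasts; the original study names no test, and these are the
standard choices for a 4 × 3 design. Raw p-value thresholds 0.1 / 0.05 /
0.01 form the reported cascade (no multiple-testing correction, matching
how such cascades are printed; BH q-values are emitted alongside).
Degenerate inputs follow explicit conventions: all-equal values give
p = 1, zero within-group variance with differing means gives p = 0.
`hierarchicalCluster()` uses average linkage on 1 − Pearson correlation of
stage-mean log2 vectors, distance 1 for zero-variance probes, probes
pre-sorted by id for deterministic ties. "Signal" is defined as the
maximum linear stage mean, and `strengthFilter()` keeps probes with
signal ≥ 500.

# STC profile clustering

`enumerateProfiles()` builds all unit-change model profiles: step vectors
in {−1, 0, +1} per stage transition, flat excluded — for 4 timepoints
exactly 3³ − 1 = **26 profiles**, the count this construction uniquely
reproduces. Each probe's log2 series relative to E35 is assigned to the
profile minimizing the Euclidean distance to the least-squares-scaled
cumulative template. The scale is clipped at zero (`s = max(0, ⟨x,t⟩/⟨t,t⟩)`)
so that a profile and its mirror image are never tied at distance zero;
remaining ties go to the lower profile id. A dead-zone of 0.25 log2 units
discretizes per-interval steps for reporting.

Profile significance is a permutation test: each round permutes the
timepoints of every probe independently, re-anchors each series to its new
first element, re-assigns, and counts members; `p = (1 + exceedances) /
(1 + nPerm)` with ties counted as exceedances. Permuting the columns
*identically across probes* may look like the more obvious scheme, but
with 4 timepoints that null has only 24 support points including the
identity, so no profile could ever reach p below about 1/24; per-probe
permutation (as in STEM-style analyses) resolves conventional significance
levels and is calibrated under the global null (tested). The default is
1000 permutations.

# Targets, enrichment, network, key miRNAs

Target prediction is a transparent seed rule: a (miRNA, gene) edge exists
where the reverse complement of miRNA positions 2–8 (the 7-mer seed)
occurs verbatim in the gene's UTR. This replaces score-based engines
(miRanda/TargetScan) with a rule that is reproducible and exactly
checkable; free-energy scoring and 3′-supplementary pairing are
non-goals. `conservedTargets()` keeps pairs supported in ≥ 3 species sets
(orthology by shared gene id). `enrichTerms()` computes hypergeometric
upper-tail p-values with BH correction per category and applies the
asymmetric thresholds used in this kind of screen: GO terms at p and FDR
< 1e−5, pathways at p and FDR < 0.05. `buildNetwork()` restricts edges to
genes present in both passing-GO and passing-pathway gene sets and ranks
nodes by degree. `selectKeyMirnas()` then applies the selection chain:
drop candidates with no edge in the intersection network (degree < 1),
then drop survivors with signal < 500; the removals are disjoint and the
arithmetic `key = candidates − no-target − low-signal` is asserted. The
candidate list itself is an explicit input: how a profile-significant set
is narrowed to the candidate list is a judgement call in the original
analysis and is not derivable from printed rules.

# qPCR concordance

`deltaDeltaCt()` averages replicate CTs per (miRNA, stage), subtracts the
internal control (a miR-24 analogue), then the E35 baseline:
`fold = 2^(−ΔΔCT)`, so the baseline fold is identically 1. Averaging
before differencing is a choice (the order is not specified in such
protocols); per-replicate propagation can be layered on top.
`validateConcordance()` correlates qPCR and array fold changes per miRNA
over the four stages on the log2 scale (log2 symmetrizes up- and
down-regulation; the linear scale is a switch) and passes at R > 0.9,
reporting the two-sided p from the t-transform at n = 4.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions:

* **Genome** (`generateGenome()`): uniform A/C/G/T background with planted
  stem–loop loci (perfect-complement stems of mature + 6 bp, all-A loops
  of 4–15 nt, matures 20–24 nt with a 3-nt margin inside the 5′ arm,
  alternating strands). The margins and non-pairing loops make planted
  hairpins pass the folder's rules deterministically, so classifier tests
  are not flaky.
* **References** (`generateReferences()`): planted loci are split into
  same-species known, other-species known, EST-covered novel and
  genome-only novel roles; foreign records exercise the gp2/gp3 branches;
  decoy sets are random mRNA/Rfam/Repbase-sized records.
* **Reads** (`simulateReads()`): mature-derived reads with a zipf-like
  (exponent 1.5) copy distribution — chosen so the count ≥ 3 cut-off is
  non-trivial and some matures genuinely fall below it — with up to 2 nt
  of 3′ trimming and the adapter appended; contaminant reads are decoy
  substrings; junk is random, half of it unligated.
* **Signal matrix** (`simulateSignalMatrix()`): log2 intensity = log2
  (base) + cumulative profile template + Gaussian noise; per-probe bases
  are log-normal (median 500, sd 1.5 log2 in `simulateStudy()`), per the
  log-normal character of real single-channel intensities.
* **CT tables** (`simulateQpcr()`): CT = control CT − log2(fold) +
  jitter, control constant, triplicate wells.

Not emulated: real genome composition and repeat structure, true miRBase
content, cross-hybridization, dye/spot artefacts, amplification
efficiency. Passing recovery tests therefore demonstrates correctness of
the algorithms under the stated generative model, not performance on real
libraries.

# Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen to
exercise every branch while keeping the full suite around a minute: 20-kb
genomes with 24 loci, 3000–5000 reads, 84–200 array probes, 2000 null
probes for calibration, 200 random windows for the folding oracle,
200–1000 permutations for STC. Every stochastic step takes an explicit
seed, and all generators save and restore the caller's RNG state, so
end-to-end runs are byte-reproducible. The large headline counts of the
motivating study (total read yield, 637 candidates, 166/116/52 cascade)
depend on the unavailable raw data and are *not* reproduction targets;
what is reproduced is the arithmetic and algorithmic structure: 26
profiles, the 742-probe manifest construction, and the 38 → 26 → 18
selection chain.

# Known limitations

* The hairpin folder maximizes weighted pairings, not free energy;
  borderline real pre-miRNAs may be judged differently than by
  thermodynamic folders.
* Contaminant and mapping matching are substitution-only; indel variants
  are unhandled by design.
* Quantile normalization is inappropriate when a majority of probes
  changes; use `normalize = FALSE` on pre-normalized or heavily perturbed
  matrices.
* With n = 4 stages, per-miRNA Pearson concordance has little power;
  R > 0.9 is a descriptive criterion, not a calibrated test.
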