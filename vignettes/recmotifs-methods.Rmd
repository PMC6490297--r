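---
title: "Methods: repeat-motif density and recombination-rate landscapes"
author: "recmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-motif density and recombination-rate landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the pipeline answers

In *Drosophila*, recombination does not concentrate in narrow hotspots the
way it does in humans; instead, rates vary along chromosomes in peaks and
valleys on kilobase-to-megabase scales, and short tandem-repeat motifs such
as poly-A runs and CA/GCA repeats co-vary with that variation. Two sister
species make the question sharp: *D. melanogaster* shows a gradual decline
of recombination toward centromeres and telomeres, while *D. simulans* is
nearly flat with abrupt terminal drops. If repeat-motif density drove the
landscape, the two species' motif distributions ought to differ the way
their maps do. `recmotifs` implements the full analysis needed to ask this
question of any genome + recombination map pair: map smoothing and
segmentation, motif discovery and consensus construction, exact-p-value
motif scanning with FDR-discounted density tracks, and a motif x
chromosome x scale association grid. Because the real inputs (hundreds of
sequenced haplotypes, external rate estimators) are heavy and external, the
package also ships a synthetic-data generator that produces genomes and
rate landscapes with *known planted structure*, so every stage — and the
pipeline end to end — is validated against ground truth.

# The recombination map and its preparation

A `RecombinationMap` is a per-chromosome tiling of fixed-width bins (1 kb
by default) each carrying a rate, either the population-scaled rate
$\rho$ (proportional to $N_e r$) estimated from polymorphism data, or a
genetic rate in cM/Mb. Maps in $\rho$ units are converted to cM/Mb by
anchoring: given marker intervals with known genetic lengths,
`normalizeToCM()` multiplies the whole map by the single constant
$c = \sum_i \mathrm{cM}_i \,/\, \sum_i g_i$, where $g_i$ is the map's
genetic length over anchor interval $i$ before scaling. Bin-to-bin ratios
are untouched; only the overall scale is fixed.

Raw linkage-disequilibrium based maps are noisy, so analysis runs on
smoothed maps at several scales. The primary smoother is a **moving
median** (`movingMedian()`) with windows of 1, 5, 25, 101, 501 and
2,501 kb. The moving median is preferred to a moving mean for its outlier
robustness and for a structural property worth testing: with an odd
window, every output value is a member of the raw window's multiset, so
the smoothed map contains only values that occur in the raw map. Design
choices where the procedure is underdetermined:

* **Edges** — windows are truncated at chromosome ends so the output has
  the same length as the input. A truncated window can have even size;
  we take the *lower* of the two central order statistics, which keeps
  the membership property at edges too.
* **Missing bins** — excluded from each window's multiset; an output bin
  is missing only when its entire window is missing.
* **w = 1** is the identity, so the raw map is just the 1-kb "scale".

A local-regression alternative (`loessSmooth()`) is provided: plain local
linear regression with tricube weights over the $q = \lceil\,\mathrm{span}
\cdot n\,\rceil$ nearest bins, negative fits clipped to zero. It is
implemented directly from that definition (rather than through
`stats::loess`) so that its contract — exact reproduction of linear
tracks, equality with a naive weighted-least-squares oracle — is testable
to 1e-9.

Segmentation for motif discovery (`splitHighLow()`) is deliberately
simple: per chromosome, bins strictly above the median rate are "high",
the rest "low", missing bins excluded. Ties at the median go to "low"
(making "higher than the median" literal); on continuous rates ties are
rare. The split is recomputed on each smoothed map, so discovery can be
run per scale.

# Motif discovery: an enumerative stand-in

The original analysis used MEME's EM-based differential enrichment. Every
motif that analysis recovered is a short tandem repeat (poly-A, poly-G,
CA, TA, GCA repeats), so `recmotifs` replaces the EM search with a
transparent, exactly testable procedure — **this is not MEME and is not
claimed to be**:

1. `enumerateCandidates()` generates all pure tandem repeats with unit
   length 1–3 and total length 8–12, deduplicated by canonical unit
   (the lexicographically smallest rotation of the minimal repeat unit or
   of its reverse complement — so CACACA…, ACACAC… and GTGTGT… are one
   candidate family). The default space has 42 candidates.
2. `differentialEnrichment()` counts, for each candidate, exact
   occurrences (both strands, overlaps allowed) whose start positions lie
   in high- vs low-labelled bins, and tests excess in "high" with a
   one-sided hypergeometric test on the 2x2 table of (match / non-match
   start positions) x (high / low). The counting unit is start positions,
   not bases.
3. E-values are Bonferroni-style, $E = p \times$ (number of candidates),
   echoing the "expected number of equally enriched motifs" semantics of
   motif-discovery E-values.

`buildConsensusSet()` then collapses discovered records across species
and scales: records with $E > 0.01$ at every scale are dropped; survivors
are grouped by canonical repeat unit; each group's consensus length is the
longest length representable in *both* species (the minimum over species
of the per-species maximum record length); groups seen in a single
species are kept but flagged. Probability-matrix motifs are first reduced
to strings by `simplifyMotif()` (most probable base per position, ties
broken alphabetically).

# Motif locations: exact-p scanning

`consensusToMatrix()` builds letter-probability matrices in two dialects:
**hard** (consensus base probability 1, others 0) and **soft** (0.97 /
0.01). `logOdds()` turns a matrix into bit scores against a 0-order
background with pseudocount regularization
$p' = (p + \epsilon\,bg_b)/(1+\epsilon)$, $\epsilon = 0.1$ by default —
the pseudocount is what keeps hard-matrix mismatches at a finite penalty.
The background (`estimateBackground()`) is the strand-symmetrized
empirical base frequency of the genome, zeros regularized to 1e-6.

P-values are exact, not approximated: `scorePvalueTable()` discretizes
per-column scores to 1e-3-bit steps and convolves the per-column score
distributions under the background, giving the complete null distribution
of window scores at that discretization; the scanner and the table share
the same discretized matrix, so every scanned window score hits the table
support exactly. The table is verified against brute-force enumeration of
all $4^L$ words (to $L = 8$) with max absolute difference below 1e-12.

`scanGenome()` scores every position of both strands (reverse strand =
reverse-complemented matrix at the same coordinates) and reports windows
with $p \le 10^{-4}$, overlaps and all; windows containing N are skipped.
The heavy window scoring is delegated to `Biostrings::matchPWM()` (C
code) with a margin below the passing threshold, after which every
candidate window is rescored exactly against the integer score matrix —
the reported hit set is identical to scoring every window directly, which
the test suite asserts against a naive full-scan oracle.

`computeQvalues()` attaches a q-score per occurrence: Benjamini–Hochberg
step-up over the occurrence p-values with denominator equal to the
**total number of scanned positions on both strands**, not the number of
reported occurrences — an occurrence that barely passed the threshold in
a 10-Mb scan is corrected against the ~2x10^7 tests actually performed.
The cited scanning tools use a q-value estimator of the same family; the
BH choice here is deterministic and oracle-checkable, and any difference
is a monotone rescaling that cannot change the ordering of density
tracks.

## A note on hard vs soft dialects

With an *exactly* uniform background both dialects rank windows purely by
mismatch count with identical null class probabilities, so their
occurrence location sets coincide exactly at any threshold — the package
asserts this on synthetic fixtures using the fixture's true background.
With an empirical (slightly non-uniform) background the two dialects
order words near the threshold differently, and for several of the
consensus motifs the $10^{-4}$ threshold sits almost exactly on a
mismatch-class boundary, so entire classes can flip in or out between
dialects. Concordance between dialects is therefore a property of the
threshold-vs-class geometry, not an identity; on real genomes the two
dialects should be expected to agree qualitatively, not match for match.

# Motif density: the q-discounted track

`densityTrack()` converts occurrences into the pipeline's central
statistic: per 1-kb bin, the sum of $1 - q$ over the occurrences starting
in that bin. High-confidence matches count fully; marginal matches are
discounted by their false-discovery-rate. Each occurrence is assigned to
exactly one bin by its start coordinate (boundary-spanning matches are
not split), which makes the statistic conservative in the best way:
the sum over all bins equals the genome-wide discounted count
(`totalCount()`) exactly, and remains so under `rebinTrack()`, which sums
consecutive bins into coarser windows (the trailing partial group is kept
as its own shorter bin). Windows are non-overlapping tiles; a sliding
(stride < width) variant is deliberately out of the default path because
tiled bins are what the correlation stage consumes.

# Association: the motif x stratum x scale grid

`associationGrid()` computes, for every motif density track and every
smoothing scale of the map, per-chromosome and pooled associations
between per-bin density and rate:

* **Spearman's rho** (`spearmanAssoc()`): average ranks for ties, rho =
  Pearson correlation of rank vectors; p from the $t$ approximation with
  $n-2$ df for $n \ge 10$ and from exact enumeration of all $n!$
  permutations below that. Constant input on either side leaves rho
  undefined (NA with a warning), never silently 0.
* **OLS** (`olsFit()`): `stats::lm` of rate on density with the two-sided
  slope $t$ test. A numerically perfect line has an unbounded statistic;
  its p is reported as the floor constant 1e-300 rather than 0 so that
  downstream log-transformations stay finite.

Pooling is by concatenation of per-chromosome bin vectors (no
per-chromosome weighting), present whenever at least two chromosomes
exist. Bins with missing rates are dropped pairwise inside each test. Raw
p-values are reported per cell; a BH-adjusted column across cells is
attached for convenience but no correction is imposed on the grid itself.
Mismatched bin sizes between a track and a map abort with a contract
error — rebinning is always explicit.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline's claims are validated.

`simulateLandscape()` produces one chromosome's binned rate track in two
empirical shapes. The *mel-like* shape is a plateau times a logistic
decay toward each end, $r(d) = R \cdot \mathrm{logit}^{-1}((d -
2s)/s)$ with $d$ the distance to the nearer chromosome end and $s$ the
decay length constant — a two-parameter rendering of a gradual
centromere/telomere decline. The *sim-like* shape is a flat plateau
dropping to $R/50$ within a fixed terminal zone — flat arms with sharp
ends. Multiplicative lognormal noise with mean 1 and coefficient of
variation `noiseCV` models the bin-to-bin noise of raw LD-based rate
estimates. Defaults, chosen once as realistic for the system being
emulated and not revisited: plateau 3 cM/Mb (a typical *Drosophila*
autosome-arm rate), terminal drop zone 1 Mb (comparable to the sharp
suppression regions of the flat-landscape species, and wide enough to
survive a 2,501-kb median window on a 5-Mb fixture arm), decay scale
1 Mb, noise CV 0.3 (no quantitative noise figure exists for the real raw
maps; 0.3 gives visibly noisy but structure-preserving tracks).

`plantMotifs()` draws a genome i.i.d. from a 0-order background over the
map's coordinates, then writes motif copies at per-bin Poisson counts
with intensity $(a + b\,r_i)$ per kb — $a$ the baseline density, $b$ the
coupling to the local rate. Copies are placed uniformly within their bin
and never overlap each other (rejection sampling); overlaps with chance
background matches are allowed and expected. Expected planted bases above
20% of the genome are refused as saturation. The truth list records
every planted interval; the plus-strand substring at a plus-strand truth
interval equals the motif exactly, which the suite asserts.

A single global seed expands into fixed per-component offsets (landscape
seed + 1, genome/planting seed + 2), recorded in the manifest, so
`generateFixture()`/`makeFixture()` are bit-reproducible from the
manifest alone.

**What the generator does not emulate**: linked selection and demography
(which bias real $\rho$ maps), sequence composition heterogeneity
(isochores, repeat expansions), genes and chromatin context, and
coalescent noise in haplotype-based rate estimation. Passing tests
demonstrate that the pipeline recovers the statistical structure it
assumes — Poisson-planted, rate-coupled repeat occurrences on an i.i.d.
background — not that real genomes satisfy those assumptions.

# Validation design and problem sizes

The suite validates three layers, at sizes chosen to keep a full run in
minutes on one core:

* **Oracles** — the p-value table against brute-force enumeration over
  all words ($L \le 8$, three backgrounds); the moving median against a
  per-window sort oracle on 10^5 bins for all five window sizes; BH
  q-scores and Spearman rho against hand-formula oracles on 10^3 random
  inputs; the scanner against naive full-window scoring on small genomes
  with N.
* **Recovery** — on 2 x 5 Mb sim-like fixtures with noise CV 0.3 and a
  CA-repeat planted at $a = 0.2$/kb, $b = 0.5$/kb per cM/Mb, the pooled
  1-kb Spearman rho is positive (p < 1e-3) with a sign consistent across
  all six smoothing scales in at least 19 of 20 seeds; with $b = 0$ the
  pooled |rho| stays below 0.05 and the slope test rejects at most
  2 of 20 times. Discovery retains the planted repeat family at
  $E \le 0.01$ in at least 19 of 20 seeds while an unplanted control
  repeat stays unretained.
* **Contracts** — conservation of density totals under rebinning,
  strand symmetry of the scan, threshold monotonicity, partition
  exactness of the median split, byte-identical regeneration of fixtures
  and pipeline runs.

# Known limitations

* The enumerative discovery only sees pure short tandem repeats; complex
  or gapped motifs are out of its candidate space by design.
* BH q-scores are a deterministic stand-in for the empirical-null
  q-value estimators used by some scanning tools; absolute q magnitudes
  may differ even though orderings agree.
* The exact permutation branch of the Spearman p is only used below
  n = 10 and grows factorially; it exists for correctness at toy sizes,
  not for production inference.
* `loessSmooth()` is O(n * q) per chromosome and is intended for maps of
  up to ~10^5 bins, not whole-genome base-resolution tracks.
* Anchor sets for rho normalization are user-supplied; the package does
  not ship marker tables.
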