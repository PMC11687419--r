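---
title: "crosspeak: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crosspeak: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspeak)
```

This vignette documents the statistical models behind each `crosspeak`
stage, the parameters that matter, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was open.

## Coordinates and interval algebra

All public functions speak GRanges (1-based, closed). BED and narrowPeak
files — 0-based, half-open — are converted at the reader/writer boundary, so
a read→write round trip is coordinate-exact. Two consequences of the
half-open convention are enforced throughout: intervals that merely touch do
not overlap, and `merge_union()` collapses only strictly overlapping runs
(`reduce(min.gapwidth = 0)`), never adjacent ones. Overlap requires at least
one shared base by default (`min_overlap = 1`, the BEDTools convention);
chromosome names are matched exactly, with no aliasing between naming
schemes, because silent aliasing hides genome-build mix-ups. Peak sets carry
an optional `genome_id` in their metadata and pairwise operations refuse to
combine sets whose labels differ.

## The cross-reactivity screen

An antibody that also binds a second factor produces peaks at that factor's
sites. Two complementary read-outs expose this:

* **Compendium overlap.** For a query set $Q$ and reference sets $R_1,
  \dots, R_m$ for the *other* factor, the profile reports $f_i = |\{q \in Q
  : q \cap R_i \neq \emptyset\}| / |Q|$ and the median over $i$. References
  are deliberately not matched by cell type: binding of the reference
  factor is assumed broadly conserved, and matching would shrink the
  compendium for no gain in specificity.
* **Classification.** With the same factor assayed by two antibodies,
  `classify_peaks(A, B)` anchors on A's intervals: `common` (A peaks
  overlapping B), `a_specific` (the rest of A), `b_specific` (B peaks
  overlapping no A peak). Anchoring makes the counts well-defined —
  `|common| + |a_specific| = |A|` exactly — at the cost of asymmetry, which
  is intentional: the question is always "what does antibody A report that
  antibody B does not".

`reproducible_peaks()` generalises replicate intersection: `all` keeps
first-replicate peaks supported by every other set, `any` is the merged
union, and `at_least_k` exposes the intermediate rules, since published
descriptions of replicate handling are often ambiguous between the two
extremes.

## Motif scanning

A PWM is stored as a $4 \times w$ probability matrix with background
$b$. Windows score $s(x) = \sum_j \log_2 p_j(x_j) / b(x_j)$ on both strands;
windows containing N are skipped. The score threshold for a requested null
tail probability $p$ is computed exactly by dynamic programming: column
scores are discretised to a grid (default granularity $10^{-3}$), the full
distribution of the window score under i.i.d. background is built by
convolution, and the threshold is the smallest grid score whose upper tail
is at most $p$. Scanning compares window scores on the same grid, so scan
and threshold cannot disagree at a boundary. The tests verify the DP
against exhaustive enumeration of all $4^w$ words for widths up to 8; at
width 8 a handful of words whose exact scores collide within one grid step
of the cut can land on either side — the price of the $10^{-3}$
discretisation, chosen as a cost/exactness trade-off.

Defaults follow common motif-matcher conventions: pseudocount 0.8 split by
background, log base 2, $p = 5 \times 10^{-5}$. All are explicit arguments.
With `pseudocount = 0`, zero-probability cells score $-\infty$ and are
treated as forbidden: windows containing them can never be hits, and their
probability mass is dropped from the null (the finite-score tail is
unaffected).

`pair_spacing()` measures, for each hit of motif A, the distance to the
nearest hit of motif B — edge-to-edge gap by default (0 when overlapping),
centre-to-centre behind a flag, since "N bp apart" in the literature rarely
states its convention. The modal distance, its frequency, and the fraction
of modal-distance pairs inside an annotated repeat are reported; a spacing
mode driven entirely by one repeat family is a strong hint of artifact.

## Circular-permutation enrichment

The null model for region/feature overlap shifts **all** intervals on a
chromosome by one shared offset $d \sim \mathrm{Uniform}\{0, \dots, L-1\}$,
modulo $L$; intervals spanning the origin are split into two wrapped pieces
that still count once through their parent. This preserves the number of
regions, the covered length, and — critically — the inter-interval spacing,
which resampling-style nulls destroy. The Monte-Carlo p-value uses the
$(1 + x)/(1 + n)$ estimator and never reaches 0. An exhaustive mode
enumerates every offset of a single-chromosome toy and serves as the exact
oracle for the stochastic mode in the tests; under independently random
regions and features the observed rate of $p \le 0.05$ across 400 synthetic
runs stays within binomial tolerance of nominal.

For loop-anchor analysis, `anchor_enrichment_table()` computes each peak
set's fold enrichment (observed anchors overlapping peaks over the
permutation null mean), then divides every fold by the mean fold of the
*reference-flagged* sets only, applying that normaliser retrospectively to
the non-reference rows. Fold counts anchors-overlapping-peaks (anchors are
the regions); the opposite orientation would count peaks and is not
equivalent when peaks outnumber anchors.

## Spike-in calibration

Per sample, IP efficiency is reads-in-peaks over total reads, separately
for target and spike-in genomes. The absolute factor is
$(\text{spike\%} / \text{spike reads in peaks}) /
(\mathrm{eff}_s / \mathrm{eff}_t)$; relative factors divide by the maximum.
The direction of the efficiency ratio is pinned as spike-over-target with
the reciprocal available by flag, because the phrase "normalised by the IP
ratio between spike-in and target" does not define a direction. Relative
factors are invariant to expressing the spike percentage as a percent or a
fraction and to any global rescaling of read counts; both invariances are
asserted in the tests, which is why the pinned direction is safe to expose.

## GC-bias diagnostic

Reads are binned by fragment GC fraction (20 equal bins over $[0,1]$ by
default; 5% bins resolve a strong skew without emptying the tails). The
expected distribution is estimated by placing fragments uniformly at random
with the observed reads' length distribution (200k draws by default) and
rescaling to the observed total, so $\sum \text{expected} = \sum
\text{observed}$ by construction. Bins in the far GC tails hold a handful
of expected reads at realistic depths; their ratios are reported but are
Poisson-dominated, so the flatness checks in the tests read only bins with
expected mass $\ge 1000$ at 50k reads, where the $\pm 10\%$ band is several
standard deviations wide.

## Peak-to-gene assignment

Transcripts are filtered to the coding/lncRNA types, allowed support levels
(1–5; entries with missing TSL are dropped), and expression strictly above
a threshold (default 0 — "expressed" is deliberately the weakest predicate,
and the cutoff is an argument). A transcript is a candidate for a peak when
its strand-aware TSS window (2 kb upstream, 1 kb downstream) overlaps the
peak **and** the TSS-to-peak-centre distance is strictly below 2 kb; the
centre is `start + floor(width/2)` with summit-based centring behind a
flag. Per gene, one (transcript, peak) pair survives the ranked criteria —
best support level, smallest distance, highest expression, maximum length —
with a final lexicographic transcript-id tie-break so the output is a total
order and byte-reproducible.

Peaks claimed by several same-strand genes are resolved by transcript-type
priority (protein_coding > lincRNA > other), then support level 1–2 over
3–5, then named-over-unnamed (a "canonical name" is a non-empty `gene_name`
differing from `gene_id`). With more than two same-strand candidates the
priority key is evaluated once and the unique maximum wins; a tie at the
top discards the tied genes (`ambiguous_same_strand`), and resolved losers
are logged as `outranked_same_strand` rather than silently dropped. A gene
that loses its best peak is not rescued by a second-best peak — one-shot
assignment keeps the procedure deterministic and auditable. Genes sharing a
peak from opposite strands are both kept and the peak is flagged as a
bidirectional promoter.

`conserved_sites()` pools all datasets into consensus regions and keeps
those supported by at least one dataset of every cell type. Adding a cell
type can only shrink the conserved set (up to the rare case where a new
dataset's peak bridges two consensus regions into one).

## ICA deconvolution

Bulk accessibility is modelled as a mixture of cell-type profiles. The
pipeline: median-of-ratios size factors (reference = per-peak geometric
mean over peaks with no zero), a variance-stabilising `log2(x + 1)`
transform (a documented, monotone surrogate for parametric VSTs whose
dispersion-trend fitting is out of scope), then FastICA (`ica::icafast`,
logcosh contrast, whitening on, seeded) on the pseudobulk matrix with the
algorithm's own column centring. Per-peak means across pseudobulk columns
are stored and used to centre bulk samples — the source columns are
zero-mean, so this centring convention cannot leak into the projection —
but they are *not* subtracted before the ICA itself: subtracting each
peak's row mean would make the pseudobulk columns sum to zero and lose one
rank, which forbids extracting k components for k clusters.

Each component is assigned to the cluster with the largest absolute mixing
weight and sign-flipped so that weight is positive; collisions are resolved
greedily best-weight-first and flagged. Bulk samples are normalised against
the model's stored reference, projected onto the source matrix by least
squares, and the component contributions unmixed into cluster
contributions. The default `method = "unmix"` solves the mixing-matrix
system under the unit-sum constraint — exact when a bulk sample truly is a
mixture of the pseudobulk profiles (and minimum-norm when k is below the
cluster count); `method = "map"` credits each component's contribution to
its mapped cluster directly, the cruder reading of the procedure. Negative
contributions are clipped to zero and rows renormalised to sum to one,
which is the orientation convention that makes the sign correction above
meaningful.

## The synthetic-data generators

Every generator is a pure function of a `sim_config` and derives a named
substream from the global seed, so adding randomness to one generator never
perturbs another's output. The defaults describe the study conditions used
throughout the tests and the acceptance script:

* a two-chromosome 700 kb genome at GC 0.45; 400 binding sites per factor,
  200 bp peaks, 50 uniform noise peaks per set, and a planted
  cross-reactive fraction of 0.5 — sites are placed on disjoint slots so
  truth labels partition the peaks unambiguously;
* motif instances sampled from the factor PWMs (dominant probability 0.85)
  stamped at site centres on a random strand — instances therefore carry
  realistic mismatches and a minority score below scanning thresholds,
  which enrichment statistics tolerate by design;
* reads drawn with acceptance probability $\propto \exp(\beta \cdot
  \mathrm{GC})$, the simplest monotone tilt that reproduces an
  observed/expected skew;
* an annotation fixture of ten hand-constructed scenario blocks covering
  every assignment rule, whose expected output is written down from the
  construction itself — never by running the assigner — so it is a genuine
  oracle;
* five cell types over 2000 peaks with gamma-distributed baselines,
  type-specific marker peaks boosted four-fold, negative-binomial per-cell
  counts (dispersion 10, the standard overdispersion model for
  accessibility counts), and twenty bulk samples mixed with Dirichlet(1)
  proportions.

What the generators do **not** emulate: fragment-level sequence errors,
nucleosome footprints, doublets or batch effects in single-cell counts, and
peak-calling noise (peaks are intervals by construction). Passing tests
therefore demonstrate the correctness of the algorithms under their stated
models, not robustness to every failure mode of real libraries.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the generators at the default
scales above (the pipeline tests use a reduced 200 kb genome with 120 sites
per factor, where every structural and determinism contract still binds).
All stochastic stages take explicit seeds; `run_pipeline()` reports are
byte-identical across reruns of the same configuration, and the acceptance
script's JSON is a pure function of `--seed`.

## Known limitations

* The exhaustive enrichment mode is restricted to single-chromosome
  genomes; multi-chromosome nulls are Monte-Carlo only.
* `estimate_proportions()` assumes the bulk peak set matches the model's;
  there is no partial-overlap mode (missing peaks are an error, not an
  imputation).
* The log2 VST flattens variance less aggressively than a parametric VST
  at very low counts; with the default simulated depths this has no
  measurable effect on recovery, but very shallow bulk libraries may
  deconvolve less accurately.
* Ortholog mapping between species and GO enrichment are out of scope;
  conserved-site construction stops at the coordinate level.
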