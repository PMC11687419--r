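# crosspeak

Tools for auditing ChIP-seq peak sets for antibody cross-reactivity and for
quantifying where — and in whom — a transcription factor actually binds.

## The problem

A polyclonal antibody that recognises an unintended second protein produces
peaks at the off-target's binding sites. Downstream, those phantom peaks
propagate into motif tables, chromatin-loop-anchor enrichments, and
regulatory models. `crosspeak` implements the computational screens that
expose such artifacts, plus the constructive analyses that survive them:

- **Compendium overlap profiling** — for a query peak set and a compendium
  of reference peak sets for a *different* factor, the per-reference
  fraction of query peaks overlapping reference peaks and its median. A
  clean antibody's median sits near the background co-occurrence rate; a
  cross-reacting one's is far above it.
- **Peak classification** — given the same factor assayed with two
  antibodies, peaks split into `common`, `A-specific`, and `B-specific`
  (anchored on A's intervals, so `|common| + |A-specific| = |A|`), plus
  reproducible-peak construction across replicates (`all` / `any` /
  `at_least_k` support rules).
- **Motif machinery** — PWM scanning with log2 odds scores
  s(x) = Σ_j log2(p_j(x_j)/bg(x_j)), an exact dynamic-programming null so
  the score threshold for a tail probability p is computed rather than
  guessed, and motif-pair spacing with repeat-overlap diagnostics.
- **Circular-permutation enrichment** — the null shifts all intervals on a
  chromosome by one shared random offset modulo its length (wrapped
  intervals split), preserving inter-interval spacing; p = (1 + #{null ≥
  obs})/(1 + n_perm). Includes the loop-anchor *relative* fold enrichment
  table (fold normalised by the mean over reference sets only).
- **Spike-in calibration** — absolute scaling factor
  (spike% / spike reads in peaks) / (eff_spike / eff_target) with
  eff = reads-in-peaks / total reads per genome; relative factors divide by
  the maximum.
- **GC-bias diagnostic** — observed vs expected read counts per GC bin,
  expected from uniformly placed fragments with the observed length
  distribution.
- **Peak-to-gene assignment** — strand-aware TSS windows (2 kb upstream /
  1 kb downstream), a strict TSS-to-peak-centre distance (< 2 kb), ranked
  transcript choice (support level, distance, expression, length) and
  same-strand conflict resolution (coding type > support level 1–2 > named
  gene), with bidirectional promoters kept for both strands.
- **Conserved binding sites** — consensus regions supported by at least one
  dataset of *every* cell type.
- **ICA deconvolution** — bulk chromatin accessibility unmixed into
  cell-type proportions using FastICA components learned on single-cell
  pseudobulk profiles (median-of-ratios normalisation, log2 VST, and
  least-squares projection of bulk samples onto the source matrix).

A synthetic-data module (`sim_config()`, `simulate_*`) generates every input
with known ground truth — planted cross-reactive fractions, motif-stamped
genomes, GC-tilted reads, annotation fixtures covering every assignment
rule, and Dirichlet bulk mixtures — so the whole pipeline is testable with
no downloads.

## Worked example

```r
library(crosspeak)

cfg <- sim_config(seed = 3, cross_reactive_fraction = 0.5, noise_peaks = 0)
ab  <- simulate_antibody_peaksets(cfg)
cls <- classify_peaks(ab$dirty_a, ab$clean_a)
cls$counts
#>     common a_specific b_specific
#>        400        194          0

planted <- ab$b_sites[ab$crossreactive_idx]
count_overlapping(planted, cls$a_specific) / length(planted)
#> [1] 1
```

The dirty antibody's set contains the 400 genuine factor-A sites (common
with the clean antibody) plus 194 peaks the clean antibody never sees — and
those dirty-specific peaks recover 100% of the planted off-target sites.
Running the full analysis:

```r
report <- run_pipeline(pipeline_config(seed = 1))
report
#> Pipeline report (seed 1 )
#>   cross-reactivity screen: median overlap clean 0.000, dirty 0.215
#>   classification: common 406, dirty-specific 242 (recovery 1.000)
#>   motif z: common~A 6.4, dirty-specific~B 5.8
#>   anchors: planted relative fold 1.75 (max reference 1.13)
#>   deconvolution: MAE 0.022, mean per-type r 0.994
```

Read: the dirty antibody overlaps the off-target compendium at a median of
21.5% while the clean one sits at 0%; the common peaks are enriched for the
target factor's motif (z = 6.4) while dirty-specific peaks carry the
off-target's motif (z = 5.8); a peak set planted at loop anchors tops the
relative-fold ranking; and bulk mixtures are deconvolved to within 0.022
mean absolute proportion error.

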