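---
title: "Calling differential chromatin accessibility: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential chromatin accessibility: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNase I preferentially cuts nucleosome-free DNA, so the genomic positions of
sequenced DNase tag 5' ends trace open chromatin. Given two tag libraries —
a vehicle control and a treatment that globally perturbs chromatin (an HDAC
inhibitor such as valproic acid) — we want (i) the regions of concentrated
cutting (DNase I hypersensitive site clusters, DHSS), (ii) which of them are
specific to one condition, and (iii) how the condition-specific regions
relate to promoters, repeat elements, enhancers and transcription-factor
motifs. A paired CAGE experiment (sequencing of capped mRNA 5' ends) gives
base-resolution transcription start sites and expression levels for the same
conditions.

## The window model

The genome is scanned at two scales: big windows of `big_window` = 10 kb
(step 9600 bp, i.e. consecutive windows overlap by 400 bp) each tiled by
small windows of `small_window` = 500 bp (step 400 bp, overlap 100 bp).
The big window serves as a *local background*: conditional on the `N` tags
observed in a big window and under local homogeneity, the count `n` in a
contained small window is Binomial(`N`, `p`) with `p = l/L`, the ratio of
small- to big-window length. When a mappability track is supplied, `l` and
`L` are *effective* lengths — the number of uniquely mappable positions in
the window — so that repeat-rich stretches where tags cannot be uniquely
placed do not deflate `p`.

Both conditions are pooled into one detection statistic. With library
totals `N_tot,veh` and `N_tot,vpa` and `r = N_tot,veh / N_tot,vpa`:

```
n_norm     = n_veh + r * n_vpa
E(n_norm)  = E(n_veh) + r * E(n_vpa)
sigma_norm = sqrt(sigma_veh^2 + r^2 * sigma_vpa^2)
z_norm     = (n_norm - E(n_norm)) / sigma_norm
```

with `E` and `sigma` the per-condition binomial moments. Scaling the
treated counts by `r` puts both libraries on the vehicle scale; the
variance combination assumes the two libraries are independent. When
`sigma_norm = 0` (an empty big window, or `p` in {0, 1}) the window carries
no evidence and is skipped rather than assigned `z = 0` — padding with
zeros would distort the calibration distribution below.

### Empirical FDR calibration

Analytic binomial tails are not trusted for the cutoff because windows are
overlapping, counts are discrete and the local-homogeneity assumption is
only approximate. Instead, alongside every real count a random count
`n_rand ~ Binomial(N, p)` is drawn per condition and combined into `z_rand`
by the identical formula. The `z_rand` population is the scan's own null.
The cutoff is the smallest value `c` on a 0.1-spaced grid over the observed
z range with

```
FDR(c) = #{z_rand >= c} / max(1, #{z_norm >= c}) <= 0.05
```

If no grid point qualifies (typical when the two distributions coincide,
i.e. there is no signal anywhere), no windows are called. The 0.1 grid
matches the coarse resolution at which such cutoffs are conventionally
reported; on genome-scale data a cutoff near 5.5 is a typical outcome, and
that value is available as a fixed fallback (`calibrate = FALSE`) when
calibration is deliberately disabled. The cutoff is data-dependent by
design, not a constant of the method.

Small windows with `z_norm >= c` that overlap are merged into DHSS
clusters. Merging is strict-overlap (abutting half-open intervals stay
separate): significant windows 400 bp apart share 100 bp, so any
contiguous run of significant windows merges, while separate sites do not.

### Differential classification

Cluster tag counts are re-counted over the merged span — summing window
counts would double-count the overlaps. Each cluster's table

```
[[ n_vpa, N_tot,vpa - n_vpa ],
 [ n_veh, N_tot,veh - n_veh ]]
```

is tested with a one-tailed Fisher's exact test in each direction, and
Benjamini-Hochberg correction is applied per direction across all clusters.
A cluster is `vpa_induced` if its VPA-direction q-value is below 0.05,
`vehicle_specific` if only the vehicle direction is, otherwise `shared`.
The two one-tailed tests on the same table cannot both be significant, so
the three statuses partition the clusters. The Fisher tail is evaluated in
log space: margins reach library totals in the tens of millions on real
data, far beyond direct factorial arithmetic.

## CAGE TSS clusters

CAGE tags keep their strand. Transcription start site clusters are
single-linkage: tags merge transitively whenever their spans overlap on the
same chromosome and strand, with zero gap tolerance — only true overlap
merges, which is the literal single-linkage construction on tag spans.
Expression is normalized to tags per million mapped tags (TPM,
`count * 1e6 / N_tot`), and clusters below 10 TPM in *both* samples are
discarded. Differential status (`induced` / `downregulated` /
`non_induced`) uses the same Fisher + per-direction BH machinery as the
DHSS clusters.

Promoter regions run from 1 kb upstream of the annotated TSS to the start
of the coding region, in transcript orientation, excluding the first coding
base. For non-coding models the coding-start endpoint is undefined; the
surrogate `[tss - 1000, tss + 500)` is used and flagged. Exon-1 tag ratios
count tag 5' ends (consistent with TSS semantics), and the TSS profile
averages DNase-tag TPM in 500-bp bins over ±5 kb around each TSS — the
figure range is configurable since nothing pins it down — with a two-pass
outlier rule: promoters on chrM are excluded, bin means are computed across
all remaining promoters, and any promoter with a bin above 10× that bin's
cross-promoter mean is dropped before the final average.

## Annotation and enrichment

* **Repeat assignment** — a region overlapping several repeats takes the
  one with the greatest shared length; ties break toward the longer repeat,
  then the leftmost, so assignment is deterministic. A separate
  "any-overlap" query answers class membership questions independent of the
  longest-overlap winner.
* **Genomic categories** use the fixed precedence promoter > gene body >
  intergenic; the underlying figures give no precedence rule, and this
  ordering matches the biological reading (a TSS inside another gene's
  intron is still a promoter).
* **Distances** are edge-to-edge gaps (overlap = 0), binned at < 1 kb
  (proximal), 1 kb – 1 Mb (semi-distal) and > 1 Mb (distal). Midpoint
  distances were the alternative; edge gaps were chosen because cluster
  widths vary over two orders of magnitude.
* **Enhancer overlap** is tested against an analytic uniform-placement
  null: the probability that a random interval of the mean query length
  overlaps the merged enhancer set is, per chromosome,
  `min(chrom_len, coverage + n_enh * (mean_len - 1)) / genome_len`, summed
  and capped at 1; the observed overlap count is then an upper-tail
  binomial. A seeded randomization alternative (`distance_ks_vs_random`)
  compares nearest-distance distributions with a two-sample
  Kolmogorov-Smirnov test, with random intervals resampled from the query
  length distribution.

## Motif scanning

JASPAR-format count matrices become log-odds matrices with a
background-split pseudocount (total 0.8 per column, a common toolkit
default; no value is dictated by the analyses this package reproduces, so
it is a parameter). The "% similarity" scale is the relative score
`(score - min) / (max - min)` over the attainable score range, thresholded
at 0.8. Windows containing `N` are skipped; both strands are scanned;
overlapping hits all count (no masking rule is imposed). Group
over-representation compares per-region hit counts with a one-tailed
Wilcoxon rank-sum test. Hit counts are raw, not length-normalized,
matching the match-count comparison convention; a caveat is that group
length distributions should be similar, and region groups produced by the
caller are.

## Statistical primitives

All tests the pipeline relies on are implemented in the package and
cross-checked against independent oracles in the test suite:

* Fisher's exact test: log-space hypergeometric tail (`dhyper(log = TRUE)`
  + log-sum-exp); exact down to underflow, no 2.2e-16 flooring.
* Benjamini-Hochberg: the step-up `q_(i) = min_{j>=i} p_(j) m / j`.
* Wilcoxon rank-sum: exact enumeration of rank assignments for pooled
  samples of at most 12 without ties (deterministic for fixtures), else the
  normal approximation with tie and continuity corrections.
* Two-sample KS: exact `D`, asymptotic Kolmogorov p at effective size
  `n_x n_y / (n_x + n_y)`.
* Welch's t with Satterthwaite degrees of freedom; the pooled-variance
  variant is exposed (`var_equal = TRUE`) because figure-level t tests do
  not always state the variance assumption — the unequal-variance form is
  the default everywhere.
* qPCR accessibility: delta-Ct = Ct(digested) − Ct(undigested), compared
  between conditions by Welch's t.

## The synthetic data generator

`sim_config()` defines a toy study whose defaults are the package's
standing test conditions: 3 chromosomes × 2 Mb; 200,000 DNase tags and
100,000 CAGE tags per library; 90% of the genome mappable (100-bp blocks
dropped independently); 300 planted accessible regions of 500 bp at 10×
the background cutting rate in both conditions, a random 25% of which get
a further 5× in the VPA library only; 120 non-overlapping gene models
(3–8 exons, ~90% coding) whose promoters receive 90% of CAGE tags, sharp
promoters as Normal(TSS, 20 bp) and broad as Uniform(±150 bp) in equal
shares, with 10% of promoters 8-fold up-regulated in VPA and a symmetric
10% down; 3000 repeats mixed 55/25/15/5% SINE/LINE/LTR/DNA, 30% of SINEs
carrying an exact embedded motif consensus; 150 intergenic enhancers.
Planted region width (500 bp), repeat widths (~150/600/400/300 bp by
class), the enhancer count and the 10% down-regulated fraction are the
package's own choices at realistic magnitudes for the emulated data type;
everything else follows the stated study conditions. At this scale the
full pipeline runs in well under a minute.

Backgrounds are homogeneous Poisson on the mappable genome. Real DNase
data has covariate structure (GC, chromatin domains, copy number) that the
generator does not model; the caller's big-window local background is what
makes the homogeneity assumption mild, and passing the recovery tests
demonstrates correctness of the machinery, not robustness to every real
covariate. Tag positions are 5'-end only — no fragment-length model —
matching the caller's counting rule. Because both libraries are sampled at
a fixed total while the VPA intensity carries extra mass in induced
regions, non-induced regions are mildly *diluted* in the VPA library; a
small number of `vehicle_specific` calls on synthetic data is therefore
expected and mirrors the dilution phenomenon seen in the motivating
experiment, and the acceptance analyses score only the `vpa_induced`
direction against truth. Likewise, planted accessible regions are placed
independently of repeats and enhancers, so bundle-level enrichment tables
behave as nulls; positive-signal behavior of the enrichment and motif
statistics is validated by dedicated planted constructions in the test
suite. One consequence of the toy scale worth knowing: at 100,000 CAGE
tags per library a single tag is already 10 TPM, so the expression floor
retains singleton background clusters; they are classified `non_induced`
and are harmless, but the cluster count is dominated by them, unlike at
genome scale.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally (BED-native); 1-based
  formats are converted at the boundary. Chromosome names match verbatim.
* Window tiling is phase-0 (multiples of the step); each small window is
  provably contained in exactly one big window under the default geometry,
  and the property is tested. Windows truncated at a chromosome end are
  kept if at least one step (400 bp) long, else dropped.
* Tag membership is by 5'-end position; DNase tag strand is ignored
  (cut sites are strandless events), CAGE strand is kept.
* `z_rand` draws are per condition and combined exactly like the real
  statistic; draws are seeded, and changing only the seed changes `z_rand`
  but never `z_norm`.
* Modal peak positions break ties toward the leftmost base; repeat
  assignment ties break toward longer, then leftmost repeats.
* Degenerate Fisher margins return p = 1; empty samples are argument
  errors for the rank and distribution tests; a motif whose score range is
  a single point is rejected.

## Problem sizes and runtime

The test suite and the acceptance analyses run at the default synthetic
scale: 20 null replicates for cutoff calibration (~15,000 windows each),
10 planted replicates for differential-call FDR, one full-scale bundle for
recovery and byte-stability of the pipeline's eleven output tables, and
brute-force oracle comparisons at 300–1000 random instances per primitive.
These sizes keep the whole suite in the low minutes on one core while
leaving every statistical check adequately powered.

## Known limitations

* No replicate modeling: each condition is one pooled library, as in the
  emulated design; biological variance is not separable from counting
  noise.
* The binomial local-background model ignores overdispersion beyond the
  big-window scale.
* Single-linkage CAGE clustering can chain adjacent promoters bridged by
  stray tags; no peak-shape deconvolution is attempted.
* The enhancer-overlap null assumes uniform placement across the mappable
  genome; GC- or annotation-matched nulls are out of scope.
* GTF gene models and RepeatMasker `.out` files are not parsed; gene
  models enter as BED12 and repeats as a BED-plus-class table.
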