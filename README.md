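# dhssremodel

Differential chromatin accessibility analysis from DNase I hypersensitivity
(DHSS) and CAGE tag libraries of two conditions — e.g. a vehicle control
versus an HDAC-inhibitor treatment that globally remodels chromatin in
brain tissue. The package is aimed at regulatory-genomics analysts who have
uniquely mapped tag 5'-end positions (BED), a gene annotation and repeat /
enhancer region sets, and want condition-specific accessible regions plus
the standard downstream enrichment analyses, with every statistical step
reproducible and testable on synthetic data with known ground truth.

## The model

The genome is scanned in 10 kb **big windows** (step 9600 bp), each tiled
by 500 bp **small windows** (step 400 bp). Within a big window holding `N`
tags, a small window's count `n` is modeled as Binomial(`N`, `p = l/L`)
where `l` and `L` are the *effective* (uniquely mappable) window lengths.
The two conditions are pooled into one normalized score with
`r = N_tot,veh / N_tot,VPA`:

    z_norm = (n_veh + r·n_vpa − E(n_veh) − r·E(n_vpa)) / sqrt(σ_veh² + r²·σ_vpa²)

Alongside each real count a random draw `n_rand ~ Binomial(N, p)` yields a
matched null score `z_rand`; the detection cutoff is the smallest `c` with
`#{z_rand ≥ c} / #{z_norm ≥ c} ≤ 0.05` — an empirical 5% FDR that adapts
to the data instead of trusting analytic tails. Significant windows merge
into DHSS clusters, whose recounted tags are tested per cluster with
one-tailed Fisher's exact tests (both directions, Benjamini-Hochberg per
direction, q < 0.05) to label them `vpa_induced`, `vehicle_specific` or
`shared`. CAGE tags are clustered into single-linkage TSS clusters,
filtered at ≥ 10 TPM in either sample, and classified the same way.
Downstream modules annotate clusters against promoters, repeats (longest
overlap wins), enhancers (analytic binomial and distance-KS nulls) and
position-weight-matrix motifs at 80% relative score.

## Worked example

Generate a synthetic study (3 × 2 Mb genome, 200k tags per library,
300 planted accessible regions of which a quarter are VPA-enriched 5-fold)
and call differential DHSS clusters:

```r
library(dhssremodel)

cfg    <- sim_config(seed = 42)
bundle <- simulate_bundle(cfg, "sim_bundle")
res    <- call_dhss(bundle$dhss$veh, bundle$dhss$vpa,
                    bundle$genome$chrom_sizes, bundle$genome$mappability,
                    seed = 7)
res$z_cutoff
#> [1] 3.2
table(res$clusters$status)
#>           shared vehicle_specific      vpa_induced
#>              212               21               75
head(subset(res$clusters, status == "vpa_induced"), 3)[,
     c("chrom", "start", "end", "n_veh", "n_vpa", "max_z", "q_vpa")]
#>    chrom  start    end n_veh n_vpa    max_z        q_vpa
#> 1   chr1  18400  19300   119   511 45.58061 1.597314e-58
#> 2   chr1  47200  48500   173   609 84.80644 1.633001e-57
#> 11  chr1 188000 188900   153   589 68.03208 7.327193e-61
```

The calibrated cutoff (3.2 here) is a data-dependent outcome of the
z_rand calibration. 75 clusters are called VPA-induced — the generator
planted 75 — each with several-fold more VPA than vehicle tags at
negligible q-values; the 21 `vehicle_specific` calls reflect the dilution
of non-induced regions in a fixed-size treated library. Region-set
enrichment uses the same log-space Fisher machinery; for example, a
contingency of 391/1209 focal hits against 7500/1,500,000 background hits
gives

```r
overlap_fisher(391, 1209, 7500, 1500000)
#> odds ratio: 95.1   p: 0 (below double-precision underflow, i.e. < 1e-300)
```

`run_all(bundle_paths("sim_bundle"), "out", seed = 1)` executes every
stage and writes eleven TSV/BED summary tables (cluster calls, Venn
counts, promoter overlap, exon-1 ratios, distance bins, repeat assignment,
motif comparison, overlap tests, TSS profile, qPCR statistics) plus a run
log; reruns with the same inputs and seed are byte-identical.

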