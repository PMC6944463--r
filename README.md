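# occuclass

Comparative regulatory genomics for a wild-type vs. mutant
transcription factor: which promoters lose occupancy when the factor is
mutated, what distinguishes the lost binding sites, and which expression
changes are direct consequences of that loss.

The package is aimed at analysts of paired ChIP-seq + RNA-seq designs of
the kind used to dissect selective DNA-binding mutations (the motivating
case is the disease-associated THAP11 F80L substitution, which removes the
factor from a subset of its promoters without creating new sites). It
implements the full pipeline as tested, composable functions, plus a
seeded synthetic-data generator with complete ground truth so every stage
can be validated by recovery.

## What it computes

**Peak detection.** Per 300-bp bin, a one-sided exact binomial test of the
IP count against `n = ip + input` with success probability
`T_IP / (T_IP + T_input)`, BH-adjusted; runs of enriched bins (`q ≤ 0.05`)
merge into summit-bearing peaks. Externally called narrowPeak files can be
ingested instead and filtered by intersection with enriched bins.

**Peak score.** Per condition,
`score = log2((ip+1)/(T_IP·w)) − log2((input+1)/(T_input·w))` —
the IP/input log2 contrast after per-sample library-size (and width)
normalization.

**Classification.** Peaks are TSS-associated if any nucleotide falls
within ±250 bp of a TSS; wild-type peaks split into `common` (overlap a
mutant peak) and `F80L_absent` (no overlap), unmatched mutant peaks are
`F80L_only`.

**Motif analysis.** Log-odds scanning of a 22-bp bipartite motif
(5' `CTGGGA` / 3' `TGTAGT` anchors) on both strands; per-peak nearest hit
within ±1000 bp of the summit; per-category consensus matrices with
per-position information content `IC_j = 2 + Σ_b p_bj log2 p_bj` and a
5'-half vs 3'-half contrast.

**Expression.** RPKM normalization, the expressed-gene filter (RPKM < 1.2
in all samples discards), a calibrated negative-binomial Wald test for
2 + 2 designs (median-of-ratios size factors, trend-floored moment
dispersions), and up/down calls at `adj p ≤ 0.05`, `|log2FC| ≥ 0.5`.

**Direct targets.** Changing genes linked to TSS-associated `F80L_absent`
peaks, ranked by fold change within direction.

## Worked example

Simulate a small two-condition experiment and run the whole analysis:

```r
library(occuclass)

cfg <- synthetic_config(genome_length = 5e5, n_genes = 100,
                        n_bound_promoters = 50, depth_ip = 5e4,
                        depth_input = 5e4, n_direct_down = 15,
                        n_indirect = 12, n_silent = 10, seed = 42)
res <- run_synthetic_pipeline(cfg)

print(res$truth)
#> Synthetic occupancy experiment (seed 42)
#>   genome: 5e+05 bp; 100 genes; 50 bound promoters
#>   site classes: no_motif=9, strong=21, weak=20

str(res$summary)
#> $ n_peaks_wt                 : int 51
#> $ n_peaks_mut                : int 26
#> $ n_tss_common               : int 25
#> $ n_tss_f80l_absent          : int 25
#> $ f80l_absent_no_tam_fraction: num 0.24
#> $ common_no_tam_fraction     : num 0.08
#> $ n_genes_down               : int 15
#> $ n_genes_up                 : int 3
#> $ n_direct_targets_down      : int 13
#> $ n_direct_targets_up        : int 0
```

Reading: 51 wild-type peaks were called, of which half (the weak-3' and
motif-less sites) vanish in the mutant; a quarter of the lost,
TSS-associated peaks have no nearby motif instance versus 8% of the
retained ones; and 13 of the 15 planted occupancy-coupled genes are
recovered as direct targets, none spuriously up.

The motif-level signature — 3'-half consensus degradation among lost
peaks with an intact 5' half — comes out of the consensus contrast:

```r
round(unlist(res$ic_contrast[c("delta5", "delta3")]), 3)
#> delta5 delta3
#>  0.069  0.808
```

The top direct targets, ranked by fold change:

```r
head(res$direct_targets[, c("gene_id", "direction", "log2fc", "adj_p")], 3)
#>   gene_id direction    log2fc        adj_p
#> 1   g0020      down -2.014938 1.621048e-03
#> 2   g0030      down -1.975463 2.188126e-12
#> 3   g0094      down -1.824452 5.992696e-08
```

A thin CLI over the same functions is installed as `exec/occuclass`
(`simulate`, `callpeaks`, `express`, `integrate`, `acceptance`).

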