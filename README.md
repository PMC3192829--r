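# glyconet

Reconstruction of carbon-utilization ("glycobiome") gene co-expression
networks from a substrate × growth-phase two-color microarray design.

Thermophilic anaerobes such as *Thermoanaerobacter* ferment both hexoses
and pentoses to ethanol, and the transcriptional organization of their
sugar catabolism can be read out of a modest transcriptome set when the
experiment is designed for it: a handful of carbon substrates (glucose,
xylose, fructose, cellobiose, and an equimolar glucose+xylose mixture)
crossed with growth phases (early, mid, late exponential), each in three
biological replicates — 33 arrays in total. `glyconet` implements the
complete analysis path from such a design to an annotated module map, and
ships a synthetic-data generator that emulates the design with planted
ground truth, so that every stage of the pipeline is testable end to end.

## What the pipeline computes

1. **Differential expression.** Per gene and condition, the replicate mean
   log₂ ratio (sample vs. common genomic-DNA reference), its standard
   deviation, and the replicate Z score `z = mean / (sd / √n)`. A gene is
   called significant when `|log₂R| ≥ 1.0` and `|Z| ≥ 2.0` with at least
   two quantifiable replicates (spots with signal-to-noise ratio < 2 are
   masked). Condition-vs-condition contrasts use the Welch form. A
   peak-phase classifier summarizes each gene's early/mid/late dynamics.
2. **Correlation network with an RMT-selected cutoff.** Pairwise-complete
   Pearson correlations `r_ij` feed a thresholded adjacency `A(τ)`. For
   each candidate τ, the nearest-neighbour spacing distribution (NNSD) of
   the unfolded eigenvalues of `A(τ)` is tested by χ² against the Poisson
   law `P(s) = e^(−s)` and the Wigner surmise
   `P(s) = (πs/2)·e^(−πs²/4)`. The selected cutoff is the smallest τ at
   which the spectrum becomes (and stays) Poisson — the random-matrix
   signature of a system that has decomposed into independent modular
   blocks. The reported network connects gene pairs with `r ≥ τ`.
3. **Modules.** Fast greedy modularity optimization (agglomerative
   merging by the largest gain in `Q = Σ_c [l_c/m − (d_c/2m)²]`, with a
   deterministic tie-break), keeping communities of five or more genes as
   modules.
4. **Reports.** Module COG-category composition (with the "top-3
   categories cover X%" arithmetic), hub tables ranked by degree,
   inter-module link counts and standalone-module flags, first-neighbour
   subnetworks, and machine-readable run reports, plus TSV/SIF/GML
   exports for graph viewers.

The synthetic generator plants modules as condition-responsive
common-factor blocks: member genes share, per sample, a latent factor and
a mean-shift profile, with the factor loading calibrated so the expected
pairwise Pearson correlation across the 33-sample axis equals the
requested value. Background genes and negative-control probes are
independent noise. The `paper_preset_spec()` preset carries the scale of
the real array: 2322 genes, 20 negative controls, 13 planted modules of
614 genes (largest 138).

## Worked example

```r
library(glyconet)

spec <- synthetic_spec(
  n_genes = 300,
  modules = list(
    planted_module("A", 30, responsive = data.frame(substrate = "xylose",
                                                    phase = "mid")),
    planted_module("B", 20, responsive = data.frame(substrate = "glucose",
                                                    phase = "mid"))),
  n_negative_controls = 5, snr_dropout_rate = 0.05, seed = 7)
sim <- simulate_expression(spec)
sim$expr
#> expr_matrix: 300 genes x 33 samples (11 conditions)
#>   masked cells: 509 (5.1%); SNR table: present (snr_min = 2)

calls <- summarize_contrast(sim$expr, c("xylose", "mid"))
count_significant(calls)
#>   n_up n_down
#>     30      0

cm  <- pearson_matrix(sim$expr)
net <- build_network(cm, 0.9)
net
#> coexpr_network: 50 nodes, 621 edges (tau = 0.90, positive mode)

part <- fast_greedy_modules(net)
part
#> module_partition: Q = 0.4196, 2 modules (>= 5 genes), 0 unassigned
#>   sizes: 30, 20
partition_quality(part, sim$truth)
#> $ari
#> [1] 1
#> $recovered_fraction
#> [1] 1
```

The 30 genes of module A are exactly the genes called upregulated under
xylose at mid phase (`n_up = 30`), the network at τ = 0.9 contains
exactly the 50 planted module members, and the detected partition matches
the planted one (adjusted Rand index 1).

The `analysis/` directory holds the same workflow at full preset scale as
numbered drivers (`01_simulate.R` … `05_report.R`); each writes its
tables under `results/`.

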