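---
title: "Methods: RMT-thresholded co-expression networks for a substrate x phase microarray design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RMT-thresholded co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyconet)
```

# The data model

`glyconet` analyzes normalized two-color microarray log~2~ ratios: each
value is log~2~ of the Cy5 (sample cDNA) over Cy3 (common genomic-DNA
reference) intensity for one gene on one array. Because every array is
hybridized against the same genomic reference, a condition's expression
level is summarized directly by the mean log-ratio over its biological
replicates, and conditions can be contrasted as differences of means.
Per-spot signal-to-noise ratios accompany the values where available;
spots with SNR < 2 are treated as not quantifiable and are excluded from
every downstream summary (the `snr_min = 2` cutoff is exposed but rarely
worth changing: it is the conventional quantifiability line for spotted
arrays).

The reference design has 33 arrays: glucose, xylose, fructose and
cellobiose at mid-exponential phase, an equimolar glucose+xylose
condition at mid phase, and early/mid/late time courses for glucose,
xylose and glucose+xylose — 11 distinct (substrate, phase) conditions
with three biological replicates each, the mid-phase conditions being
shared between the substrate comparison and the time courses.

# Differential expression

For a condition with replicate values $x_1,\dots,x_n$ (unmasked spots
only), the pipeline reports the mean $\bar x$, the sample standard
deviation $s$ ($n-1$ denominator), and the replicate Z score
$z = \bar x / (s/\sqrt{n})$. A gene is *significant* when
$|\bar x| \ge 1.0$ (a two-fold change) **and** $|z| \ge 2.0$ **and** at
least two replicates are quantifiable. Both cutoffs are parameters
(`r_min`, `z_min`); their defaults are the filter the assay family
conventionally applies, and the significant set is monotone in both (a
property the test suite exercises).

Two points were genuinely open and are resolved as follows:

* **Z-score definition.** The Z score is computed per gene from the
  biological replicates of the condition — a one-sample Z of the
  log-ratio against 0. This is the simplest statistic consistent with
  using $|Z|$ as a replicate-reliability filter alongside the fold-change
  cutoff. Per-array variance models are deliberately out of scope; so is
  any multiple-testing correction (the filter is a screen, not an
  inference).
* **Condition-vs-condition contrasts** (e.g. xylose vs glucose at mid
  phase) use the difference of condition means with the Welch standard
  error $\sqrt{s_1^2/n_1 + s_2^2/n_2}$, since each condition's log-ratios
  are already expressed against the common reference.

Phase dynamics are summarized by `peak_phase()`: the phase with the
largest replicate-mean, `undetermined` when fewer than two phases are
quantifiable or the top two means are within `tie_eps = 1e-9` (only
exact ties are ties on continuous data — the tolerance exists to absorb
floating-point noise, not biology).

# The synthetic-data generator

The generator is first-class: it defines the conditions under which the
pipeline's recovery claims are tested.

Each planted module $m$ has a size, a set of responsive conditions, a
mean shift $\mu_m$ (log~2~ units), and a target within-module Pearson
correlation $\rho_m$. A member gene's value at sample $t$ is

$$ x_{gt} = \mu_m \, \mathbf{1}[\text{cond}(t) \in R_m] \; + \; a_m f_{mt} \; + \; e_{gt}, $$

with a latent factor $f_{mt} \sim N(0,1)$ shared by all members at that
sample, unique noise $e_{gt} \sim N(0, u_m^2)$, and
$a_m^2 + u_m^2 = \sigma^2$ fixed at `noise_sd`$^2$. The loading is
calibrated so that the *total* expected pairwise correlation across the
sample axis — mean-shift profile included — equals $\rho_m$:
$a_m^2 = \rho_m (V_p + \sigma^2) - V_p$, where $V_p$ is the variance of
the shift profile over the design. When the profile alone already
induces more correlation than requested ($V_p/(V_p+\sigma^2) > \rho_m$),
the combination is infeasible and the generator refuses it rather than
silently overshooting. Background genes and the negative-control probes
are independent $N(0, \sigma^2)$ noise.

Defaults, and why:

* `noise_sd = 0.25` log~2~ units of replicate scatter. The source assay
  family does not publish its array noise; 0.25 is a typical
  between-replicate SD for spotted two-color arrays after normalization,
  and is small enough that a 2-unit shift is unambiguous while large
  enough that the Z filter is doing real work.
* `mean_shift = 2.0` (a four-fold change) for condition-responsive
  modules — comfortably past the two-fold cutoff without being
  caricatural.
* `within_correlation = 0.95`, matching the regime the network method is
  built for (reported co-expression cutoffs sit near 0.94).
* `snr_dropout_rate = 0.05`: a few percent of spots on a good array are
  unquantifiable.
* Hubs: each preset module's first member gets its unique-noise SD
  scaled by `hub_noise_scale = 0.3`, raising its correlation with every
  peer (capped at $\sqrt{\rho_m}$) so that it out-connects them once the
  cutoff begins to thin the module's edges.
* The `paper_preset_spec()` catalogue: 13 modules with sizes 138, 80,
  65, 55, 50, 45, 40, 35, 30, 25, 20, 16, 15 (sum 614) on a 2322-gene
  array with 20 negative controls — the scale of the real network
  (614 genes in thirteen modules, largest 138) without any claim to
  reproduce the real partition. Modules 1–11 respond to one condition
  each; modules 12–13 are constitutively co-expressed, so that distinct
  modules do not share mean-shift profiles (shared profiles would plant
  cross-module correlation as a side effect).

What the generator deliberately does **not** emulate: dye bias, spatial
artifacts, probe-sequence effects, and — most consequentially —
*correlated background*. Real background genes share regulation and
array-level effects, giving the genuine correlation distribution a long
upper tail; synthetic background genes are independent, so their
correlations are pure sampling noise of $n = 33$ pairs. Passing recovery
tests on this generator therefore demonstrates the pipeline's
correctness on cleanly separated structure, not its behavior on the
murkier real distribution (see the threshold-selection discussion
below).

# Correlation and the RMT threshold

Correlations are pairwise-complete Pearson coefficients over mutually
unmasked samples. Pairs with fewer than `min_pairs = 9` shared samples
(about a quarter of the design) are unusable: with fewer points, sample
correlations near a 0.9+ cutoff are dominated by small-sample noise.
Zero-variance genes are likewise flagged rather than propagating NaNs.

For each candidate cutoff $\tau$ the scan forms the weighted adjacency
$A_{ij}(\tau) = r_{ij}\,\mathbf{1}[|r_{ij}| \ge \tau]$ (zero diagonal)
and computes its eigenvalue spectrum. Isolated nodes are dropped before
the eigendecomposition: they contribute exact-zero eigenvalues that the
degeneracy-removal step would collapse anyway, so the submatrix spectrum
is exact, not an approximation. Thresholding on $|r|$ is the scan
default (spectral statistics concern magnitude structure); the reported
network uses positive mode, the convention for co-expression displays.
Whether the binarized adjacency should be used instead is not settled in
the source methodology; the weighted form is the default and
`binary = TRUE` is exposed.

The nearest-neighbour spacing distribution is computed as:

1. sort eigenvalues, collapse near-degenerate values with gaps below
   $10^{-8}$ (this also absorbs the rank deficiency of correlation
   submatrices larger than the sample count, which otherwise produces
   spikes of identical eigenvalues);
2. *unfold* through a monotone (Hyman) cubic spline fitted to every
   ~20th point of the empirical cumulative spectral distribution —
   roughly $n/20$ knots, enough smoothing to estimate the local density
   without tracking fluctuations — mapping eigenvalue $e_i$ to
   $\hat e_i = N \hat F(e_i)$ so the mean spacing is 1;
3. bin the spacings on $[0, 3]$ into 20 equal bins, merge bins with
   expected count below 5 from the right, and compute χ² against
   Poisson $P(s) = e^{-s}$ and the Wigner surmise
   $P(s) = \frac{\pi s}{2} e^{-\pi s^2/4}$, each with
   $\text{bins} - 1$ degrees of freedom.

A spectrum needs at least `min_eigs = 100` distinct eigenvalues to be
evaluated; smaller candidates are recorded but not judged.

**Selection rule.** The selected $\tau$ is the smallest candidate whose
spacing law is accepted as Poisson ($p >$ `p_accept` $= 10^{-3}$) *and
stays accepted* over the next `stability_window = 5` evaluable
candidates. The persistence window implements the rule's purpose — an
isolated false acceptance cannot be selected — without its literal
all-larger-candidates form, which proved brittle: a single marginal χ²
rejection at the top of the grid (where the surviving spectrum is
smallest and the test noisiest) would otherwise veto a uniform
acceptance plateau and force the fallback. If no candidate qualifies,
the scan returns the largest grid value with a warning flag.

**Grid choice.** The scan is meaningful only if the grid starts inside
the GOE regime. For 33-sample null correlations the background subgraph
percolates (and mixes the spectrum into Wigner statistics) only up to
$\tau \approx 0.55$–$0.60$, so the preset analyses scan 0.50–0.98 in
steps of 0.01. The narrower conventional default (0.70–0.99) is kept on
the function signature for data whose background correlations are
stronger.

**A known, measured limitation.** On the synthetic preset the
GOE-to-Poisson transition tracks the *percolation* of the background
correlation subgraph, not the boundary between the within-module and
background correlation distributions: once background noise edges
fragment (around $\tau \approx 0.6$ at $n = 33$), the thresholded matrix
is already a superposition of independent module blocks and its spacing
law is Poisson, even though stray background correlations reach far
higher. With independently generated background, those two landmarks are
separated by the wide empty gap between the null tail and the planted
0.95 correlation bulk; in real data, whose background correlation tail
reaches up to the module bulk, the two coincide — which is precisely the
regime the RMT recipe was designed for. The acceptance suite measures
this distance honestly on the preset (it computes the
misclassification-minimizing cutoff between the two empirical pair
distributions and compares it to the scan's selection) and the
corresponding check documents the discrepancy rather than papering over
it.

# Module detection

Fast greedy modularity optimization is implemented in-package: starting
from singleton communities, repeatedly merge the connected pair with the
largest $\Delta Q = l_{ij}/m - d_i d_j / (2m^2)$ until no merge
increases $Q$. Edges are unweighted for $Q$ (module descriptions count
links, not weights). Ties in $\Delta Q$ (within $10^{-12}$) are broken
by the pair whose canonical labels — each community's smallest member
gene id — sort lexicographically lowest, making the partition
deterministic. The incremental $Q$ bookkeeping is required to agree with
a from-scratch recomputation to $10^{-12}$, and on disjoint unions of
cliques the algorithm must return exactly the clique partition that
exhaustive search over all set partitions confirms is the maximizer;
both are enforced by tests, with igraph's independent fast-greedy
implementation as a cross-check on random graphs (greedy merge orders
may differ under ties, so the cross-check compares achieved $Q$, not
labels).

Communities with fewer than `min_module_size = 5` members ("more than
four genes") are reported as unassigned, and surviving modules are
numbered by decreasing size with ties on the smallest member id — the
numbering is structural, not matched to any published module labels.
Partition recovery against planted truth uses the adjusted Rand index
(via `mclust`) restricted to planted members present in the network,
alongside the fraction of planted members landing in any reported
module.

# Reporting conventions

* Percentages are reported to one decimal; the integer display style
  rounds the one-decimal value half away from zero (so a 36.2% top-3
  COG share displays as "36%", and 39.1% stays 39.1%).
* Module interaction requires at least one edge; a module with no
  inter-module edge is *standalone*.
* Hub tables rank by degree, ties by gene id, truncated to 23 entries by
  default. With strongly heterogeneous module sizes a global top list is
  dominated by the largest module's members (degree ranges of
  near-complete blocks do not interleave), so planted-hub recovery is
  evaluated within modules: at a cutoff on the shoulder of the
  within-module correlation distribution, each planted hub should be the
  top-degree gene of its own module.
* The genome-percentage denominator is the number of non-control genes
  on the array, configurable where a different genome size is
  appropriate.
* Run reports carry the package version, seed and a configuration hash;
  two runs with the same seed and configuration are byte-identical
  except for timestamp lines (including the timestamp igraph embeds in
  GML `Creator` headers).

# Problem sizes and runtime

The shipped analyses and tests run the generator at the full preset
scale (2322 genes × 33 arrays) for the network experiments, with smaller
designs (60–450 genes) for calibration, property and determinism checks;
spectral oracles use 500-dimensional GOE matrices and 10-block
superpositions over 20 seeds. A complete preset pipeline — simulation,
correlations, a 49-point threshold scan, module detection and reports —
runs in a few minutes on one CPU.

# Limitations

* The pipeline starts from normalized log-ratios; raw-image
  quantification, within-array normalization and GEO ingestion are out
  of scope.
* No edge p-values, partial correlations or mutual-information scores —
  the network is a thresholded Pearson graph by design.
* The DE filter is a screen without multiple-testing control; its
  false-call behavior is characterized empirically on planted-null genes
  in the test suite.
* Synthetic recovery results bound what the pipeline can do on cleanly
  separated planted structure; the threshold-selection caveat above is
  the main place where real-data behavior is expected to differ.
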