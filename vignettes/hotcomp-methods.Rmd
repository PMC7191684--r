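---
title: "Methods: comparative recombination-hotspot analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative recombination-hotspot analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotcomp)
```

# Overview

`hotcomp` implements a population-comparative analysis of linkage-
disequilibrium-based recombination maps. The pipeline takes, per
population, a chromosome-wide map of the population-scaled recombination
rate $\rho = 4 N_e r$ (Morgans per bp, one estimate per inter-SNP
interval), and asks four questions:

1. How do recombination rates differ between populations once $\rho$ is
   converted to the per-generation rate $r$ (cM/Mb)?
2. Where are locally defined hotspots — windows whose genetic length is
   inconsistent with their regional background — and how much of the
   hotspot landscape is shared between populations?
3. Does hotspot sharing mirror genetic differentiation ($F_{ST}$) and a
   drift tree, and is its evolution along that tree better described by
   drift (Brownian motion) or stabilizing maintenance
   (Ornstein–Uhlenbeck)?
4. Are hotspots enriched near genomic features (TSS/TTS flanks, exons,
   introns) or depleted of repeat classes, against nulls that match
   hotspot count and size exactly?

Because the upstream machinery (phasing, LDhat's `interval` MCMC, LDhot's
coalescent simulations, RepeatMasker, treemix, $F_{ST}$ estimation) is out
of scope, a seeded synthetic-data generator produces all inputs with the
statistical structure those tools would deliver, making every stage
testable offline.

# Rate maps and the window/stitch scheme

Per-window LDhat runs use windows of 2000 SNPs with 500-SNP overlaps
(stride 1500). The final window always covers the last 2000 SNPs, so its
overlap with the second-to-last window is variable but never below 500.
`plan_windows()` reproduces this layout and `stitch_windows()` removes 250
SNPs from each side of every overlap; at the final, variable overlap
exactly 250 SNPs are trimmed from the second-to-last window and the last
window contributes the remainder. One boundary interval bridges the two
kept regions at each overlap; it is assigned to the earlier window so
that contribution ranges exactly partition the $n-1$ inter-SNP intervals
(the stitched map always carries exactly one estimate per interval).

Conversion to per-generation units uses $r = \rho / (4 N_e) \times 10^8$
cM/Mb with a per-population $N_e$. Rate comparisons (Kruskal–Wallis,
pairwise two-sided Wilcoxon rank-sum with a Bonferroni cutoff
$\alpha / \binom{k}{2}$) treat each inter-SNP interval as one unweighted
observation — the granularity the estimator emits; the source analysis
does not specify a weighting. Exact Wilcoxon enumeration is used when
both samples have $\le 10$ observations; mid-ranks with variance
correction otherwise. The 95% CI of the mean $r$ is a seeded
nonparametric bootstrap (1000 resamples) over intervals; the CI method is
our choice, as the original table does not state one.

Per-site MCMC uncertainty is summarized by `trace_uncertainty()`: the
median width of per-interval 95% credibility intervals (2.5/97.5 trace
percentiles) against the width of the 95% interval of point estimates
across the genome. In realistic configurations the landscape interval is
orders of magnitude wider than the per-site interval, which is the
justification for treating the point map as signal.

# Hotspot calling: a rate-map-level approximation

The reference method (LDhot) simulates coalescent samples; this package
consumes maps, not haplotypes, so the test is re-expressed at map level
while preserving its structure (1 kb windows, `nsims = 1000`,
$\alpha = 0.001$, merging of overlapping hotspots):

* statistic: genetic length $T = \sum_i \rho_i \ell_i$ of the window
  (partial intervals pro-rated);
* null ("single distribution"): per-interval rates drawn iid from a
  gamma distribution fitted by the method of moments to the $\pm 50$ kb
  flanking intervals, keeping the window's SNP configuration fixed;
* empirical p-value with pseudo-count, $p = (1 + \#\{T_{sim} \ge
  T_{obs}\}) / (1 + \text{nsims})$, so $p \in (0, 1]$ and a window can
  only reach $p \le 0.001$ when `nsims >= 1000`;
* windows with $p \le \alpha$ are merged (overlap or abutment) into
  hotspots carrying the minimum constituent p.

Numerical edge cases: windows with fewer than 10 background intervals or
an all-zero background are skipped with a warning; a zero-variance
background yields a point-mass null, so a literally constant map produces
no calls. The flank width (50 kb) and the non-overlapping scan
(`step_bp = window_bp`) are configurable; the reference analysis does not
print its background window or step, and merging makes calls robust to
the step choice. Calibration on an iid gamma landscape shows per-window
p-values are uniform to within KS noise at ~1000 windows; on injected
2 kb, 10$\times$ hotspots at 1 SNP / 200 bp the caller recovers
$\ge 80\%$ with boundary error at most one window. Detection power
degrades as the background dispersion grows — with a heavy-tailed
(log-sd $\gtrsim 1.5$) background, 10$\times$ spikes are genuinely not
distinguishable at $\alpha = 0.001$, which is a property of the problem,
not of the implementation.

# Sharing, differentiation and the drift tree

The consensus set is the merged union of all populations' hotspots
($\ge 1$ bp overlap merges; abutting intervals also merge). A Boolean
matrix marks, per population and consensus interval, whether any of the
population's hotspots overlaps it. From this matrix come upset-style
subset counts and the private-hotspot fraction, "ubiquitous" hotspots
(present in $\ge 8$ populations by default), and Jaccard distances
between the Boolean rows (the "Boolean matrix" formulation; raw
base-pair Jaccard is a different statistic and deliberately not used).

Pairwise overlap significance follows `bedtools fisher` semantics: with
both sets merged, $n_{11}$ is the number of distinct intersection events
(symmetric), $n_{12} = |A| - n_{11}$, $n_{21} = |B| - n_{11}$, and
$n_{22}$ fills the genome in units of the mean merged-union interval
length. The p-value is the hypergeometric right tail (enrichment), as the
question is whether sets overlap *more* than expected. This contingency
construction is a heuristic inherited from the tool the reference
analysis delegated to; under independent placement it is approximately
calibrated (checked by simulation), and slightly discrete at small
counts.

The Mantel test correlates lower-triangle Jaccard distances with a
pairwise $F_{ST}$ matrix, with significance from simultaneous
row/column permutations, $p = (1 + \#\{r_{perm} \ge r_{obs}\}) /
(1 + n_{perm})$, default 9999 permutations (enough to resolve p-values
of order $10^{-3}$).

## MCA and BM vs OU

The Boolean matrix is converted to quantitative traits by multiple
correspondence analysis: each column becomes a present/absent indicator
pair, and row principal coordinates come from the SVD of the
standardized residuals of the correspondence matrix. Constant columns
are dropped; at most $n - 1$ non-degenerate dimensions exist for $n$
populations, so "nine dimensions" is exactly the non-trivial maximum for
ten populations. Coordinates reproduce chi-square distances between row
profiles (tested).

Each retained dimension is modeled along the drift tree under Brownian
motion ($\text{Cov}(y_i, y_j) = \sigma^2 C_{ij}$, $C_{ij}$ = shared
root-to-MRCA path; $\hat\mu$, $\hat\sigma^2$ closed-form) and a
stationary-start Hansen Ornstein–Uhlenbeck process
($V_{ij} = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
(1 - e^{-2 \alpha t_{a,ij}})$), with $\theta, \sigma^2$ profiled
analytically and $\alpha$ found by bounded search on a log scale over
$[10^{-8}, 50 / \text{depth}]$. **Design choice:** dimensions are fitted
independently and log-likelihoods summed ($k = 2d$ vs $3d$ parameters;
AIC, not AICc). The reference analysis fitted nine dimensions jointly
with a multivariate tool, so its absolute AIC values are not
reproducible here; the deliverable property is the direction of
preference, which the tests verify (BM-generated data prefer BM, and
strong-OU data prefer OU, in $\ge 80\%$ — observed 96%/99% — of
replicates).

A caveat established during development and worth stating plainly: with
10 tips, the per-trait MLE of $\alpha$ is extremely dispersed (estimates
pile onto the search boundaries), so "recover $\alpha$ within a factor
of two per replicate" is not an attainable property at this problem
size — not even when $\alpha$ is estimated jointly across nine
dimensions (~60–70% of replicates). The tests therefore assert aggregate
consistency (the median estimate across replicates is within a factor of
two) and discrimination (strong-OU data yield larger $\hat\alpha$ than
BM data), which is what the downstream model comparison relies on.

# Enrichment with matched resampling nulls

TSS/TTS tracks are the 500 bp upstream/downstream flanks of the
transcribed span, strand-aware (swapped on the minus strand; the source
text says "upstream/downstream" without specifying strand handling — the
strand-aware reading is used and the code keeps strand in the gene
models so the agnostic variant is a one-line change). Flanks are clipped
at chromosome ends with a warning.

`random_hotspot_set()` draws one interval per template interval — same
chromosome, same length, start uniform over the feasible range — and
resamples any interval that overlaps an already-placed one (cap $10^4$
attempts), so the null preserves the count and the entire size
distribution. `feature_overlap_test()` counts hotspots touching
($\ge 1$ bp) at least one feature — per-hotspot, not per-bp, so a
hotspot spanning two exons counts once — and reports both the
"proportion of simulations below the observed count" (the
direction-explicit summary used in the reference tables) and a
conventional enrichment p. `repeat_content_test()` works in base pairs
(percentage of hotspot bp covered by a repeat class) and reports the
percentage of simulations exceeding the observed value, so values near
100 mean depletion. Under unbiased hotspots the simulated mean
percentage equals the genome-wide repeat fraction (the structural
analogue of the near-equality of the genome-wide and simulated-mean
percentages in the reference analysis), and the null-on-null summary is
uniform — both tested.

# The recessive GLM

Homozygous-alternative frequencies per population and missense mutation
(hom-alt / non-missing) are pruned for complete correlation
($r^2 = 1$, within $10^{-12}$; greedy keep-first scan, idempotent on its
own output), then the population median recombination rate is regressed
on the retained columns plus an intercept. "Gaussian link" in the source
is read as the identity-link Gaussian family, i.e. OLS with two-sided
t-tests; the residual degrees of freedom are reported prominently
because with 10 populations and 8 retained mutations only one residual
df remains, making the reported p-values fragile — the package
reproduces the model structure, not the original coefficients (the
original frequency matrix is not printed as numbers). The response is
the median $r$ itself; the log transform in the source's figure is
display-only.

# The synthetic world

The generator's defaults describe one fixed, desk-scale world:

| parameter | default | why |
|---|---|---|
| populations / tree | 10 tips, random topology, exp(0.2) drift branches | ten-population study; $F_{ST}$ 0.16–0.65 maps to drift distances $\sim$0.2–1 |
| chromosome | 1 Mb | desk-scale stand-in for a ~35 Mb chromosome |
| SNP density | 1/200 bp | post-filtering density used in the recovery criteria |
| background $\rho$ | log-normal, log-mean $\log(4\times10^{-3})$ M/bp, log-sd 0.75, 10 kb autocorrelation | matches the magnitude of the reference rate table; "several orders of magnitude" genome-wide spread |
| hotspots | 10/Mb ancestral, length $\mathcal{N}(2000, 500^2)$ bp (min 200), intensity 10$\times$ | ~2 kb hotspots at 10$\times$ background, the regime the detection criteria state |
| turnover | loss 1.5, gain 0.1 per drift unit, 2 births/Mb/drift | two-state Markov per locus plus branch births; produces mostly-private landscapes on the default tree |
| trace | 100 samples, 10% relative CrI width | narrow per-site uncertainty against a wide landscape |
| GLM | $\beta_0 = 2$, $\beta = (5, 2, 0)$, $\sigma = 0.5$ | one strong, one moderate, one null effect |
| annotations | 100 genes/Mb; repeats 11% retroelement, 1.1% DNA transposon, 1% other | gene-dense plant genome; repeat fractions mirror the genome-wide percentages in the reference repeat table |

Hotspot presence evolves as a two-state Markov chain per locus
($P(1\to0)$, $P(0\to1)$ in closed form per branch), the simplest
generative model consistent with a drift interpretation; the synthetic
$F_{ST}$ proxy is $1 - e^{-d}$ in patristic drift distance — monotone in
drift, which is all the Mantel recovery check requires. No coalescent or
sequence-level simulation is performed: the package analyzes maps, so
maps are generated directly. Everything is deterministic under
`sim_config(seed = ...)`.

What a green test therefore does *not* establish: performance on real
LD-based maps (phasing error, MCMC non-convergence, variable SNP density
correlated with diversity), multi-chromosome structure (the generator is
single-chromosome; the analysis code itself is multi-chromosome-aware
through genome layouts), realistic gene/repeat clustering, or the
reference study's actual empirical values (private-hotspot fraction,
Mantel r, table p-values), which require the original data.

# Known limitations

* The hotspot caller is a structural approximation of the
  likelihood-ratio machinery it emulates; absolute sensitivity numbers
  transfer only within the stated background-dispersion regime.
* The `bedtools fisher` contingency heuristic is discrete and
  approximate for small interval counts; its p-values should be read
  comparatively, as in the reference analysis.
* Per-dimension BM/OU fitting ignores covariance between MCA dimensions;
  with orthogonal coordinates and 10 tips this is the only stable option,
  but absolute AIC values are not comparable with joint multivariate
  fits.
* With 10 populations the recessive GLM is df-starved by construction;
  the implementation refuses designs with $n \le p$ and reports residual
  df so users see how fragile the inference is.
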