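---
title: "Models and methods behind chromage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromage)
```

# Scope

`chromage` implements the computational core of a cell-type-resolved study
of chromatin aging: detecting cCREs (candidate cis-regulatory elements)
whose accessibility changes between young and old animals in single-nucleus
ATAC-seq pseudo-bulk data, linking those cCREs to genes through correlated
expression, finding megabase-scale clusters of age-up cCREs, and
quantifying the decay of broad H3K9me3 heterochromatin domains in specific
cell types. Every stage is exercised end to end on synthetic data with
planted effects, so the statistical behaviour of the whole pipeline is
testable without any external dataset. This vignette records the models,
the tunable parameters, and the design decisions taken where more than one
reasonable construction existed.

Coordinates are 0-based half-open (BED convention) everywhere. Inputs in
1-based conventions must be converted by the caller; the package validates
rather than silently shifts, because the surrounding toolchains mix
conventions and a single internal convention prevents off-by-one drift.

# Differential accessibility: NB likelihood-ratio testing

Pseudo-bulk counts for feature $i$ in sample $j$ are modelled as negative
binomial,

$$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_i), \qquad
  \log \mu_{ij} = \beta_{i,g(j)} + o_j,$$

with $o_j$ the log library size and $g(j)$ the age group. Differential
features are found by the likelihood-ratio test of group-specific means
against a shared mean, referred to $\chi^2_1$; the primary contrast is 18
months versus 3 months with two replicates per group, and accessibility
calls use a raw p-value cutoff of 0.01 (transcript-level calls use a
BH-adjusted cutoff of 0.1).

Dispersion estimation is deliberately a re-implementation rather than a
call into an existing count-model package: the inference the pipeline
needs is a plain two-group LRT, and owning the code keeps the estimator
auditable. Two numerical choices matter at these tiny replicate numbers:

* **Cox–Reid adjustment.** The common dispersion maximizes the summed
  profile log-likelihood with the $-\tfrac12 \log\det(X^\top W X)$
  degrees-of-freedom correction. Without it, profiling out one mean per
  group with $n = 4$ samples biases $\hat\phi$ low by roughly the factor
  $(n-p)/n$, which inflates the null $p<0.01$ rate to two to three times
  nominal. With the correction, a null simulation (5,000 features,
  $\mu \sim$ log-normal, $\phi = 0.1$, 2 vs 2) estimates
  $\hat\phi \approx 0.10$ and holds the $p<0.01$ rate at 0.008–0.014 with
  a Kolmogorov–Smirnov distance from uniformity below 0.02.
* **Tagwise shrinkage at the likelihood level.** Per-feature dispersions
  maximize $\mathrm{APL}_i(\phi) + (d_{\mathrm{prior}}/d)\,
  \overline{\mathrm{APL}}(\phi)$, where $d$ is the per-feature residual df
  and $d_{\mathrm{prior}} = 10$ by default. Interpolating per-feature
  *estimates* toward the common value on the log scale — the more obvious
  construction — is badly behaved here: with $d = 2$ the per-feature MLE
  frequently sits at the search boundary, and even a one-sixth weight on
  $\log\hat\phi_i \to -\infty$-like values drags tagwise dispersions far
  below truth. The likelihood-level weighting (the standard
  empirical-Bayes form) lets flat per-feature likelihoods defer to the
  pooled evidence. `prior_df = Inf` collapses every feature onto the
  common value.

Log2 fold changes come from offset-adjusted group totals with a half-count
continuity adjustment, so features observed in only one group stay finite;
features with all-zero counts are flagged and given $p = 1$.

A caveat worth stating plainly: with $\phi = 0.1$ and two replicates per
group, the LRT noncentrality for a fold change $f$ is bounded by
$\ln^2 f/(\phi + 1/\mu)$. At $f = 2.25$ and $\mu = 100$ this is about 6.2,
which caps power at $\alpha = 0.01$ near 45% *for any calibrated test* —
a brute-force likelihood-maximization oracle and an independent
count-model package both land at 41–44% on identical data. Detection at
these depths is a coin flip per feature; the pipeline's cluster and
domain statistics are designed to aggregate over many features precisely
because single-feature power is modest.

# TSS enrichment and nucleus QC

Each fragment contributes two Tn5-corrected insertion events: the start
shifted $+4$ and the end$-1$ shifted $-5$. The usual statement of this
correction gives the shifts but not the per-end strand assignment; the
package follows standard ATAC practice (start = plus-strand cut, end =
minus-strand cut). Events are
aggregated at strand-corrected positions within ±2,000 bp of every TSS,
normalized by the mean of the distal flanks (both ±1,900–2,000 bp windows
pooled, 202 positions), smoothed by a centered 11-bp moving average with
shrinking windows at the array edges (no padding), and the score is the
maximum of the smoothed profile. A crafted profile with 10 events/bp in
the flanks and a 200 events/bp 51-bp plateau evaluates to exactly 20 under
this arithmetic. If the flank signal is exactly zero the flank mean is
floored at $N/(4001 \times 50)$ with a warning rather than dividing by
zero.

Because the score is a maximum over ~4,001 positions, it is upward-biased
when the per-position event counts are small: a truly uniform profile with
$m$ events per position scores about $1 + 3\sqrt{2/(11m)}$ rather than
exactly 1. Flat-profile checks therefore need on the order of $10^5$
events inside the windows before the score settles within 0.2 of 1.

Nuclei are kept when they have at least 500 fragments *and* a TSS
enrichment of at least 10 (a cutoff of 7 is appropriate for tissues with
globally weaker signal; both thresholds are arguments). Per-sample fair
comparisons use exact down-sampling to 1 million reads: a sequential
multivariate-hypergeometric draw (sampling without replacement, matching
the subsampling of real reads), so the output total is exactly the target
and under-depth samples are removed rather than scaled.

# Gene–cCRE linking

Replicates are merged into one data point per (cell type, age) — with the
default twelve cell types and three ages, 36 points — and each gene is
tested against every cCRE whose midpoint lies within 500 kb of its TSS.
The statistic is the weighted Pearson correlation of CPM values with
weights equal to the number of cells behind each data point, which damps
the influence of sparsely sampled cell types. The correlation's p-value is
an approximation chosen here and flagged as such: $t = r\sqrt{(n_e - 2)/(1
- r^2)}$ with the Kish effective sample size $n_e = (\sum w)^2 / \sum
w^2$, two-sided. No exact small-sample distribution exists for a weighted
correlation; with equal weights the statistic reduces exactly to the
ordinary Pearson test. BH adjustment is applied across **all** tested
pairs (the stricter of the two plausible conventions; per-gene adjustment
would be more permissive), and a significant link additionally requires
$r > 0$, the enhancer-like direction of coupling.

The concordance check collects, at the pair level, the RNA log2 fold
changes of genes linked to age-up cCREs and to age-down cCREs and compares
the two sets with a two-sided Wilcoxon rank-sum test (normal approximation
with tie correction). A gene linked through several cCREs contributes once
per pair, mirroring the pair-level bookkeeping of the linking step.

# Clusters of age-differential cCREs

Strongly differential cCREs ($p < 0.001$) are counted in 100-kb bins
(midpoint assignment; the last partial bin is kept) and smoothed with a
truncated Gaussian kernel of window length 20 bins. The smoother's shape
parameter is not fully pinned down by a window length alone; the package
uses $\sigma = \text{window}/4 = 5$ bins, truncated at ±window/2 and
renormalized — both configurable. Smoothing is mass-conserving: each
source bin distributes its count over the in-bounds kernel taps with edge
renormalization, so per-chromosome score totals equal count totals and no
mass bleeds across chromosomes.

No published rule defines when a smoothed density peak is a "cluster", so
the caller builds its own null: the differential labels are permuted over
all tested cCREs (count preserved, positions fixed), the binning and
smoothing are recomputed `n_perm` times, and the calling threshold is the
$(1-\text{fdr\_level})$ quantile (default 0.999) of all null bin scores.
Contiguous observed bins at or above the threshold merge into a cluster;
calls with fewer than 5 member differential cCREs are discarded. The
permutation is seeded and the records are put in a canonical order first,
so calls are reproducible and invariant to input row order.

# Broad H3K9me3 domains and their decay

The domain caller is a window/gap island scheme in the SICER spirit,
intentionally simplified and run without an input library: 5-kb bins are
"eligible" when their count clears the Poisson upper tail at $p < 0.01$
against the genome-mean rate; eligible bins at most 10 kb apart are
chained (sub-threshold intervening bins included); candidates longer than
100 kb are kept. Exact agreement with the original island-score machinery
is a non-goal — the downstream statistics only need reproducible broad
intervals.

Per-domain differential statistics reuse the NB LRT per modality
(H3K9me3, ATAC, RNA aggregated over identical domain intervals), with
dispersions estimated once per modality from the full cell-type × age
design and BH adjustment within each (cell type, modality) stratum. The
joint-across-cell-types alternative is available
(`stratify_by_cell_type = FALSE`); an eight-seed simulation study showed
the stratified default recovers every planted decaying domain at every
seed, while joint adjustment sacrifices marginal domains, at a similar
(low) rate of spurious strata. One subtlety the simulation surfaced: the
library-size offsets for domain counts must be the per-sample sequencing
depths, *not* the in-domain column totals — with 40% of the domain mass
decaying, in-domain totals absorb the decay into the offsets, halving the
apparent effect and pushing stable domains spuriously upward.

Two overlap-enrichment statistics accompany the domain analysis. The
Fisher test crosses the top 1% of cCREs (ranked by p-value, ties broken by
$|$log2FC$|$ then id) against ≥1-bp overlap with a region set; the
two-sided p comes from direct hypergeometric enumeration, and the reported
odds ratio is the sample OR with the Haldane correction — deliberately not
the conditional MLE, so the number printed matches the familiar
$ad/bc$ arithmetic. The cluster–domain statistic reports the fraction of
domains overlapping at least one cluster against two baselines: an
analytic one (the genome fraction covered by clusters, reported for
transparency) and a shuffle null in which the domain set is re-placed
uniformly at random (sizes preserved, same chromosome, mutually disjoint),
which respects domain sizes and is the headline. Shuffle p-values are the
standard $(1 + \#\{null \ge obs\})/(n+1)$; with ten domains the statistic
is coarse, so these p-values are discrete and slightly conservative —
their null mean sits near 0.55–0.65 rather than 0.5, which tests of the
null behaviour must anticipate. Note also a geometric constraint: with
Mb-scale domains and clusters on a 40-Mb toy genome, the chance overlap
probability is ~20%, capping any achievable fold enrichment near 1.5;
meaningful enrichment folds require the chance-overlap scale of a real
genome, which the 2 × 100 Mb configuration used in the enrichment checks
emulates.

The per-cell "fraction of reads in domains" statistic divides each cell's
reads in a domain subset by its total; zero-read cells are excluded and
counted. Age groups are compared with the rank-sum test, which is what
distinguishes a uniform shift across all cells from a subpopulation
effect.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions every acceptance check runs under.

* **Design**: 2 chromosomes × 20 Mb; 12 cell types (one flagged
  excitatory-neuron-like, "ExN"), 3 ages (3, 10, 18 months), 2 replicates;
  4,000 disjoint cCREs of 200–1,000 bp; 600 genes with one stranded TSS
  each; 10 heterochromatin domains of 0.5–1.5 Mb, 40% decaying. Twelve
  cell types give the 36 correlation data points the linking stage is
  designed around; with only three cell types the nine merged points make
  a weighted correlation of 0.8 statistically invisible after
  multiple-testing correction over ~60,000 candidate pairs, so no planted
  link could ever be recovered — the larger default keeps the linking
  question answerable.
* **Counts**: NB with dispersion 0.1 around log-normal baselines scaled to
  a 2-million-read library per pseudo-bulk sample (500 cells). Affected
  cCREs (5% up, 5% down) change by 1.5× per age step in one affected cell
  type only, so 10-month samples sit between the extremes and trends are
  monotone. Library-size metadata records realized column totals.
* **Clusters**: three planted inside the largest decaying domains, spans
  up to 1 Mb, 50 member cCREs each, all age-up in ExN. Fifty members per
  Mb — about half the local cCRE density — is both the realistic picture
  of a dense differential cluster and the operating point at which
  recovery is reliable: per-member detection power at $p<0.001$ is ~0.25,
  so ~12 detected members produce a smoothed density of ~0.85 against a
  permutation threshold near 0.5. Domains keep at least 1.5 Mb of
  separation: structures closer than the smoothing kernel's 2-Mb support
  would be merged by any density-based caller, making "recovery" of them
  ill-defined rather than hard.
* **RNA coupling**: a fifth of the genes carry a truth link to one cCRE
  (stratified one-third each over age-up, age-down and stable cCREs so the
  concordance contrast has members on both sides). Linked pairs share a
  latent per-(cell type, age) log-activity with unit standard deviation —
  the gene's activity is correlated with the cCRE's, not copied from it,
  so the measured WPCC is a genuine estimate. The latent correlation is
  inflated above the target by the analytic attenuation factor
  $1 + \phi/\sigma_u^2$ so that the *realized* count-level correlation
  lands on the 0.8 target (the default run realizes a median truth-pair
  WPCC of 0.79–0.80).
* **H3K9me3**: domain pseudo-bulk counts use a modality-specific
  dispersion of 0.005. Megabase-aggregated broad-domain signal genuinely
  fluctuates far less between replicates than individual peaks, and the
  value follows from a power analysis: the planted 30% decay by 18 months
  ($|$log2FC$| = 0.51$) must be detectable at 2 vs 2 replicates, which
  requires $\sqrt{\phi + 1/\mu} \ll 0.51/\;z_{\mathrm{crit}}$; at
  $\phi = 0.1$ the decay would be statistically invisible by construction.
  Decay applies as $1 - \delta\,\mathrm{step}/2$ in decaying domains of
  the ExN-like cell type only. Per-cell read-to-domain assignments are
  multinomial with domain weights 5× background per bp (scaled by decay),
  ~2,500 reads per cell, recorded for the FRiP statistic. A binned
  genome-wide signal (Poisson, 5-kb bins, 5× rate inside domains) feeds
  the domain caller.
* **Fragments**: per-barcode counts are log-normal around a 2,000-fragment
  median. Each fragment's first cut is background-uniform or TSS-targeted
  (normal, sd 75 bp, around a random TSS); the second cut sits one
  gamma-distributed fragment length downstream. The targeted fraction is
  calibrated numerically — the expected aggregate profile of both cut
  sites is computed on the ±2-kb grid and the mixing proportion solved by
  root finding — so the expected enrichment score equals the configured
  fold (default 15×). A configurable fraction of barcodes is low quality,
  half by fragment count (< 500) and half by background-only insertions.
* **Reproducibility**: each stage seeds its RNG from the master seed plus
  a fixed offset, so annotations, counts, fragments, and the entire
  pipeline output are byte-identical across runs at the same seed.

What the generator does **not** emulate: sequence content, doublets, batch
effects, GC or mappability bias, trans effects, TSS-proximal accessibility
structure in the count matrices, or any correlation between cCRE width and
signal. Passing tests demonstrate that the statistical machinery recovers
planted structure under the stated noise model; they are not evidence
about artefacts real data might add.

# Problem sizes used by tests and the acceptance script

Simulation sizes were chosen so each statistical check has clear resolving
power at desk scale: 5,000 features for calibration checks (binomial
standard error ~0.0014 on a 1% rate), 2,000 features for dispersion
recovery, 1,000 permutations for cluster thresholds, 1,000 shuffles for
enrichment p-values down to 0.001, 200 outer seeds for null-uniformity
checks, and the full default design (4,000 cCREs × 72 samples) for
end-to-end recovery. The complete test suite and the acceptance script
each run in a few minutes on one CPU.

# Known limitations

* The LRT is asymptotic; at two replicates per group it is mildly liberal
  even with the Cox–Reid correction (null $p<0.01$ rates up to ~0.014 in
  simulation). Quasi-likelihood F-tests would be more conservative and are
  out of scope.
* The WPCC p-value rests on the Kish-effective-sample-size t
  approximation; its small-sample behaviour with highly unequal weights is
  unverified beyond simulation.
* The domain caller has no input-library correction and a plain Poisson
  bin test; on real data with copy-number or mappability artefacts it
  would need a matched input track.
* Cluster calling assumes differential cCREs are exchangeable under the
  null; regional differences in cCRE density are preserved by the
  permutation, but regional differences in *detectability* (depth,
  dispersion) are not.
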