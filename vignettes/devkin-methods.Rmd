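---
title: "devkin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{devkin: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devkin)
```

## The problem

Embryos of related species pass through equivalent developmental stages at
different absolute speeds, so gene-expression time courses measured in
hours post fertilization (hpf) cannot be compared between species
directly: a mismatch of even a few hours badly distorts apparent
conservation, because developmental expression is highly dynamic. devkin
implements a quantitative workflow for two-species comparisons: put the
species on a common developmental clock using gene activation times, then
ask — per orthologue pair and per developmental stage — what is conserved
and what has diverged.

## The activation model

Zygotic genes typically switch on once and saturate. devkin models log
expression of one gene as the four-parameter sigmoid

$$\log mRNA(t) = a - \frac{b}{1 + e^{c\,(t - t_i)}}$$

* `a` — final (plateau) log level;
* `b` — total rise above the basal level (`a - b` is the maternal
  baseline as `t -> -Inf`); `b >= 0` for activation;
* `c` — slope (per hour), `c > 0` for activation;
* `t_i` — the **initiation time**: at `t = t_i` log expression is exactly
  `a - b/2`, the half-rise point.

The half-rise definition makes `t_i` insensitive to the log base and to
any per-gene multiplicative level factor (platform, primer efficiency):
both only shift/rescale `a` and `b` jointly. devkin uses the natural log
with pseudocount `eps = max(1e-6, smallest positive value / 10)`.

`fit_sigmoid()` minimises the residual sum of squares by BFGS with an
analytic gradient from 12 deterministic starts (`c` at 0.3/1/3 times the
natural slope scale `4/window`; `t_i` at the 20/40/60/80% quantiles of
the window), then polishes the best start at tight tolerance; ties are
broken towards the smallest `t_i`, so identical inputs always give
identical fits. Because `(a, b, c, t_i)` with `c < 0` describes the same
curve as `(a - b, -b, -c, t_i)`, fits are canonicalised to `c > 0` and
the sign of `b` alone distinguishes activation from decay. Replicates
enter the fit as repeated `(t, y)` points, so batch scatter contributes
to the RSS without requiring a variance model.

Classification: *activated* requires a fitted rise `b` of at least
`rise_threshold` (default 0.5 natural-log units, about 1.65-fold), `c >
0`, and `t_i` inside the observed window extended by one sampling
interval; a fitted drop of the same size is *decaying* (maternal
transcripts); a small |rise| is *flat*; an activation-shaped fit whose
`t_i` escapes the extended window is *unfit*. The threshold is an
explicit argument because "a clear activation curve" is a judgment call:
datasets whose genes rise only ~1.5-fold need a lower threshold, and the
default deliberately refuses to report initiation times for such genes.

Sampling density matters most inside the activation window;
`recommend_sampling_interval()` encodes the rule of thumb that the
interval should be about a tenth of the developmental window studied
(3 h for a 30 h window, 4.8 h for 48 h).

## Developmental-time scaling

For orthologous developmental regulators, initiation times in a target
species are regressed on those in a reference species
(`fit_time_scaling()`), giving the linear map

$$T_{target} = shift + rate \times T_{reference}.$$

The intercept is the offset of the maternal-to-zygotic transition; the
slope is the relative developmental rate (for the two sea urchins used
as the reference example, `T_Sp = 2.42 + 1.037 * T_Pl`). Plain OLS is
the default; whether the original trend-line minimised vertical
residuals or was a major-axis fit is not documented anywhere, so devkin
assumes OLS on the plotted orientation and computes the inverse map
algebraically (`invert_scaling()`) rather than by re-fitting, keeping
the two directions exactly consistent. A Theil–Sen estimator
(`method = "theilsen"`) is available because individual genes can be
heterochronic: a single outlying gene then barely moves the median
pairwise slope.

Profiles are compared on the percent-of-maximum scale
(`normalize_to_max()`): each linear value divided by the profile maximum,
times 100. This removes technical level differences while preserving
shape; it is computed on linear values, before any log transform, and is
exactly idempotent and scale-invariant (the implementation divides by the
maximum *first*, so the output maximum is exactly 100 in floating point).
`resample_profile()` linearly interpolates profiles onto the scaled
grid and refuses to extrapolate outside the measured window.

## Clustering and conservation

`kmeans_cluster()` is Lloyd's algorithm exactly as classically stated:
k measured profiles drawn at random as initial means, genes assigned to
the nearest (Euclidean) mean, means recomputed, repeat until no gene
moves. devkin keeps this textbook form (rather than calling a library
implementation) because the conservation definition is anchored in its
artefacts — member-to-centroid distances — and because tests compare it
against an exhaustive minimum-inertia oracle on small instances. Empty
clusters are re-seeded at the profile farthest from its centroid. A
single user seed derives all restart sub-seeds (20 restarts by default);
the lowest-inertia restart wins, ties broken by the lexicographically
smallest canonical assignment, so results are reproducible. `k = 10` is
the default for ~7-stage profiles; no automatic `k` selection is done.

`classify_conservation()` supports the two published definitions:

* **distance** (default): an orthologue pair is conserved when the
  Euclidean distance of the target-species profile from its partner's
  reference-cluster centroid is at most that cluster's cutoff. The
  cutoff is anchored in the reference species itself: the maximal
  member-to-centroid distance per cluster (`"max"`), a per-cluster
  quantile (`"quantile:q"`), or a single global maximum
  (`"global_max"`). Per-cluster maxima are the default reading; by
  construction, self-comparison (target = reference) is then 100%
  conserved.
* **membership**: the target profile is assigned to its nearest
  reference centroid and the pair is conserved iff that cluster equals
  the partner's.

Distances are computed on percent-of-max profiles over the matched grid
with no further per-stage standardisation; whether the original
distances were computed on normalized or log values is not documented,
so the normalized scale (consistent with the normalization step above)
is used and the profiles fed in are under the caller's control.

`class_enrichment()` is a hypergeometric over-representation test of
user-supplied class labels (a stand-in for GO enrichment, which would
require ontology databases and is out of scope), BH-adjusted across
classes.

## Stage-by-stage conservation patterns

`interspecies_correlation_matrix()` correlates expression across
orthologues between every stage of species A and every stage of species
B — Pearson on `log(value + eps)` (technical level effects are additive
there), Spearman on raw values with average ranks. Per-gene
normalization before correlating is exposed as an option
(`per_gene_normalize`): it makes the matrix exactly invariant to
per-gene technical factors, but collapses the cross-gene signal at
stages where most profiles sit at their maximum, so the default
correlates measured levels. `divergence_profile()` gives the
complementary variance view: per stage, the across-species variance of
each gene's (normalized) value, averaged over genes.
`pca_sample_projection()` projects stage samples of both species into a
common component space to check that equivalent stages group together.

`pattern_summary()` reduces a correlation matrix to its
*equivalent-stage series* (matched stages come either from an explicit
list or from `equivalent_stages()`, which applies the fitted time
scaling and snaps to the nearest measured stage) and classifies the
shape:

* *hourglass* — interior peak exceeding both ends by a margin `m`
  (default 0.05 correlation units): conservation maximal at
  mid-development, the pattern expected of developmental genes within a
  phylum;
* *funnel* — positive Spearman trend of the series over the zygotic
  stages, one-sided at `alpha = 0.05`: conservation rising with
  developmental progression, the pattern of housekeeping expression
  (ribosomal, RNA-processing, mitochondrial genes) whose dynamics track
  universal embryonic transitions rather than morphology;
* *flat* — series range below `m`; *mixed* — anything else, e.g. the
  superposition seen when all classes are pooled.

The margin and significance level are configurable; the shapes are
defined only pictorially in the literature, so these two thresholds are
this package's own operationalisation. The first equivalent stage is
treated as maternal (pre-zygotic) and excluded from the funnel trend by
default. The *diagonality index* — the fraction of reference stages
whose best-correlated target stage is their equivalent stage — equals 1
for self-comparison.

## The synthetic two-species world

`simulate_two_species_dataset()` generates the package's test bed: a
reference species sampled at seven stages over 0–36 hpf, a target
species on the clock `T_B = 2.42 + 1.037 * T_A` sampled at the
equivalent (scaled) stages, three biological replicates, and 450 genes
in four classes (200 developmental, 100 housekeeping, 50 maternal, 100
environmental) drawn from ten temporal archetypes: seven rising sigmoids
with increasing initiation times, a maternal decay, a housekeeping ramp
(linear log-increase after the zygotic transition), and a transient
pulse. Each archetype owns a characteristic log-rise `b0` (per-gene
variation ±15%); the plateau level `a` is free per gene. Giving the rise
to the archetype rather than the gene keeps an archetype's percent-scale
shape coherent — with a free global rise, k-means splits archetypes by
basal level instead of timing, and archetype recovery degrades badly.
Timing jitter is N(0, 1 h) clipped at 2 sd, so adjacent archetypes
(3.6 h apart) stay separable.

Target-species curves are the same gene curves evaluated on the scaled
clock, so target initiation times obey the configured scaling exactly.
Three stochastic layers sit on top:

* **measurement noise** — log-normal, multiplicative, sd = 3% of the
  gene's log dynamic range, independent per replicate (batch-to-batch
  level variation is why at least three replicates are recommended);
* **lineage drift** — an independent per-gene, per-stage log
  perturbation applied to *both* species with sd `delta/sqrt(2)`, giving
  cross-species divergence sd `delta`. Symmetry matters: the
  conservation cutoffs are calibrated on the reference species' own
  cluster scatter, and one-sided drift would systematically push
  conserved orthologues past cutoffs that never saw the drift mechanism.
  Both lineages diverging from the common ancestor is also the
  biologically coherent model.
* **archetype swaps** — each environmental gene's target-species profile
  is, with probability 0.5, re-drawn from a different archetype; these
  are the ground-truth *diverged* orthologues.

The drift magnitudes are class- and stage-specific and encode the
qualitative world the generator is meant to emulate: developmental genes
drift least at mid-development (0.015 log units, rising to ~0.07 at the
ends — an hourglass), housekeeping drift decays with developmental
progression (0.09 early to 0.01 late — a funnel), maternal drift is
small and flat, environmental drift intermediate and flat. The absolute
values were calibrated once, at design time, so that the two stated
properties of the world hold simultaneously — class-resolved
equivalent-stage correlation series classify as hourglass
(developmental) and funnel (housekeeping), while >= 95% of
non-swapped orthologues stay within their per-cluster max cutoff — and
were then frozen. The relevant physics: the correlation dip a given
drift produces depends on the ratio of drift to cross-gene signal sd at
that stage (small at basal/plateau stages, so small drift suffices at
the ends), while the distance penalty depends on the drift's absolute
percent-scale effect, amplified at stages near the profile maximum where
drift rescales the whole normalized profile.

What a green test on this world does **not** establish: performance
under count noise (no negative-binomial sequencing model), non-sigmoid
activation shapes, many-to-many orthology, heterochrony beyond the
linear clock, spatial expression differences, or >2-species comparisons
with phylogenetic correction.

## Numerical choices and edge cases

* Deterministic everything: generator output is a pure function of its
  configuration; clustering derives all restart seeds from one seed;
  fitting uses a fixed start grid with stated tie-breaks.
* `normalize_to_max()` errors on all-zero profiles; genes with more than
  25% missing cells are excluded from fitting and clustering with a
  logged count.
* Profile resampling refuses extrapolation (tolerance 1e-9 h at the
  window edges).
* The time-scaling fit refuses fewer than two distinct reference times
  and a non-positive slope ("anti-scaling" — almost certainly a pairing
  error).
* On the default 7-stage grid (6 h interval, coarser than the
  recommended tenth-of-window rule) single-gene initiation times for
  edge archetypes carry ~1 h bias; the scaling regression over many
  genes still recovers the clock, but the package's own end-to-end
  recovery checks run the generator at the recommended density, which is
  what the fitting protocol prescribes.

## Limitations

devkin compares exactly two species per analysis; multi-species
conservation chains and phylogenetic-distance corrections are out of
scope, as are GO ontology access, hierarchical clustering, nonlinear
time warping between species, and expression quantification upstream of
the matrices.
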