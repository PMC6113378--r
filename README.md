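# devkin

Comparative analysis of developmental gene-expression kinetics between
species.

Embryos of related species develop at different absolute speeds, so
their expression time courses (hours post fertilization, hpf) cannot be
compared directly. devkin implements the full quantitative workflow for
two-species comparisons of developmental transcriptomes or QPCR /
nanostring time courses:

1. **Activation kinetics.** Zygotic gene activation is modelled as a
   four-parameter sigmoid in log expression,
   `log mRNA(t) = a − b / (1 + exp(c (t − t_i)))`, where `t_i` is the
   *initiation time* — the half-rise time at which log expression equals
   `a − b/2`.
2. **Developmental-time scaling.** Orthologue initiation times in two
   species are regressed on each other, giving the linear clock map
   `T_target = shift + rate × T_reference` (intercept = offset of the
   maternal-to-zygotic transition, slope = relative developmental rate;
   e.g. `T_Sp = 2.42 + 1.037 × T_Pl` for two sea urchin species).
3. **Conservation by clustering.** Percent-of-maximum profiles are
   clustered by k-means in the reference species (Lloyd's algorithm,
   random-profile initialization, deterministic seeded restarts); an
   orthologue is *conserved* when its profile in the second species lies
   within a cutoff distance (per-cluster maximum of reference member
   distances, by default) of its partner's cluster centroid, *diverged*
   otherwise.
4. **Stage-by-stage patterns.** Interspecies Pearson/Spearman
   correlation matrices across orthologues, per gene class, reduced to
   equivalent-stage series and classified as **hourglass** (conservation
   peaking at mid-development, typical of developmental genes),
   **funnel** (conservation rising with developmental progression,
   typical of housekeeping genes), flat or mixed; plus per-stage
   cross-species variance profiles and PCA stage grouping.
5. **Synthetic data.** A deterministic two-species generator with known
   sigmoid parameters, time scaling, temporal archetypes and
   conserved/diverged ground truth, used by the whole test suite.

See the methods vignette (`vignettes/devkin-methods.Rmd`) for the model
assumptions, parameter defaults and design rationale.

## Worked example

```r
library(devkin)

# a two-species dataset with known ground truth: 450 genes in four
# classes, 7 stages (0-36 hpf reference), clock T_B = 2.42 + 1.037 T_A
sim <- simulate_two_species_dataset(simulation_config(seed = 1))
sim$a
#> ExpressionMatrix 'speciesA': 450 genes x 7 time points (0-36 hpf), 3 replicates

# 1. recover the developmental clock from fitted initiation times of
#    developmental genes sampled at the recommended density (window/10)
kin <- simulate_two_species_dataset(simulation_config(
  n_dev = 100, n_hk = 0, n_maternal = 0, n_env = 0,
  a_times = seq(0, 36, length.out = 11), seed = 1))
ta <- initiation_times_batch(kin$a, rise_threshold = 0.3)
tb <- initiation_times_batch(kin$b, rise_threshold = 0.3)
ok <- ta$classification == "activated" & tb$classification == "activated"
fit_time_scaling(ta$t_i[ok], tb$t_i[ok])
#> TimeScaling: T_target = 2.405 + 1.035 * T_reference (r2=0.9947, n=100)
# true clock: shift 2.42, rate 1.037

# 2. cluster reference profiles, classify orthologue conservation
pa <- percent_of_max(collapse_replicates(sim$a))
pb <- percent_of_max(collapse_replicates(sim$b))
cl <- kmeans_cluster(pa, k = 10, seed = 11)
calls <- classify_conservation(cl, pb, sim$map)
table(truth = sim$truth$conserved,
      call = calls$label[match(sim$truth$ref_id, calls$ref_id)])
#>        call
#> truth   conserved diverged
#>   FALSE         0       46     # all archetype-swapped pairs diverge
#>   TRUE        392       12     # 97% of noise-only pairs stay conserved

# 3. class-resolved stage-correlation patterns
am <- collapse_replicates(sim$a); bm <- collapse_replicates(sim$b)
eq <- cbind(1:7, 1:7)  # equivalent stages by construction
for (cls in c("developmental", "housekeeping")) {
  gs <- sim$classes$gene_id[sim$classes$class == cls]
  sc <- interspecies_correlation_matrix(am, bm, gene_set = gs, label = cls)
  print(pattern_summary(sc, eq))
}
#> PatternSummary: shape 'hourglass', diagonality 1.00, peak at 18
#> equivalent-stage series: 0.913 0.975 0.991 0.996 0.989 0.941 0.868
#> PatternSummary: shape 'funnel', diagonality 0.43, peak at 36
#> equivalent-stage series: 0.763 0.840 0.887 0.942 0.967 0.978 0.985
```

Reading the output: the developmental-gene series peaks at an interior
stage (18 hpf) and falls off at both ends — the hourglass of
morphology-linked conservation — while the housekeeping series rises
monotonically after the maternal stage — the funnel of
transition-linked conservation that superimposes on (and can distort)
the hourglass when all genes are pooled.

## Command line

Every step is also available as a CLI (`inst/cli/devkin`, or
`devkin_cli()` in-process):

```sh
devkin simulate --out-dir sim/ --seed 42
devkin fit-kinetics --matrix sim/speciesA.tsv --out kinA.tsv
devkin scale --ref-times kinA.tsv --target-times kinB.tsv \
             --pairs sim/orthologs.tsv --out scaling.tsv
devkin cluster --matrix sim/speciesA.tsv --k 10 --seed 17 --out clusters.tsv
devkin conserve --clusters clusters.tsv --target sim/speciesB.tsv \
                --pairs sim/orthologs.tsv --out calls.tsv
devkin correlate --a sim/speciesA.tsv --b sim/speciesB.tsv \
                 --pairs sim/orthologs.tsv --classes sim/classes.tsv --out corr/
```

All interchange formats are plain TSV; matrix headers encode time and
replicate as `t<hpf>` / `t<hpf>_r<rep>`.

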