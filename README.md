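# delcall

Indirect genotyping of a recurrent alpha-globin deletion from SNP-array
data: an evaluation pipeline for population geneticists and GWAS analysts
who need to know whether a structural variant that is invisible to their
array can be recovered indirectly — from flanking haplotypes, from probe
intensities, or from trained classifiers — instead of by direct PCR typing.

The motivating case is the 3.7 kb alpha-thalassaemia deletion: a strongly
malaria-protective allele that recurs by unequal crossover between the
duplicated *HBA* genes, so it sits on many unrelated flanking haplotypes.
The resulting linkage disequilibrium with any nearby SNP is tiny
(max r² ≈ 0.08–0.16 in the motivating cohort), which silences it in
standard association scans and breaks LD-based imputation — while probes
*inside* the deletion still show a dosage-dependent intensity signal.

## What the package provides

* **Synthetic cohort generator** (`sim_config()`, `simulate_dataset()`) —
  phased founder-mosaic haplotypes carrying the deletion on a configurable
  number of independent origins, dosage-dependent two-channel probe
  intensities with heavily overlapping classes, and case/control phenotypes
  with protective odds ratios (0.79 het / 0.59 hom) confounded by sex,
  ethnicity and a sickle-like locus. Fully seeded and deterministic.
* **Haplotype statistics** — `pairwise_ld()` (r, r², signed D′ from phased
  counts), `ld_profile()`, `ehh()` (extended haplotype homozygosity),
  `haplotype_spectrum()` / `haplotype_diversity()` (Nei), `tajimas_d()`,
  `cluster_haplotypes()`.
* **Intensity callers** — `density_cutoffs()` + `call_by_cutoffs()`
  (KDE trough/shoulder cut points C1 < C2; call rule hom ≤ C1 < het < C2 ≤ WT)
  and `hierarchical_call()` (heatmap-style clustering cut at 3).
* **Model callers** — `fit_mrm()` / `predict_mrm()` (multinomial softmax on
  per-probe X, Y, X·Y terms, heterozygote reference) and `fit_cart()` /
  `predict_cart()` (Gini trees, stop at node size < 5), with
  `bootstrap_training_curve()` and `roc_curves()`.
* **Imputation** — `impute_deletion_haplotype()` (Li–Stephens
  forward–backward over a reference panel; stands in for IMPUTE2),
  `impute_deletion_genotype()`, `call_genotypes()` (0.7/0.9 thresholds with
  no-call) and `imputation_cross_validation()` (repeated 100-individual
  reference panels).
* **Association** — `fit_logistic()` (IRLS with separation flagging),
  `genetic_association()` (additive / genotypic / dominant / recessive /
  heterozygous, covariate-adjusted), `region_scan()` (Bonferroni 0.05/m).
* **Evaluation & pipeline** — `performance_report()` (confusion metrics,
  adjusted-correct, no-call, dosage correlation), `compare_methods()`,
  `run_pipeline()` and a `delcall` CLI (`inst/exec/delcall`).

## Worked example

```r
library(delcall)

cfg <- sim_config(n_individuals = 800, seed = 5)
ds  <- simulate_dataset(cfg)
g   <- deletion_genotypes(ds$genotypes)

# low LD despite a common deletion
max(ld_profile(ds$panel)$r2, na.rm = TRUE)
#> [1] 0.1209634

# cross-validated imputation of the masked deletion
cv <- imputation_cross_validation(ds$panel, ds$map,
        imputation_config(runs = 3, seed = 2))
cv
#> imputation_cv: 3 runs, thresholds 0.7/0.9
#>   threshold 0.7 : mean adjusted-correct = 0.964 , mean no-call = 0.0338
#>   threshold 0.9 : mean adjusted-correct = 0.981 , mean no-call = 0.159

# covariate-adjusted genotypic association of the true genotypes
as.data.frame(genetic_association(g, ds$phenotypes, model = "genotypic"))[,
  c("term", "or", "ci_low", "ci_high", "p")]
#>   term        or    ci_low  ci_high         p
#> 1  het 0.9236909 0.6721794 1.269311 0.6245060
#> 2  hom 0.8888359 0.5754622 1.372860 0.5952192
```

Reading the output: the deletion is at 38% frequency yet no flanking SNP
exceeds r² ≈ 0.12 — the recurrent-origin regime. Imputation from a
100-individual reference panel still recovers ~96% of callable genotypes
here (the synthetic world is cleaner than a real cohort; see the methods
vignette for what is and is not emulated). At n = 800 the protective ORs
(true 0.79/0.59) are estimated with wide CIs covering the truth; the
study-scale n = 3036 recovers them reliably (see
`tests/testthat/test-acceptance.R`, criterion 4).

The heterogeneity mechanism in one experiment: hold the seed fixed and vary
only the number of deletion origins —

```r
for (k in c(1, 8)) {
  p <- simulate_haplotype_panel(sim_config(n_individuals = 600,
                                           n_del_origins = k, seed = 3))
  cv <- imputation_cross_validation(p, attr(p, "map"),
          imputation_config(runs = 10, seed = 3, thresholds = 0.7))
  cat(k, "origin(s): adjusted-correct",
      round(cv$summary[["0.7"]]["mean", "adjusted_correct"], 3), "\n")
}
#> 1 origin(s): adjusted-correct 0.997
#> 8 origin(s): adjusted-correct 0.957
```

Intensity-based callers are unaffected by this change (the deletion
genotypes are identical under the shared seed); only the LD-based route
degrades.

## Command line

```sh
Rscript inst/exec/delcall simulate --config inst/extdata/example_config.json \
    --seed 13 --out-dir out/
Rscript inst/exec/delcall run --seed 13 --out-dir out/   # full pipeline + manifest
```

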