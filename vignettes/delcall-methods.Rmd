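---
title: "Indirect genotyping of a recurrent alpha-globin deletion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect genotyping of a recurrent alpha-globin deletion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delcall)
```

## The problem

The 3.7 kb alpha-thalassaemia deletion (-α3.7) is one of the commonest human
structural variants and a strong malaria-protective allele, yet it is
essentially invisible to SNP-array association scans: it recurs by unequal
crossover between the duplicated *HBA1*/*HBA2* units, so the deletion sits on
many unrelated flanking haplotypes and its linkage disequilibrium with any
nearby SNP is very low. `delcall` packages the full evaluation workflow for
*indirect* genotyping of such a variant from array data: haplotype and LD
statistics, intensity-based callers, model-based callers trained on a small
directly typed subset, haplotype-copying imputation with cross-validation,
and covariate-adjusted case-control association testing — all runnable on a
synthetic cohort whose statistical structure mimics the real one.

Genotypes are coded `0` (two intact copies, WT), `1` (heterozygote) and `2`
(deletion homozygote) throughout; copy number at probes inside the deletion
is `2 - genotype`.

## The synthetic cohort

`sim_config()` / `simulate_dataset()` generate phased haplotypes, diploid
genotypes, two-channel probe intensities and phenotypes. The defaults are the
study-scale conditions: 3,036 individuals, 178 flanking SNPs plus the
deletion, deletion allele frequency 2320/6072 ≈ 0.382 (giving genotype
proportions ≈ 38/47/15% under Hardy–Weinberg, matching the cohort's
37.5/48.6/13.9%), six probes inside the deletion and three flanking control
probes, and case/control labels with protective genotype odds ratios 0.79
(het) and 0.59 (hom) confounded by sex, ethnicity (four groups at the
cohort's frequencies) and a strongly protective independent biallelic locus
(sickle-like, allele frequency 0.054, per-allele OR 0.25 — the study does not
print this effect in its subset, so the default is a deliberate package
choice).

**Haplotype model.** Chromosomes are mosaics of `n_founders = 60` founder
haplotypes: a founder is drawn per chromosome and re-drawn between adjacent
markers with probability `1 - exp(-n_generations * d)` for map distance `d`
in Morgans (`n_generations = 300`, uniform 1.5 cM/Mb map by default, ~1.8
switches per chromosome over the 313 kb region). Founder alleles follow a
neutral-ish `P(k) ∝ 1/k` carrier-count spectrum, plus one private "tag" SNP
per founder at the markers nearest the deletion. The deletion rides on
`n_del_origins` founders whose combined copying weight equals `del_freq`.
This construction controls LD analytically: with a single origin the
deletion coincides with that founder's tag (max r² ≈ 1 under tight linkage);
with 8 origins each tag is nested in the deletion at frequency ≈ 0.048, so
max r² is capped near `p(1-q)/(q(1-p)) ≈ 0.08` — the low-LD regime the real
cohort shows. A small per-site flip noise (0.002) emulates array/phasing
error. Because carrier founders always occupy the leading portion of the
cumulative copying weights, two simulations differing *only* in
`n_del_origins` under the same seed produce identical deletion genotypes —
which makes the heterogeneity experiment exactly paired.

**What the generator does not emulate.** Chromosomes are exchangeable draws
from a 60-founder mosaic, not a coalescent: haplotype-frequency spectra,
Tajima's D (mildly negative here, strongly positive in the study region) and
recombination hot-spot structure are not calibrated. Probe intensities are
conditionally independent given copy number, whereas real array probes share
sample-level noise; multi-probe callers (MRM, hierarchical clustering)
therefore look better here than on real data, and imputation accuracy at 8
origins (~0.96 adjusted-correct at n=600) exceeds the study's real-data
value (~0.85). Green tests establish internal correctness and the
*direction* of the heterogeneity mechanism, not real-data performance
levels. Breakpoint micro-heterogeneity and other deletion types are not
simulated; telomeric intensity attenuation is out of scope.

**Intensities.** Summed intensity `s = x + y` at in-deletion probes is a
truncated normal (at zero; a hard clamp would create a spurious point mass)
with copy-number means 0.12/0.40/0.75 and SDs 0.10/0.12/0.14 — chosen so
that kernel-density cut-offs land near the published calibration (C1 ≈ 0.2,
C2 ≈ 0.5–0.87) and the heterozygote/WT overlap is substantial, which is the
regime that defeats intensity-only calling. The X/Y split at a probe is an
independent noisy ratio around 0.5; the study gives no generative model for
channel asymmetry inside the deletion, so this is a package decision.

## Callers

**Density cut-offs** (`density_cutoffs()`, `call_by_cutoffs()`). A Gaussian
KDE (Silverman's rule by default, overridable) is segmented by the sign of
its second derivative into concave "bumps" (mixture components). Fragments
closer than two bandwidths are merged (KDE noise fractures modes) and bumps
holding under 5% of probability mass are dropped. With three bumps, each cut
point is the density minimum between adjacent bump peaks (a trough) or, on a
monotone stretch, the midpoint between the bump-closing inflection and the
interior slope extremum (a shoulder). The calling rule is exact:
hom-del `s <= C1`, het `C1 < s < C2`, WT `s >= C2`. At the default
calibration only a shoulder separates hom-del from het (the true mixture
density is monotone there), exactly as the study describes for its
features; like the study, roughly 4 of 6 probes yield usable cut points.

**Hierarchical clustering** (`hierarchical_call()`). Per-probe standardised
summed intensities, complete linkage on Euclidean distance (heatmap
defaults), tree cut at 3, clusters labelled by ascending mean intensity.
Complete linkage is outlier-sensitive; occasionally a run yields one outlier
cluster and badly mixed remaining clusters — a realistic failure mode that
the comparison harness reports rather than hides.

**MRM** (`fit_mrm()`, `predict_mrm()`). Multinomial softmax regression with
the heterozygote as the reference class: per non-reference class `g`,
`l_g = a_g + Σ_k (b_gk x_k + c_gk y_k + d_gk x_k y_k)` over probes `k`, and
`p(het) = 1/(1 + e^{l_hom} + e^{l_wt})` etc. Fitted by BFGS with analytic
gradient on a ridge-penalised likelihood (default `1e-4`, intercepts
unpenalised) so separable training sets still have a finite optimum.
Prediction is the argmax with ties broken toward the lowest genotype code. A
summed-intensity-only feature mode (`features = "sum"`) supports comparison
with the cut-off caller.

**CART** (`fit_cart()`, `predict_cart()`). Greedy binary splits minimising
weighted Gini impurity, thresholds at midpoints between sorted unique
values, growth stopped when a node is pure or smaller than five samples (the
study's rule); leaves predict their majority class, ties toward the lowest
code. No pruning, matching the stop-rule-only design. A known limitation,
visible in our tests and in the study's own results: with ~14 homozygote
training samples at n = 100 the tree's hom-del sensitivity is unstable
(0.76–1.00 across seeds), so the package's property tests pin the stable MRM
bound and CART's monotone degradation with class separation rather than a
fixed CART sensitivity.

**Training-size bootstrap** (`bootstrap_training_curve()`). For each size in
the grid (default 50–500 by 50; the study's Results mention 10–500, its
Methods 50–500 — the grid is configurable) draw training sets, fit, score
the held-out remainder; the "plateau" is the smallest size whose mean
accuracy is within one SD of the largest size's.

## Imputation

`impute_deletion_haplotype()` is a Li–Stephens haplotype-copying HMM
standing in for the IMPUTE2 binary (out of scope to invoke): each test
haplotype copies one of `H` reference haplotypes; between markers the copy
switches with probability `rho_j = 1 - exp(-4 Ne c_j / H)` spread uniformly
over all `H` (default `Ne = 20000`, the study's setting), and the emitted
allele matches the copied one with probability `1 - theta`
(default `theta = 1e-3`). The recursion is the scaled forward–backward,
vectorised across test haplotypes; the deletion column is masked
(uninformative emission) and its posterior is the state posterior at that
marker dotted with the theta-smoothed reference deletion alleles. Map
distances come from the cumulative map with a `1e-8` Morgan floor per
interval; a zero-width map falls back to that floor with a message. Genotype
posteriors compose the two (phased) chromosome posteriors independently;
calls require the argmax class to reach the threshold (relaxed 0.7 / strict
0.9, boundary equality called), otherwise no-call. This model differs from
IMPUTE2's surrogate-family MCMC, but implements the same panel-matching
principle and is exactly testable against path enumeration.

`imputation_cross_validation()` reproduces the study's design: each run
draws a 100-individual reference panel, masks the deletion in the remainder,
imputes, calls at both thresholds, and records correct, adjusted-correct
(`correct / (total - no-calls)`), no-call proportions, one-vs-rest
sensitivity/specificity/accuracy/PPV per class, and the Pearson correlation
of called vs true dosage; runs are summarised as
min/quartiles/mean/SD/max. The default is 1,000 runs; tests and the
acceptance suite scale down to ≤ 10 runs per cross-validation to stay within
their time budgets, stated where done.

## Association

`fit_logistic()` is iteratively reweighted least squares to relative
deviance tolerance 1e-8 (max 50 iterations), with explicit separation
flagging (diverging |β| > 15) and rank-deficiency errors naming the
collinear columns. `genetic_association()` encodes the genotype per model —
additive dosage; genotypic het/hom indicators against WT; dominant
`g >= 1`; recessive `g == 2`; heterozygous `g == 1` — adds sex, ethnicity
indicator contrasts and sickle-locus dosage, drops no-calls complete-case
with the count reported, and reports Wald odds ratios, 95% CIs
(`exp(β ± 1.96 SE)`) and p-values, matching the study's reporting style
(likelihood-ratio tests are not implemented). The "overall" association is
operationalised as the additive model; a chromosome-level allelic 2×2 OR is
available implicitly through the oracle construction in the tests.
`region_scan()` fits every polymorphic variant and reports the Bonferroni
threshold `0.05/m` (0.00028, printed as P < 0.0003, for the 178-SNP region).

## Numerical choices and degenerate inputs

* Monomorphic variants give explicit undefined-LD errors, never silent NaN;
  profiles record a per-variant reason instead.
* Signed D′ is reported; its magnitude is what the study quotes.
* All posteriors/probabilities are renormalised per row; forward–backward is
  per-site scaled.
* Undefined performance rates (empty denominators) are `NA`, never 0.
* All randomness descends from one integer seed via derived sub-seed
  streams (`withr::with_seed`); no global RNG state is disturbed.
* Configs are JSON (the environment pins `jsonlite`; YAML is not guaranteed
  offline), consumed by `read_pipeline_config()` and the `delcall` CLI.

## Known limitations

Besides the generator caveats above: the CLI is a thin dispatcher (no shell
completion, no parallelism); EHH has no iHS/XP-EHH extension; CART has no
cost-complexity pruning; imputation handles a single biallelic deletion in
one contiguous region only. The cut-off shoulder detector formalises what
the study's authors did by eye; its placement rule was fixed once against
the published calibration values and is not tuned per dataset.
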