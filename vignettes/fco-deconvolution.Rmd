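---
title: "Estimating fetal-cell-origin fractions from methylation beta values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fetal-cell-origin fractions from methylation beta values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcomix)
```

## The model

Differentiated cells retain DNA methylation marks laid down in early
development, so a bulk tissue sample can be read as a mixture of cells of
fetal (embryonic-lineage) origin and cells of adult-stem-cell origin. Given
a reference panel of ontogeny-informative CpG probes — each with a mean
beta value (methylation fraction, $\beta = M/(M+U) \in [0,1]$) in fetal
tissue ($f_j$) and in adult tissue ($a_j$) — the observed beta vector $y$
of a sample is modelled as a convex combination of the two profiles. The
fetal-cell-origin (FCO) fraction $w_F$ is estimated by constrained least
squares over the sample's non-missing panel probes $j$:

$$\min_{w_F, w_A} \sum_j (y_j - w_F f_j - w_A a_j)^2
\quad \text{s.t.} \quad w_F \ge 0,\; w_A \ge 0,\; w_F + w_A \le 1 .$$

The inequality $w_F + w_A \le 1$ (rather than equality) is a deliberate
choice: tumors plausibly contain cell states resembling neither reference
profile, and an FCO near 0 with $w_A < 1$ must be representable. The
unexplained remainder $1 - w_F - w_A$ is implicit. The canonical panel has
27 CpGs; any panel of at least 2 probes with non-identical profiles is
accepted.

Because the problem has only two unknowns over a triangular feasible
region, `project_sample()` solves it exactly by KKT case enumeration: the
unconstrained $2 \times 2$ normal-equation solution is used when feasible,
otherwise the best of the three edge projections and the vertices. This is
deterministic, has no convergence tolerance in the usual sense (all
arithmetic is closed-form; ties between candidates are broken by candidate
order, which is fixed), and was preferred over an iterative QP solver
because it is exact. `fco_grid_search()` provides an independent
brute-force check: exhaustive evaluation over a $(w_F, w_A)$ grid, ties
broken toward smaller $w_F$ then smaller $w_A$. The test suite holds the
two routes to within $2 \times 10^{-3}$ at grid step $10^{-3}$ on random
instances, and to $10^{-6}$ of the truth on exact mixtures.

Missing probes are dropped per sample (pairwise deletion), never imputed;
this mirrors the tolerance of the upstream analysis for a small number of
absent panel probes, and the quality-control rule below bounds how many may
be missing. `probe_dropout_stability()` quantifies the resulting
sensitivity by re-estimating $w_F$ under all leave-$k$-out probe subsets
($k \le 5$ by default), exhaustively while $\binom{L}{k} \le 10{,}000$ and
by a seeded random sample of 10,000 subsets beyond that (at $L = 27$,
$\binom{27}{5} = 80{,}730$).

## Quality control

Input matrices arrive as probes-by-samples beta tables in three dialects
(plain TSV; TCGA level-3-like with `"NA"` masking of SNP/repeat-adjacent
and non-detected probes; GEO series-matrix with `!`-prefixed metadata
lines). `"NA"`, `"na"`, `"NaN"` and empty cells all map to one missing
marker; betas exactly 0 or 1 are legal (clipped values occur in normalized
exports). `align_to_library()` reorders to panel order and keeps panel
probes absent from the platform as all-missing rows, so the QC denominator
stays at the panel size. `qc_filter_samples()` then retains samples with at
least `min_present` (default 25) of the 27 panel probes non-missing — the
same "at least 25 of 27" rule applied to the real cohorts, where two panel
probes were unavailable in the discovery platform's masked export.

## The three-way comparison

`fco_compare()` tests, per cohort, whether tumor tissue carries less FCO
signal than nontumor normal tissue, three ways:

1. **Wilcoxon rank-sum** (`rank_sum_test()`): exact enumeration when the
   combined n is at most 10 with no ties, otherwise the midrank normal
   approximation with tie-corrected variance and continuity correction.
2. **Covariate-adjusted OLS** (`adjusted_linear_model()`): FCO fraction
   regressed on group plus age, gender, race and vital status where
   available and relevant. `screen_covariates()` drops a covariate with a
   single observed level (e.g. gender in an all-female cohort) or more than
   50% missingness, recording the reason. Categoricals are dummy-coded with
   the first sorted level as reference, so the group coefficient is tumor
   minus nontumor. Complete cases only; rank deficiency is a hard error
   naming the collinear columns.
3. **Randomization-based test** (`randomization_test()`): because
   homoscedasticity and residual normality cannot be assumed for these
   outcomes (FCO is bounded, zero-inflated), the group t-statistic is
   compared against an empirical null built by permuting the tumor/nontumor
   labels — covariates stay attached to their samples — and refitting,
   50,000 times by default. The two-sided empirical p is
   $\#\{|t^*| \ge |t_{obs}|\}/B$ with no add-one correction; when no null
   statistic reaches $|t_{obs}|$ the value is reported at the floor $1/B$
   and rendered as a bound (`"<2E-05"` at $B = 50{,}000$). The count/B
   convention is what makes a sub-$1/B$ report possible at all. Permuted
   refits use the Frisch–Waugh–Lovell identity (covariates residualised
   once), which is algebraically identical to a full refit and makes
   50,000 permutations take well under a second at cohort sizes of a few
   hundred; an `exhaustive` mode enumerates all label assignments for
   small n, recovering the exact permutation test.

Cohorts with fewer than 3 samples in either group, and cohorts whose FCO is
one constant in both groups (zero variance — the prostate pattern, where
both groups sit at 0%), yield `NA` rows rather than errors.
`residual_diagnostics()` exports fitted values, standardized residuals,
$(i - 0.5)/n$ normal quantiles and $\sqrt{|r_i|}$ for QQ and
spread-location plots.

## Sensitivity analyses

`correlate_fco()` correlates FCO with age, tumor purity, or leukocyte
infiltration percentages. Spearman is the default — FCO distributions are
heavily zero-inflated, and rank correlation is the safer general choice —
with Pearson selectable; the pipeline reports both. Spearman is computed as
Pearson on midranks with the t approximation, so it is invariant under
strictly monotone transforms. Zero-variance inputs return a flagged `NA`
rather than an error. `purity_adjusted_model()` refits the purity–FCO
association with demographic adjustment; `iqr_screen()` restricts secondary
analyses to cohorts with nonzero FCO interquartile range (type-7
linear-interpolation quartiles, the most common convention — pinned here
for reproducibility); `stage_association()` fits a linear trend on
integer-coded stage (I–IV as 1–4, sub-stages collapsed by
`parse_tumor_stage()`; a trend test was chosen over ANOVA as the more
powerful option against the monotone alternative of interest, and is
labelled as such). All of these run through the same OLS core as the group
comparison — one code path, verified by identical toy-table results in the
tests. `extract_probe_betas()` pulls chosen panel probes (e.g. the three
EZH2-associated CpGs) into a long probe/sample/group/beta table for
external plotting.

## The synthetic cohort generator

Real inputs at cohort scale are not redistributable, so every stage is
exercised on simulated cohorts with known ground truth
(`simulate_cohort()`). The generator emulates the statistical structure the
estimator assumes:

* **Reference panel**: 27 probes by default, per-probe fetal–adult
  separation jittered around `delta = 0.5` (about the separation a usable
  ontogeny panel needs) with alternating direction, midpoints uniform.
  Probe IDs carry a `cgS` prefix: the packaged panel is synthetic, since
  the real 27-CpG reference profiles are not published in a reusable form.
* **True fractions**: truncated normals on $[0,1]$; defaults
  nontumor $\sim N(0.30, 0.15)$, tumor $\sim N(0.10, 0.10)$. The direction
  (nontumor above tumor) is the one observed in tissue; the magnitudes sit
  inside the 0–44.9% range reported for normal tissues. Null regimes are
  configured by equating the two distributions.
* **Observation noise**: logit-normal with sd 0.05 by default — the
  standard methylation noise model, which keeps betas in bounds without
  clipping artifacts (exact 0/1 mixtures are nudged by $10^{-6}$ before the
  logit). An additive-Gaussian-with-clipping alternative sits behind
  `noise_model = "additive"`.
* **Covariates**: age $\sim N(61.85, 13.60)$ truncated to $[18, 95]$,
  48.9% male, race frequencies 0.804/0.111/0.081/0.004 — the pooled
  demographics of the cohorts this analysis targets; optional linear
  age/gender effects on the true fraction for confounding scenarios.
* **Missingness**: independent per-cell masking at a configurable rate.

One global seed drives derived per-component streams, so a cohort is
bit-reproducible from its config. `make_fixture_suite()` writes a small
canonical cohort (library, betas in two dialects, sample sheet, truth
table) byte-identically for a given seed.

What the simulator does *not* emulate — array chemistry, type I/II probe
bias, batch effects, the mixed normalization pedigrees of public series,
correlated probe noise, genome-scale matrices — bounds what passing tests
show: they validate the estimator, QC and inference machinery under the
model's own assumptions, not robustness to every artifact of real arrays.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, by design, at desk scale:
solver-versus-oracle agreement on 100 random 5-probe instances (grid step
$10^{-3}$), parameter recovery on a 200-sample cohort at noise sd 0.05
(mean absolute error under 0.05, rank correlation above 0.95), null
calibration of the randomization test over 500 cohorts of 15+15 at
$B = 1{,}000$ (empirical size within $[0.03, 0.07]$ of nominal 0.05), and
the permutation floor on a 30+30 extreme-effect cohort at $B = 50{,}000$.
These sizes keep the whole suite under a minute while leaving each check
statistically meaningful.

Degenerate inputs are handled explicitly: fewer than 2 usable probes or
identical profiles on the usable probes are hard errors (annotated with the
sample ID at cohort level); an all-tied rank-sum comparison returns p = 1;
zero-variance correlations and single-level stage vectors return flagged
`NA`s; comparison cohorts below the minimum group size return `NA` rows.

## Limitations

Estimated fractions carry no confidence intervals; the panel dichotomy is
fetal/adult only (no K > 2 references); stage sub-levels are collapsed; and
the per-cohort p-values are reported without multiple-testing correction
across cohorts, matching the per-study reporting convention of the analyses
this package reimplements.
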