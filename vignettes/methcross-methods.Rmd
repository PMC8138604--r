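---
title: "Models and design choices in methcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in methcross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcross)
```

`methcross` compares DNA methylation between a murine tumour model and
human methylome datasets. This vignette explains the statistical models
the package implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions taken where
more than one reasonable convention exists.

## Scales and transforms

Methylation at a CpG is summarised as the fraction
$\beta = \frac{\#\text{methylated reads}}{\#\text{total reads}}$ and
transformed to $M = \log_2\frac{\beta + c}{1 - \beta + c}$ with
stabilising constant $c = 0.01$. $\beta$ is bounded and heteroscedastic
(variance shrinks near 0 and 1); $M$ is unbounded with approximately
constant variance, the scale on which per-locus linear models are fitted.
The transform is a bijection on $[0,1]$ for any $c > 0$
(`beta_from_m()` inverts it exactly), and antisymmetric around
$\beta = 0.5$. All effect sizes reported to users are differences of
group means on the $\beta$ scale, because "a 30% difference in
methylation" is only meaningful there.

Coordinates are **1-based inclusive** everywhere inside the package, so a
region's width is $end - start + 1$; conversion to the 0-based half-open
convention happens only inside the BED/BedGraph writers.

## Locus filtering

Two rules, both with count units:

* `min_coverage = 8` (reads): a locus is kept only if its *minimum*
  coverage across all samples reaches 8×, i.e. every sample contributes an
  informative $\beta$. The alternative reading (mean or any-sample
  coverage) would admit loci whose $\beta$ in some samples is estimated
  from a handful of reads.
* `min_meth_reads_total = 6` (reads): at least 6 methylated reads summed
  over all samples, so that some methylation signal exists; loci
  methylated nowhere carry no contrast.

Rule order does not matter and the filter is idempotent (both are tested
properties). Zero-coverage records are already dropped at read time: they
carry no information, and removing them early keeps the count-table
invariant ($n_{total} \ge 1$) simple. Whether coverage files were
strand-merged upstream is taken as given — the package applies no
strand collapsing of its own.

Array probes are filtered by detection p-value instead
(`detection_p = 0.01`, removed if exceeded in *any* sample). 0.01 is the
common convention for Infinium-style arrays; it is configurable because
only "high detection p-values" is inherent to the design.

## Per-CpG inference: moderated t on M-values

Each testable locus gets an OLS fit of $M$ on intercept + group
indicator (closed form: the coefficient is the difference of group means,
$d = n - 2$ residual df). With few samples per group, per-locus variance
estimates are unstable, so they are moderated: assuming
$s^2 \mid \sigma^2 \sim \sigma^2 \chi^2_d / d$ and an inverse-chi-squared
prior $\sigma^2 \sim s_0^2 d_0 / \chi^2_{d_0}$, the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and
$t = \hat\beta_1 / \sqrt{\tilde s^2 (1/n_1 + 1/n_2)}$ follows a
t-distribution with $d_0 + d$ df. The hyperparameters are estimated by
matching the mean and variance of $\log s^2$ to their theoretical values
(digamma/trigamma expressions), with the trigamma equation inverted by
Newton iteration. Numerical decisions:

* when the observed spread of $\log s^2$ does not exceed the pure
  sampling term, the moment equation has no finite solution; $d_0$ is
  capped at $10^6$ instead of special-casing infinity (at that df the
  t reference is indistinguishable from normal);
* identical variances short-circuit to complete shrinkage with
  $s_0^2$ equal to the common value;
* fewer than 10 testable loci fall back to $d_0 = 0$ (no moderation) with
  a warning — there is not enough information to estimate a prior;
* `d0 = 0` can be forced, which reduces the whole pipeline to per-locus
  two-sample t-tests (used as an oracle equivalence in the tests, which
  also cross-check the estimates against limma's `eBayes` on the same
  matrices).

Tests are two-sided (both hyper- and hypomethylation are of interest).
FDR control is Benjamini–Hochberg step-up over *testable* loci only — BH
is defined over tested hypotheses, so loci untestable in a dataset are
excluded from its denominator. Significance thresholds: FDR < 0.10 for
RRBS-style data, FDR < 0.05 for arrays, whose larger sample sizes support
the more conservative cut. Unpaired contrasts are used throughout, also
for datasets with matched samples, since pairing metadata is not part of
the input contract.

## Region detection and beta-binomial testing

Candidate regions are agglomerations of `min_cpgs = 15` CpGs within
`max_span_bp = 200` bp, each member covered (≥1 read) in
`min_presence = 0.75` of samples. The thresholds define *what* a
candidate is but not *how* to scan for one; the package uses a greedy
left-to-right scan per chromosome emitting maximal non-overlapping
windows (advance by one locus when a maximal window is too small).
Greedy maximal windows are deterministic and verifiable against an
exhaustive enumeration oracle, which the test suite does on random locus
layouts.

Each candidate is tested with the smallest model that is genuinely
beta-binomial "regression for the region": methylated counts
$y_{ij} \sim \mathrm{BetaBin}(n_{ij}, \mu_{ij}, \rho)$ with
$\mathrm{logit}(\mu_{ij}) = b_0 + b_1 \cdot \text{group}(j)$ shared
across member CpGs and a *single* region-level dispersion $\rho$
(intra-class correlation parameterisation). Maximum likelihood uses
Nelder–Mead (BFGS in one dimension, where Nelder–Mead is unreliable)
on $(b_0, b_1, \mathrm{logit}\,\rho)$ with relative tolerance
$10^{-10}$; the p-value is the likelihood-ratio statistic of $b_1$
against $\chi^2(1)$. As $\rho \to 0$ the likelihood collapses to the
logistic-binomial model, an equivalence the tests verify against `glm`
(dispersion fixed at 0, $|\Delta p| < 10^{-3}$). Non-converging regions
are flagged and excluded from the region FDR with a warning rather than
reported with an untrustworthy p.

Region summaries report group medians across member CpGs of the per-CpG
group-mean $\beta$, and `median_difference` = the median across member
CpGs of the per-CpG differences. These are distinct statistics: for
heterogeneous regions the median of differences does not equal the
difference of medians, and only the former is used for ranking
(descending $|$median difference$|$, ties broken by chromosome then
start for determinism). Region significance uses FDR < 0.10, matching
the CpG-level RRBS threshold, since no separate regional threshold is
inherent to the design. Both the regional LRT p (used for FDR) and the
median of per-CpG p-values (`median_p`) are emitted, as the two are
complementary summaries.

Gene context labels a region `genic` if it overlaps any gene body,
else `promoter` if it overlaps a window `promoter_window_bp = 1500` bp
upstream of a TSS (strand-aware), else `intergenic`. 1.5 kb matches the
annotation convention of the human array data this pipeline is meant to
interoperate with; gene bodies take precedence because a body overlap is
the more specific claim.

## Sample-level analyses

`average_methylation()` works on one number per sample (the mean β over
retained loci), not per locus: group comparisons of global methylation
are claims about samples. Inference is one-way ANOVA with Tukey HSD
contrasts when more than two groups are present; with two groups the
ANOVA p equals the pooled two-sided t-test (a tested identity). If all
sample means are identical the F statistic is reported as 0 with p = 1
rather than the 0/0 form.

Clustering uses the `top_k = 10000` most variable loci (variance of β
across samples; ties broken by position) to suppress uninformative loci,
then agglomerative clustering on Euclidean distances between sample β
profiles. Average linkage is the default — the least extreme choice —
with single/complete/ward available, since no linkage is inherent to the
design. An optional mode clusters on the rows of the sample-covariance
matrix instead of raw profiles, preserved for fidelity experiments with
covariance-based distance descriptions.

The BS/oxBS contrast (`assess_hydroxymethylation()`) estimates 5hmC as
$\beta_{BS} - \beta_{oxBS}$ per locus and sample — deliberately simple,
not a joint maximum-likelihood 5hmC estimator. The dataset verdict is a
z-type criterion: "indistinguishable from noise" when the mean estimate
lies within `z_mult = 2` standard errors of zero. Under a simulated null
this calls noise in ≥95% of seeds (tested).

## Orthologs and cross-species tests

Ortholog resolution applies, per mouse gene: (1) restrict to
high-likelihood candidates when any exist; (2) keep maximal homology
percentage, compared after rounding to 4 decimals so float noise cannot
break ties nondeterministically; (3) prefer case-insensitively identical
symbols (human symbols are upper-case where mouse symbols are
title-case, so FILIP1L must match Filip1l); (4) keep all survivors.
Which of the two directional homology percentages feeds the table is the
caller's choice; the package consumes a single column.

Gene-level summaries define a gene's direction as the sign of Δβ at its
strongest significant locus (largest $|\Delta\beta|$) — deterministic and
dominated by the clearest signal. `has_clear_dm` requires a significant
locus with $|\Delta\beta| \ge$ `clear_delta = 0.30`. Enrichment and
direction-concordance use Pearson chi-squared on 2×2 tables without
continuity correction (configurable), Bonferroni-adjusted across
subtypes; expected cells below 5 warn but still report. The risk-group
concordance test is a one-sided exact binomial tail
$P(X \ge k),\ X \sim \mathrm{Bin}(n, 0.5)$: the direction hypothesis is
pre-specified by the tumour-vs-control comparison, making the one-sided
test the natural choice.

## The synthetic generator

`simulate_rrbs()` emulates the statistical structure the pipeline is
designed for:

* **bimodal baselines**: 60% of CpGs from Beta(1.5, 13.5) (low mode,
  mean ≈ 0.10) and 40% from Beta(12, 3) (high mode, mean ≈ 0.80), the
  characteristic two-peaked β histogram of CpG-dense sequencing;
* **coverage**: negative binomial, mean 30, size 8 — realistic RRBS
  depth with overdispersion; zero draws become missing records, which
  exercises the presence rules;
* **counts**: beta-binomial with intra-class correlation ρ = 0.02,
  mild biological within-group variability
  (variance $n\mu(1-\mu)(1 + (n-1)\rho)$, a tested moment identity);
* **planted DMRs** in 5% of genes: 20 CpGs across 150 bp with a target
  β-difference of 0.4. Effects are injected on the logit scale — the
  per-CpG offset is chosen so the group-mean difference equals the
  target exactly, with DMR baselines drawn away from the boundary so no
  clipping can occur;
* **global hypermethylation**: a common logit offset solved numerically
  so the overall tumour-vs-control increase in mean β (planted regions
  included) hits `global_shift_mean_beta = 0.128`, the mouse-like
  headline condition; setting it to 0 disables the shift entirely;
* **sample sizes**: 6 tumours vs 6 controls, the design scale of a small
  animal study.

`simulate_array()` fabricates human-like probes for the orthologs of the
simulated mouse genes: logit-scale Gaussian noise (sd 0.5) around group
means, planted effects (±0.35) in genes flagged as shared, direction
agreeing with the mouse direction with probability `concordance_prob`,
and a 5% fraction of probes with failing detection p-values. Everything
is byte-identical under a fixed seed, and the generator writes exactly
the file formats the readers parse, so synthetic runs exercise the real
I/O paths.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: read-level error and bisulfite
conversion failure, strand structure, positional autocorrelation of
methylation outside planted regions, batch and composition effects,
array probe cross-hybridisation, and paired-sample correlation. Results
on real data additionally depend on annotation quality and on upstream
alignment choices that are out of scope here.

## Problem sizes and runtime

Default generator sizes (500 genes, ~20 CpGs per gene, 6+6 samples) keep
a full pipeline run in the seconds range. The test-suite and acceptance
simulations use 40–200 genes and 6–20 seeds per property — sizes chosen
so each stochastic check has clear Monte-Carlo margins (3 standard
errors for calibration bounds) while the whole suite stays fast enough
to run on every change.

## Known limitations

* The beta-binomial fit uses one dispersion per region; strong per-CpG
  dispersion heterogeneity will be absorbed into the mean model.
* No smoothing of methylation levels along the genome is applied before
  region testing.
* No covariate adjustment (age, sex, batch) — the target designs have
  none; extending the locus model to additional columns would be the
  natural route.
* M-values from low (but filter-passing) coverage are discrete; at 8×
  the normal approximation underlying the moderated t is rough, which is
  why calibration is verified by simulation rather than assumed.
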