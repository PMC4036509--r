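---
title: "Methods: pooled-variance factorial differential expression and N-acquisition efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-variance factorial differential expression and N-acquisition efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroot)
```

This vignette is the package's own account of the statistics it
implements: the model and its assumptions, what every tunable parameter
means, what the synthetic-data generators do and do not emulate, the
numerical conventions, and the design choices made where more than one
defensible option existed.

## The differential-expression model

For each transcript the normalized log2 expression signal is modelled as a
balanced two-way factorial,

$$Y_{ijk} = \mu + G_i + N_j + GN_{ij} + E_{ijk},\qquad
E_{ijk} \sim \mathcal N(0, \sigma^2),$$

with genotype $i$ (wild type vs. mutant), nitrate supply $j$ (high vs.
low) and biological replicate $k = 1,\dots,r$. On a balanced design the
total sum of squares about the grand mean partitions exactly into the
three factorial terms and the residual:

$$SS_G = 2r\sum_i(\bar y_{i\cdot\cdot}-\bar y_{\cdot\cdot\cdot})^2,\quad
SS_N = 2r\sum_j(\bar y_{\cdot j\cdot}-\bar y_{\cdot\cdot\cdot})^2,$$
$$SS_{G\times N} = r\sum_{ij}(\bar y_{ij\cdot}-\bar y_{i\cdot\cdot}
-\bar y_{\cdot j\cdot}+\bar y_{\cdot\cdot\cdot})^2,\quad
SS_E = \sum_{ijk}(y_{ijk}-\bar y_{ij\cdot})^2,$$

each factorial term with one degree of freedom and the residual with
$4(r-1)$. `fit_gene_anova()` computes this decomposition vectorised over
genes; the test suite cross-checks it against a least-squares projection
oracle (`stats::lm` + `stats::anova`) and verifies the conservation
identity to a relative tolerance of $10^{-9}$. Unbalanced designs are
rejected outright rather than approximated: with unbalance the
decomposition is no longer unique (Type I/II/III ambiguity), and the
experimental design this package targets is balanced by construction.

### Why a global variance, and which reference distribution

With $r = 3$ the per-gene residual variance $s^2 = SS_E/8$ is far too
noisy to test against. The package therefore pools a **global residual
variance** across genes after discarding genes with extreme per-gene
variance, and treats it as known in the test statistic

$$T_c = SS_c / \hat\sigma^2_{\text{global}} \sim \chi^2(1)
\quad\text{under } H_0.$$

Treating $\hat\sigma^2$ as known is justified by its pooled degrees of
freedom (thousands of genes × 8 df each); the alternative
$F(1, \text{pooled df})$ reference is available via
`contrast_tests(..., reference = "f")` and is numerically
indistinguishable at genome scale (the suite checks agreement to
$10^{-3}$).

### Variance trimming

"Extreme variation" is removed by a two-sided quantile trim, by default at
the 0.025 and 0.975 quantiles of the per-gene $s^2$ distribution
(inclusive linear-interpolation quantiles, `stats::quantile()` type 7;
genes strictly outside the bounds are dropped). Both bounds are exposed
(`trim_q`), and `c(0, 1)` disables trimming. Two-sided symmetric trimming
was chosen because low-variance outliers (flat-lined probes) distort the
pool just as high-variance ones do.

A known property of this estimator: the $s^2$ distribution under the null
is right-skewed ($\sigma^2\chi^2_8/8$), so a symmetric two-sided trim
removes more mass from the right tail and the trimmed mean underestimates
$\sigma^2$ by roughly 2% at 8 residual df. The contrast statistics are
correspondingly inflated by the same factor, which makes the pipeline
mildly anti-conservative: its realised family-wise error rate under the
complete null sits slightly above the nominal 0.05 rather than at it. We
keep the plain trimmed mean because it is the transparent, standard
reading of "pooled variance after removing extreme genes"; the
`scripts/acceptance.R` script measures the realised FWER directly on
1,000 simulated null datasets.

### Multiplicity and declaration

Raw p-values are Bonferroni-adjusted **per contrast family**
($p_{\text{adj}} = \min(1, m\,p)$): the genotype, nitrate and interaction
families are corrected independently, each over the $m$ genes tested.
Bonferroni then controls the family-wise error rate within each family;
the union of the three families is necessarily larger (three independent
contrasts each controlled at 0.05 yield a union rate near
$1-(1-0.05)^3 \approx 0.14$), which is an inherent property of per-family
correction, not a defect. The multiplicity universe $m$ defaults to the
number of probes passing the expression filter — the tests actually
performed — and can be set to the full probe count instead. A gene is
declared differentially expressed at $p_{\text{adj}} < \alpha$ (strict
inequality; a gene sitting exactly at $\alpha$ is not declared).

### Expression filter

Probes are retained when their **maximum** normalized signal across all
samples is strictly greater than the threshold (default 4 on the log2
scale): signal above the detection cutoff in at least one sample. Ties at
exactly 4 are removed. Filtering precedes all testing, so the default $m$
is the filtered count.

### Direction and magnitude calls

For the two main effects the direction is the sign of the marginal-mean
difference (MUT − WT, resp. LN − HN), with a `strong` flag when the
absolute log2 difference exceeds 1 (the conventional two-fold threshold).
The interaction has no single direction and is rejected by
`effect_direction()` — its four cell means are the interpretable summary.
An exactly zero difference is deterministically reported as "down" with a
`tie` flag, so property tests and repeated runs see identical output. A
per-nitrate conditional genotype test (a genotype effect present only
under one nitrate level) is *not* implemented: it is a different
hypothesis than the three factorial contrasts and would need its own
multiplicity treatment.

## The expression simulator

`simulate_expression()` generates the balanced 2×2×r design on the
normalized log2 scale: per-gene baselines uniform on 2–14 (the span of
normalized array intensities), independently drawn gene subsets carrying
genotype, nitrate and interaction effects (independent draws let the
subsets overlap, as real factorial responders do), and i.i.d. Gaussian
noise. Default study conditions: 2,000 genes, $r = 3$, 5% / 5% / 1%
effect fractions, effects of 2 log2 units, noise sd 0.5 log2 — three
replicates matching the experimental design the package targets, and a
noise level typical of between-replicate variability of normalized
arrays.

Effects are planted in the effect-coded form: main effects split
$\pm e/2$ across the two levels so that the marginal-mean difference
equals the nominal $e$; the interaction as $(+i/4,-i/4,-i/4,+i/4)$ on the
four cells so the classical interaction contrast
$(\bar y_{22}-\bar y_{21})-(\bar y_{12}-\bar y_{11})$ equals $i$. This
makes the `GroundTruth` table directly comparable to `coef()` of the
fitted model, with no conversion factors. Effect sizes are applied as
given (signed scalar, or drawn uniformly from an interval); they are not
randomly sign-flipped, so a configured $+2$ means "up in the mutant" for
every affected gene.

What the simulator does **not** emulate: probe-level intensities and
normalization (inputs are post-normalization by assumption), correlated
noise between genes, intensity-dependent variance, and array batch
effects. Passing tests on these simulations therefore validate the
statistical machinery under its own assumptions — they do not show that
real arrays satisfy those assumptions.

## The growth simulator and the efficiency metrics

`simulate_growth()` emulates destructive sampling at days 7, 10, 14, 21
and 28 after transfer, with four genotype × nitrate scenarios. The
deterministic core: exponential total dry weight
$TDW(t) = TDW_0 e^{rt}$; fixed root allocation $RDW = a\,TDW$; root
surface area proportional to root mass; N accumulation
$dTotN = u\cdot\text{area}(t)\,dt$ at the scenario's specific uptake rate
$u$; leaf area proportional to shoot mass. A fixed fraction of plant N
(default 0.25) resides in roots, from which `%ShootN` and `%RootN` are
back-computed so that the TotN identity holds exactly in noise-free
records. Default scenario parameters (relative growth rates 0.13–0.20
day⁻¹, allocation 0.30–0.45, uptake 0.8–2.0 × 10⁻⁵ g N cm⁻² day⁻¹) were
chosen once as realistic seedling-stage values, with the mutant slower,
more root-allocating and uptake-depressed than the wild type — the
qualitative phenotype of a highly branched N-limited mutant.

**Integration convention.** Measurements exist only at the sampling days,
so between sampling days the simulator treats root area as linear in
time, and integrates it by the trapezoid rule on a fine internal grid of
that interpolant. Since `interval_efficiencies()` computes the interval
NUR denominator as the trapezoid of the day-mean areas over the same
interval, the generator↔analysis loop closes exactly: with zero noise
the recomputed NUR equals the configured $u$ to machine precision, and
the NUR estimate is invariant to refining the internal grid whenever area
is linear in time. Had the generator integrated the continuous
exponential area instead, the closed loop would carry an
$O((rh)^2/12)$ discrepancy (~4% at a 7-day interval) that says nothing
about the analysis code — the convention isolates what the tests are
meant to check. The real-data caveat is the mirror image: on real plants
the trapezoid NUR inherits exactly that interpolation error relative to
the true continuous uptake.

Noise is multiplicative lognormal (all state variables are positive),
unit-mean, CV-parameterised, and split into a per-replicate (tank)
component shared within a biological replicate (default CV 0.05) and an
independent per-plant component (default CV 0.10). Whether tank-level or
plant-level variability should dominate is genuinely open for pooled
hydroponic designs — six plants share a tank, three tanks make the
replicates — so both CVs are exposed; the defaults put most variability
at the plant level.

`derive_plant_variables()` conventions: a plant with no laterals
(`LRN = 0`) and `TRL = PRL` gets `LRL = 0`; `LRN = 0` with `TRL > PRL` is
an inconsistency and errors; `TRL < PRL` likewise. NLA is undefined
(flagged, not thrown) on intervals with zero N increment. The NUR
denominator basis is root surface area by default ("the root surface
area pilots the entrance of N"); a root-dry-weight basis is a switch
(`nur_basis = "rdw"`), changing the units to g N (g root)⁻¹ day⁻¹. NUR
and NLA are computed on group means per day — plants are destroyed at
sampling, so no within-plant time series exists — and the units
(g N cm⁻² day⁻¹; cm² (g N)⁻¹) are this package's convention, stated
because field practice rarely prints them.

## LSD letter groupings

`lsd_compare()` runs the one-way pooled-variance comparison: pooled MSE
across groups, $LSD_{ij} = t_{1-\alpha/2,\,df_E}
\sqrt{MSE\,(1/n_i + 1/n_j)}$, letters assigned by insert-and-absorb on
the means sorted descending. Two invariants define correctness, and are
property-tested on random instances: means differing by more than their
LSD share no letter; means differing by at most it share at least one.
The experimental unit defaults to the biological-replicate mean
(`lsd_by_day()`), matching a design of three replicate tanks of six
plants — plants within a tank are subsamples, not replicates; per-plant
units are a switch. Degenerate all-identical groups give $MSE = 0$, which
is floored at machine epsilon × squared grand mean so letters remain
well defined (clearly separated groups still letter apart).

## qPCR quantification

The relative standard curve (ΔCT) method: per-gene least-squares line of
CT on $\log_{10}$(quantity) over a dilution series (≥ 3 distinct points;
non-negative slopes rejected), efficiency $E = 10^{-1/\text{slope}}$,
quantities $10^{(CT-\text{intercept})/\text{slope}}$. Technical
replicates are averaged on the CT scale — CT is the near-Gaussian
measurement scale; averaging quantities would skew under the exponential
transform. Normalization divides each sample's target quantity by the
geometric mean of its reference-gene quantities (arithmetic mean
available): the geometric mean is the natural choice for ratio-scale
quantities and makes normalization exactly invariant to per-sample
loading factors. With two references of equal true abundance both rules
coincide, which the suite exploits as a consistency check. An
exact-doubling shortcut (`assume_e2 = TRUE`) skips curve fitting and uses
$2^{-CT}$, useful when no standard series was run.

`simulate_qpcr()` plants known fold changes and efficiencies, adds
Gaussian technical CT noise (default sd 0.1 cycles — typical plate
repeatability) and lognormal per-sample loading factors that the
normalization must cancel, with three technical × three biological
replicates as in the validation design it emulates. It does not simulate
amplification curves, primer-dimer artefacts, or inter-plate calibration.

## Numerical and I/O conventions

* TSV dialect: tab separator, UTF-8, `.` decimal, no quoting; numeric
  values written at 17 significant digits so `read → write → read` is
  bit-exact (verified at the full 61,278 × 12 array scale).
* Parse errors name the file, line and offending column.
* All simulators take one seed; internal sub-streams are derived from it
  deterministically, and the caller's RNG state is restored afterwards.
  Identical seed + configuration ⇒ bit-identical output, which the
  `run_*()` pipeline runners lift to byte-identical result files.
* Genes with zero total variance have all $SS = 0$ and get $p = 1$ for
  every contrast (an automatic consequence of the $\chi^2$ upper tail at
  0).

## Problem sizes used in verification

The test suite and `scripts/acceptance.R` run at the study's design scale
(2,000 genes × 12 samples) for distributional checks — null p-value
uniformity, planted-effect sensitivity — and 1,000 replicate datasets for
the family-wise error simulation; the I/O round trip runs once at the
full 61,278-probe array scale. These sizes keep every distributional
estimate's Monte-Carlo error well below the tolerance it is compared to
(e.g. FWER standard error ≈ 0.007 at 1,000 datasets).

## Known limitations

* The χ²(1) test treats the global variance as exactly known and common
  to all genes; genes with genuinely heterogeneous variance (not removed
  by trimming) are tested against the wrong denominator. No
  empirical-Bayes shrinkage or per-gene moderation is attempted.
* The trimmed-mean global variance is slightly downward-biased under the
  null (see above), so realised FWER sits marginally above nominal.
* No FDR procedures: Bonferroni only, as the method this package
  re-implements prescribes.
* The growth model is a smooth allometric caricature: no ontogenetic
  drift in allocation, no diurnal dynamics, no N-pool remobilisation.
  NUR/NLA on real data inherit the interval-trapezoid approximation.
* qPCR quantities are relative to each gene's standard series; no
  absolute copy-number calibration.
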