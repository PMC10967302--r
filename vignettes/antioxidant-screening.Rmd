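---
title: "Methods: dual cell-free and cell-based antioxidant screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual cell-free and cell-based antioxidant screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antioxscreen)
```

## The screen and its readouts

`antioxscreen` analyses microplate screening campaigns in which a library of
plant extracts is profiled by two cell-free chemical assays and two cellular
stress assays, with a viability assay guarding the cellular readouts:

* **TPC** (Folin–Ciocalteu total phenolic content, absorbance at 750 nm)
  calibrated against gallic acid and reported as mg GAE/L of undiluted
  extract;
* **FRAP** (ferric-reducing antioxidant power, kinetic absorbance at 593 nm)
  calibrated against Trolox and reported as µmol TE/L;
* **ROS**: DCF fluorescence time courses in AAPH-stressed Caco-2 cells,
  reduced to a percent-of-stress-control scale;
* **NO**: Griess nitrite absorbance in LPS-stimulated RAW264.7 macrophages,
  as percent of the LPS stress control;
* **viability**: resazurin reduction, with extracts below 80% of the
  untreated control excluded from the cellular endpoint of that cell line.

All measurements arrive as long-format CSV tables joined to a plate map that
assigns each well a role (`blank`, `standard`, `untreated_control`,
`stress_control`, `positive_control`, `treatment`). Every sample is measured
in triplicate wells; per-extract values are triplicate means.

## Calibration (TPC and FRAP)

Standard curves are ordinary least-squares lines
$A = \beta_1 c + \beta_0$ fitted per plate on blank-corrected standard
absorbances. The intercept is left free rather than forced through the
origin: the blank subtraction removes most of the reagent background, and
the free intercept absorbs what remains. Samples convert back through
$c = d\,(A - \beta_0)/\beta_1$ with $d$ the dilution factor (default 17 for
TPC and 31 for FRAP, from the assay volumetrics: 100 µL extract in ~1.7 mL
reaction, and 6 µL in 186 µL respectively). Sub-blank absorbances yield
negative concentrations; they are flagged, not clipped, so downstream rank
statistics see unbiased values.

The FRAP reaction is read every minute until it stops. The kinetic endpoint
is the first read from which every subsequent minute-to-minute change stays
below `delta_tol` (default 0.005 AU, configurable; if the whole trace is
flat the plateau is the first read, and a trace still moving at the last
read is reported unconverged with the last value). 0.005 AU sits above the
read noise of a typical plate reader but below any real reaction drift.

## ROS normalization

Each DCF well is read at 0/15/30/60/90 min. The chain is:

1. **Background correction**: subtract the per-time mean of the cell-free
   blank wells. A corrected baseline $f(0) \le 0$ leaves nothing to
   normalize by; such wells are excluded (with the exclusion logged and the
   replicate count reduced — never imputed).
2. **Start-value normalization**: divide the trace by $f(0)$. The ratio
   (rather than subtraction) makes traces dimensionless, cancels
   well-to-well differences in cell number and probe loading exactly, and
   is what makes the anchor identities below hold for any noise
   realization.
3. **AUC**: trapezoidal integral of the relative trace over the actual read
   times (deviations from the nominal schedule are tolerated).
4. **Two-anchor rescaling**: per plate,
   $\mathrm{ROS\%} = 100\,(\mathrm{AUC} - \overline{\mathrm{AUC}}_\text{untreated}) /
   (\overline{\mathrm{AUC}}_\text{stress} - \overline{\mathrm{AUC}}_\text{untreated})$.
   Stress-control wells average to exactly 100% and untreated controls to
   exactly 0% by construction; values above 100% (pro-oxidant) and below 0%
   are legitimate and preserved.

The Griess NO endpoint uses the same two-anchor construction on endpoint
absorbances, with the medium-only (DMEM) control as the zero anchor and the
LPS stress control as 100%. The assay description pins only the LPS anchor;
using the DMEM control as the blank anchor is this package's design choice —
without it, reagent background would inflate every percentage — and
deliberately parallels the ROS normalization. No nitrite standard curve is
fitted: results are percentages, not µM.

## Viability gate

Viability is the triplicate mean resazurin signal as percent of the
untreated-control mean. An extract is cytotoxic when that mean is *strictly
below* 80% (exactly 80.0% is retained). The gate is per cell line: an
extract cytotoxic to RAW264.7 macrophages is excluded from the NO endpoint
but keeps its ROS value, and vice versa. The gate uses the per-extract mean
(not any-single-well), is idempotent, and gated extracts propagate as `NA`
into results and correlations.

## Hit calling: Dunnett many-to-one comparisons

Within each plate, all treatment groups share that plate's stress control
and form one comparison family (per-plate families match the physical
design in which every plate carries its own controls). With groups
$g = 0 \ldots k$ (0 = control), the pooled variance is the one-way ANOVA
MSE with $\nu = \sum_g (n_g - 1)$ degrees of freedom and each treatment's
statistic is

$$t_i = \frac{\bar y_i - \bar y_0}{\sqrt{\mathrm{MSE}\,(1/n_i + 1/n_0)}}.$$

Under the null, $(T_1,\dots,T_k)$ is multivariate t with the product
correlation structure $\rho_{ij} = \lambda_i \lambda_j$,
$\lambda_i = \sqrt{n_i/(n_i + n_0)}$ (equicorrelated at 1/2 when balanced).
The adjusted two-sided p-value $P(\max_j |T_j| \ge |t_i|)$ is evaluated by
exact two-dimensional Gauss–Legendre quadrature over the shared normal
factor and the pooled-variance chi factor (`dunnett_pmax_le()`; 48 nodes
per dimension by default, accurate to about $10^{-4}$ and indifferent to
family size), cross-checked in the test suite against `mvtnorm::pmvt` and a
$10^6$-draw Monte-Carlo simulation of $\max|T|$.

A hit is a *significant decrease* (`p_adj < 0.05`, two-sided, and mean
below the 100% stress level) or *significant increase*; independently of
significance, extracts at or below 70% carry the ≥30%-reduction flag. The
0.05 level is the field convention; it is configurable.

## Selectivity classification

Non-excluded extracts are classified by a fixed rule order on the
normalized levels: **dual** if both NO and ROS are below 60%;
**NO-selective** if the NO decrease is significant while ROS stays above
90%; **ROS-selective** symmetrically; otherwise **unclassified**. Extracts
failing the viability gate on either endpoint are **excluded**. The classes
partition the library. The 60/90 thresholds are the screen's published
operating points and are applied as a general classifier, not merely a
top-hits report.

## Correlations

Cross-assay agreement uses Spearman's rank correlation on per-extract
triplicate means (pairwise-complete, non-excluded), with mid-ranks for ties
and the two-sided t approximation
$t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ df for the p-value. Perfect
correlations report a p-value at the machine floor rather than zero.

## The synthetic campaign generator

No raw data are deposited for screens of this kind, so the package carries
a generator that emulates a full campaign — ground truth plus raw plate
files for all five assays — and the whole pipeline is tested end-to-end
against it.

**Latent structure.** Each extract has a log-normal phenolic latent $P$
(log-SD 0.8). True TPC is $800 P$ mg GAE/L and true FRAP $4000 P^{1.1}$
µmol TE/L, each with multiplicative log-normal noise whose SD is solved
analytically (via $\rho = 2\sin(\pi r_s/6)$) so the TPC–FRAP rank
correlation hits its 0.857 target in expectation. These scales put the
library median near 800 mg GAE/L / 4000 µmol TE/L and the 375-extract
maxima near $8\,000$ mg GAE/L and $50\,000$ µmol TE/L — the span such a
screening library realistically covers.

**Selectivity classes.** Extracts belong to one of five truth classes with
calibrated frequencies per 375: 20 dual, 16 ROS-selective, 38 NO-selective,
40 NO-increasing, the rest inactive; 3 extracts are cytotoxic to Caco-2 and
15 to RAW264.7 (drawn from the inactive class so the calibrated
active-class counts stay interpretable). Class-conditional level
distributions (e.g. dual: ROS $\sim N(48,10^2)$, NO $\sim N(45,10^2)$;
inactive: $N(95,4^2)$/$N(96,4^2)$) are chosen so that about 34 extracts
fall at or below 70% ROS and about 57 at or below 70% NO — the
reduction-count scale of a real campaign. Active classes are drawn
preferentially from high-$P$ extracts (exponential tilt 1.6) and
NO-increasers from low-$P$ extracts (tilt 0.9); within class, levels follow
a Gaussian-copula monotone link to $P$ (strength 0.65/0.48 for ROS/NO in
active classes, 0.55/0.38 otherwise). These link strengths were calibrated
once, by simulation, so the library-wide rank correlations approach the
configured targets (TPC–ROS ≈ −0.44, TPC–NO ≈ −0.46, and an emergent
NO–ROS coupling of ≈ 0.24), and then frozen.

**Measurement models.** Raw signals invert each assay's analysis model:
standards and extract absorbances from the configured curves at the assay
dilution; FRAP wells as saturating kinetic traces
$A(t) = b + a(1 - e^{-t/\tau})$, $\tau \sim U(0.8, 1.5)$ min, read for
12 min; DCF wells as linear-in-time fluorescence
$f(t) = b + F_0(1 + rt)$ with the rate interpolating between basal
(untreated) and stress (AAPH) values according to the extract's true
inhibition; Griess absorbance proportional to the NO level; resazurin
centred at 100% (or 60% for cytotoxic extracts) of control. The quercetin
positive control is emitted at 3.6% ROS and 66.5% NO of stress, so the
positive-control channel doubles as a pipeline sanity check.

**Noise.** The 2% default noise CV acts as *well-level* multiplicative
noise (pipetting, loading, probe uptake) — the component the start-value
ratio is designed to cancel; kinetic reads additionally carry 0.5%
per-read instrument noise, endpoint absorbances a small additive read
noise (0.002 AU), and cellular responses a biological replicate spread of
SD 3 (ROS) / 2.5 (NO) percentage points per well, consistent with the
replicate scatter a positive control shows in practice. Linear-in-time DCF
kinetics is deliberately the *simplest* model consistent with an AUC
readout; the analysis never assumes a kinetic form, so any
generator/analysis mismatch is a robustness test, not a bug.

**Determinism.** Identical config and seed produce byte-identical CSVs; all
randomness flows from the single config seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: plate-position and evaporation gradients, day and
batch effects, probe photobleaching and leakage, compound autofluorescence
or Folin interference from non-phenolic reductants, and dose–response
cytotoxicity. Conclusions about those failure modes need real plates.

## Numerical and boundary choices

* Trapezoidal AUC uses actual read times; it agrees with a fine-grid
  Riemann oracle to $10^{-9}$ relative error.
* The Dunnett quadrature uses probability-scale Gauss–Legendre nodes;
  flagging by `p_adj < alpha` is exactly equivalent to `|t| >`
  `dunnett_critical()`.
* Exactly 80.0% viability is retained (the gate is strictly "below");
  exactly 70.0% counts as a ≥30% reduction.
* Zero pooled variance, coincident anchors, non-positive control means and
  degenerate calibration designs are hard errors, not silent `NA`s.
* Negative concentrations and >100% levels are reported as-is.

## Recovery checks and problem sizes

The test suite exercises, among others: anchor identities under deliberately
inflated noise; parameter recovery on the default 375-extract campaign
(pipeline TPC vs truth, Spearman ≥ 0.99; TPC–FRAP within [0.80, 0.91] under
the 0.857 target); selectivity recovery for extracts whose true levels
clear every decision boundary of the rule — the 60 and 90 thresholds *and*
the 100% direction anchor — by at least 5 points (≥95% agreement; extracts
within 5 points of 100% are genuinely boundary-significant under a
triplicate design and cannot be attributed a stable class); calibration of
the reduction counts (median over 50 library realizations within ±8 of 34
for ROS and ±10 of 57 for NO); and family-wise error control of the hit
caller on 1000 null campaigns of 100 extracts (4 plate families of 25).
These sizes keep the default suite around a minute while leaving the
statistical assertions well-powered.

## Limitations

The per-plate Dunnett family is a design choice; a library-wide family or
FDR control across 375 extracts would be stricter and is out of scope, as
are Welch-type heteroscedastic comparisons, 4PL calibration, per-plate
drift correction, absolute nitrite quantification and IC50-style
cytotoxicity modelling. The NO/ROS "selectivity" labels inherit the
screen's fixed 60/90 thresholds; they are operating points, not biological
constants.
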