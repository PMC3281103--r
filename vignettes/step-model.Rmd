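---
title: "A stochastic step model of replicative senescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic step model of replicative senescence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senstep)
```

## The model

Primary fibroblast cultures passaged towards their Hayflick limit show a
smooth, roughly exponential rise of population-mean mitochondrial ROS
production (MitoSOX fluorescence) with population doubling (PD). One common
reading of such kinetics is gradual per-cell damage accumulation. `senstep`
implements the alternative this package is built around: a **stochastic step
model**, in which every cell carries a phenotype drawn from a *proliferating*
distribution until, at a random PD, it switches once — and irreversibly — to
a value drawn from a broader, higher *senescent* distribution. Smooth
population kinetics then need no per-cell drift at all: they are the mixture
of two static distributions with a changing mixing weight.

For a population with senescent fraction $s$ (and proliferating fraction
$p = 1 - s$), the expected phenotype is

$$\phi_{Mix} = p\,\phi_P + s\,\phi_S, \qquad p + s = 1, \qquad
  \phi_S = \alpha\,\phi_P,\ \alpha \ge 1,$$

which collapses to the affine form implemented in `mixture_mean()`:

$$\phi_{Mix}(s) = \phi_P\,\bigl(1 + (\alpha - 1)\,s\bigr).$$

Composing this with an empirically estimated senescent-fraction curve
$s(\mathrm{PD})$ gives the full time course, `predict_trajectory()`. The two
parameters are calibrated from boundary populations (`calibrate_params()`):
$\phi_P$ from a culture known to be essentially fully proliferating (low PD)
and $\phi_S$ from one that has stopped dividing, with
$\alpha = \phi_S / \phi_P$. The hTERT-immortalised control is the
$\alpha = 1$ limit: a flat trajectory.

A variance analogue, `mixture_variance()`, is provided under the assumption
of zero covariance between the two state distributions:
$\mathrm{Var} = (1-s)v_P + s\,v_S + s(1-s)(\mu_S - \mu_P)^2$. The covariance
assumption is genuinely open — the two distributions are estimated from
different populations, so no joint information exists — and independence is
the only supported option; it is exact for the step simulator, where each
cell's two values are drawn independently.

## The senescent-fraction curve and its uncertainty

`fraction_curve()` stores knots of $s(\mathrm{PD})$ with a 95% confidence
band and interpolates all three series linearly (`interpolate_fraction()`),
exactly at knots. Monotonicity of the mean curve is enforced because
replicative senescence is an irreversible loss of division potential; an
isotonic-repair option exists for noisy input tables but is off by default.
Queries outside the knot range **clamp** to the end values rather than
extrapolate: $s$ is a fraction estimated only over the observed PD window.

When per-cell state assignments are needed (`sample_states()`,
`simulate_intermediate_population()`), the uncertainty in $s$ is propagated
by drawing, per cell, a probability $s^*$ from a Beta distribution
moment-matched to the interpolated mean and to
$(s_{upper}-s_{lower})/(2 \times 1.96)$ as standard deviation. The Beta was
chosen for its bounded $[0,1]$ support matching a fraction; the upstream
posterior samples behind the band are not available, so this is an explicit
stand-in, and a deterministic `mode = "mean"` bypass is provided. The
standard deviation is capped just below the Bernoulli bound
$\sqrt{m(1-m)}$ so the moment match always yields a proper Beta.

## The per-cell step simulator

`simulate_cells()` realises the model literally: per cell a proliferating
value, a senescent value, and a transition PD. Two design points:

* **Non-decreasing steps.** The model assumes no cell's phenotype falls at
  transition. This is enforced by rejection sampling: the senescent value is
  redrawn until it is at least the proliferating value (capped, then an
  error). Rejection preserves the senescent distribution's shape in the
  intended regime where it lies far above the proliferating one; a
  truncation formula would impose a conditional law the model never states.
* **Transition times from the fraction curve.** Treating $s(\mathrm{PD})$ as
  the CDF of the transition PD and inverting it by linear interpolation
  makes the simulated senescent fraction agree with the growth-curve-derived
  estimate by construction; draws above the curve's maximum never transition
  (immortalised cells).

One master seed is expanded into deterministic per-cell substreams, so
growing `n_cells` extends a population without reshuffling existing cells —
convenient for convergence studies and exact regression tests.

The simulator's population mean at every PD must agree with the closed form
`mixture_mean()` evaluated at the realised senescent fraction; this
equivalence (within Monte-Carlo error) is the module's primary correctness
property and is asserted in the test suite at $n = 10^4$ cells within 1%.

## Distribution machinery and the dip test

Per-cell phenotype distributions come in three kinds (`dist_gamma()`,
`dist_empirical()`, `dist_digitized()`). Gamma is the parametric family used
for microscopy intensities (positive, right-skewed); fitting is by maximum
likelihood (`fit_gamma()`, backed by **fitdistrplus**). Digitized densities
— tables read off published figures — are interpolated linearly,
renormalised by the trapezoid rule, and sampled by inverse CDF with exact
segment-wise quadratic inversion.

A central question for the model is whether a mixture of two such
distributions should *look* bimodal at realistic sample sizes. The package
answers it with Hartigan's dip statistic, implemented from scratch
(`dip_statistic()`) via the greatest-convex-minorant / least-concave-majorant
construction with iterative modal-interval narrowing. Implementation notes:

* Ties are handled with the weak-inequality ECDF convention and no
  jittering; the unimodal reference class admits an atom at the mode, which
  is what makes the tie-handling exact.
* The implementation was validated against an independent brute-force
  oracle — a linear program over unimodal CDFs minimising the sup-distance
  to the ECDF — on hundreds of samples including ties; the test suite keeps
  this oracle (at small $n$, where the LP solver is exact) as a permanent
  regression check.
* `dip_test()` bootstraps the null from uniform(0,1) samples of the same
  size (2000 replicates by default), the convention of the reference
  implementation of the dip test, with a $+1/(n_{boot}+1)$ continuity
  correction. Because the null depends only on $n$, `dip_null_table()` lets
  a table be computed once and shared across many tests.

A consequence worth stating plainly: the uniform is the asymptotically
*least favourable* unimodal distribution, so for smoother unimodal data
(e.g. gamma draws) the test is **conservative** — its type-I error at
$n = 500$ is far below the nominal 0.05 (we measure ≈ 0 against a gamma
null, while uniform data sit near 0.04). This is a property of the standard
dip test itself, not of this implementation, and it only strengthens the
package's headline use: when a 50:50 step-model mixture is *not* flagged as
bimodal, that is the expected behaviour in the reported heterogeneity
regime.

`exceedance_fraction()` compares simulated against observed samples as the
probability that a simulated value exceeds an observed one. The default is
the deterministic full-pairwise Mann–Whitney estimator; a `"sampled"` mode
draws one observed partner per simulated cell, mirroring a per-cell
comparison, at the cost of extra Monte-Carlo noise.

## Kinetics and model validation

Time courses are handled strictly by linear interpolation between
observations — no smoothing or splines — and normalised by their
(interpolated) value at a common reference PD (`normalize_series()`), making
channels measured in different arbitrary units comparable. The
MitoSOX-to-mitochondrial-mass ratio (`msmm_ratio()`) divides the two
separately normalised channels on the union of their knot grids inside the
overlapping PD range; the union grid preserves all observed structure
without inventing a resolution. `compare_model_to_observed()` reports the
Pearson correlation on a common grid (union-of-knots by default; an
observed-knots-only mode is provided since either convention is defensible)
plus per-PD residuals. A constant series — the flat $\alpha = 1$ prediction
— has no defined correlation and yields `NA` rather than a spurious number.

## Marker classification

`classify_cells()` maps (Ki67, γH2A.X focus count) to three categories:
Ki67+ cells are cycling regardless of foci; Ki67− cells with more than 5
foci satisfy the quantitative senescence criterion; the rest are Ki67− low
foci. A count of exactly 5 is assigned to the low-foci group because the
senescence criterion is strictly "more than 5 foci per nucleus"; the
complementary "<5" label seen in figure legends leaves 5 ambiguous, and we
resolve it in favour of the strict criterion. `group_summary()` is a
reporting stage, not a modelling contribution: a standard two-factor
(category and PD) analysis of variance with Tukey pairwise contrasts,
flagging the high-foci group when it exceeds both others significantly.

## The synthetic-study generator

No per-cell dataset is distributed with the package, so `generate_study()`
produces complete, seeded, byte-reproducible study bundles with the
statistical structure the analysis assumes. Defaults (in `study_config()`):

* PD window 25–47, the span over which the senescent fraction rises from
  about 0 to 1; the sigmoid midpoint (PD 36) and steepness (0.45/PD) are
  chosen to reproduce that qualitative shape, and the curve is pinned to 0
  and 1 at the window ends so the boundary snapshots are pure states.
* Per-cell gammas `gamma_P = (shape 4, scale 0.25)` (mean 1, sd 0.5) and
  `gamma_S = (shape 2, scale 3.3)` (mean 6.6, sd 4.67). These encode the
  two reported ratio constraints — senescent sd more than 8-fold the
  proliferating sd (here 9.3) while the mean fold-change stays below 7
  (here $\alpha = 6.6$) — with *unimodal* members. Shapes at or below 1
  would satisfy the ratios too, but give a J-shaped senescent density with
  its mode at zero, which is not what per-cell fluorescence distributions
  look like; shapes 4 and 2 keep both members unimodal and right-skewed.
  The construction enforces `mean(gamma_P) = phi_P` and
  `mean(gamma_S) = alpha * phi_P`, so mixture parameters and per-cell
  distributions can never drift apart.
* Measurement noise on population means is multiplicative log-normal
  (default 5% log-sd): fluorescence means are positive, and no additive
  noise model is implied by anything upstream.
* The mass channel gets its own milder fold-change (default 2) — senescent
  cells carry more mitochondria — so the MitoSOX channel rises by
  $\alpha \times \alpha_{mass}$ and the derived MSMM ratio by $\alpha$.
  Both *measured* channels follow the affine mixture form exactly; their
  ratio is then monotone but slightly convex in $s$, so a noiseless MSMM
  comparison gives $r \approx 0.99$, not exactly 1 — a structural fact
  about ratios of affine functions, not an implementation artefact.
* `microscopy.csv` gives Ki67/foci marker tables (about 50 cells per PD, a
  typical microscopy yield) in which exactly the Ki67−, >5-foci cells draw
  from the senescent phenotype distribution.
* `hTERT = TRUE` produces the immortalised control: fold-change forced to
  1, identical state distributions, $s(\mathrm{PD}) \equiv 0$, flat series.

What the generator deliberately does **not** emulate: flow-cytometer
artefacts (spillover, gating truncation), cell division and lineage
structure, death, telomere dynamics, or any within-cell phenotype drift.
Passing tests on these bundles therefore show that the analysis machinery is
correct and internally consistent under the model's own assumptions — not
that real cultures obey the step model.

## Problem sizes and numerical choices

The test suite and the acceptance script use sizes chosen to keep
Monte-Carlo error well inside each asserted tolerance: $10^4$ cells for
closed-form/simulation equivalence (the per-cell distributions there use a
senescent sd of 1 so that three standard errors of the population mean stay
under the 1% band), $10^4$ cells per boundary snapshot for parameter
recovery within 5%, 500-cell samples with a shared 2000-draw null table for
dip calibration (500 type-I replicates, 200 mixture replicates), and
$10^4$-cell intermediate simulations for exceedance fractions. Degenerate
inputs are handled explicitly: constant samples have dip 0 and no defined
gamma fit; constant series have no defined correlation (`NA`); a noisy flat
series whose senescent reference falls below the proliferating one is
clamped to the $\alpha = 1$ boundary by the pipeline rather than erroring,
since that is the model-consistent reading of such data.

## Known limitations

* The Beta uncertainty model for $s(\mathrm{PD})$ is a documented stand-in
  for unavailable upstream posterior samples.
* The dip test inherits the conservativeness of the uniform bootstrap null;
  it should not be used as a calibrated 0.05-level test against smooth
  unimodal alternatives, only as the field-standard screen for bimodality.
* `mixture_variance()` supports only the zero-covariance case.
* The pipeline's hTERT-like flag is a threshold on the calibrated
  fold-change (default 1.2, about two standard errors of the calibration
  ratio under 5% noise) — a reporting convenience, not a formal test.
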