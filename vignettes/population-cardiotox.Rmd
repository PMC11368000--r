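---
title: "Population-based cardiotoxicity assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based cardiotoxicity assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cardiopop` turns per-well calcium-flux recordings from iPSC-derived
cardiomyocytes of many donors into population-level cardiotoxicity
assessments: points of departure, inter-individual variability factors,
priority rankings and probabilistic margins of exposure. This vignette is
the package's own account of the science: the models, their assumptions,
the tunable parameters, and the choices made where the design was open.

## 1. Phenotypes from calcium traces

Each well is recorded twice (baseline and 90 minutes post-treatment) at
8 frames/s for 100 s (800 frames). Five phenotypes are scored:

- **positive / negative chronotropy** — treated beat rate relative to the
  same well's baseline and to vehicle controls;
- **decay-to-rise ratio** — per beat, the time from peak maximum back to
  baseline divided by the time from baseline up to the peak; prolongation of
  the calcium-transient decay is an in vitro proxy for QT prolongation;
- **asystole** — zero treated peaks with no concurrent cell loss;
- **cytotoxicity** — the nuclei count in the imaged field.

`detect_peaks()` finds local maxima whose topographic prominence exceeds 20%
of the trace range, at least 0.25 s apart (a 240 bpm ceiling). Both defaults
are configurable; the original screening scripts' thresholds are unpublished,
so these are declared, not inferred. A 3-frame moving average is applied
before candidate detection only — detected peaks are snapped back to the raw
local maximum — because single-frame noise excursions at ~5% of pulse
amplitude can otherwise create spurious candidates. All kinetic measurements
are made on the raw trace.

Rise and decay times are measured at a baseline level of 10% of each beat's
prominence above the local inter-beat minimum (the crossing is linearly
interpolated between frames). The choice of 10% is a design decision: the
underlying publications do not state the level, and any low fraction gives
the same ratio up to frame quantization. Beats whose crossings would fall
outside the recording window are excluded from the decay-to-rise average.
Feature extraction is deterministic, and all phenotypes are invariant to
positive rescaling of the trace.

The cytotoxicity flag used to separate asystole from cell death is defined
downstream of normalization: a well is cytotoxic when its nuclei count falls
below 0.9 of the plate's vehicle mean, mirroring the EC10 benchmark
direction.

## 2. Plate quality control

Raw phenotypes are normalized well-by-well to the mean of the same plate's
vehicle wells (0.5% DMSO), so 1.0 is the control level; normalization is
idempotent and fails loudly (naming the plate) if a plate has no vehicle
wells. Plates are gated on directional positive-control behavior —
isoproterenol must raise the normalized beat rate above 1, propranolol must
lower it, sotalol must raise the decay-to-rise ratio — plus spontaneous
beating in vehicle wells. The gates are directional only, because control
effect magnitudes are genuinely donor-specific.

Control-well variability is decomposed by REML (`lme4`) under a nested
random-effects model: donor and plate-within-donor random, vehicle-vs-media
as a fixed contrast whose contribution is measured as the variance of its
fitted values. Components are reported as fractions of total variance and as
coefficients of variability (`sqrt(component) / grand mean × 100`),
computed on raw units. Single-level factors get a zero component with a
warning rather than an error.

## 3. The hierarchical Hill model

For one chemical and phenotype, the vehicle-normalized response of donor
*i* at concentration *c* is

$$y = 1 \pm \frac{E_{max,i}\, c^{n}}{EC_{50,i}^{n} + c^{n}} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma_{err}),$$

with lognormal donor random effects, non-centered:
$\log EC_{50,i} = \mu_1 + \sigma_1 z_{1i}$,
$\log E_{max,i} = \mu_2 + \sigma_2 z_{2i}$, $z \sim N(0,1)$. The Hill
coefficient is shared across donors: four test concentrations cannot
identify donor-specific slopes, and the random effects on potency and efficacy
carry the population story. The residual is normal on the response-ratio
scale. Donor-level $E_{max,i}$ is not truncated at 1 (only the population
median is, through its prior); with a decreasing phenotype an extreme donor
draw can therefore nominally exceed a 100% decrease, which the data scale
itself prevents from mattering in practice.

**Priors** (declared defaults, overridable via `hill_priors()`): the
published analysis references prior settings that are not themselves
published, so the package declares weakly-informative ones:
log EC50 centered mid-range of the tested concentrations, SD 2; log Emax
centered at log(0.2), SD 1, upper-truncated at 0 so the population-median
efficacy cannot exceed a 100% change; log n centered 0, SD 0.5; half-normal(0, 1)
on both population SDs; half-normal(0, 0.2) on the residual SD.

**Sampler.** No Bayesian engine is bundled with the package's dependency
stack, and the model is the package's core, so the sampler is authored here:
an adaptive Metropolis-within-Gibbs scheme in compiled code. Each parameter
gets a Gaussian random-walk proposal whose log step size is adapted in
batches of 25 during warmup (targeting ~0.44 acceptance) and frozen
afterwards; donor-level updates only recompute that donor's likelihood
slice. Four independent chains are run with prior-drawn overdispersed
starts; the first half of every chain is warmup and is discarded.
Convergence is diagnosed with rank-normalized split R̂ (the larger of the
bulk and folded statistics) at the 1.2 acceptance threshold; on failure the
iteration count doubles, from 8,000 up to 32,000 per chain in full mode
(desk mode: 2,000 up to 8,000). A converged fit is subsampled to 1,000
retained draws, 250 per chain, under the fit's seed. Simulation-based
calibration — truth drawn from the fitting priors, 200 reduced fits — holds
the 90% credible interval coverage for the population EC50 at its nominal
level within binomial error (the test suite recomputes this).

## 4. PODs, censoring and summaries

The benchmark inversion has the closed form

$$POD = EC_{50}\left(\frac{b}{E_{max} - b}\right)^{1/n},$$

with $b$ = 0.05 for chronotropes and the QT proxy (a 5% change from
vehicle), 0.95 for asystole, 0.10 for cytotoxicity. When $E_{max} \le b$ the
benchmark is unreachable and the POD is censored at `Inf`. Per posterior
draw the package computes the median individual's POD (population-median
parameters), each donor's POD (donor-level parameters), and the sensitive
individual's POD as the empirical 5th percentile over 1,000 virtual
individuals drawn from the random-effect distribution (seeded). Summaries
are posterior medians with 90% CIs; a summary is flagged censored when more
than half its draws are. All quantiles over draw vectors use the empirical
(type-1) definition so censored `Inf` values never enter an interpolation.

## 5. Activity criteria and TDVF

A chemical-phenotype combination is **active** when (i) R̂ ≤ 1.2, (ii) the
model-fit coefficient of variability is < 20%, (iii) the median-individual
POD is below 3× the top tested concentration (300 µM by default), and (iv)
the posterior 5th percentile of Emax exceeds a 10% change. It additionally
qualifies for population-variability analysis when (5) the 90% CI of the
median POD spans < 100-fold, (6) the 90% CI of the sensitive POD spans
< 100-fold, and (7) at least half the donors have non-zero (usable,
QC-passing) data at three or more concentrations.

Criterion (ii) is ambiguous in the source methodology — "coefficient of
variability for model fit" could mean residual error or POD posterior
spread. The package implements it as the posterior median residual SD
expressed as a percentage of the control-normalized response (a residual
CV), with the POD-posterior CV available behind `fit_cv_method = "pod"`;
the choice is surfaced in the output so users can audit it.

TDVF₀₅ is the toxicodynamic variability factor: the ratio of the median
individual's POD to the sensitive individual's POD, computed **draw-wise**
(posterior of the ratio, not ratio of posterior summaries), which preserves
the ordering $POD_{05} \le POD_{50}$ in every draw. Draws with a censored
sensitive POD are excluded and their fraction reported. The summary is
compared against the default toxicodynamic uncertainty factor bands
$<10^{1/2}$, $10^{1/2}$–10, $>10$. With a random effect on log EC50 only and
unit Hill slope, TDVF₀₅ has the closed form $\exp(1.6449\,\sigma_1)$, which
the tests use as a recovery oracle.

## 6. ToxPi integration

Per phenotype slice, scores are linear in $-\log_{10} POD$ between the
slice's observed extremes, so 0 marks the highest POD (least bioactive) and
1 the lowest; censored or inactive entries score 0, as does an entire
constant slice. The slice input is the most sensitive (minimum)
donor-specific POD per chemical — the donor-resolved reading of the ToxPi
input convention — configurable to population-median PODs. The overall score
is the weighted mean (equal weights by default) and ranking is descending
with ties broken lexicographically. The transform itself is a design
decision: the methodology names the inputs and the 0–1 scale but not the
within-slice scaling, and linear-in-log-POD is the established ToxPi
convention. Slices were implemented per phenotype (five), not per
donor × phenotype (eighty): the published figure text describes five slices.

## 7. Probabilistic IVIVE and margins of exposure

Oral exposure estimates arrive as a median and upper 95th bound of the
predicted population-median intake (mg/kg BW/day) and are fit exactly to a
lognormal: $\mu = \ln(\text{median})$,
$\sigma = (\ln u_{95} - \ln \text{median})/1.6449$. The steady-state plasma
concentration per unit dose uses the well-stirred three-compartment
closed form

$$C_{ss} = \frac{1000 / MW}
{f_{up}\,GFR \cdot 24 + 24\,\frac{Q_{liver} f_{up} Cl_{int}}{Q_{liver} + f_{up} Cl_{int}}}
\quad \mu M \text{ per mg/kg/day},$$

with defaults GFR = 1.53 mL/min/kg and liver blood flow 1.24 L/h/kg. This
closed form replaces the external toxicokinetics database the original
analysis queried (out of scope here); its parameters travel in a small
per-chemical table, and method (ii) sets $Cl_{int} = 0$ (renal filtration of
the unbound fraction only). A zero fraction unbound would make $C_{ss}$
infinite; such chemicals are excluded with a reason.

MOEs divide the 5th percentile of a POD distribution by the 95th percentile
of the internal-concentration distribution (Monte-Carlo lognormal exposure ×
Css factor; biomonitoring ranges are used directly as internal
concentrations with the upper bound as the 95th percentile — no
toxicokinetic conversion). The population-median MOE uses the posterior
distribution of the median individual's POD; the random-individual MOE
draws one virtual individual's Z-scores per posterior draw and is only
derived for combinations that passed the population-variability criteria.
The minimum across active phenotypes and internal-concentration methods is
banded at the conventional thresholds: < 1 likely of concern, 1–100 of
potential concern, ≥ 100 protective. The exposure-distribution percentile is
exposure-only; compounding toxicokinetic uncertainty into the internal
concentration is left as a hook (the source analysis is ambiguous on this
point).

## 8. Structure–activity analysis

The bioactivity matrix holds log10 PODs for every phenotype × donor plus the
across-donor minimum per phenotype (85 variables at the full design).
Censored or inactive entries are imputed at 300 µM — 3× the top tested
concentration, the same bound as activity criterion (iii) — a declared
choice (exclusion is available); the source's handling of censored PODs is
unstated.

Substructure-count descriptors pass a variation filter that keeps a
descriptor only when at least two chemicals differ from its modal value
(the modal-value reading of the published filter). Spearman correlations
(average ranks, two-sided t-approximation p-values) are screened at BH
q < 0.1 across all descriptor × phenotype pairs.

Cross-validated prediction uses ridge regression with one common penalty:
leave-one-out outer folds by default (the literal reading of "n-fold" with n
chemicals; k = 5/10 available), the penalty chosen per training fold by
closed-form leave-one-out PRESS over a log-spaced grid, and descriptor
standardization inside each training fold. The implementation works from a
per-fold SVD of the standardized design, which makes the permutation
calibration tractable: the SVD and hat diagonals are y-independent, so
10,000 label permutations reuse them and each permutation costs a few
matrix-vector products. The empirical p-value is
$(1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$, Holm- and BH-adjusted
across phenotypes. Desk mode defaults to 999 permutations; full mode to
10,000. Spearman screening is rank-based and thus invariant to monotone
rescaling of the phenotype; the ridge predictions use raw log-POD values —
a documented asymmetry.

## 9. The synthetic-study generator

`study_config()` encodes the stated screening world: 16 donors, the 56-PFAS
registry across its eight structure-based subclasses, 0.1/1/10/100 µM,
384-well plates with 308 interior wells (76 edge wells are non-experimental,
filled with buffer against edge effects), 15 vehicle and 5 media wells,
three positive-control drugs in concentration response, six intra-plate
replicate chemicals, and donors split across six batches.

Generative choices, held fixed:

- Hill truth per chemical is sampled at the **measure** level (beat rate,
  decay-to-rise, nuclei): the beat-rate curve serves both chronotropy calls
  and — when its efficacy approaches 1 — asystole, which mirrors how one
  physical dose-response underlies several phenotype calls. Activity
  probabilities default to 0.5 / 0.3 / 0.25 for the three measures, with 70%
  of active beat-rate curves decreasing (negative chronotropy dominates for
  this chemical class).
- Donor random effects are lognormal on EC50 (log-SD 0.3) and Emax (log-SD
  0.2); each plate carries one multiplicative lognormal factor (log-SD
  0.05); well noise is multiplicative Gaussian with 5% CV. Baseline beat
  rates are donor-specific, drawn around 25 ± 6 bpm within 12–40 bpm (the
  observed donor range), decay-to-rise around 2.0, nuclei around 1,200 per
  field.
- Calcium transients are fast-exponential-rise / slower-exponential-decay
  pulses whose 10%-amplitude crossings sit exactly at the target rise and
  decay times; the waveform shape is otherwise unconstrained by the source,
  and any shape reproducing peak timing and rise/decay durations would do.
  Pulses are evenly spaced so the beat count is exact by construction.
- Exposures, toxicokinetic parameters and descriptor matrices are sampled
  from documented ranges when not supplied (oral medians 10⁻⁸–10⁻³
  mg/kg/day, lognormal spread σ 0.5–1.5; fup 0.005–0.5; MW 200–700; Poisson
  substructure counts with 35% structural zeros). A structure–activity
  signal can be planted by making beat-rate log-potency a linear function of
  informative descriptors.
- One root seed; every stream (layout, truth, donor effects, traces,
  descriptors, exposures, ...) derives a deterministic child seed, so
  identical seeds give byte-identical bundles and modules can be regenerated
  independently.

What the generator does **not** emulate: pixel-level microscopy,
plate-freezing/stability artifacts, arrhythmic waveform morphologies
(early-afterdepolarization-like shapes), batch-by-sex/ancestry structure
beyond labels, or correlated descriptor blocks. A green test therefore
establishes that the analysis machinery recovers what the stated statistical
world planted — not that real screening data meet these assumptions.

## 10. Numerical choices and degenerate inputs

- Empirical type-1 quantiles everywhere a draw vector can contain censored
  `Inf` values.
- A constant trace yields zero peaks (not an error); a non-beating baseline
  flags the well unusable and leaves chronotropy undefined.
- Perfectly identical responses (zero variance) are a valid input to the
  fit: the posterior concentrates on "no effect within the tested range"
  (Emax and EC50 are only jointly identified there, so the concentrated
  quantity is the predicted change at the top concentration, and criterion
  (iv) fails as it should).
- Negative method-of-moments-style variance components cannot occur under
  REML; singular fits are tolerated and near-zero components reported as
  such.
- In ToxPi, a slice with a single finite POD is constant and scores 0 for
  everyone — with sparse activity at small study sizes, whole rankings can
  legitimately be all-zero.
- MOE bands use strict `< 1` and `< 100` comparisons so the documented
  boundary semantics (`>= 100` protective) hold exactly.

## 11. Known limitations

The sampler is a random-walk scheme: adequate for this 40-parameter
posterior (and validated by simulation-based calibration), but less
efficient than gradient-based samplers for much larger hierarchies. Donor
Emax is untruncated, as noted. The exposure percentile ignores
toxicokinetic parameter uncertainty. Headline counts from the original
screening campaign (numbers of active chemicals, TDVF band membership, the
top ToxPi score) depend on the undeposited raw data and are deliberately
out of scope: the package reproduces the *methodology*, and its tests
validate each stage against closed forms, brute-force references and
planted-truth recovery.
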