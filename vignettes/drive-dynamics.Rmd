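---
title: "Sex-ratio drive under pesticide stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-ratio drive under pesticide stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srdrive)
```

## The scientific problem

An X-linked sex-ratio meiotic driver (SR) destroys Y-bearing sperm in
carrier males, so SR sires transmit their X to (essentially) every
offspring and produce all-daughter broods. Naively this transmission
advantage should carry SR to fixation, after which a male-less
population collapses — yet natural populations of *Drosophila
pseudoobscura* and relatives hold SR at stable intermediate
frequencies without any molecular suppressor. `srdrive` implements a
compact, fully testable pipeline for one explanation: genotype-specific
fitness costs (viability and fecundity) interacting with a novel
environmental stressor (a pyrethroid pesticide) set an interior
equilibrium.

The pipeline has four stages, each usable on its own:

1. **Synthetic experiments** (`generate_mortality_dataset()`,
   `generate_fecundity_dataset()`) emulate a vial-based dose-response
   assay and a per-female fecundity assay with known ground truth.
2. **Parametrization** (`fit_mortality_glm()`, `fit_fecundity_mixed()`,
   `lrt_drop()`, `genotype_contrasts()`) fits the two statistical
   models a field ecologist would fit, and exports mortality reaction
   norms and brood sizes.
3. **Drive model** (`simulate_drive()` and friends): a deterministic
   five-genotype recursion with pre-mating mortality, random mating,
   genotype-specific brood sizes and density-dependent recruitment.
4. **Experiments** (`run_sweep()`, `find_extinction_threshold()`,
   `shape_diagnostic()`, `run_pipeline()`): equilibrium sweeps over
   dose and fecundity.

## The drive model

Five genotypes are tracked as continuous densities: hemizygous males
`SR` and `ST`, females `SRSR`, `SRST`, `STST`. Generations do not
overlap. Each generation, at pesticide dose $i$:

1. **Mortality.** Each genotype $j$ survives with probability
   $1 - d_{i,j}$, where $d_{i,j} = \mathrm{logit}^{-1}(\alpha_j +
   \beta_j \, i)$ is its fitted (or ground-truth) reaction norm. Dose
   is measured throughout in ml of an 11.5 µg ml⁻¹ permethrin-acetone
   solution applied to the vial, the unit of the emulated experiment.
2. **Mating.** Every female mates exactly once, with sires drawn in
   proportion to male relative abundance; if the male density is zero
   no offspring are produced. A dam of genotype $j$ produces $b_j$
   offspring regardless of sire (drive kills sperm, it does not shrink
   the brood). Offspring genotypes follow X-linked Mendelian
   segregation with drive efficacy fixed at 1: SR sires produce
   all-daughter broods, each daughter inheriting the paternal SR.
3. **Recruitment.** All offspring are regulated by a common
   Beverton–Holt factor $1/(1 + \theta N_{\mathrm{off}})$, where
   $N_{\mathrm{off}}$ is the total brood production. Proportions are
   untouched; the recruited total is bounded by $1/\theta$.

The SR-male frequency (SR males / all males) and SRSR-female frequency
at $t = 1000$ are taken as equilibrium values, with no convergence
test, matching the source analysis; the model is asymptotically
well-behaved because $d_{i,j} \le 1$ and recruitment saturates.

### Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $\alpha_j, \beta_j$ | logit-linear reaction norm per genotype | calibrated world (below) | exported verbatim from the mortality GLM |
| $b_j$ | offspring per brood, female genotype $j$ | 31.4 / 58.7 / 40.0 (SRSR/SRST/STST) | genotype means of the fecundity records |
| $\theta$ | density-dependence strength (per offspring) | $(1 - 2/b_{STST})/N_0$ | places the pesticide-free wild-type equilibrium at the initial density $N_0$ |
| $t_{\max}$ | equilibrium horizon | 1000 | empirical drive systems equilibrate in tens of generations |
| $\varepsilon$ | extinction threshold | $10^{-6} N_0$ | numerically meaningful density floor |
| efficacy | drive strength in SR sires | 1 (locked in production) | idealization of a near-perfect natural driver |

A note on $\theta$: for Beverton–Holt recruitment
$N' = N_{\mathrm{off}} / (1 + \theta N_{\mathrm{off}})$ with
$N_{\mathrm{off}} = b N/2$, the wild-type equilibrium is
$N^* = (1 - 2/b)/\theta$, so matching $N^* = N_0$ gives
$\theta = (1 - 2/b)/N_0$ (with $b = b_{STST}$, ignoring the small
dose-0 mortality). The functional form is a package design choice —
the stated requirement is only a saturating density dependence
governed by one parameter — and `density_regulate()` is the single
place to swap in, e.g., a Ricker variant.

### Extinction semantics

Because females in this model always mate while male density is
positive, total density never collapses through male scarcity alone:
male numbers can decay geometrically toward zero while females sit at
carrying capacity. Any finite population in that state is doomed, so
`simulate_drive()` flags extinction when **either** the total density
**or** the total male density falls below $\varepsilon$. This is what
makes the classic driving-X result expressible: with all costs removed,
SR-male frequency exceeds 0.99 and the male population then collapses
below threshold — fixation followed by extinction.

`find_extinction_threshold()` scans a dose grid for the first extinct
simulation and bisects the bracketing interval to 0.005 ml. Near the
asymptotic threshold decay is slow, so the measured threshold is the
dose at which the population crosses $\varepsilon$ *within*
$t_{\max}$ generations — slightly above the asymptotic value, and the
quantity actually plotted by equilibrium figures.

## The statistical models

**Mortality.** Vial-level death counts are binomial with a logit link.
Sex is a deterministic function of genotype in this system (SR/ST are
male), so a 5-level genotype factor plus a sex term is rank-deficient.
The default maximal model is `sex + drive_class * dose_ml`, where
`drive_class` ∈ {wild, het, drive-homozygous}; its term degrees of
freedom (genotype 2, sex 1, dose 1, interaction 2) are exactly those of
the empirical analysis this package mirrors. A saturated
`per_genotype` coding (one intercept and slope per genotype-sex class)
is available and is what parameter-recovery tests use. Because dose
enters linearly on the logit scale in every offered formula, each
class's predicted curve is itself logit-linear, and
`build_dose_response()` reads the intercept and slope straight off the
linear predictor — the simulation's $d_{i,j}$ equals the GLM's
prediction to machine precision, which is the load-bearing coupling of
the whole pipeline (and is tested to 1e-12).

**Fecundity.** Offspring counts are Poisson with a log link, fixed
effects `dose_ml * genotype`, and a random intercept for individual
nested in exposure vial. When the individual-level variance collapses
to numerically zero (boundary fit, or SD below 1% — a negligible
multiplicative effect on a Poisson rate), the model is refit with a
vial-only intercept and flagged, reproducing the singular-fit fallback
of the emulated analysis. Counts of zero are excluded before fitting
(a zero cannot be distinguished from a failure to mate), so the fitted
means are zero-truncated-Poisson means; at the brood sizes involved
($\lambda > 10$) the truncation bias is far below sampling error.

**Model selection and contrasts.** `lrt_drop()` is the sequential
likelihood-ratio primitive ($\chi^2 = 2\Delta\ell$, df = parameter
difference); its statistic is invariant to factor coding and its
type-I error is calibrated against the $\chi^2$ asymptotics in the
acceptance suite. `genotype_contrasts()` computes marginal means per
genotype on the link (log) scale, averaging model-matrix rows over an
equal-weight dose grid — the emulated analysis averages "across all
exposure concentrations" without stating weights, and equal weights
are the transparent choice. All pairwise differences are z-tested
with a Tukey-style multiplicity adjustment computed as the exact
multivariate-normal max-|z| tail probability, evaluated by Monte Carlo
(10⁵ draws, fixed internal seed, caller RNG untouched) on the joint
distribution of the marginal means. No equal-SE studentized-range
shortcut is assumed, so the adjustment is valid on unbalanced designs;
adjusted p-values are floored at the raw p and are monotone in |z| by
construction. (The marginal-mean covariance is sampled rather than the
contrast covariance, which is singular for all-pairwise contrasts.)

## The synthetic world

The generators are a *stated world*, not a tuning dial. Mortality is
binomial around logit-linear truth; fecundity is Poisson with vial
(SD 0.3) and optional individual (default SD 0) random intercepts, a
dose effect of −0.25 log units per ml, and the zero-count exclusion
applied exactly as in the emulated experiment. Default design sizes
follow the experiment: 35 vials per genotype (175 total), 7–11 flies
per vial, doses on an even grid over 0–1.8 ml; fecundity uses two
measures per female with a `survival_thinning` option to reproduce the
genotype-unbalanced realized sample sizes (146/368/238), off by
default.

The default truth values were calibrated **once** against the
published qualitative patterns of the system this package emulates,
and then frozen:

* drive classes carry baseline (dose-0) excess mortality — SR males
  0.12 vs ST 0.076; SRSR females 0.083 vs STST 0.047;
* male curves converge at the top of the empirical range (equal at
  1.8 ml);
* female log-mean brood sizes sit at the published link-scale
  contrasts (heterosis +0.384, drive-homozygote cost −0.243) around
  $b_{STST} = 40$;
* the resulting all-genotype lethal point is ≈ 2.33 ml, just beyond
  the empirical range, with the 26-point sweep grid extending to
  2.5 ml to cover it.

With these values the model reproduces: an interior equilibrium
SR-male frequency at every sub-lethal dose (no fixation); a
dose-frequency curve with an interior minimum near 1.5 ml (the
"concave" shape, driven by the SRSR mortality excess peaking at
intermediate doses on the probability scale); an extinction threshold
invariant to the initial SR frequency; a persistent, monotone, and
dominant effect of $b_{SRSR}$ on both SR-male and SRSR-female
equilibrium frequencies; and near-insensitivity to $b_{STST}$
(dose-wise never exceeding the $b_{SRSR}$ effect).

**What a green test does not establish.** The generators draw
independent binomial/Poisson counts: no overdispersion beyond the vial
effect, no age structure, no measurement error, and the absolute
fecundity scale ($b_{STST} = 40$) is a calibration choice, not a
published value. One published pattern is only partially reproducible
in this model class: the heterozygote-fecundity effect on SR-male
frequency is positive and peaked at intermediate doses (as published)
but is strongly *negative* at low doses here — boosting the
heterozygote engine parks SR alleles in high-mortality SRSR females —
whereas the source reports no strong effect at the extremes. A scan
over baseline-cost calibrations shows this low-dose reversal is
structural, so the acceptance suite asserts the interior-dose claim
and documents the low-dose discrepancy rather than asserting either
direction there. The published model's exact density-dependence
derivation lives in supplementary material that is not reproduced in
its main text; the Beverton–Holt form here is a documented choice
behind a pluggable interface.

## Numerical choices and degenerate inputs

* Frequencies with a zero denominator (no males, no females) return
  `NaN` rather than a silent 0; extinct sweep cells carry `NA`
  frequencies with `extinct = TRUE`.
* Curvature is summarized by second differences, not a fitted
  quadratic — no functional form is claimed. `shape_diagnostic()`
  reports both the interior-extremum and chord-deviation readings of
  "concave".
* Quasi-complete separation in the mortality GLM (an all-dead or
  all-alive class) is flagged with a warning, never silently returned.
* LRT statistics are clipped at zero, with a warning beyond −1e-6.
* CSV validation reports every violated row with its line number;
  configuration validation reports every violated constraint at once.
  Drive efficacy ≠ 1 is rejected in the production profile and
  permitted only in test profiles.
* All randomness flows from one root seed (generators take explicit
  seeds; the pipeline splits its seed per stage), so every data
  artifact is byte-reproducible; the run log additionally records the
  seed, a content hash of the resolved configuration and per-stage
  timings (the log is the one artifact that is not byte-stable, by
  design).

## Known limitations

Deterministic densities only: no drift, so "extinction" is a
threshold-crossing statement. Monandry, no sperm competition or sperm
depletion, no sexually selected trait costs, no suppressor evolution —
the model deliberately excludes the mechanisms known to depress SR
frequency further, and its equilibrium frequencies are accordingly on
the high side. Brood size is dose-independent in the dynamical model
(the empirical dose effect on fecundity is estimated but deliberately
not propagated, matching the emulated parametrization; a dose-on-
fecundity hook would be a one-line change in `run_sweep()`'s parameter
substitution). The logit-linear extrapolation beyond 1.8 ml is exactly
that — an extrapolation.
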