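---
title: "Two-stage global sensitivity analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage global sensitivity analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emugsa)
```

# The problem

Mechanistic models of physiology — here, the iodide kinetics and thyroid
function of a near-term pregnant woman and her fetus — carry dozens of
uncertain inputs: body weight, blood flows, clearances, Michaelis–Menten
transporter constants, hormone turnover rates.  A local, one-at-a-time
sensitivity analysis perturbs each input a percent or two around its
nominal value; it is cheap but blind to interactions and to behavior away
from the nominal point.  Global sensitivity analysis varies all inputs
simultaneously over their full plausible ranges and decomposes the output
variance into contributions of single inputs and their interactions — but
the standard variance-based estimators need many thousands of model runs,
which is prohibitive when one simulation takes minutes.

This package implements the established two-stage answer for expensive
deterministic simulators:

1. **Screening** with the Morris elementary-effects method ranks all
   inputs cheaply (about `r` runs of `k + 1` evaluations for `r`
   trajectories over `k` inputs) and eliminates the non-influential ones.
2. **Emulation**: the screened model is run a few hundred times over a
   maximin Latin hypercube; a Gaussian-process (GP) emulator is fitted to
   those runs, validated by cross-validation, and the variance-based
   indices are computed on the emulator, which evaluates in microseconds.

# Parameter spaces from mean/CV tables

Uncertain inputs are summarized by a mean and a coefficient of variation
(CV = SD/mean).  Ranges are the 2.5th and 97.5th percentiles of a Gaussian
with that mean and CV:

$$[\,\mu(1 - 1.96\,\mathrm{cv}),\ \mu(1 + 1.96\,\mathrm{cv})\,].$$

The multiplier is fixed at 1.96 exactly (not `qnorm(0.975)`) so that
full-precision worked ranges in the packaged table reproduce digit for
digit.  For positive physical quantities the Gaussian lower percentile can
go non-positive — this happens exactly when cv ≥ 1/1.96 ≈ 0.5102 — and the
range then falls back to one standard deviation either side,
$\mu(1 \pm \mathrm{cv})$.  A CV of 30% is the assumed default where no
variability data exist.  A handful of stored table ranges match neither
rule (their sources set them by other means); the loader keeps them as
stored and flags them in its cross-check report rather than failing:

```{r}
sp <- hpt_parameter_table()
chk <- attr(sp, "bound_check")
subset(chk, !(lower_ok & upper_ok))$name
```

**Mass balance.**  Lumped compartment fractions (blood-flow splits,
tissue-volume splits) must sum to a fixed total.  Following the standard
re-parameterization for such constraints, sampled fractions are rescaled
post hoc so each constraint group hits its total exactly
(`map_unit_to_physical()`); this is the simplest rule that preserves the
constraint without distorting marginal ranges appreciably.  Six
lumped-complement rows of the packaged 66-parameter table are not printed
in the source table; they are reconstructed so each group's nominal means
sum to the required total, assigned the default 30% CV, and marked
`assumed_default` — they are completions, not transcriptions.

**Sampling law.**  Within a range, sampling is uniform for both stages.
The source analysis samples "finite distributions" over ranges without
stating a within-range law; uniform is the standard choice for GP-emulator
sensitivity analysis and makes the variance decomposition well defined.

# Morris screening

For a trajectory that perturbs one coordinate at a time by
$\Delta = p/(2(p-1))$ on a $p$-level grid, the elementary effect of input
$i$ is $(y(x + \Delta e_i) - y(x))/\pm\Delta$.  With $r$ trajectories each
input gets $r$ effects, summarized by $\mu$ (mean; overall influence),
$\mu^\*$ (mean absolute value; immune to sign cancellation) and $\sigma$
(standard deviation; nonlinearity or interaction propensity).  Defaults
follow standard practice: $p = 4$ levels, one effect per input per
trajectory, trajectories drawn from a 500-candidate pool and reduced to
$r$ by the distance-spread criterion (greedy accretion plus swap
refinement; exhaustive subset search is combinatorially infeasible, but
the test suite verifies the heuristic equals full enumeration on small
pools).  Because the raw $\mu$ is subject to sign cancellation, ranking
uses $|\mu|$ and the report always carries $\mu^\*$ alongside; ties break
by $\sigma$, then name, so rankings are reproducible.  Screening keeps
every input whose $|\mu|$ exceeds the threshold in *any* repeat (the
method is stochastic; three repeats is the default in the pipeline), plus
any forced inclusions.  The screening threshold is expressed in output
units and defaults to the application's historical value (6e-4, output in
pmol/L); it is fully configurable since its scale is model-specific.

A failed simulator run drops its whole trajectory, which keeps the
per-input sample counts equal — simpler and statistically cleaner than
patching individual effects.

# Maximin Latin hypercube designs

Emulator training uses an LHS with one point per stratum and column-wise
jitter (midpoint placement is available but jitter avoids grid artifacts
in the emulator).  The design is improved by a stochastic pairwise-swap
hill climb on the minimum inter-point distance: a swap exchanges two runs'
values in one column (which preserves the LHS property by construction)
and is accepted only if the minimum distance strictly increases.  Half of
all proposals involve a run from the current closest pair, since only
those swaps can improve the criterion.  The default budget is 10,000
proposals.  The exact algorithm used by the original emulation software is
unpublished; this implementation is property-checked (stratum invariant,
monotone criterion) rather than design-identical.

# The Gaussian-process emulator

The emulator is the standard deterministic-simulator formulation: mean
basis $h(x) = (1, x_1, \dots, x_k)$, squared-exponential correlation
$c(x, x') = \exp\{-\sum_i ((x_i - x_i')/\ell_i)^2\}$ with one length per
input, outputs standardized internally.  Given lengths, the basis
coefficients $\beta$ and process variance $\sigma^2$ have closed-form
generalized-least-squares solutions; the lengths maximize the concentrated
log-likelihood, optimized by L-BFGS-B from 8 starts (1 moderate + 7
randomized, seeded) within $\ell \in [10^{-2}, 10^2]$ on the unit-cube
scale.  Concentrated maximum likelihood was chosen over a full Bayesian
treatment of the lengths because it is deterministic, fast and testable;
emulator-uncertainty bands on sensitivity indices are out of scope.

Numerical choices: the default nugget is $10^{-8}$ on the standardized
scale (conditioning only; `nugget = 0` gives exact interpolation and a
"stochastic simulator" mode is available by setting a larger nugget); if a
correlation matrix is numerically singular the jitter escalates by decades
and the escalation is recorded on the fitted object; one step of iterative
refinement on the interpolation solve keeps training-point reproduction at
interpolation accuracy even for ill-conditioned correlation matrices.

Validation is leave-one-out cross-validation computed by the closed-form
universal-kriging downdating identity (hyperparameters fixed; the identity
is verified against explicit refits in the test suite).  The report gives
the LOO root-mean-square error, the fraction of standardized errors beyond
±2 (about 5% when the emulator is calibrated), and the slope/intercept of
predicted versus actual — an unbiased emulator sits on the 1-to-1 line.
No output transform is applied; if a simulator produces near-zero outputs
with skew, bias shows up in the validation report rather than being hidden
by a transform.

# Variance-based indices on the emulator

For independent uniform inputs, the main effect
$S_i = \mathrm{Var}(E[Y|X_i])/\mathrm{Var}(Y)$ is the expected fractional
variance reduction if $X_i$ were known; the total effect
$T_i = 1 - \mathrm{Var}(E[Y|X_{-i}])/\mathrm{Var}(Y)$ is the fraction that
would remain if everything else were known.  $T_i \ge S_i$, and the gap
measures interaction involvement.  Closed pairwise fractions
$V_{ij} = \mathrm{Var}(E[Y|X_i,X_j])/\mathrm{Var}(Y) - S_i - S_j$ localize
the interactions.

Estimators are the standard pick-freeze forms on two base matrices with
column substitution — Saltelli (2010) for $S_i$ and the closed pair,
Jansen (1999) for $T_i$ — run on the emulator's posterior mean, with
$N = 2^{14}$ base samples and seed 20150527 by default.  Every estimate
carries a Monte-Carlo standard error; small estimates can come out
slightly negative and are reported as-is with their errors (transparency
over cosmetics).  Main-effect curves $x_i \mapsto E[Y|X_i = x_i]$ are
computed by averaging the emulator over the other inputs with common
random numbers across the grid.

The conventional influence cut — keep parameters whose main and/or total
effect exceeds 0.5% of the output variance — is available as
`influential_parameters()`.

The same indices can be computed by the textbook double-loop Monte Carlo
directly on a cheap model (`brute_force_indices()`, with the standard
inner-noise bias correction).  That route is hopeless for an expensive
simulator but serves as the independent oracle: the test suite requires
the emulator route to agree with it, and with analytic decompositions of
the benchmark functions (Ishigami, Sobol' g, additive and product models).

**Lowry presentation.**  Parameters are ordered by descending main effect;
the lower envelope is the cumulative sum of main effects and the upper
envelope the running cumulative total effect capped at 100% — an
interpretation of the ribbon construction that is stated in the plot
legend, since the original phrasing is ambiguous.  The band between the
envelopes is variance attributable to interactions.  Every figure has a
CSV twin so downstream checks never parse images.

# The thyroid–iodide stand-in model

The original application is a 66-parameter biologically based
dose-response model of the maternal–fetal thyroid axis whose equations
live in a prior publication and a proprietary simulation environment; it
is not reproducible here.  The package therefore ships a deliberately
small steady-state stand-in (`hpt_model()`) with the same qualitative
input–output structure, used to exercise every pipeline stage in physical
units.  It makes no claim of numeric agreement with the original model's
published indices — the acceptance surface asks for directional and
structural agreement only.

Structure (all rates first-order unless noted):

* Dietary iodide (200 µg/day at the euthyroid evaluation condition;
  126.9 g/mol) enters a single plasma pool.
* Urinary clearance `clu` competes with thyroidal sequestration.
* Thyroidal uptake is NIS-mediated Michaelis–Menten transport
  (`vmax`, `km`) plus passive permeability (`pa_thy`), **rate-limited by
  thyroid plasma flow** `q_thy`: delivery and uptake act as conductances
  in series, with the capillary concentration solved from the quasi-steady
  delivery balance.  Flow limitation is physiologic (the gland extracts a
  substantial fraction of delivered iodide) and is what lets transporter
  capacity saturate: beyond a point, more `vmax` cannot capture iodide
  that is not delivered.  Without it, a one-pool competition model has a
  structural identity — the elasticity of steady-state output to urinary
  clearance and to uptake capacity are equal in magnitude at every
  operating point — which contradicts the well-established empirical
  pattern that renal clearance dominates; the flow-limited form is
  therefore both more realistic and necessary for structural fidelity.
* A fraction 0.7 of uptaken iodide is organified.  The organification
  fraction is a structural constant of the stand-in, fixed at 0.7 as a
  plausible round value rather than asserted from literature; since it
  only rescales the organified flux, its exact value shifts the output
  level without changing the sensitivity structure.  4 iodine atoms make
  one T4.
* Serum total T4 follows from production over first-order disposal:
  deiodination (`kdeg`) acting on the distribution volume `vd`, plus a
  fixed non-deiodinative (biliary/fecal) clearance equal to one third of
  the nominal deiodinative clearance, i.e. a 25% non-deiodinative share of
  T4 disposal, in line with textbook T4 mass balance.
* Free T4 is `frconv` times total T4 (in pmol/L).
* Iodine liberated by hormone turnover is salvaged efficiently: a fraction
  `frecycle` (nominal 0.9, CV 5%) of the total organified throughput
  re-enters the plasma iodide pool, regardless of disposal route.
* Fetal free T4 is a placental share (`placental_share`, calibrated 0.20)
  of maternal free T4 plus an endogenous term that tracks the maternal
  level, so the maternal-origin fraction equals the share at any
  operating point.

Nominal parameter values are the packaged table means scaled to whole-body
units by the nominal maternal body weight (72.3 kg, exponent 0.75);
thyroid plasma flow carries the plasma fraction (1 − hematocrit, 0.33 in
late pregnancy).  At nominal the model sits comfortably in physiological
ranges — serum inorganic iodide ≈ 15 nM, total T4 ≈ 96 nmol/L, free T4 ≈
8.7 pmol/L — and responds in the expected directions (output falls with
clearance, affinity constant and degradation rate; rises with transporter
capacity, free fraction, thyroid flow).

The ten varied inputs (`hpt_space()`) take the revised, physiologically
plausible ranges of their table counterparts; the steady state is solved
algebraically by bracketed root finding to relative tolerance $10^{-10}$
(time-domain behavior is out of scope), and iodide mass balance at the
root is checked to below $10^{-8}$ relative.  The T4 production rate
constant `kprod` cancels at steady state (production tracks organified
flux); it is kept among the varied inputs deliberately, as a known-null
input that screening must rank last.

**What the stand-in does not emulate** — and hence what passing tests do
and do not show: no time-course or periodicity, no TSH feedback, no
perchlorate competition, no multi-compartment PBPK disposition, a
one-compartment fetus, and no claim that its numeric indices match the
original model's.  Tests on the stand-in demonstrate that the *machinery*
(screening, design, emulation, decomposition) recovers the structure of a
model of this class, not that the original model's published numbers are
reproduced.

# Problem sizes and reproducibility

The package's own studies use sizes chosen to keep every result tight at
desk scale: emulator demonstrations train on 250-run designs (the
application-scale design size) over 10 inputs; screening demonstrations
use 50–100 optimized trajectories from pools of 150–500; pick-freeze
estimates use $2^{14}$–$2^{16}$ base samples on the emulator where a
margin matters.  Every stochastic stage takes an explicit integer seed,
derived per-stage from one master seed in the pipeline, and re-running a
pipeline configuration reproduces every CSV artifact bit for bit; the
manifest records seeds, versions and artifact hashes.

# Known limitations

* Uniform within-range sampling only; truncated-Gaussian or lognormal
  laws and the meta-analytic pooling of multi-study CVs are out of scope.
* Single-output emulation; no treed or nonstationary GPs; no full-Bayes
  length-scale posteriors.
* Pairwise interaction estimates on a smoothing emulator inherit emulator
  error on top of Monte-Carlo error; weak interactions (below ~0.5% of
  variance) should be read with caution, as the validation chapter of the
  report reminds the user.
* The stand-in is a structural analog, not a surrogate of record, for the
  original 66-parameter model.
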