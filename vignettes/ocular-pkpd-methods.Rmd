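---
title: "Methods: two-compartment ocular PK/PD of intravitreal anti-VEGF therapy"
author: "ocupkpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-compartment ocular PK/PD of intravitreal anti-VEGF therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ocupkpd)
```

## The model

`ocupkpd` models the suppression of ocular VEGF after a single
intravitreal bolus of an anti-VEGF antibody (the defaults describe
ranibizumab, a 48 kDa Fab, in the cynomolgus macaque eye). The eye is
reduced to two well-mixed compartments, the vitreous and the aqueous
humor. VEGF is a homodimer with two identical antibody-binding sites, so
three VEGF-containing species exist: free VEGF (V), the singly bound
complex VR and the doubly bound complex RVR. Mass action with statistical
factors gives

$$V + R \underset{k_{off}}{\overset{2k_{on}}{\rightleftharpoons}} VR,
\qquad
R + VR \underset{2k_{off}}{\overset{k_{on}}{\rightleftharpoons}} RVR,$$

with the dissociation constant $K_D = k_{off}/k_{on}$. The association
rate is never stored: it is always derived from $k_{off}$ and $K_D$.
VEGF is produced by the retina at a constant rate $V_{in}$ (pM·mL/day)
and delivered to the vitreous; every species transfers unidirectionally
from vitreous to aqueous humor with a first-order elimination rate
constant $k_{el,i}$ (1/day) and is cleared from the aqueous humor by
aqueous turnover at rate $CL/V_{aq}$. Amounts are conserved across the
transfer, which introduces the volume ratio $V_{vit}/V_{aq}$ on
concentrations. The retinal route is neglected: for molecules of this
size retinal permeation is a small fraction of total ocular elimination,
and including a retinal compartment would add parameters the aqueous
humor data cannot constrain.

The resulting eight-state ODE system (four species, two compartments) is
implemented twice: a readable R version (`ode_rhs()`) used as a
verification oracle and a compiled C version integrated by `lsoda`
(deSolve) in `simulate_model()`. Two algebraic consequences anchor the
implementation and the tests:

* drug-free steady state: $v_{vit}^* = V_{in}/(k_{el,v} V_{vit})$ and
  $v_{aq}^* = V_{in}/CL$, an exact fixed point of the RHS;
* VEGF-moiety balance: the total VEGF amount changes at rate
  $V_{in} - CL\,(v_{aq}+c_{aq}+h_{aq})$ independently of the binding and
  transfer terms.

With binding disabled ($K_D \to \infty$) the antibody follows a linear
two-compartment cascade with a closed-form solution, which the test suite
compares against at $10^{-6}$ relative error.

The dose enters as an initial condition: the injected mass (default
0.5 mg) is converted to a vitreous concentration through the antibody
molecular weight and the vitreous volume; 0.5 mg in 2 mL is
$5.21\times 10^6$ pM — more than six orders of magnitude above the
~2 pM VEGF baseline, which is what makes the system stiff immediately
after injection.

### Units, volumes and molecular weights

All internal concentrations are pM and time is in days. Volumes default
to $V_{vit} = 2.0$ mL and $V_{aq} = 0.105$ mL (midpoints of the
literature ranges for the macaque); they are physical constants, not
inferred. Observations use per-series units chosen so both noise SDs are
of order 0.1–0.3: aqueous VEGF in pM and aqueous antibody in µM (the
antibody peak is ~1 µM).

Molecular weights default to $MW_R = 48$ kDa and $MW_V = 44$ kDa. The
VEGF homodimer weight deserves a note: cube-root molecular-weight scaling
of the elimination rate (below) reproduces the literature rate constants
$k_{el,v} = 0.309$ and $k_{el,h} = 0.210$/day at their printed precision
with 44 kDa, while 45 kDa misses the RVR value at the third decimal.
44 kDa is within the range quoted for glycosylated VEGF-165 homodimer, so
it is adopted as the default; both weights are constructor arguments.
The complex weights are always derived ($MW_C = MW_V + MW_R$,
$MW_H = MW_V + 2MW_R$).

### Elimination-rate scaling and hydrodynamic radius

Ocular elimination of a macromolecule is controlled by its hydrodynamic
radius, which for a compact globular protein scales as $MW^{1/3}$
(Stokes–Einstein with partial specific volume $\nu = 0.73$ cm³/g):

$$R_h = \left(\frac{3 \nu\, MW}{4 \pi N_A}\right)^{1/3}, \qquad
k_{el,target} = k_{el,ref}\left(\frac{MW_{ref}}{MW_{target}}\right)^{1/3}.$$

`scale_elimination_rate()` and `hydrodynamic_radius()` implement these;
the VR rate deviates ~1.5% from the printed literature value under the
pure cube-root rule, so the tests allow 2% there. Half-lives are
$t_{1/2} = \ln 2 / k_{el}$.

### Pharmacokinetic output metrics

Three scalar summaries (`pk_metrics()`) describe a simulated profile:

* **PM1**, the time of the initial aqueous VEGF uplift — first time after
  the post-dose minimum at which $v_{aq}$ recovers to $f_1$ of baseline;
* **PM2**, the VEGF relaxation time — first time after the minimum at
  which $v_{aq}$ reaches $f_2$ of baseline and stays there;
* **PM3**, the antibody half-life — $\ln 2$ over the terminal slope of
  $\log r_{aq}$ fitted on the final third of the horizon.

The profile annotations behind PM1/PM2 are qualitative, so the
thresholds are explicit parameters with defaults $f_1 = 0.10$ and
$f_2 = 0.90$. Crossing times are refined by interpolation inside the
bracketing grid interval; on the default grids the refinement error is
far below 0.01 day (verified against a 0.001-day brute-force scan). The
"sustained" condition in PM2 guards against the small overshoot of the
VEGF rebound. When a trajectory never crosses a threshold (e.g. zero
dose) the metric is flagged "not reached" rather than raising an error.

## Synthetic data

`generate_dataset()` emulates the aqueous humor sampling experiment: the
model is evaluated at a schedule of days, independent additive Gaussian
noise of SD $\sigma_N$ is applied on each series' own observation unit,
negative draws are clipped to zero, and each point is flagged as below
the assay's lower limit of quantification by comparing the *noisy* value
to the limit — what an experimenter would actually observe. The ELISA
limits (9.0 pg/mL for VEGF, 0.156 ng/mL for ranibizumab) are converted to
0.205 pM and 3.25×10⁻⁶ µM through the molecular weights at run time
rather than hard-coded.

Schedules (`make_schedule()`) include the macaque study's days
{0, 1, 3, 7, 14, 21, 28, 35, 42, 49, 56}, a uniform grid (default: 10
points over 9 weeks, the synthetic protocol used throughout), and the
design variants below. Default experiment noise is $\sigma_N = 0.25$ for
the correction study and $\sigma_N = 2.5\times10^{-3}$ for the schedule
studies, matching the corresponding synthetic protocols.

What the generator does *not* emulate: inter-animal variability (the
fits are to pooled means), assay drift, and any mechanistic ELISA
behaviour beyond the additive noise and the linear contamination model
below. Passing the synthetic-recovery tests therefore demonstrates
correctness of the inferential machinery under the stated noise model,
not robustness to the full complexity of in-vivo data.

### Phases of the VEGF profile

The aqueous VEGF curve has four phases: P1, the pre-dose point
($t = 0$); P2, suppression (reference VEGF below the LLQ); P3, the
transition (recovery from the LLQ up to $f_2$ of baseline); and P4, the
return to equilibrium. `classify_phases()` labels schedule times using
the *noiseless* reference trajectory, so labels are invariant to
observation noise; descending-limb points above the LLQ (possible only
with very early sampling) are assigned to P2. At the reference
parameters the 10-point uniform schedule has P2 = {7, 14, 21} days,
P3 = {28} and P4 = {35...63}.

Phase-removal schedules drop the labelled VEGF points;
transition-density schedules replace the P3 points of the base schedule
with exactly k ∈ {0, 1, 3, 5} equally spaced points strictly inside the
transition interval. Because the phases are features of the VEGF curve,
these variants alter the VEGF series only; the antibody series keeps the
full base schedule.

## Below-LLQ correction

`apply_correction()` implements the three standard substitution rules:
M5 (replace every censored value with LLQ/2), M6 (replace the first
censored value of each maximal censored run with LLQ/2, delete the
rest), M7 (replace every censored value with 0). The per-run reading of
M6 matters only for series with several censored runs; in this system
VEGF censoring occurs as a single mid-series run and antibody censoring
as a single tail run, where the global and per-run readings coincide.
Corrections never stack: applying one to an already-corrected series is
an error, and censoring flags survive on retained points.

## Bayesian inference

The free parameters are the four elimination rates, $k_{off}$, $K_D$,
$CL$, $V_{in}$ and the two observation SDs (10 in the base model; the
adapted ELISA model below adds $\gamma$ and $\eta$). Priors are
independent truncated normals on the natural scale, centred on the
literature values with generous spreads; the $K_D$ prior
(TN(5000, 8000) on [1, 30000] pM) deliberately spans the four orders of
magnitude of disagreement among published estimates. Volumes and
molecular weights are fixed.

The likelihood is additive Gaussian on the linear concentration scale,
per series in its own unit. The linear scale is a deliberate choice: it
makes the zeros produced by M7 ordinary observations (a log-scale
likelihood cannot absorb them), and it matches the printed magnitudes of
the inferred noise SDs. Points removed by M6 simply drop out of the sum.
Solver failures at a proposed parameter set yield log-likelihood
$-\infty$ with a warning.

### Sampler

`demcmc_sample()` is the ter Braak differential-evolution MCMC: chain
$i$ proposes $x' = x_i + \gamma (x_a - x_b) + \epsilon$ with
$\gamma = 2.38/\sqrt{2d}$, $\gamma = 1$ every tenth generation (mode
jumping), and Gaussian jitter $\epsilon$ at $10^{-6}$ of the prior SD.
Three implementation choices matter for desk-scale budgets:

* **Log-coordinate walk** (`transform = "log"`): all free parameters are
  positive, and their posteriors span orders of magnitude ($K_D$) or
  contract violently (noise SDs under low-noise data). Running the walk
  on $\log x$ with the Jacobian correction makes proposals scale-free
  and mixes far better; the sampled distribution is unchanged.
* **Initialization** (`init_strategy`): `"prior"` draws the population
  from the prior, with $K_D$ placed log-evenly across (10, 22000) pM so
  the population starts dispersed over all plausible magnitudes — the
  reference strategy, under which the convergence diagnostic is honest.
  `"laplace"` finds the posterior mode with a bounded quasi-Newton
  search in the working coordinates and scatters the population with the
  inverse-Hessian covariance. Experiments use the Laplace start to reach
  stationarity within desk-scale iteration budgets.
* **Warm-up outlier rejuvenation**: chains stranded far below the
  population log-posterior (interquartile rule) are restarted from the
  current best chain, only before the burn-in cut, so the retained
  sample keeps detailed balance.

Convergence is monitored with the rank-normalized split R-hat: chains
are split in half, pooled draws replaced by the inverse-normal transform
of fractional ranks, and the classic $\sqrt{((n-1)/n\,W + B/n)/W}$
computed on the transformed draws. Zero-variance input returns 1 by
convention. Posterior summaries report mean, SD, Fisher–Pearson moment
skewness $g_1 = m_3/m_2^{3/2}$, and type-7 (linear interpolation)
quartiles over pooled post-burn-in draws (default burn-in: first half).

The reference configuration for a full fit is 50 chains × 10,000
iterations; the packaged experiments and tests use reduced
configurations (20–24 chains × 1,000–2,500 iterations) chosen so each
study completes in minutes on one core, with the Laplace start and log
walk compensating for the shorter runs. The experiment drivers also
relax the likelihood solver to `rtol = 1e-6`, which keeps the model
error several orders below the smallest observation noise used anywhere
while roughly halving the cost of a likelihood call.

For the low-noise schedule studies the observation SDs are *fixed* at
their known generating value (`fix_sigma`): with $\sigma_N = 2.5\times
10^{-3}$ the noise posterior is a near-degenerate funnel that dominates
sampler effort while being irrelevant to the design question (which
schedule constrains the kinetic parameters best). Fixing known noise in
a simulation design study is standard practice; the correction study and
the recovery tests infer the SDs as usual.

### Posterior products

* `posterior_predictive()` simulates the final draws (default 1000) and
  returns pointwise mean and SD bands for all eight species.
* `regress_cl_vin()` regresses $V_{in}$ on $CL$ over the final 1000
  draws. At steady state $v_{aq}^* = V_{in}/CL$, so the draws lie near a
  line whose slope estimates the baseline aqueous VEGF — a route to a
  patient-specific production-rate estimate from a single pre-dose
  sample.
* `average_posteriors()` averages kernel densities across replicate
  synthetic datasets on a shared grid and normalizes by the maximum, the
  convention used to overlay repeated-experiment posteriors;
  `overlap_coefficient()` computes $\int \min(f, g)$ after renormalizing
  both curves to unit mass.

### Adapted ELISA model and profile likelihood

A sandwich ELISA that captures free binding sites can count partially
bound VEGF (which retains one free site) and, through competitive
binding, some fully bound VEGF. The adapted observation model is
$mv_{aq} = v_{aq} + \gamma c_{aq} + \eta h_{aq}$ with contamination
fractions $\gamma, \eta \in [0, 1]$ given near-flat truncated-normal
priors. `profile_likelihood_gamma()` fixes $\gamma$ on a grid (with
$\eta = 0$), maximizes the remaining 10-parameter posterior by
multi-start L-BFGS-B — in log coordinates, so finite-difference steps are
scale-free — and warm-starts each grid point from its predecessor,
which keeps the profile smooth. Failed grid points are flagged, not
fatal.

## Global sensitivity analysis (eFAST)

`efast_indices()` implements the extended Fourier amplitude sensitivity
test: each parameter in turn is driven along the space-filling curve
$x(s) = \tfrac12 + \tfrac1\pi \arcsin(\sin(\omega s + \phi))$ at the
focal frequency $\lfloor (N_s-1)/2M \rfloor$ while the complementary
parameters oscillate at low frequencies; the first-order index $S_i$ is
the output variance at the focal frequency and its first $M = 4$
harmonics, and the total-order index $S_{Ti}$ is one minus the
low-frequency (complementary) variance fraction. Estimates are averaged
over random-phase curves and their confidence intervals obtained by
bootstrap over curve-level estimates. Designs violating the
$N_s \ge 4M^2 + 1$ anti-aliasing constraint are rejected before any
model run; constant outputs return all-zero indices (relative variance
below $10^{-12}$) instead of dividing by zero. The implementation is
validated against the analytic Ishigami decomposition and an additive
linear model.

The default parameter ranges widen each literature range by 50% on each
side (point values become $[0.5v, 1.5v]$), with $K_D \in [10, 22000]$ pM
and $V_{in} \in [1, 10]$ pM·mL/day; the design includes the two noise
SDs (inert for deterministic outputs) and an inert dummy parameter whose
indices estimate the estimator's artefact floor. PK-metric values not
reached within the 63-day horizon are imputed with the horizon and the
imputed fraction reported. Time-course indices reuse one ODE solve per
sampled parameter vector for every time point.

## Numerical choices

* Solver: `lsoda`, `rtol = 1e-8`, `atol = 1e-10` pM by default; small
  negative excursions are clipped to zero, excursions beyond tolerance
  are an error. An analytic Jacobian is compiled alongside the
  derivatives. Sensitivity sweeps use `rtol = 1e-5` (crossing-time error
  ~1e-4 day, immaterial for variance decomposition); experiment
  likelihoods use `rtol = 1e-6`.
* The fixed-step verification oracle runs RK4 at $\Delta t = 10^{-4}$
  day: the post-bolus binding transient relaxes at ~$1.2\times10^4$/day,
  so coarser fixed steps sit outside RK4's stability region.
* Ties and degenerate inputs: zero-variance R-hat returns 1; an
  un-suppressed profile labels all non-zero times P4; M6 on a censored
  run of length one reduces to M5 on that run.
* Reproducibility: every stochastic routine takes an explicit seed;
  replicate $r$ of an experiment uses dataset seed `seed + r` and
  sampler seed `seed + 1000 + r`, identical across conditions so
  comparisons are matched.

## Problem sizes used by the packaged studies

The analysis drivers and the test suite run: parameter recovery with 10
replicates of the 10-point, $\sigma_N = 0.25$, M7 protocol at 20 chains ×
2,500 iterations (prior-dispersed initialization, log walk); the
correction comparison with 3 replicates × 4 methods at 24 × 2,000
(Laplace start; the between-method posterior differences are resolved
only near convergence, so this study gets the largest sampler the suite
budget affords); the schedule studies with 2 replicates per variant at
20 × 1,200 with fixed noise SDs; the contamination profile on
$\sigma_N = 2.5\times10^{-3}$, M7-corrected data over
$\gamma \in \{0, 0.25, 0.5, 0.75, 1\}$; eFAST validation at 4 curves ×
10,000 (Ishigami) and a reduced 4 × 1,026 design on the PK model, with
the full 4 × 10,000 PK design reserved for the standalone acceptance
script (the PK-metric indices are stable from 4 × 1,026 upward). These
sizes are the package's own desk-scale choices; the underlying functions
accept the full-scale settings unchanged.

## Known limitations

* The posteriors from reduced sampler runs are honest in location but
  can overestimate spread when R-hat is well above 1; the experiment
  reports carry per-replicate R-hat so this is visible.
* The substitution corrections are compared as-is; a censored (Tobit)
  likelihood would use the below-LLQ information more efficiently and is
  deliberately out of scope.
* Single-bolus only; the initial-state design extends to repeated doses
  but no multi-dose scheduling is implemented.
* No inter-individual variability: the model describes one pooled eye.
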