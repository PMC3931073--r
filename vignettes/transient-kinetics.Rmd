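---
title: "Modelling and fitting myosin stopped-flow transients with myokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting myosin stopped-flow transients with myokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(myokin)
library(dplyr)
```

## The problem

The motor domain of muscle myosin (subfragment 1, S1) cycles through a
series of nucleotide- and actin-bound states. Transient kinetics resolves
the elementary steps of that cycle: a stopped-flow instrument mixes S1 (or
the actin.S1 rigor complex) with ATP or ADP within a millisecond or two and
records a fluorescence transient whose exponential phases report individual
steps. Two optical probes carry essentially all of the information. The
intrinsic tryptophan fluorescence of the motor domain rises when ATP binding
drives the recovery stroke, and pyrene attached to actin Cys-374 is quenched
while myosin is bound, so its recovery reports dissociation of the complex.

`myokin` packages this analysis end to end for the human beta-cardiac motor
domain and its hypertrophic-cardiomyopathy variant R453C: it simulates both
standard kinetic schemes as linear rate systems, fits single and double
exponentials the way stopped-flow software does, implements the secondary
analyses that convert observed rates and amplitudes into elementary
constants, and generates seeded synthetic studies so the whole chain can be
validated by parameter recovery. No raw transients from the original
experiments are publicly deposited, which is exactly why the package treats
the *printed fitted constants* as ground truth and asks whether the complete
simulate -> fit -> analyze chain returns them.

## The kinetic schemes

**S1 + nucleotide.** ATP binding is modelled as a rapid equilibrium
(association constant $K_1$, in $\mu M^{-1}$) followed by an effectively
irreversible isomerization $k_{+2}$ that produces the enhanced-fluorescence
state, then the reversible hydrolysis/recovery-stroke step
$k_{+3} + k_{-3}$ and a lumped product-release exit. The observed fast
phase of the tryptophan signal therefore rises hyperbolically with ATP:

$$k_\mathrm{obs} = \frac{k_{+2}\,[\mathrm{ATP}]}{1/K_1 + [\mathrm{ATP}]},$$

with initial slope $K_1 k_{+2}$ (the apparent second-order binding
constant) and plateau $k_{+2}$; the slow phase plateaus at
$k_{+3}+k_{-3}$.

**Acto-S1 + nucleotide.** The rigor complex exists in two conformations:
a nucleotide-accessible A.M and a blocked A.M$'$, exchanging with rates
$k_{+\alpha}$ (A.M$'\to$A.M) and $k_{-\alpha}$, equilibrium
$K_\alpha = k_{+\alpha}/k_{-\alpha}$. ATP binds A.M in rapid equilibrium
($K'_1$) and the complex dissociates through the isomerization $k'_{+2}$.
ATP-induced dissociation is therefore biphasic: the fast phase follows the
hyperbola above (primed constants), the slow phase is limited by
$k_{+\alpha}$, and the fast/slow amplitude ratio estimates $K_\alpha$, from
which $k_{-\alpha} = k_{+\alpha}/K_\alpha$. ADP binds A.M with overall
affinity $K_{AD}$ and its bound complex partitions into A.M$'$.D with
$K_{\alpha D}$.

Both schemes are encoded as generators $Q$ with `build_rate_matrix()`
(columns sum to zero; concentrations folded in under pseudo-first-order
conditions, enforced as ligand $\ge 10\times$ protein) and propagated
analytically through the eigen-decomposition of $Q$. `eigen_phases()`
exposes the exact relaxation rates and signed amplitudes and serves as the
oracle for every fitting routine; the test suite cross-checks the
propagation against brute-force matrix exponentials and a stiff ODE
integrator.

### Two subtleties of the rapid-equilibrium reduction

Collapsing A.M and A.M.T into one pool is only correct if transitions that
require the *nucleotide-free* conformer are scaled by the free fraction
$1/(1+K'_1[\mathrm{ATP}])$ of the pool: A.M$'$ cannot hold nucleotide, so
the backflow A.M $\to$ A.M$'$ is gated by that factor, and so is ADP
binding (ADP competes with ATP for the same site). Without the gating the
reverse isomerization acts on nucleotide-occupied complexes and distorts
the fast eigenvalue at sub-saturating ATP.

Second, the stored $K_{AD}$ is an *operational* constant: the competition
experiment that measures it sees ADP competing against the whole apo pool
(A.M + A.M$'$), and, when the primed ADP state is modelled, the bound
ligand distributed over A.M.D + A.M$'$.D. The elementary A.M + D
dissociation constant used in the rate matrix therefore unfolds both
partition factors,
$K_{ADP} = K_{AD}\,(1 + 1/K_{\alpha D})\,/\,(1 + 1/K_\alpha)$,
so that a simulated competition experiment measures back the stored
$K_{AD}$.

The algebraic relation between $K_{AD}$, $K_{ADP}$ and $K_{\alpha D}$ alone
is exposed as `overall_KAD()`. Its exact convention is genuinely open (the
defining equation is only available as a figure in the source literature),
so both candidate forms are implemented behind a `convention` switch; the
default, `"partition"`, makes the extra bound state tighten the overall
affinity, $K_{AD} = K_{ADP} K_{\alpha D}/(1+K_{\alpha D})$, which is the
physically expected direction. The inverse (`implied_KADP()`) round-trips
exactly under either convention.

### The irreversible-dissociation limit

The textbook analysis of ATP-induced dissociation treats the two phases as
kinetically decoupled: every A.M that captures ATP is committed to
dissociation, and every A.M$'$ that isomerizes leaves immediately, so the
fast phase *is* the hyperbola and the slow phase *is* $k_{+\alpha}$, with
amplitudes split by the pre-mix $K_\alpha$ equilibrium. In the fully
coupled system the backflow $k_{-\alpha}$ mixes the two eigenmodes and
shifts the fast eigenvalue by a few percent at the low end of a titration.
Because the published binding constants are themselves the product of the
decoupled analysis, the dissociation-titration design simulates that limit
(`alpha_backflow = FALSE`: the pre-mix A.M/A.M$'$ split uses $K_\alpha$,
the transient neglects return to A.M$'$). The coupled simulator remains the
default everywhere else, and the package's tests quantify the residual
coupling bias instead of hiding it: the amplitude-ratio estimator of
$K_\alpha$, for example, carries an $O(k_{+\alpha}/k_\mathrm{obs})$
truncation bias of order 10% on a realistic grid.

## Observables are calibrations, not physics

Absolute per-state fluorescence yields are not published; only phase
amplitudes are. `observable_map()` therefore assigns yields chosen to
reproduce the printed amplitude structure and documents them as
calibration: tryptophan 1.00/1.17/1.18 for the apo, post-isomerization and
post-hydrolysis states (a 17% fast and 1% slow rise), and pyrene-actin 1.0
for every actin-bound state versus 1.34 for free pyrene-actin (a ~34%
total rise on dissociation, matching the printed 29% + 4.7% phases).
Traces are normalized to the pre-mix level, except in titration series
where all traces share the free-actin scale so that amplitudes stay
proportional to the bound complex.

```{r amplitudes}
p <- reference_params("R453C", "figures")
eigen_phases(p$scheme1, atp = 250)
```

## Fitting transients

`fit_exponentials()` performs unweighted nonlinear least squares (additive
instrument noise is approximately homoscedastic) with deterministic
initialization: fast rate $3/t_{10}$ (time to 10% of the total change),
slow rate a twentieth of that, amplitudes and baseline by linear
projection. Six log-spaced perturbations of the rate guess are tried before
a fit is flagged non-convergent; the flag is always carried in the result,
never silent. Amplitudes are reported in percent of pre-mix fluorescence,
signed (rise positive), extrapolated to time zero, and sorted fast to slow.
Standard errors come from the local quadratic approximation at the optimum.

The choice between one and two phases (`select_phase_count()`) uses the
extra-sum-of-squares F-test at $\alpha = 0.01$, with ties, duplicated
rates, vanished second amplitudes and machine-precision residuals all
resolved toward the single exponential. The original analyses chose the
phase count by eye; the F-test is this package's reproducible replacement.

Near rate degeneracy (ratio below 1.5) a double exponential is not
identifiable: the batch analysis falls back to the dominant
single-exponential rate, and additionally requires each claimed phase to
contribute at least 2% of the *recorded* signal change after dead-time
attenuation — a phase faster than roughly $1/t_\mathrm{dead}$ leaves almost
no trace in the data and would otherwise be reported from noise.

## Secondary analyses

* `fit_hyperbola()` fits $k_\mathrm{max}[S]/(K_{0.5}+[S])$; the initial
  slope is reported as the derived ratio $k_\mathrm{max}/K_{0.5}$ with a
  delta-method standard error, never as a third free parameter. Series
  without curvature (maximum concentration below $0.3\,K_{0.5}$) error out
  rather than extrapolate.
* `fit_linear_low_conc()` estimates the second-order constant from the
  linear regime ($\le 0.2\,K_{0.5}$), through the origin by default.
* `fit_adp_competition()` fits
  $k_\mathrm{obs}(0)/(1+[\mathrm{ADP}]/K_{AD})$ with $k_\mathrm{obs}(0)$
  estimated jointly — fixing it to the single zero-ADP measurement would
  propagate that one error straight into $K_{AD}$.
* `fit_quadratic_titration()` fits the physically significant root of the
  tight-binding quadratic (the root in $[0, \min(A_0, [M])]$), warns when
  the best fit enters the stoichiometric regime ($K_D < A_0/50$, upper
  bound only), and reduces to the hyperbola when $A_0 \ll K_D$.
* `assign_fast_phase()` implements the half-saturation diagnostic: with an
  irreversible second binding step, a fluorescence change on *binding*
  half-saturates at $[\mathrm{ATP}] = k_\mathrm{max}/K_1k_{+2}$ while one
  on *hydrolysis* half-saturates at half that concentration. The function
  reports both predictions, the diagnosis by log-distance to the observed
  $K_{0.5}$, an `indeterminate` verdict when the distances agree within
  10%, and a degeneracy flag when the supplied slope is algebraically the
  ratio of the other two inputs.
* `derive_constants()` and `compare_constructs()` compute the derived rows
  of a summary table ($1/K_1$, detached lifetime $1000/(k_{+3}+k_{-3})$ in
  ms, affinity ratios) and the mutant/wild-type comparison. Significance
  uses Welch's unequal-variance t-test on per-preparation means — the
  replicate scatter of the published values differs visibly between
  constructs, so a pooled-variance test would be wrong.

```{r diagnostic}
assign_fast_phase(k_max = 102, K_half = 93, K1k2 = 1.1)
```

## The synthetic study generator

`generate_experiment()` emulates the five experiment designs of the study
with the published post-mix concentration ranges as defaults: the
tryptophan ATP titration (0.2 uM S1, ATP 10-400 uM, beyond four times the
half-saturating concentration), pyrene dissociation (50 nM actin.S1, ATP
250-4000 uM; below ~200 uM the transient is effectively single-exponential
so the biphasic grid starts above that), ADP competition (20 uM ATP, ADP
0-100 uM), ADP displacement (50 uM ADP pre-incubation, 2 mM ATP), and the
actin titrations (30 nM actin; S1 0-160 nM without and 0-1.6 uM with
100 uM ADP).

The instrument model is deliberately minimal: a 1.5 ms dead time handled by
truncation (no convolution), additive iid Gaussian noise at 0.5% of the
pre-mix fluorescence by default (the true instrument noise is not
published; 0.5% is a calibration default consistent with the smallest
resolved amplitudes), and 600 log-spaced samples per trace spanning the
dead time to 20 time constants of the slowest observable phase. There is no
shot-noise model, no photobleaching, no mixing artifacts and no
inner-filter effect — passing recovery tests therefore demonstrates that
the *analysis chain* is faithful, not that it is robust to every pathology
of real instruments.

`battery()` replicates the whole design grid over synthetic protein
"preparations": each preparation draws a lognormal multiplicative
perturbation of every rate and equilibrium constant, mean-corrected, with
per-parameter coefficients of variation read from the replicate scatter of
the published summary table (4.6% for $k'_{+2}$ up to 60% for $K_{DA}$;
10% where no scatter is published). All randomness descends from one master
seed through the documented splitting rule
`(seed + 1000003 * index) mod (2^31 - 1)`, so identical seeds give
bit-identical studies.

```{r battery, eval = FALSE}
b <- battery(reference_params("WT"), reference_params("R453C"), seed = 42)
b$report
autoplot(b)
```

## Numerical choices

* Hydrolysis-step split: only $k_{+3}+k_{-3}$ is observable; it is split
  with a forward equilibrium constant of 9 (hydrolysis lies well to the
  right). Nothing downstream depends on the split, only on the sum.
* Product release is lumped at 0.05 s$^{-1}$, a typical basal turnover;
  steady-state recycling is irrelevant on the observed seconds window, and
  the release mode carries <0.1% amplitude by construction (the release
  state keeps the post-hydrolysis yield).
* The mutant slow phase is taken as 4 s$^{-1}$; its replicate range
  (0.6-3.8 s$^{-1}$) is recorded with the reference values.
* The mutant tryptophan generator uses the two printed fit constants
  ($k_\mathrm{max} = 88$ s$^{-1}$, slope 1.08 uM$^{-1}$s$^{-1}$, hence
  $1/K_1 = 81.5$ uM); the separately printed half-saturation of 93 uM is
  not consistent with that pair and the fitted pair wins.
* Degenerate eigenvalues (e.g. two conserved pools at zero ATP) are
  separated by a 1e-9 s$^{-1}$ diagonal jitter with a logged warning.
* Nonlinear fits run Levenberg-Marquardt to `ftol = ptol = 1e-14`;
  the secondary fits use the residual-function interface directly so that
  boundary solutions (tight-binding limits) cannot abort on a singular
  model-matrix factorization.
* Problem sizes are chosen so the full test suite runs in well under a
  minute: 8-10 concentrations per titration, 600-700 points per trace,
  three preparations per construct.

## Limitations

The package models unloaded solution kinetics only: no strain-dependent
rates, no phosphate-burst/quench-flow observables (the hydrolysis step is
seen only through the slow tryptophan phase), no temperature or
ionic-strength corrections (all reference constants are 20 °C, 100 mM
KCl), and no global multi-experiment fitting — each experiment is analysed
on its own, as in the original work, so correlated errors between derived
constants are not propagated.
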