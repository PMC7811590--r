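---
title: "Methods: Bayesian uncertainty quantification for 1D pulmonary haemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian uncertainty quantification for 1D pulmonary haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Pulse-wave propagation in the pulmonary arterial tree of a mouse is
modelled by the 1D mass and momentum balance on each straight vessel
segment,

$$
\frac{\partial A}{\partial t} + \frac{\partial q}{\partial x} = 0,
\qquad
\frac{\partial q}{\partial t}
 + \frac{\partial}{\partial x}\!\left(\frac{q^2}{A}\right)
 + \frac{A}{\rho}\frac{\partial \tilde p}{\partial x}
 = -\frac{2\pi\mu r}{\rho\delta}\,\frac{q}{A},
$$

with blood density $\rho = 1.055$ g/ml, viscosity $\mu = 0.049$ g/(cm s),
and a friction term derived from a Stokes boundary layer of thickness
$\delta = \sqrt{\mu T / 2\pi\rho}$, where $T$ is the cardiac period
(0.11 s by default, a resting mouse heart rate). The system is closed by
an algebraic wall law: either the linear elastic relation
$p = \tfrac{4}{3}\chi(\sqrt{A/A_0} - 1)$ or the empirical nonlinear
relation $p = \chi\tan[(\pi/\gamma)(A/A_0 - 1)]$, where
$\chi = Eh/r_0$ (g cm$^{-1}$ s$^{-2}$) is the wall stiffness and
$\gamma$ fixes the maximal lumen area $A_\infty = A_0(1 + \gamma/2)$.
The printed form of the nonlinear law is typographically ambiguous
between $\tan[(\pi/\gamma)u]$ and $\tan[\pi\gamma u]$; we adopt
$(\pi/\gamma)$, the only reading under which the support
$\gamma \in (1, 2\pi)$ yields a finite maximal area larger than $A_0$.
Stiffness may be constant, vessel-specific, or radius-dependent through
$\chi(r_0) = f_1 e^{f_2 r_0} + f_3$, which encodes the stiffening of
small distal arteries.

Junctions impose pressure continuity and flow conservation; each
terminal vessel carries a three-element Windkessel (RCR) model for the
unresolved micro-circulation. Nominal Windkessel parameters are
initialized from Poiseuille resistance: the total distal resistance
$R_{tot} = \mathrm{conv}\cdot\bar p/\bar q$ is distributed over
terminals with conductance weights proportional to $r_0^4$, the
root-to-leaf Poiseuille resistance $8\mu L/\pi r_0^4$ of the resolved
tree is subtracted, a fraction 0.2 is assigned to the proximal resistor
(a conventional approximation of the characteristic impedance), and the
capacitance follows from a peripheral time constant
$R_2 C = 0.025$ s, about a quarter of the cardiac period. Three global
scaling factors $(\psi_1, \psi_2, c)$, shared by all terminals, scale
the nominal values and are estimated from data. The paper's capacitance
unit as printed (ml$^{-1}$ cm$^{-1}$ s$^{-2}$ g$^{-1}$) is dimensionally
inconsistent with an RCR capacitor; this package stores the reciprocal
(ml cm s$^2$ g$^{-1}$), which makes $R_2 C$ a time.

# Numerics

The solver (`simulate_network()`, compiled core) advances $(A, q)$ with
the two-step Richtmyer Lax–Wendroff scheme, second order in space and
time; the momentum flux uses the exact integral
$B(A) = \int (A/\rho)\, d\tilde p$ for both wall laws so no geometric
source terms arise (vessels are untapered). Boundary nodes are closed by
the outgoing characteristics: the Riemann invariants
$W_\pm = u \pm \int_{A_0}^A c(a)/a\, da$ are extrapolated from a
predictor-corrected foot point with a friction correction, and combined
with (i) the prescribed inflow at the root, (ii) six junction equations
(three characteristics, two pressure continuities, flow conservation)
solved by damped Newton iteration with analytic Jacobian (tolerance
1e-10 on nondimensionalized residuals, at most 30 iterations), and
(iii) the Windkessel ODE discretized by the trapezoidal rule at each
outlet. The CFL number is monitored at every step and a violation aborts
the run with a diagnostic rather than producing a silently unstable
solution. Simulations start from rest and run until the pressure field
is cycle-to-cycle periodic within a relative tolerance (default 1e-3,
at most `n_cycles` cycles); the last cycle is returned.

Grid defaults mirror a production run ($\Delta x$ = 0.025 mm,
$\Delta t$ = 1.34e-5 s); the desk-scale studies in the test suite use
$\Delta x$ = 0.08–0.1 cm and $\Delta t$ = 1.2–1.5e-4 s on a 3-vessel
tree, which keeps a forward solve at the millisecond scale so that
full MCMC calibrations remain interactive. Synthetic data are always generated
with the same grid used for inference, so the desk studies isolate the
statistical question (wrong noise model) from discretization error.
The spatial step applies network-wide; each vessel uses
$\lceil L/\Delta x\rceil$ intervals so nodes align with vessel ends.

The observation site within a vessel defaults to its midpoint
(`obs_frac = 0.5`), where a pressure catheter tip would sit.

# Error models and likelihoods

Residuals between measured and modelled pressure are assumed Gaussian.
Two likelihoods are implemented:

* **iid**: $y \sim \mathrm{MVN}(m(\theta), \sigma^2 I)$. Maximizing it
  is equivalent to least squares on the Euclidean distance.
* **GP model mismatch**: $y = m(\theta) + \Gamma(t)$ with
  $\Gamma = f + u$, $f \sim GP(0, K)$, $u \sim \mathrm{MVN}(0,
  \sigma_n^2 I)$, so $y \sim \mathrm{MVN}(m(\theta), K + \sigma_n^2 I)$.
  The mismatch aggregates model discrepancy and noise-model error; the
  two are not separately identifiable from a single retrospective
  dataset and are represented by one GP.

The kernel is the non-stationary arcsine ("neural network") covariance
with augmented input $(1, t)$ and exactly two hyperparameters — bias
variance $b$ and weight variance $w$:

$$
k(t,t') = \frac{2}{\pi}\,
 \mathrm{asin}\frac{2(b + w t t')}
 {\sqrt{(1 + 2(b + w t^2))(1 + 2(b + w t'^2))}} .
$$

Time enters in seconds, unscaled: with $t \in [0, 0.11]$ s the printed
ranges $w \in (1, 9)\times 10^4$ and $b \in (1, 500)$ put the kernel in
its responsive regime. No separate signal-magnitude parameter is used,
matching the two-hyperparameter description; the kernel variance is
bounded by 1 mmHg$^2$, which is ample for residuals at a signal-to-noise
ratio near 100. Multi-vessel data use a block-diagonal covariance with
the same $(w, b, \sigma_n^2)$ in every block: the error parameters are
shared across vessels and no cross-vessel correlation is assumed.

Under a correlated likelihood, WAIC needs a pointwise decomposition; we
use the conditional per-observation log densities from the Cholesky
factor, which sum exactly to the joint log-likelihood. A joint variant
(one block per draw) can be obtained by passing the total log-likelihood
as a single "observation" column.

# Priors and samplers

Biophysical parameters carry rescaled beta(1,1) (i.e. uniform) priors on
physiological boxes (the model catalogue A–I in `model_spec()` records
the boxes), chosen so that the stiffness remains in the
pressure-sensitive regime and the systolic pressure stays near the
physiological window 12–35 mmHg; the acceptance suite checks the window
at representative posterior-median parameters. Noise variances ($\sigma^2$, $\sigma_n^2$) carry the
weakly informative conjugate IG(0.001, 0.001) prior; $(w, b)$ are
log-uniform on their ranges. The residual variance $\sigma_n^2$ of the
mismatch model is sampled with the same IG prior as $\sigma^2$ (its
prior is not otherwise constrained).

Sampling is adaptive random-walk Metropolis on transformed coordinates
(logit for box-bounded parameters, log for variances) with the exact
Jacobian correction, covariance adaptation every 100 iterations toward
an acceptance rate of 0.25, one joint block for $(\theta, \eta)$, and a
conjugate Gibbs refresh of $\sigma^2$ in the iid case. Chains discard
the first half as burn-in. Reference iteration counts mirror a full
study (150 000 direct, 300 000 hierarchical, 5 000 emulated); the
package's desk studies use 2 000–2 500 iterations, which the
convergence diagnostics (Geweke, split-chain MPSRF) flag as adequate for
the low-dimensional, well-initialized desk posteriors.

For vessel-specific stiffness the hierarchical model places
$\chi_j \sim N(m_\chi, \sigma_\chi^2)$ truncated to positive values,
with hyperpriors $m_\chi \sim N(6\times 10^4, (2.4\times 10^4)^2)$ and
$\sigma_\chi^2 \sim IG(2, 2\times 10^8)$, calibrated so the prior
predictive places roughly 90% of its mass on $(2, 10)\times 10^4$. The
truncation is ignored in the conjugate updates of $m_\chi$ and
$\sigma_\chi^2$ (the population mass below zero is about $10^{-6}$ at
these hyperpriors) and enforced in the Metropolis updates of each
$\chi_j$. The alternative construction that integrates the
hyperparameters out in closed form is not implemented. The limiting
cases — $\sigma_\chi^2 \to 0$ (shared stiffness) and
$\sigma_\chi^2 \to \infty$ with a flat mean prior (independent
stiffness) — are exercised by the test suite.

# Synthetic-data generator

`generate_dataset()` emulates the study conditions: error-free pressure
from the forward model at a model-E-style truth (linear wall,
radius-dependent stiffness with $f_1 = 5.11\times10^6$, $f_2 = -171$,
$f_3 = 4.32\times10^4$; scalings $\psi_1 = 0.29$, $\psi_2 = 0.87$,
$c = 1.34$ — representative posterior medians), plus correlated Gaussian
noise from the neural-network kernel ($w = 5.39\times10^4$, $b = 138$)
with a residual-noise variance fixed at 5% of the kernel scale, shared
by all observed vessels. Twenty instantiations are generated by default,
in 1, 3 or 21 vessels.

Design choices the data do not dictate:

* **SNR definition and calibration.** SNR is the per-vessel variance
  ratio var(signal)/var(noise), averaged over observed vessels. The
  kernel shape is fixed and the overall covariance scale is calibrated
  per instantiation (shared across vessels) so the realized ratio equals
  the target (default 100) exactly; the realized scale is stored with
  the truth, so whitening the noise by the generating Cholesky factor is
  exact. Calibrating the expectation instead would leave the mean of
  realized ratios biased upward, because the sample variance of a
  strongly correlated GP draw has few effective degrees of freedom.
* **Monotonicity rejection.** Physiological pressure decreases towards
  the periphery; an instantiation is rejected and redrawn (cap 1000,
  counted) if the cycle-averaged noisy pressure increases along any
  observed parent-to-child edge. Cycle averages, rather than pointwise
  values, make the criterion robust to noise crossings.
* **Inflow.** The measured flow wave is replaced by a parametric
  waveform: a squared-sine systolic ejection (duration 0.045 s, peak
  0.8 ml/s), a small retrograde lobe at valve closure (5% of peak), and
  zero diastolic flow, giving a stroke volume of about 0.018 ml — a
  resting anaesthetized mouse. The spec was calibrated once so that the
  21-vessel tree with representative constant-stiffness parameter
  medians produces a systolic MPA pressure inside 12–35 mmHg, and then
  frozen.
* **Geometry.** The imaged 21-vessel geometry is unpublished;
  `generate_tree()` provides a synthetic stand-in: a binary tree grown
  by splitting the widest leaf, daughter radii scaled by 0.82 per
  generation with a seeded ±6% sibling asymmetry (so the two lungs
  receive unequal flow), lengths 9 radii, root radius 0.047 cm.

What passing the desk tests does **not** show about real data: the
generator shares the solver with the inference (no true model
discrepancy, only noise-model mismatch), uses a smooth parametric
inflow, and omits the measurement chain (catheter dynamics, 5 kHz
sampling, ECG-gated averaging). Conclusions about the bias-correction
mechanism transfer; conclusions about absolute parameter values in mice
do not.

# Emulation

`train_emulator()` fits an anisotropic squared-exponential GP surrogate
of the log-posterior, with hyperparameters (length-scales, signal
variance, nugget) set by marginal-likelihood maximization on a seeded
Latin-hypercube design; non-finite design points are resampled. Two
problems make the naive global surrogate useless here and dictate the
design. First, the raw log-posterior spans hundreds of log-units over
the prior box, far beyond what a stationary GP can interpolate; we
therefore emulate the smooth monotone transform
$z(\theta) = -\log(b_0 + \mathrm{SSR}(\theta)/2)$ — with $\sigma^2$
integrated out analytically under its conjugate prior in the iid case —
and recover the chain target exactly as $(a_0 + n/2)\,z$. Second, the
posterior occupies a tiny, strongly anisotropic fraction of the prior
box (some posterior widths are ~1% of the box), so after a first global
fit the posterior mode is located by direct Nelder–Mead ascent of the
true target, the emulation box is shrunk to the mode ± 6 Laplace widths
(per-coordinate curvature at the mode, clipped to the prior box), and
the final GP is fitted to a fresh space-filling design inside that box.
`emulated_mcmc()` then runs the standard sampler on the emulator mean,
rejecting draws outside the localized box (which carry essentially no
posterior mass); $\sigma^2$ draws are reconstructed from their conjugate
conditional afterwards. The no-bias property (emulated vs direct
marginals) is checked by Kolmogorov–Smirnov distance in the acceptance
suite.

# Model selection and diagnostics

`waic()` implements the standard Watanabe definitions
(log-sum-exp-stabilized lppd, variance-based $p_{waic}$, sample
variance with denominator $S - 1$); lower WAIC is better.
`geweke()` compares the first 10% and last 50% of a chain with spectral
standard errors from Welch periodogram averaging (8 half-overlapping
Hann segments, lowest nonzero frequencies); p-values are reported raw,
with no multiplicity correction across parameters. `mpsrf()` is the
Brooks–Gelman multivariate factor with the 1.1 convergence rule.
`kde_density()` uses the normal-optimal bandwidth
$1.06\,\hat\sigma S^{-1/5}$ (univariate) and diagonal Silverman
bandwidths (multivariate); joint densities of parameters spanning
several orders of magnitude are evaluated after scaling each column to
order one (`scale_to_unit_magnitude()`), mirroring how the study
reports joint posterior densities of the truth.

Interval bands (`predict()` / `interval_bands()`) propagate a posterior
subsample through the forward model: pointwise quantiles of $m(\theta)$
give the credible (explanatory) band, and adding a draw of the
conditioned mismatch GP plus residual noise (or iid noise) gives the
prediction band; solver failures on stored draws are skipped and
counted.

# Problem sizes and known limitations

The test and acceptance suites use a 3-vessel network, 64 observation
points per vessel, 2 000-iteration chains with 10 synthetic replicates,
and a 21-vessel network for the generator-level checks — sizes chosen so
the entire suite runs on a laptop-class single core while preserving
every qualitative conclusion. At these sizes the chains are short:
marginal-density and coverage comparisons are made on the identifiable
parameters ($f_3, \psi_1, \psi_2, c$), while $f_1, f_2$ remain
prior-dominated, as in the full-scale study. Very stiff corners of the
$(f_1, f_2)$ prior box exceed the coarse grid's CFL limit; such
proposals are rejected (zero likelihood), which truncates a few percent
of prior mass in a region the data do not inform. More fundamentally,
because the likelihood pins $\chi(r_0)$ at the observed radii while
$f_1$ is uniform over four decades, the posterior excludes the
(large $f_1$, weak decay) corner outright: the $f_2$ marginal tilts
towards strongly negative values even though $f_1$ and $f_2$ are
individually non-influential, so "flat" holds only approximately for
$f_2$. Exact reproduction of
full-scale WAIC values is additionally convention-dependent (conditional
vs joint pointwise terms and the data length entering them), so the
package asserts WAIC *orderings*, not printed values. Viscoelastic
walls, tapered vessels, junction minor losses, structured-tree outflow
and 3D/FSI coupling are out of scope.
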