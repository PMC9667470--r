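---
title: "Methods: free-energy profiles and release kinetics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy profiles and release kinetics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfrelease)
```

## The problem

Hydrophobic drugs loaded in a polymer matrix (for example docetaxel in
PLGA nanoparticles) leave the particle by diffusing from the matrix
interior, across the polymer–water interface, into the surrounding
solution. In a solubility–diffusion picture, the release rate of a compound
is controlled by its translocation free energy $\Delta G_t^{*}$ — the depth
of the free-energy well at its preferred location (matrix interior or
interface) relative to bulk water:

$$k_t \propto D\, e^{\beta \Delta G_t^{*}}, \qquad \beta = 1/k_B T .$$

With equal diffusion coefficients the prefactor cancels in ratios, so a
compound whose well is $\Delta\Delta G$ deeper releases
$e^{-\beta\,\Delta\Delta G}$ times slower. The empirical time course of
release is summarized by the Ritger–Peppas power law
$M_t/M_\infty = K t^n$, with $n \approx 0.43$–$0.5$ indicating Fickian
diffusion.

This package implements the computational side of that programme at desk
scale: umbrella sampling + WHAM for $G(z)$ and $\Delta G_t^{*}$, MBAR for
solvation/transfer free energies and $\log P_{ow}$, Boltzmann-inversion
fitting of coarse-grained bonded terms, rate ranking and Ritger–Peppas
fitting, and contact-cutoff aggregation analysis. Because microsecond
coarse-grained simulations are far outside a desk budget, a seeded
stochastic engine on analytic potentials generates every input with
*planted* ground truth, so each estimator can be validated end to end.

## The toy sampling engine

`simulate_langevin()` integrates position-only (overdamped) dynamics with
the Euler–Maruyama update

$$z \leftarrow z - \beta D\, U'(z)\,\Delta t + \sqrt{2 D \Delta t}\;\xi,
  \qquad \xi \sim \mathcal N(0,1),$$

whose stationary law is the Boltzmann distribution of $U$. This replaces an
MD engine's inertial stochastic-dynamics integrator deliberately: the
downstream estimators consume *distributions* of a reaction coordinate, not
dynamics, and the overdamped chain reaches them at a fraction of the cost.

Parameters that matter:

* **Temperature** — 310 K by default (the production temperature of the
  release simulations this emulates); 300 K in the alchemical examples.
  $k_B = 0.008314462618$ kJ mol$^{-1}$ K$^{-1}$.
* **Diffusion coefficient** — $D = 0.01$ nm$^2$/ps, a typical small-molecule
  value; under equal-$D$ rate ratios it never enters a result.
* **Timestep** — $\Delta t = 0.001$ ps. Euler–Maruyama has an $O(\Delta t)$
  weak error: in a harmonic trap of stiffness $k$ the sampled variance is
  inflated by roughly $\beta D k \Delta t / 2$. The stiffest trap in the
  default protocol is the 1000 kJ mol$^{-1}$ nm$^{-2}$ umbrella spring, for
  which $\beta D k \Delta t \approx 4\times10^{-3}$; we chose $\Delta t$ so
  that the resulting systematic error in a reconstructed 70–90 kJ/mol
  profile (a few tenths of kJ/mol) stays below its statistical error.
  Halving $\Delta t$ again changed recovered barriers by less than the
  bootstrap error, which is the criterion we applied.
* **Stride and burn-in** — umbrella windows record every 1000th step and
  discard 10 000 steps. The position autocorrelation time in the umbrella
  trap is $\tau = 1/(\beta D k) \approx 0.26$ ps $\approx 260$ steps, so
  recorded samples are $\sim 4\tau$ apart (effectively independent, which
  the i.i.d. bootstrap below assumes) and the burn-in is $\sim 40\tau$.
* **Seeding** — one master seed; every window, lambda state, bootstrap
  replicate and noise stream derives its own seed through the documented
  splitting rule `split_seed(seed, index)`. Identical inputs and seed give
  bit-identical outputs.

A divergence guard aborts a trajectory that leaves a configured domain,
reporting the offending step.

The translocation landscape is modelled analytically
(`make_translocation_potential()`): a flat well of depth $d \le 0$ inside
the matrix, a cubic smoothstep across the interface of half-width $w$, and
a zero plateau in water. The profile and its derivative are continuous and
the derivative vanishes on both plateaus. The true interfacial profile of a
polymer–water system is of course a simulation output, not a smoothstep;
the analytic stand-in is what makes planted-truth recovery tests possible.

Bonded ensembles and alchemical states are drawn by inverse-CDF sampling of
$e^{-\beta V}$ accumulated on a 4096-point grid — exact draw counts,
deterministic under seed, no rejection loop. Release curves add Gaussian
noise to $K t^n$ and clip to $[0,1]$. Particle configurations plant clusters
as straight chains (consecutive spacing below the contact cutoff) with
cluster centres placed so that inter-cluster surface distances exceed the
cutoff; a global offset modulo the box exercises the periodic boundary.

## Umbrella sampling and WHAM

`wham()` combines the binned window histograms through the standard
self-consistency

$$p(z) \propto \frac{\sum_i n_i(z)}
      {\sum_j N_j\, e^{\beta(F_j - w_j(z))}},
\qquad
e^{-\beta F_j} = \sum_z p(z)\, e^{-\beta w_j(z)} ,$$

and returns $G(z) = -k_BT \ln p(z)$ anchored so the reference region
averages zero. Numerically the offsets are found by a damped Newton
minimization of the equivalent convex objective
$\sum_z c_z \ln \sum_j N_j e^{f_j} B_{zj} - \sum_j N_j f_j$ (typically 3–6
iterations), but convergence is *certified* by a plain self-consistent
sweep: the solver only returns when one more fixed-point iteration moves no
offset by more than `tol` (default $10^{-8}$ kJ/mol). Non-convergence
raises a condition carrying the full residual history; a window graph with
disconnected components (no shared populated bins) is an error rather than
a silently tilted profile.

Numerical choices:

* **Bin width** 0.05 nm by default; for the stiff production spring the
  window width is $\sqrt{k_BT/k} \approx 0.05$ nm, and analyses at that
  protocol use 0.025 nm (half the window width), beyond which the recovered
  barriers no longer change. Empty bins are kept as `NA`, never
  interpolated. Bin centres are anchored at integer multiples of the bin
  width: a grid anchored at the sample minimum makes the binning phase — and
  hence the profile's discretization error — a random function of the seed,
  which a fixed-grid bootstrap cannot see.
* **Reference region** — the caller's explicit choice, or by default the
  outermost 10 % of the sampled range on the solvent (high-$z$) side.
* **Barrier extraction** — $\Delta G_t^{*}$ is the minimum of $G$ over
  *well-sampled* bins minus the reference mean. Well-sampled means at least
  `min_counts` (default 10) samples and inside the restrained range
  spanned by the window centres: outside the outermost restraints the
  profile is a reweighted single-window tail whose noise is strongly
  skewed downward by the $-\ln$ transform, and a raw minimum search there
  returns artifact minima. The minimum may legitimately sit in the matrix
  interior or at the interface; both occur.
* **Errors** — i.i.d. bootstrap over samples within each window
  (`bootstrap_pmf_error()`), re-running WHAM on the original grid per
  replicate; the barrier error is the spread of the same min-minus-reference
  statistic across replicates. This is honest only because samples are
  decorrelated by the stride above; with correlated input it would
  underestimate.
* **Overlap diagnostics** — `check_overlap()` reports the
  histogram-intersection fraction of adjacent windows and flags pairs below
  0.03.

Calibration under the default protocol (60 windows, 20 000 samples/window),
repeated over independent master seeds, gives barrier deviations whose
spread matches the reported bootstrap error and whose residual bias
(integrator discretization plus minimum-selection) is a fraction of that
error; the acceptance checks require agreement within two bootstrap
standard errors.

## Alchemical free energies: MBAR with soft-core scaling

`mbar_solve()` estimates the reduced free energies $f_k$ of $K$ states from
pooled samples via the multistate Bennett acceptance ratio,

$$f_i = -\ln \sum_{n}
  \frac{e^{-u_{in}}}{\sum_k N_k\, e^{f_k - u_{kn}}},$$

solved by BFGS on the convex MBAR objective followed by self-consistent
polish to `tol` $=10^{-10}$, all in log-sum-exp arithmetic. Uncertainties
come from the estimator's asymptotic covariance, computed from the weight
matrix by SVD; a stderr-calibration test checks the reported error against
the empirical spread over 50 replicates. States with no configuration-space
overlap are diagnosed by the overlap matrix and named in the error.

Interaction scaling uses the Beutler soft-core form with $\alpha = 0.5$ and
$\lambda$-power 1 (the conventional choices; the protocol this emulates
names soft-core but not its constants):

$$V(r;\lambda) = 4\epsilon \lambda \left[
 \frac{\sigma^{12}}{(\alpha\sigma^6(1-\lambda)+r^6)^2}
 - \frac{\sigma^6}{\alpha\sigma^6(1-\lambda)+r^6}\right],$$

exactly Lennard-Jones at $\lambda = 1$, zero at $\lambda = 0$, finite at
$r = 0$ for $\lambda < 1$. The `coulomb_then_lj` schedule mode (20 states,
for charged solutes at atomistic resolution) is bookkeeping over two
stacked sub-schedules; the toy engine computes no electrostatics.

Transfer free energies compose as
$\Delta G_{A\to B} = \Delta G_{solv,B} - \Delta G_{solv,A}$ with errors in
quadrature, and
$\log P_{ow} = \Delta G_{O\to W} / (\ln 10\, k_B T)$ — positive when moving
the solute into water costs free energy, i.e. for hydrophobic compounds.

## Coarse-grained bonded terms

`map_trajectory()` collapses atom groups to mass-weighted centres
(the centre-of-mass mapping used to project atomistic trajectories onto
bead resolution). `extract_distributions()` computes per-frame distances,
angles (arccos of the normalized dot product) and signed dihedrals (atan2
convention), with degenerate frames excluded and counted, Freedman–Diaconis
histograms, and circular statistics for dihedrals so that distributions
peaked at $\pm180^\circ$ fit without wrap artifacts.

`fit_bonded()` performs Boltzmann inversion: the equilibrium value is the
distribution mean (circular mean for dihedrals) and the force constant
follows from the variance, $k = k_BT/\mathrm{var}(x)$ for harmonic terms
(variance in radians for angle-type terms) and
$k = k_BT/\mathrm{var}(\cos\theta)$ for the harmonic-cosine form. Two
caveats are worth knowing. First, moment inversion is exact only in the
narrow-distribution (Gaussian) limit; for a harmonic-cosine angle term
wider than $\sigma_{\cos\theta} \gtrsim 0.2$ the flat-measure asymmetry of
$\theta \mapsto \cos\theta$ biases both the mean and the inverted constant
by several percent — which is precisely why the parametrization stage ends
with iterative refinement rather than a single inversion. Second, a
zero-variance distribution has no finite force constant; the fit refuses
and advises a constraint.

`refine_iteratively()` systematizes the trial-and-error stage: per
iteration each term is re-sampled from its current parameters, the force
constant rescaled by $(\text{width}_{cur}/\text{width}_{target})^2$, the
equilibrium shifted by the mean mismatch, until the Jensen–Shannon
divergence between current and target histograms (the package's mismatch
metric; none is prescribed by the source procedure) falls below `tol`. If
the mismatch rises twice consecutively the update is damped by half and the
event recorded. Multimodal dihedral targets (stereo-regularity effects) are
fit per mode after user-supplied mode splitting; automatic mode detection
is out of scope.

## Release kinetics

`relative_rate()` exposes only rate *ratios*, where the diffusion prefactor
cancels under the equal-$D$ assumption; `absolute_rate()` exists but labels
its prefactor arbitrary. `rank_compounds()` orders barriers descending
(least negative = fastest), reporting ties. `fit_peppas()` fits
$K t^n$ by nonlinear least squares restricted to $M_t/M_\infty \le 0.6$ —
the standard validity domain of the power law; the source analysis does not
state its fitting range, so the conventional one is used — initialized from
a log–log regression and inverse-variance weighted when per-point errors
are present.

## Aggregation

`find_clusters()` builds single-linkage connected components of the contact
graph at a 0.6 nm minimum-image cutoff in an orthorhombic periodic box
(cutoffs at or beyond half the smallest edge are rejected as ambiguous).
Because it is unstated whether a plotted "average cluster size" counts
monomers, `cluster_trace()` reports both conventions per frame: the number
average $N/\#\text{clusters}$ and the mass average $\sum s_i^2/\sum s_i$.

## What the synthetic data do and do not show

The generators emulate: biased sampling of a compound's centre-of-mass
coordinate across a matrix–water interface with a planted well depth;
$\lambda$-scaled sampling of analytically solvable potentials; Boltzmann
ensembles of bonded terms; power-law release with additive noise; and
planted-cluster configurations in a 15 nm periodic box with 27 molecules at
$\sim$5 nm separation (the dispersed start of the aggregation analysis).
They do **not** emulate: bead-resolved polymer/solvent structure, slow
matrix relaxation, interface fluctuations, correlated pulling histories,
electrostatics, or polymer degradation. Passing recovery tests therefore
demonstrates that the *estimators* are correct and honestly error-barred,
not that a smoothstep well is a faithful PLGA–water landscape. Real
headline values (microsecond MARTINI barriers, experimental log P) are out
of reach at desk scale by construction.

## Problem sizes and determinism

The test suite and the acceptance script run the full 60-window protocol
with $2\times10^4$–$5\times10^4$ samples per window for the free-energy
stages, $10^5$ samples for bonded fitting, 100 replicates for release-curve
recovery, and 200 random configurations for the clustering oracle — sizes
at which each estimator's statistical error is several times smaller than
the acceptance tolerance it is checked against. Every random quantity in
the package descends from an explicit seed, and the demo pipeline
(`run_demo()`) writes every intermediate artifact so that each number in
its report is traceable to a stage output file.

## Known limitations

* One-dimensional reaction coordinates only; no 2-D umbrella grids and no
  MBAR-based profile estimation.
* The i.i.d. bootstrap relies on the stride-decorrelated sampling above; it
  is not a block bootstrap and will understate errors on correlated input.
* Histogram WHAM evaluates the bias at bin centres; with the default bin
  width and spring this contributes less than the statistical error, but
  very stiff springs with coarse bins would need finer binning.
* Boltzmann inversion's narrow-distribution bias, discussed above.
* Orthorhombic boxes only for minimum-image distances.
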