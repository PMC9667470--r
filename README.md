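# pmfrelease

Predicting how fast a hydrophobic drug leaves a polymer matrix, from
free-energy profiles to release curves — at desk scale.

## The problem

Hydrophobic drugs (docetaxel and its oleate/PEG prodrugs are the motivating
examples) are loaded into polymer nanoparticles such as PLGA and escape by
diffusing from the matrix, across the polymer–water interface, into
solution. In the solubility–diffusion picture the release rate of a
compound is governed by its **translocation free energy**
ΔG<sub>t</sub><sup>\*</sup> — the depth of the free-energy well at its
preferred location (matrix interior or interface) relative to bulk water:

    k_t ∝ D · exp(β ΔG_t*),    β = 1/(k_B T)

so for two compounds with equal diffusion coefficients

    k_a / k_b = exp(β (ΔG_a − ΔG_b)),

and a compound with a 21 kJ/mol deeper well (at 310 K) releases about 3300×
slower. The observed release time course is summarized by the
Ritger–Peppas power law M<sub>t</sub>/M<sub>∞</sub> = K·tⁿ.

`pmfrelease` implements the full computational chain that turns simulation
data into those predictions:

* **`toy_sim`** — a seeded overdamped Langevin engine (Euler–Maruyama, in
  C++) on analytic potentials, plus generators for umbrella windows,
  λ-state samples, bonded Boltzmann ensembles, noisy release curves and
  planted-cluster configurations. Every generator returns its ground truth,
  so every estimator below is testable end to end without an MD package.
* **`umbrella_wham`** — WHAM reconstruction of G(z) from umbrella windows
  (60 windows × 0.2 nm × 1000 kJ mol⁻¹ nm⁻² spring by default), bootstrap
  error bars, window-overlap diagnostics, and extraction of
  ΔG<sub>t</sub><sup>\*</sup>.
* **`alchemical_mbar`** — MBAR over a λ schedule with Beutler soft-core
  Lennard-Jones scaling; solvation and transfer free energies and
  log P<sub>ow</sub> = ΔG<sub>O→W</sub>/(ln 10 · k_B T).
* **`cg_fit`** — center-of-mass bead mapping, bond/angle/dihedral
  distributions, Boltzmann-inversion parameter fits and iterative
  width-matching refinement.
* **`release_kinetics`** — rate ratios, compound ranking, Ritger–Peppas
  fitting (restricted to M/M∞ ≤ 0.6).
* **`aggregation`** — contact-cutoff (0.6 nm) single-linkage clustering
  under periodic boundaries, number- and mass-averaged cluster sizes.
* **`run_demo()`** — the whole pipeline on synthetic data, from planted
  well depths to recovered barriers, ranking, rate ratios and fitted
  release curves, with every artifact written to disk.

## Worked example

Reconstruct a translocation profile with a planted −69.8 kJ/mol well and
rank the four study compounds:

```r
library(pmfrelease)

pot <- make_translocation_potential(well_depth = -69.8, well_center = 1.77,
                                    interface_center = 5.31, interface_width = 1.53)
centers <- seq(0, by = 0.2, length.out = 60)          # the umbrella protocol
ws  <- generate_umbrella_dataset(pot, centers, spring = 1000,
                                 config = langevin_config(seed = 5),
                                 n_samples = 20000)
pmf <- bootstrap_pmf_error(ws, n_boot = 16, seed = 2)
extract_barrier(pmf)
#> <translocation_barrier> dG = -70.11 kJ/mol +/- 0.77 at z = 0.3 nm

barriers <- c("DTXL" = -69.8, "OA-DTXL" = -75.3,
              "PEG10-DTXL" = -76.9, "PEG25-DTXL" = -90.7)
rank_compounds(barriers)
#> [1] "DTXL" "OA-DTXL" "PEG10-DTXL" "PEG25-DTXL"
relative_rate(-69.8, -90.7, temperature = 310)
#> [1] 3323.204
barrier_relative_difference(-75.3, -76.9)
#> [1] 2.080624
```

The recovered barrier agrees with the planted depth within its bootstrap
error; the ranking says free docetaxel releases fastest and the long-PEG
prodrug slowest, with the oleate and short-PEG prodrugs separated by only
~2 % in barrier height. Fitting a noisy synthetic release curve recovers
its generating kinetics:

```r
curve <- generate_release_curve(K = 0.3, n = 0.45,
                                times = seq(0.2, 4.5, length.out = 20),
                                noise_sigma = 0.02, seed = 1)
fit_peppas(curve)
#> <peppas_fit> K = 0.3018 h^-n, n = 0.4533 (19 points, fraction <= 0.6)
```

The end-to-end demo (`run_demo(pipeline_config(seed = 1))`, or
`inst/scripts/pmfrelease demo --seed 1 --out DIR` from a shell) does all of
the above for the four compounds and writes window tables, PMF tables,
release curves, a cluster trace and a JSON report.

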