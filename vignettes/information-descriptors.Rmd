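---
title: "Information-theoretic descriptors for water force-field evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic descriptors for water force-field evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Rigid three-site water models -- TIP3P, SPC and SPC/ε (written `SPCE`
throughout this package) -- differ in small geometric and electrostatic
parameters that propagate to large differences in bulk behaviour.
Information theory offers a compact way to compare the electronic structure
the models imply: treat the electron density as a unit-normalized
probability density ρ(r) and summarize it with five functionals,

* Shannon entropy `S = -∫ ρ ln ρ` (global delocalization, nats),
* Fisher information `I = ∫ |∇ρ|²/ρ` (local sharpness, a.u.),
* disequilibrium `D = ∫ ρ²` (distance from uniformity, a.u.),
* LMC complexity `C_LMC = D·e^S` (≥ 1 for any 3D density),
* Fisher–Shannon complexity `C_FS = I·J`, `J = e^(2S/3)/(2πe)` (≥ 3,
  with equality exactly for isotropic Gaussians),

evaluated in position space and, via a momentum-space conjugate, in
momentum space. This package implements that pipeline end to end on
*synthetic* densities, so every stage is testable on a desktop without
molecular dynamics or DFT.

## The surrogate density model

Real electron densities are replaced by isotropic Gaussian mixtures: one
component per atom, placed at the rigid force-field geometry. Two weighting
modes are provided:

* `electron_count` — weights (8, 1, 1)/10 for O, H, H. Models sharing a
  geometry (SPC and SPCE) then produce *identical* densities, which turns
  any downstream statistical separation of that pair into a detectable
  false positive; this is used as a built-in null experiment.
* `charge_perturbed` — weights proportional to the effective populations
  `Z − q` per site. This is the only mechanism by which SPC and SPCE
  densities differ; it is a sensitivity-analysis surrogate, not a claim
  about real charge transfer.

Component widths default to 0.45 bohr (O) and 0.65 bohr (H). The values
are arbitrary but fixed: every comparison made by the package is relative
(model versus model, size versus size), so only the *differences* between
configurations matter, and those are carried by geometry and weights.
Lengths are ångström at the interface and bohr internally; momenta are
bohr⁻¹; entropies are nats.

The momentum-space density of a mixture follows from the Fourier transform
of a displaced isotropic s-type Gaussian primitive, whose modulus is
displacement-independent: each position component of width σ maps to an
origin-centred momentum component of width 1/(2σ) with its weight
preserved. Components of equal width are merged exactly. Two consequences
are worth stating plainly:

* the conjugate-entropy identity `S_r + S_p = 3(1 + ln π)` holds for every
  single-Gaussian surrogate and is used as a standing numerical check;
* the momentum leg of a *jittered ensemble* is frame-invariant, because
  jitter moves only centers. Momentum-space samples therefore have zero
  variance and the statistics layer reports them as degenerate (`NA`)
  rather than pretending to test them. Momentum-space variability in real
  data comes from orbital structure that s-type surrogates cannot carry;
  all discriminating statistics in this package live in position space.

## Synthetic ensembles

`make_cluster_configuration()` places rigid waters by sequential
attachment: each new molecule sits at a nearest O–O distance drawn
uniformly from 2.6–3.2 Å (the first coordination shell of liquid water)
from a random placed molecule, with a random rigid-body orientation,
rejecting candidates that approach any oxygen closer than the range
minimum; 1000 attempts per molecule, then a loud failure.
`make_descriptor_samples()` perturbs every atomic center with isotropic
Gaussian jitter of 0.01 Å per frame — emulating the small constraint and
round-off variability of rigid-model trajectories — and computes the full
descriptor set per frame. Default ensembles use 30 frames, a typical
per-cell sample size for small-sample normality testing. Everything is
driven by explicit integer seeds and is bit-reproducible; generators
save and restore the caller's RNG state.

What the generator does *not* emulate: hydrogen-bond directionality,
thermal Boltzmann weighting, intermolecular charge rearrangement, periodic
bulk surroundings. Passing tests therefore demonstrate the correctness of
the descriptor/statistics machinery and the geometric separability of the
models, not force-field quality against real water.

## Quadrature

Descriptor integrals are tensor-product trapezoid sums over an axis-aligned
box covering all component centers ± kσ, with k set so the omitted
per-component tail mass is below 1e−8 (k ≈ 5.7). For smooth, fast-decaying
Gaussian mixtures the trapezoid rule converges super-algebraically, so
refinement doubles the points per axis (base 32, up to 3 doublings) until
the relative change of all integrals (mass, S, I, D) falls below the
tolerance of 1e−6; the last change is reported as `quad_error`.
Non-convergence raises a condition carrying the last two estimates rather
than returning silently. `ρ ln ρ` is evaluated as 0 where ρ underflows
(limit convention, floor 1e−300), and the Fisher integrand is guarded by
the same floor. The hot loop is compiled (Rcpp) and skips components whose
separable x–y factor product is already negligible, which keeps
11-molecule clusters (33 components) tractable at 128³ nodes.

Complexities are always computed from the already-integrated S, I, D
rather than re-integrated, so a bound violation (C_LMC < 1, C_FS < 3)
flags a quadrature problem, not a formula bug. Bound checks allow an
undershoot of 10× the quadrature tolerance: densities that *attain* a
bound (any single Gaussian attains C_FS = 3) land on it with a small
systematic error dominated by the truncated tail, which the
refinement-based error estimate does not see.

Grid (CUBE-backed) densities integrate by Riemann sums on their stored
voxels with second-order central differences for gradients (one-sided at
boundaries); they have no refinement and no momentum conjugate, so their
descriptor sets carry `NA` momentum legs and error estimates.

## Cluster identification

The Sevick criterion partitions molecules into clusters by transitive O–O
linkage below a cutoff. The cutoff is not fixed by the protocol this
package follows, so it is an explicit, always-visible parameter with
default 3.5 Å — the conventional first minimum of the O–O radial
distribution function, consistent with a first-shell coordination of
about 4.7. Minimum-image distances are used on orthorhombic boxes only;
non-periodic frames use raw distances. Connected components are delegated
to igraph; the test suite checks the partition against a brute-force
O(n²) breadth-first oracle and verifies cutoff monotonicity (shrinking the
cutoff only refines the partition).

## Statistics

The protocol is: Shapiro–Wilk + Filliben probability-plot screening, then
Welch's t-test per model pair.

* Shapiro–Wilk uses Royston's approximation for the weights and p-values
  (the standard computational route for 3 ≤ n ≤ 5000); for n = 3 the
  exact weight √½ coincides with it. The implementation is written out in
  full and cross-checked against `stats::shapiro.test` in the tests.
* Filliben probabilities use the ascending convention
  `p₁ = 1 − 0.5^(1/n)`, `pᵢ = (i − 0.3175)/(n + 0.365)`,
  `pₙ = 0.5^(1/n)`: ordered statistics must map to increasing
  probabilities for the plot's R² regression to be meaningful.
* The normality verdict is the conjunction p > 0.05 AND R² > 0.9.
* Welch's t and the Welch–Satterthwaite degrees of freedom are computed
  from their defining formulas with two-sided p-values (only thresholds,
  not sidedness, are prescribed by the protocol); `stats::t.test` is the
  independent oracle in the tests. No multiple-testing correction is
  applied by default (per-pair 0.05 thresholds); a Holm option exists on
  the Welch matrix.
* Box-plot summaries use type-7 quartiles (linear interpolation between
  closest ranks) and the 1.5·IQR outlier rule.

## Pipeline and problem sizes

`run_pipeline()` chains generation → descriptors → normality → Welch →
scaling and writes per-combination CSVs named
`{size}M_{position|momentum}_{model}.csv` (comma-separated, header row,
full double precision, values in a.u.), plus the normality screen, Welch
matrix and scaling series. Sub-seeds per (model, size) are derived from
the master seed with fixed prime strides, keeping runs bit-reproducible
and sub-2³¹. The scaling report returns mean-versus-size series, per-size
normalized model shares (stacked-bar data summing to 1), and strict
monotonicity flags; missing cells stay as explicit `NA` gaps.

Default study conditions are cluster sizes 1, 3, 5, 7, 9, 11 with
30-frame ensembles. The bundled analysis scripts use 30 frames for the
single-molecule discrimination study and 6 frames for the six-size scaling
study, where only means enter; the property sweeps use 100 random
mixtures of 1–12 components. These sizes were chosen as the smallest that
make the statistical conclusions stable across seeds.

## Known limitations

* Absolute descriptor scales depend on the arbitrary atomic widths; only
  relative comparisons are meaningful, and no attempt is made to match
  absolute magnitudes of DFT-based densities.
* The momentum leg is structureless by construction (see above).
* Gaussian-mixture densities cannot develop the cusps or anisotropy of
  real electron densities; Fisher information in particular is far milder
  here than for densities with nuclear cusps.
* Periodic handling is orthorhombic-only, and CUBE support is limited to
  axis-aligned grids.
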