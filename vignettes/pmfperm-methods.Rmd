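---
title: "Methods: umbrella-sampling free energies, diffusion and membrane permeability"
author: "pmfperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: umbrella-sampling free energies, diffusion and membrane permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Membrane pan-assay interference compounds (membrane PAINS) are promiscuous
molecules that act by perturbing the physical properties of lipid bilayers
rather than by binding a specific target. A sensitive way to quantify that
perturbation in silico is to drag a small hydrophobic probe across the
bilayer with umbrella sampling (US) and compare, between compound-bearing
and compound-free membranes, the potential of mean force (PMF) G(z), the
position-dependent diffusion coefficient D(z), and the membrane permeability
coefficient P that combines both. `pmfperm` implements the analysis side of
that protocol: window-scheme planning with overlap diagnostics, WHAM
estimation of G(z), D(z) from per-window position autocorrelation, ISDM
permeability and entry/exit barriers, a monolayer-referenced reaction
coordinate with local membrane thickness, and jackknife replicate errors.
It does not run molecular dynamics; it consumes per-window reaction
coordinate time series (pull-output xvg dialect) or generates synthetic ones
from known landscapes.

## Reaction coordinates and the monolayer reference

The probe coordinate z runs along the membrane normal. Two frames are
supported:

* **bilayer_center** — z = 0 at the mean plane of all phosphate (P) atoms;
  bulk water sits at large positive z (the dense default scheme spans
  0.0–3.6 nm in 0.1 nm steps, 37 windows).
* **closest_p_layer** — z = 0 at the mean plane of the *nearest* leaflet's
  P atoms, negative toward the bilayer center (z = −2.0 nm is deep
  insertion), positive toward water.

The monolayer reference exists because PMFs in the bilayer-center frame are
sensitive to membrane-thickness fluctuations: in different replicates the
probe crosses head-group regions of different compactness, and referencing
to the near P layer absorbs most of that variability.
`monolayer_coordinate()` picks the leaflet minimising
|z_probe − mean z_leaflet| (ties toward the upper leaflet; a probe exactly
at the bilayer center therefore reports minus the half thickness).  When
trajectory frames are available the transform is applied per frame, not via
window-average offsets — the reference fluctuates with the membrane, which
is the point of using it.  Applying a single per-window offset would be
cheaper but re-introduces part of the thickness noise.

Local thickness (`local_thickness()`) follows the two-radius scheme:
P atoms within 1.0 nm of the probe in the xy plane (minimum image) define
the local monolayer plane, P atoms beyond 1.5 nm — those unperturbed by the
probe — define the membrane center; the half thickness is the absolute
difference of the two mean z values. Both cutoffs are configurable
(`thickness_config()`), with the constraint local < exclusion.

## Window schemes

`build_scheme()` expands ordered, non-overlapping regions
(z_min, z_max, spacing, K_f) into windows including both region endpoints;
a window within 1e-6 nm of an existing one is merged keeping the stiffer
K_f, so touching regions share their boundary window. Two presets ship:

* `dense_37_scheme()` — 37 windows, 0.0–3.6 nm, 0.1 nm spacing,
  K_f = 1000 kJ/mol/nm².
* `reduced_22_scheme()` — 22 monolayer-referenced windows. The published
  window table for the reduced protocol is not available, so this is a
  documented reconstruction from its stated rules: 0.1 nm spacing with
  K_f = 2000 kJ/mol/nm² in the hard-to-sample phosphate region
  (−0.4…0.4 nm), wider spacing and K_f ≤ 1000 elsewhere. We chose
  −2.0…−0.6 nm at 0.2 nm (K_f 500) and 0.6…1.6 nm at 0.25 nm (K_f 1000).
  Whether and how far the water side should extend beyond +0.4 nm is a user
  choice; edit the last region of `scheme_22um.yaml` to change it.

Sampling quality is diagnosed by the histogram intersection
Σ_b min(p_i(b), p_j(b)) of unit-normalised window histograms on a shared
200-bin grid (`overlap_matrix()`, `check_coverage()`). We prefer the
intersection over e.g. the Bhattacharyya coefficient because it reads
directly as shared probability mass and stays well-behaved on small
samples. For two unit-variance Gaussians two sigma apart it converges to
2Φ(−1) ≈ 0.317.

## WHAM

`solve_wham()` iterates the standard self-consistent equations for harmonic
biases U_i(z) = ½K_i(z − z_i)²:

$$p(b) = \frac{\sum_i n_i(b)}{\sum_i N_i\, e^{\beta(F_i - U_i(z_b))}},
\qquad e^{-\beta F_i} = \sum_b p(b)\, e^{-\beta U_i(z_b)}\,\Delta z$$

until max_i |ΔF_i| < tolerance. Defaults: 200 bins, tolerance 1e-6 kJ/mol,
max_iter 1e5, F_i initialised to 0 — ordinary WHAM practice, and cheap at
this data scale. G(z) = −kT ln p(z) is anchored so its mean over the bulk
water region (by default the outermost 0.3 nm at the high-z end) is zero.
Inefficiency factors are fixed at 1 (no autocorrelation weighting), and
zero-count bins are masked rather than interpolated; the ISDM stage refuses
masked interior bins instead of silently bridging them. The equilibration
discard (300 ns by default in file-based runs, matching the long
equilibrations such membranes need) is applied before histogramming and is
configurable. Far-from-window bias factors underflow to zero harmlessly;
every counted bin keeps a positive denominator because the window that
sampled it contributes.

## Diffusion from position autocorrelation

For each window, `window_diffusion()` computes the autocovariance
C(t) = ⟨δz(0) δz(t)⟩ of the mean-free coordinate (FFT-based, O(n log n)),
the correlation time τ = ∫₀^∞ C(t)/C(0) dt, and D = var(z)/τ, attributed to
the window's mean position. The integral is evaluated by the trapezoidal
rule and truncated at the first non-positive C(t) — robust and
assumption-light; for a well-sampled harmonic window the tail beyond the
first noise-induced zero crossing carries negligible area. An exponential
fit to the positive head of C(t)/C(0) is available as `method = "expfit"`
for users who prefer a parametric estimate. If C(t) never crosses zero
within the allowed lag range the estimator refuses (`non-converged ACF`)
rather than extrapolating. The sampling interval is taken from the stored
time step, so positions must be saved densely relative to τ (the synthetic
generator writes every 1 ps by default; for a K_f = 2000 window at
D ≈ 0.5 nm²/ns, τ ≈ 2.5 ps).

For an overdamped harmonic window these identities hold and are tested:
var(z) = kT/K_f, τ = var(z)/D, so var(z)·K_f/kT → 1 with sampling — a
useful consistency check tying the thermostat temperature to the dynamics.

Across replicates D is averaged window by window, not pooled at the ACF
level: replicate membranes genuinely differ locally, and pooling ACFs from
different local environments would mix time scales. The stored profile
keeps the replicate-mean variance and reports the effective correlation
time variance/D, so D = variance/corr_time holds exactly at every point
(and reduces to the per-window τ for a single replicate).

## ISDM permeability and barriers

The resistance profile is R(z) = exp(βΔG(z))/D(z) with ΔG relative to the
bulk-water anchor and D interpolated linearly onto the PMF grid (clamped at
the profile ends). The permeability is P = 1/∫R(z)dz by trapezoidal
quadrature. The unit chain is fixed and tested: G in kJ/mol, D in nm²/ns
(×1e-5 → cm²/s), dz in nm (×1e-7 → cm), giving P in cm/s; closed forms
P = D/L (flat) and P = D/(w·e^{βB} + L − w) (square barrier) are matched to
better than 0.1%.

A monolayer-referenced PMF covers one leaflet only, while ISDM permeability
is a trans-bilayer quantity. `mirror_monolayer_profile()` therefore
reflects the profile about its membrane-center end (the low-z grid edge),
dropping the duplicated center point — a documented symmetric-bilayer
assumption. Integration then runs from one bulk-water edge through the
mirrored bilayer to the other.

Barriers follow the two-level definition: ΔG_entry is the interface maximum
relative to bulk water (= its anchored value), ΔG_exit is that same peak
minus the global minimum in the membrane interior. The interface peak is
the highest local maximum on the water side of the global minimum with
prominence above 0.1 kT (ties broken toward the water side); on a profile
that only decays from the bulk plateau into the membrane, the plateau is
the maximum, giving entry 0 and exit equal to the full range. Profiles
whose total relief is below 0.1 kT are rejected as flat rather than
yielding meaningless barriers. Energies are held in kJ/mol internally and
converted to kcal/mol only at reporting, the unit in which barriers and
permeabilities are conventionally tabulated.

`analyze_system()` chains the stages on pooled replicates and obtains
standard errors by leave-one-out jackknife: the estimator re-runs
WHAM → ISDM on every (n−1)-replicate pool (per-window D values are computed
once and subset-averaged), then SE = sqrt((n−1)/n · Σ(θ_i − θ̄)²). Re-running
on pools rather than combining per-replicate results avoids single-replicate
convergence artifacts; for linear statistics the formula reduces exactly to
the classical standard error. One mechanism serves permeability and both
barriers. With a single replicate the errors are reported as unavailable
rather than zero.

## The synthetic-data generator

Because the absolute permeabilities of an atomistic membrane require tens
of microseconds of MD, correctness here is established on synthetic data
with known ground truth. `simulate_window()` integrates overdamped Langevin
dynamics with Euler–Maruyama:

$$z \leftarrow z + \beta D(z) F(z)\,dt + D'(z)\,dt + \sqrt{2 D(z)\,dt}\;\eta$$

with F = −dG/dz − K_f(z − z_i) and η ~ N(0,1). The D′(z) spurious-drift
term is required for the stationary density to remain ∝ exp(−βG) when D
varies with position; the package demonstrates both that the density is
Boltzmann (χ² not rejected at α = 0.01 on a landscape with five-fold D
variation) and that omitting the term visibly skews the density toward low
D. We use Euler–Maruyama with the explicit drift term rather than a
higher-order scheme because it is simple, adequate at the step sizes used,
and the stationary-density invariant catches errors. A stability heuristic
(β·D·|F|·dt < 0.1·√(2·D·dt) at the start point) rejects too-large steps,
and a walk leaving the landscape range by more than 1 nm aborts with a
suggestion to reduce dt.

Landscapes are natural cubic splines through control points (D on the log
scale, guaranteeing positivity); `membrane_like_landscape()` ships a
monolayer-referenced preset with bulk water at zero, an interface barrier
of ~3 kcal/mol at the phosphate plane, a central well of ~−4 kcal/mol, and
D dropping five-fold from 0.5 nm²/ns in water to 0.1 nm²/ns inside —
magnitudes typical of a benzene-sized hydrophobic probe in a POPC bilayer.
The preset is built symmetric about the membrane center so the generated
data obey the symmetry the mirroring step assumes.

Per-window seeds derive from a documented hash of (master seed, replicate,
window) (`derive_window_seed()`), so any subset of a study is reproducible
from one integer.

`make_membrane_frames()` builds planar synthetic bilayers (shared jittered
xy grid per leaflet pair, Gaussian z-noise, optional Gaussian
depression/protrusion under the probe) for the thickness and
leaflet-assignment fixtures.

**What the generator does and does not emulate.** It reproduces the
statistical structure the estimators rely on: Boltzmann-distributed biased
sampling on a known G(z), OU-like relaxation with known D(z), replicate
scatter, membrane-like barrier/well magnitudes, and locally deformed
phosphate sheets. It does not contain lipids: no slow collective
thickness/undulation modes, no head-group packing heterogeneity between
replicates, no memory effects in the probe friction, and its time series
are exactly Markovian. Passing tests therefore validate the estimators and
their unit chains, not the convergence of any particular MD protocol;
equilibration and replicate-count choices for real membranes must still be
judged from the data (the overlap and replicate-envelope diagnostics exist
for that).

## Numerical choices and degenerate inputs

* Gas constant fixed at R = 0.0083144621 kJ/mol/K; 1 kcal = 4.184 kJ.
* Histogram grids: 200 bins by default for both WHAM and overlap
  diagnostics; the WHAM grid defaults to the span of the window centers.
* Periodic boundaries: minimum image in x/y only; z is treated as
  unwrapped, because membrane-normal analyses break under z-wrapping.
* Ties: leaflet choice toward the upper leaflet; interface-peak ties toward
  the water side; P atoms exactly on the mean plane go to the upper
  leaflet.
* Degenerate inputs error early and name the offender: empty windows after
  the equilibration discard, all P atoms on one side, masked interior PMF
  bins, non-decaying ACFs, zero-variance series, fewer than two replicates
  for the jackknife.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script size their simulations as a
deliberate trade-off between statistical resolution and runtime on a single
CPU: WHAM recovery uses the 22-window scheme with 1e5 saved samples per
window (dt = 1e-4 ns, saved every 1 ps) against a double well with a 5 kT
barrier, recovered to < 0.15 kT RMSE; diffusion recovery uses 5e5 samples
per window at dt = 1e-5 ns (within 15% of truth per window); the end-to-end
run uses 5 replicates × 22 windows × 5e4 samples, recovering the
closed-form permeability of the generating landscape within 20% and within
two jackknife SE; the stationary-density χ² uses 2000 samples subsampled
every 2 ns from an 8e7-step walk at dt = 5e-5 ns — the finer step because
the χ² check is exactly the statistic sensitive to the O(dt) Euler bias.

## Known limitations

* Inefficiency factors in WHAM are fixed at 1; strongly autocorrelated
  windows will have optimistic (too-smooth) pooled profiles, though the
  jackknife errors remain honest across replicates.
* The ACF-truncation diffusion estimator is biased low in τ (high in D) by
  a few percent at coarse saving intervals; save at least ~5 points per τ.
* The mirroring step assumes a symmetric bilayer; asymmetric membranes
  need both leaflets sampled explicitly in the bilayer-center frame.
* Permeabilities are reported as raw ISDM values in cm/s with the unit
  chain stated; published tables for comparable systems may carry
  scale conventions that are not reproducible from the profile alone, so
  cross-study comparisons should be made on ratios or on the barriers.
* The reduced 22-window preset is a reconstruction from stated placement
  rules, not a published window table.
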