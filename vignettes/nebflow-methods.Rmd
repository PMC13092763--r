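---
title: "Models and numerical choices in nebflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in nebflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nebflow)
```

`nebflow` automates the full reaction-path lifecycle — endpoint
minimization, permutation-invariant alignment, sequential pair-potential
path generation, climbing-image nudged-elastic-band (CI-NEB)
optimization with energy-weighted springs, and minimum-mode-following
(MMF) saddle refinement — on pluggable potential-energy surfaces. This
vignette records the models, the tunable parameters, and the places
where a genuinely open design choice had to be made.

## The chain-of-states model

A band is an ordered list of images `R_0 … R_{m-1}` with frozen
endpoints. Each interior image feels

* the component of the true force perpendicular to the local path
  tangent, and
* a spring force `(k_fwd d_fwd − k_bwd d_bwd) τ̂` projected along the
  tangent,

where `τ̂` is the upwinded (improved) tangent: toward the higher-energy
neighbor on monotone segments, an energy-difference-weighted mix of the
two segment vectors at local extrema, and the plain central difference
when both neighbors are isoenergetic (the degenerate case arises on the
pair-potential surface, whose converged images are all at zero energy).
The upwinded estimator is the standard choice of the CI-NEB literature;
the alternative (central-difference everywhere) is known to cause kinks
on steep walls.

Spring constants are energy-weighted,

```
k_i = k_min + (k_max − k_min) · max(E_i − E_ref, 0) / (E_max − E_ref),
```

clamped to `[k_min, k_max]` (defaults 0.972–9.72 eV/Å²), so images
concentrate near the barrier. The reference energy is not fixed by the
formula alone; `nebflow` uses `E_ref = max(E_reactant, E_product)`, the
convention of the energy-weighted-springs literature, and returns
`k_min` identically when `E_max ≤ E_ref` so the function is total. A
segment's constant is the mean of its two images' constants.

The climbing image — the interior energy argmax at the moment of
activation — replaces its NEB force by `−g + 2(g·τ̂)τ̂`, inverting the
parallel gradient component so it ascends to the saddle. "Activation at
80 % convergence" is read as: activate once the maximum band force
reaches `force_tol / 0.8` (within 25 % of threshold). Two other readings
— a fraction of images converged, or a fraction of the initial force —
are defensible; the chosen one is monotone in the band's actual
progress and is exposed as `ci_activation_fraction` for users who want a
different behavior.

### Hybrid switch to minimum-mode following

When the climbing image's force norm falls below `mmf_switch_force`
(default 0.5 eV/Å), the band is frozen and a dimer walker detaches from
the discretized path ("off-path"): a finite-difference dimer
(separation 10⁻³ Å, one-point Fourier rotation in the plane of the mode
and the rotational force, ≤ 10 rotations per translation) estimates the
lowest-curvature mode, and a bounded quasi-Newton step moves the walker
on the mode-inverted force `F − 2(F·v̂)v̂`. On the first iteration the
mode is seeded with the NEB tangent; a converged mode whose |cosine|
overlap with that tangent is below `mode_tangent_min_overlap` (default
0.8) is rejected in favor of the tangent. This gate is an
interpretation: it protects against the dimer locking onto a soft
spurious mode far from the tangent direction on the very first step,
where the tangent is the best available saddle-direction prior. Dimer
rather than Lanczos mode finding was chosen for its lower memory and
because only the lowest mode is needed. Converging to a point whose
lowest curvature is positive is reported as an error, never silently
accepted. The refined saddle is re-inserted at the climbing position.

## Optimizers

Endpoint minimization is a hand-written bounded-step L-BFGS (history
20, initial inverse-Hessian scale 1/70 Å²/eV): the contract requires a
hard per-atom displacement cap per accepted step (0.1 Å, oversized
steps rescaled uniformly so the quasi-Newton direction is preserved),
monotone energy descent (backtracking halves the step on any increase),
convergence on the *maximum per-atom* force norm (the stricter of the
two common conventions; documented and configurable), and a full
trajectory capture — none of which `stats::optim`'s L-BFGS-B exposes.

Band relaxation, pair-potential relaxation and the MMF walk act on
force fields that are not gradients of any scalar objective, so no line
search is possible. They share a quasi-Newton driver with an adaptive
trust radius: when the residual force grows by more than 50 % the
curvature memory — poisoned by tangent switches or dimer-mode rotation,
which make the field only piecewise smooth — is dropped and the trust
radius halved (floor 10⁻³ Å); steady progress relaxes it back toward
the 0.1 Å cap. This stabilization is what makes a quasi-Newton
integrator usable on the band at all; without it the iteration diverges
on stiff surfaces.

## Alignment

The permutation-invariant RMSD
`d(X, X_ref) = min_{Q,Π} sqrt(‖X − Q X_ref Π‖²_F / N)` is optimized
directly by alternating an exact species-constrained assignment
(Hungarian algorithm per species block — no linear-assignment solver is
part of the package's dependency footprint, so the O(n³) shortest
augmenting path method is implemented in R) with a Kabsch rotation fit,
from many deterministic rotation starts. Starts are frame-matching
rotations built from species-compatible atom pairs; `k_max` (Å⁻¹)
enters as the candidate-generation strictness knob: only pairs
separated by at least `1/k_max` define a frame, so a larger `k_max`
admits more (and more nearly degenerate) frames and a more exhaustive
search. The exact role of this constant inside the original
iterative-rotations-and-assignments literature is not restated here;
its mapping to multi-start strictness is a documented approximation.
Assignment ties on symmetric structures resolve deterministically by
scan order (lowest index first), so repeated runs are bit-identical.
Both structures are centroid-centered before the joint search and the
translation is recorded in the result. A hard cap of 256 atoms reflects
the combinatorial infeasibility of the joint problem for extended
systems. Intermediate band images are *not* re-permuted — only the
endpoints are aligned — so reactions with many equivalent atoms warrant
a visual check of the initial path.

Two-stage preparation centers both raw endpoints in the configured cell
(default [25, 25, 25] Å), aligns the product onto the reactant,
minimizes both, and re-aligns to correct any mapping drift introduced
by relaxation, logging the final RMSD.

## Initial path generation

The pair-potential interpolation surface penalizes deviation from
linearly interpolated pair distances,
`S = Σ_{i<j} d_ij⁻⁴ (t_ij − d_ij)²`, with the weight `d⁻⁴` taken from
the original image-dependent pair-potential formulation and the weight
differentiated along with the residual in the analytic forces. Targets
for image `k` of `m` use the index-based fraction `(k−1)/(m−1)` — the
growth order and the step-size parameter α are specified by the method,
the target-assignment rule is not, and the index fraction is the
simplest consistent choice. Sequential growth inserts one image at a
time (reactant side first, so an even image budget gives the reactant
side the extra insertion), seeds it at fraction α = 0.33 of the
*Cartesian* segment from its frontier toward the opposite frontier
(whether α should instead measure arc position on the interpolation
surface is not determinable from the method description; Cartesian is
documented), and re-relaxes all interior images after every insertion
with uniform springs (k = 5 eV/Å², ≤ 200 iterations per growth step,
force tolerance 0.01), keeping the growth cost bounded at O(m²) surface
evaluations.

## Projections

Profile nodes carry the tangential force `F·τ̂`; the
derivative-constrained piecewise-cubic Hermite interpolant fixes the
slope at each node to the *negated* stored value, which for `F·τ̂ =
−dE/ds` restores the physical energy derivative, so interpolated
barriers never overshoot the data the band actually measured. The 2D
landscape triangulates each sample's RMSDs to reactant and product,
`s = (r² − p² + D²)/(2D)`, `d = sqrt(max(r² − s², 0))`, placing the
reactant at the origin and the product at `(D, 0)`; the clamp absorbs
rounding-level triangle-inequality violations. Raw Ångström values are
reported without further scaling. Path-length coordinates divide
segment norms by √N by default so the RMSD coordinate is a true lower
bound for them (`normalize_per_atom = FALSE` restores raw Frobenius
norms). The 2D projection uses a stricter default alignment
(`k_max = 14 Å⁻¹`) so landscapes are comparable across systems; it is
configurable.

## Built-in surfaces and fixtures

The Müller–Brown surface uses the standard four-Gaussian
parameterization, treated as eV over Å so the whole pipeline runs in
one unit system. Its energies (tens to hundreds of eV) are ~50× larger
than chemical bond scales, so the shipped benchmark configuration runs
the band at a proportionally tighter force threshold (10⁻³ eV/Å with 12
images) rather than the chemical default; at the chemical threshold the
saddle is still found but the flanking images visibly cut the corner of
the steep entrance valley. The surface is frame-fixed (not translation
invariant) and has a single particle, so the alignment stage is
trivially the identity there and centering is bypassed.

The Morse cluster potential sums per-species-pair Morse terms. The
default table is tuned so that a three-atom H/C/N system realizes a
proton-hop surrogate: the C–N scaffold is stiff with an equilibrium
length (3.2 Å) deliberately exceeding the sum of the H–C (1.1 Å) and
H–N (1.0 Å) bond lengths, so the proton cannot bind both centers at
once and the hop between the two single-bond minima crosses exactly one
first-order saddle near the scaffold midpoint (verified by the Newton
oracle in the test suite). The surrogate's barrier (≈ 2.8 eV) and
endothermicity (≈ 0.7 eV) are properties of this parameter choice, not
claims about any real molecule.

Fixtures are fully deterministic: `random_cluster` draws
minimum-separated uniform positions, adds Gaussian jitter (σ = 0.05 Å)
and a species-preserving permutation plus random rotation to the
product — the alignment stress test — under a caller-isolated RNG seed.
The Newton stationary-point oracle (damped pseudoinverse Newton on the
analytic gradient with a central-difference Hessian, h = 10⁻⁴ Å,
‖g‖ < 10⁻¹⁰, Morse index from the eigenvalue signs with a 10⁻⁵
zero-mode threshold) shares no code with the band or refinement
modules; independence is the point.

## The stage graph

Seven stages — `align_pre`, `minimize_R` ∥ `minimize_P`, `align_post`,
`pathgen`, `band`, `visualize` — run in topological order; a stage
executes only when the MD5 digest of any input file or of its parameter
subtree (canonicalized, key-sorted JSON) differs from the manifest,
which is rewritten atomically after every stage so interrupted runs
resume exactly where they stopped. One deliberate wrinkle: the product
minimization consumes the *centered* product, which depends only on the
product file and the cell, not the stage-1 rotation/permutation onto
the reactant. Minimization is exactly equivariant under rigid
transforms, and `align_post` re-solves the full alignment on the
minimized pair, so the final endpoints are unchanged — while an edit to
the reactant correctly re-runs its own lineage and leaves the product
minimization untouched. The two minimizations are declared mutually
independent and may run concurrently; correctness never depends on it.

## Problem sizes and what the tests do and do not show

The shipped test systems are deliberately small: a single particle on
the 2D benchmark (12-image band), a three-atom surrogate (default
18-image band), and ≤ 6-atom random clusters for which the alignment
can be checked against exhaustive permutation × Kabsch enumeration.
Passing tests demonstrate the machinery — projection identities,
endpoint immobility, saddle recovery against an independent Newton
oracle, hash-exact incremental recomputation — on smooth analytic
surfaces with isolated, well-separated stationary points. They do not
demonstrate robustness to the pathologies of learned or ab-initio
surfaces (noise, soft modes, near-degenerate saddles, many equivalent
atoms), nor correct permutations along the interior of the path, nor
anything about periodic or condensed-phase systems, which are outside
the package's gas-phase scope.
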