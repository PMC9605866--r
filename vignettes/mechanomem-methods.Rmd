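---
title: "Methods: membrane deformation, lipid enrichment, structural comparison and photobleaching stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanomem)
```

This vignette is the package's own account of its models and numerical
choices: what each estimator assumes, which tunable parameters matter, what
the synthetic generators do and do not emulate, and where the design was
genuinely open and a choice had to be made. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Membrane thickness and density maps

### Model

A coarse bead membrane is reduced to one *reference bead* per lipid: the
phosphate bead for phospholipids and the hydroxyl bead for cholesterol
(default names `PO4`/`P`/`P8` and `ROH`/`O3`/`OH`, replaceable via
`bead_config()`). Per frame, the bilayer midplane is

> z₀ = mean z over all phospholipid phosphate beads in the frame,

and the per-leaflet "thickness" of an xy bin is the arithmetic mean of
`|z − z₀|` over all in-window phosphate samples assigned to that leaflet
and bin. Leaflet assignment is the sign of `z − z₀` (hydroxyls included for
cholesterol); a bead exactly at the midplane goes to the upper leaflet with
a warning.

### Choices that were open

* **Global versus local midplane.** The literature phrase "the bilayer
  midplane" does not discriminate. We use the global per-frame mean, which
  is exact for the synthetic generator and the simplest defensible reading;
  strongly curved membranes would need a locally smoothed midplane, which
  is out of scope here. Consequence worth knowing: a deformation applied to
  *one* leaflet drags the global mean along by half the leaflet-averaged
  displacement (for a single Gaussian of amplitude A and width σ in a box
  of area `L²`, the shift is `A·2πσ²/(2L²)` — 0.1 Å at the default
  validation settings). The tests account for this analytically rather than
  hiding it.
* **Thickness = per-leaflet distance to midplane**, not leaflet-to-leaflet
  distance, because deformations of the two leaflets are generally
  asymmetric and per-leaflet maps preserve that information.
* **Binned average, not raw histogram.** A raw count histogram has no
  length units; the quantity with Å units is the binned mean of
  `|z − z₀|`. Bin size defaults to 2 Å.
* **Empty bins are `NA`, never 0** — a protein-occupied bin must not read
  as zero thickness.
* **Frame window** defaults to the second half of the frame set (the
  convention for equilibrated trajectory averages); all functions accept
  `"full"` or explicit `c(first, last)`.

### Radial profiles and propagation distance

Occupied bins are grouped into annuli by minimum-image distance from the
protein surface, `d = |r_xy − center| − radius`, each annulus carrying a
count-weighted mean. Annuli beyond the inscribed circle
(`d > min(L)/2 − radius`) are dropped by default: they consist of corner
bins only and their means are statistically unstable. The bulk reference is
the count-weighted mean over annuli beyond `bulk_min` (default 60% of the
largest retained distance). `propagation_distance(profile, tol)` returns
the smallest d\* beyond which every annulus stays within `tol` of bulk,
flagging `converged = FALSE` when the profile never settles. For a Gaussian
deformation of amplitude A at the protein surface the analytic value is
`d* = σ√(2·ln(A/tol))`, which the acceptance suite checks to within one
radial bin.

## 2. Lipid depletion–enrichment index

For lipid species L,

`index(L) = ratio(L)_shell / ratio(L)_bulk`,

where `ratio(L)_shell` is L's fraction of all lipids whose reference bead
lies within the cutoff (default 7 Å) of the nearest protein bead
(minimum-image, union over protein copies, each lipid counted once per
frame), and `ratio(L)_bulk` is L's fraction of all lipids in the membrane.

Open choices, and what we picked:

* **Ratio of mean counts, not mean of per-frame ratios** (both are
  implemented through the `window` machinery; ratio-of-means is the
  default). Ratio-of-means is robust when a frame's shell is empty.
* **Bead-to-bead distance**, not distance to a surface mesh: the
  coarse-grained context implies bead distances.
* z is non-periodic by default (a bilayer is not its own periodic image
  across the normal at these box heights); `periodic_z = TRUE` is available.
* The cell-list acceleration (cell edge ≥ cutoff) is an implementation
  detail whose correctness is *defined* by the O(N²) brute-force route:
  `method = "brute"` is kept as a first-class argument and the acceptance
  suite asserts exact equality of the two on ≤ 5,000-bead fixtures, plus
  agreement with an independent plain-loop recount in the unit tests.

## 3. Synthetic membrane generator

`build_membrane()` emulates the *analysis surface* of a simulated membrane
patch, not its physics: two leaflets of reference beads on jittered
hexagonal lattices at `z = ±z₀ + Δz(x, y) + ε`, with
`Δz(x, y) = Σ A_i exp(−r_i²/2σ_i²)` per leaflet and `ε ~ N(0, noise_sd)`.
Species are drawn multinomially from the declared composition (default
54:32:8:6 PE:PC:SM:cholesterol), re-weighted by the shell multipliers and
renormalised inside the enrichment shell. A cylindrical protein footprint is
emitted as rings of `PROT` beads spanning the bilayer. Defaults: 400 × 400 Å
box (the patch size used in the coarse-grained simulations this package's
analyses are aimed at), 64 Å² per lipid, phosphate planes at ±19 Å, jitter
1 Å, z noise 0.8 Å, cholesterol hydroxyls 5 Å below their leaflet's
phosphate plane.

What a green test does and does not establish. The generator gives exact,
analytically invertible ground truth, so green tests establish that the
estimators are unbiased and correctly calibrated *given* the model's
assumptions: i.i.d. frames (no autocorrelation), Gaussian fields, additive
Gaussian z noise, immobile species identities, and a rigid cylindrical
footprint. It does not establish anything about force-field realism, lipid
dynamics, flip-flop, or the actual deformation fields of any particular
protein — reproducing a published μs-scale simulation result is explicitly
not claimed, and figure-read values are not asserted anywhere.

Two deliberate consequences of the lattice design:

* Because lipids sit near fixed lattice sites (lattice constant ≈ 8.6 Å at
  64 Å²/lipid) and jitter is small, fine-grained 2 Å bins between sites stay
  permanently empty. This is realistic for binned single-lipid data and
  exercises the `NA`-bin contract.
* Species identities are fixed across frames (frames redraw jitter and
  noise only), so multi-frame species counts are *not* independent draws;
  statistical tests on composition use single frames or pool across seeds.
* With cholesterol present, the two leaflets carry (binomially) different
  phosphate counts, so the estimated global midplane sits a few hundredths
  of an Å off the geometric center — a real property of the estimator, which
  exact-identity tests avoid by using cholesterol-free compositions.
* The renormalisation of shell fractions means a multiplier m on one
  species yields an expected index of `m / Σ_L f_L m_L` (1.89 for m = 2 on
  a 6% species), not m itself; the acceptance test asserts the exact
  expectation and its compatibility with the nominal value within sampling
  error.

## 4. Structural comparison

* **Superposition** is Kabsch via SVD of the cross-covariance with
  reflection correction (negate the smallest singular vector when
  `det(VUᵀ) < 0`) — mandatory for near-planar or mirror-degenerate sets.
  Collinear or < 3-point inputs are rejected. The rotation angle is
  `arccos((tr R − 1)/2)`, in [0°, 180°].
* **Domain rotation** between states E and C: superpose E onto C over the
  anchor selection, apply that transform to E's moving selection, superpose
  onto C's moving selection, report the second rotation's angle. The
  construction is symmetric in (anchor, moving) and in (E, C), which the
  tests verify on synthetic hinges.
* **Atom pairing** is by (residue, atom-name) key with an optional residue
  offset, or by global Needleman–Wunsch alignment of residue sequences
  (match/mismatch/gap = 1/−1/−2, CA atoms only). The alignment is written
  in-package (~40 lines) because the scoring scheme is fixed and simple;
  its oracle in the tests is a hand-computed toy alignment.
* **Helix bend.** Open design point: the obvious estimator (first principal
  component of each half's CA cloud) is biased by up to ~8° at 10-residue
  halves because a fractional final turn tilts the point cloud's principal
  axis. We instead use the null-space (smallest right singular) vector of
  the CA *second differences*: for an ideal helix, second differences are
  exactly perpendicular to the axis, so the estimator is exact for any
  fragment length ≥ 4 CA per half and recovers constructed kinks of
  0–30° to machine precision in the tests.
* **SASA** is Shrake–Rupley with a deterministic Fibonacci-sphere point set
  (no RNG — results are bit-reproducible), default 960 points per atom and
  probe 1.4 Å. The van der Waals radii table (C 1.70, N 1.55, O 1.52,
  S 1.80, P 1.80, H 1.20 Å, plus common ions) is replaceable because
  published buried-area figures rarely state their radii. Buried interface
  area is reported in both conventions — `A + B − AB` and its half — since
  the literature uses either.

## 5. Photobleaching step detection and stoichiometry

### Detector

Changepoints by binary segmentation of the residual sum of squares. A split
is accepted only if it reduces the RSS by more than `penalty·σ̂²·log T`
(default penalty 6, a conservative BIC-type constant), with σ̂ estimated
robustly from the median absolute first difference divided by
`√2 × 0.6745` — first differences see each step only once, so the estimate
is insensitive to the staircase itself. Post-filters then discard (with a
recorded reason, never an error) any trace whose fitted levels are not
strictly decreasing with drops ≥ `min_step` (default 50 counts = half a
fluorophore at the default brightness), or whose final level is not within
3σ̂ of the terminal baseline (a molecule that never fully bleaches cannot be
scored).

The detector is an automated surrogate for manual trace scoring; it is
validated against synthetic ground truth only (≥ 95% per-trace accuracy at
signal-to-noise 10 in the acceptance suite) and is never claimed to
replicate any human's trace-by-trace decisions. One known discretization
artifact: two fluorophores bleaching within the same camera frame merge
into a single double-height step, converting ~1% of two-step traces into
apparent one-step traces at the default bleach rate; this slightly inflates
the one-step class and leaves the maximum-likelihood n unchanged.

### Stoichiometry model

Visible step counts from an n-subunit complex with maturation probability p
follow the binomial `B(k; n, p)` conditioned on detection (k ≥ 1), since
complexes with zero mature fluorophores are invisible:
`cond(k) = B(k)/(1 − B(0))`. We mix in a uniform outlier kernel,
`P(k) = (1 − ε)·cond(k) + ε/K_max` (default ε = 0.02), because observed
k > n — e.g. coincidental colocalization — would otherwise have zero
likelihood and make model selection degenerate. p defaults to the fixed
literature estimate 0.8 for GFP-family maturation; free-p fitting by
golden-section maximisation is available but the default keeps p fixed, as
the estimate is an assumption rather than a fit. Model selection maximises
the multinomial log-likelihood over candidate n (default 1–6); ties within
1e-9 break toward the smaller n (parsimony).

## 6. Numerical conventions

* Internal length unit is Å everywhere; GRO files (nm) are converted at the
  boundary (× 10). Coordinates are wrapped into `[0, L)` on read; wrapping
  is idempotent.
* Residue identity is (chain, residue number, insertion code); alternate
  locations keep the highest-occupancy record, making selections
  deterministic.
* All generators are pure functions of their spec (which includes the
  seed); the caller's RNG state is saved and restored. Analyses that need
  no randomness (SASA included, via the Fibonacci sphere) are
  bit-reproducible.
* Degenerate inputs error early with named messages (empty selections,
  collinear point sets, no phosphate beads, unknown species/elements); the
  step detector is the deliberate exception, returning `discarded` calls
  with reasons so that bulk pipelines never halt on a bad trace.

## 7. Known limitations

* The regression against deposited coordinate files
  (`deposited_model_regression()`) needs those multi-MB files locally; the
  package ships the machinery and a default selection config, but the
  chain naming of any given deposition must be verified against its own
  header before trusting the defaults.
* No curvature tensors, Voronoi area-per-lipid, order parameters, or
  interleaflet registry metrics; no mmCIF writing; no binary trajectory
  formats in the core (text GRO/PDB only).
* The outlier kernel is uniform by construction; it is agnostic about the
  physical origin of k > n events.
* Config files for the command-line interface are JSON rather than TOML:
  no TOML parser is available in the supported dependency set, and JSON
  expresses the same sections losslessly.
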