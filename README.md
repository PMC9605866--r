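# mechanomem

Quantitative analyses for membrane-embedded mechanosensory channel
complexes, for structural biologists and simulators who need to answer four
recurring questions about such a complex:

1. **How does the protein deform the bilayer?** Per-leaflet thickness maps
   (`|z_phosphate - z_midplane|` on a 2 x 2 Å² grid), lipid density maps,
   radial deformation profiles around the protein, and the distance over
   which a deformation propagates before the membrane returns to bulk.
2. **Which lipids does it gather or exclude?** The depletion–enrichment
   index for lipid species L in the 7 Å protein shell,

   `index(L) = ratio(L)_shell / ratio(L)_bulk`,

   where each ratio is L's fraction of total lipid counts in the shell and
   in the whole membrane (1 = neutral, > 1 enriched, < 1 depleted).
3. **How do two conformational states differ geometrically?** Kabsch
   superposition with reflection correction (RMSD, rotation angle
   `θ = arccos((tr R − 1)/2)`), hinge/domain rotation between states, helix
   bend angles from CA traces, centroid separations, and Shrake–Rupley
   solvent-accessible surface area with buried interface area
   `ΔSASA = SASA(A) + SASA(B) − SASA(A∪B)`.
4. **How many subunits carry the fluorescent tag?** Photobleaching step
   detection on single-molecule pulldown traces (penalised binary
   segmentation with a monotone-decreasing level filter) and
   maximum-likelihood subunit stoichiometry under a conditional binomial:
   a complex with n subunits and fluorophore maturation probability p shows
   k visible bleaching steps with probability `B(k; n, p) / (1 − B(0; n, p))`,
   mixed with a small uniform outlier rate ε.

Every estimator ships with a seeded synthetic-data generator carrying exact
ground truth: bead bilayers (default PE:PC:SM:cholesterol 54:32:8:6) on
jittered hexagonal lattices with prescribed Gaussian deformation fields and
shell enrichment multipliers; photobleaching traces from the binomial
labeling model; and rigid-transform / kinked-helix structure fixtures.

## Worked example

Subunit counting from 600 simulated pulldown traces (dimer, 80% maturation,
signal-to-noise 10), then membrane deformation recovery:

```r
library(mechanomem)

st    <- make_traces(trace_spec(n_traces = 600, n = 2, p = 0.8,
                                unit = 100, noise_sd = 10, seed = 42))
calls <- lapply(st$traces, detect_steps)
print(step_distribution(calls))
#> <step_distribution> 563 clean, 37 discarded
#>   1 step(s):   203  (36.1%)
#>   2 step(s):   360  (63.9%)

fit <- fit_oligomer(step_distribution(calls), p = 0.8, eps = 0.02)
print(fit)
#> <oligomer_fit> best n = 2 (eps = 0.02)
#>  n   p   loglik
#>  1 0.8 -2056.77
#>  2 0.8  -376.47
#>  3 0.8  -816.96
#>  4 0.8 -1395.77
#>  5 0.8 -1996.92
#>  6 0.8 -2520.81
intensity_ratio(calls)
#> [1] 1.99
```

The observed 36/64% one-/two-step split matches the conditional binomial of
a dimer at p = 0.8 (expected 1/3 and 2/3), the likelihood table selects
n = 2 decisively, and two-step molecules are twice as bright as one-step
molecules — the three signatures of a dimeric complex.

```r
m  <- build_membrane(synthetic_membrane_spec(
  box = c(400, 400), field = deformation_field("lower", +6, 200, 200, 15),
  n_frames = 50, seed = 42))
tm <- thickness_map(m$frames, "lower")     # second-half frame window
print(tm)
#> <thickness_map> lower leaflet: 200 x 200 bins of 2 A, frames 26-50, 59700 samples
#>   occupied-bin mean thickness 18.95 A

rp <- radial_thickness_profile(tm, c(200, 200), radius = 0, r_bin = 2)
gf <- fit_gaussian_profile(rp)
c(gf$amplitude, gf$sigma, gf$bulk)
#> [1] -5.90 14.99 19.00
as.numeric(propagation_distance(rp, 0.5))
#> [1] 34
```

The imposed 6 Å-deep, σ = 15 Å thinning of the cytosolic leaflet is
recovered within 2% (amplitude −5.90 Å, width 14.99 Å against a 19.00 Å
bulk), and the deformation stops being detectable (|deviation| < 0.5 Å)
34 Å from the protein — the analytic value for this field is
`σ√(2 ln(6/0.5))` = 33.4 Å, within one radial bin.

## Command line

`inst/cli/mechanomem` exposes the pipeline as subcommands
(`synth-membrane`, `synth-traces`, `thickness`, `density`, `enrich`,
`steps`, `fit-oligomer`, `compare`, `sasa`), with JSON configuration files;
see the header of that script and `inst/extdata/` for examples.

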