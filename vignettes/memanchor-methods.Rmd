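---
title: "Methods: membrane, diffusion and anchoring analyses in memanchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane, diffusion and anchoring analyses in memanchor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memanchor)
```

memanchor post-processes membrane/protein trajectories for the question of
how an isoprenoid-anchored peripheral protein (the motivating system is a
small GTPase carrying one or two C-terminal geranylgeranyl chains) couples
to bilayers of different composition. This vignette documents the models
behind each analysis, the parameters that matter, what the synthetic
generators do and do not emulate, and the design decisions taken where the
methods literature leaves choices open.

## Coordinate model and conventions

All analyses assume an orthorhombic box with the bilayer built in the
x,y-plane, so the membrane normal is globally +z; no normal estimation is
performed. Internal units are nm (lengths) and ns (times); Angstrom-native
formats (PDB, DCD) are converted at the I/O boundary. Leaflets are assigned
per frame by a median-z split of the phosphate phosphorus atoms — a rule
that is parameter-free and robust to whole-membrane drift. Cholesterol,
which has no phosphate, is classified by the z of its hydroxyl oxygen
relative to the same median plane. Minimum-image displacements map into
(−L/2, +L/2], keeping the boundary case at +L/2; this tie-break is asserted
in the tests. Whether an upstream engine wrote wrapped or whole-molecule
coordinates cannot be inferred reliably from a file, so the package defines
its own convention: tracks are re-wrapped/unwrapped internally and the
unwrap→rewrap round trip is exact by construction.

DCD time metadata is ignored (its AKMA-unit encoding varies across tools);
the frame interval is an explicit argument. Topologies are read from PDB or
GRO; XTC is not supported — DCD covers the compressed-trajectory role here
and keeps the I/O stack free of a bespoke decompressor.

## Membrane structure

**Thickness** is the difference of mean phosphate z between leaflets —
a phosphate-plane (not electron-density) thickness. **Area per lipid** is
the lateral box area over the per-leaflet molecule count, with cholesterol
counted like any other lipid; Voronoi per-lipid areas are out of scope. The
all-molecule denominator is a deliberate choice where conventions differ —
per-phospholipid areas would be systematically larger in sterol-rich
membranes.

**Acyl order parameters.** For each saturated sn-1 chain carbon Ci
(C2–C15), S_CD(Ci) = ⟨P2(cos θ_CH)⟩ over both C–H bonds, all selected
lipids and frames, with θ_CH measured against +z. When explicit hydrogens
exist they are used directly; for H-less systems the two C–H directions are
reconstructed from the carbon skeleton by placing them symmetrically about
the local C–C–C plane at the ideal tetrahedral H–C–H angle (109.47°) — the
carbon-skeleton route familiar from united-atom analyses. Both routes agree
to machine precision on ideally built chains and within 0.01 on the test
fixtures. The reported chain average uses |S_CD| so that the planar limit
(all C–H in the membrane plane, S_CD = −0.5) appears as the positive 0.5
convention used in order-parameter tables. Uncertainty is the sd of the
chain average over 5 contiguous time blocks; 5 blocks is a pragmatic
compromise between bias (few blocks) and block-length requirements.

**Local order maps** grid the lateral plane (default spacing 0.2 nm) and
assign each lipid, per frame, its chain-average order at the cell holding
its chain-carbon centroid; cells never visited are flagged as no-data and
excluded. Values are reported as deviations from the global average, so the
count-weighted mean deviation is exactly zero. The anchor-proximal scalar
averages lipids whose chain centroid lies within a cutoff (default 0.5 nm)
of the per-frame anchor centroid, minimum-imaged.

## Lateral diffusion

Tracks are unwrapped by replacing every consecutive displacement with its
minimum image before cumulative summation. Jump distance analysis pools the
lateral displacements |r(t+Δ) − r(t)| over particles and overlapping time
origins and fits the 2D Brownian mixture density
p(r) = Σᵢ fᵢ · r/(2Dᵢ Δ) · exp(−r²/(4 Dᵢ Δ)) by maximum likelihood (EM on
the raw jumps). ML on raw jumps was chosen over least squares on a
histogram because it has no bin-width sensitivity; a histogram-free CDF
least-squares fit is kept as an independent cross-check
(`fit_jda_cdf()`). The number of subpopulations is selected by BIC between
1 and 2 components, keeping the richer model only when it improves BIC by
more than 10 — diffusion tables conventionally report one coefficient per
species, so the default errs towards parsimony. Components with fraction
< 0.01 are pruned with a warning. Uncertainties are the sd of D refitted
on 5 contiguous trajectory segments. The default lag is 1 ns; a lag sweep
is a one-liner over `jump_distances()` if lag dependence is suspected.

The MSD cross-check fits MSD(t) = 4Dt over a window defaulting to 2–20% of
the track duration: long lags have few effective origins and would dominate
an unweighted linear fit with noise, while the shortest lags are the best
sampled. On single-population synthetic data the two estimators agree
within 10% (a property test), with JDA markedly more precise — the reason
JDA is the primary estimator for multi-species membranes.

Units: nm²/ns internally; reported as 10⁻⁷ cm² s⁻¹ (1 nm²/ns = 100 ×
10⁻⁷ cm² s⁻¹). Ratios between systems are rounded to 2 significant figures
with first-order (delta-method) uncertainty propagation, cross-checked
against Monte-Carlo propagation in the tests.

## Anchoring geometry

**Insertion depth** is the z-distance from the mean of neighbouring
same-leaflet phosphate atoms (within 1.0 nm lateral distance of the anchor
centroid; falling back to the whole leaflet with a warning when fewer than
3 qualify) down to the deepest anchor carbon. Depths are signed and never
clamped, so desorption events remain visible as negative values. The 1.0 nm
neighbour cutoff is exposed; "surrounding headgroups" is not a standardized
notion and local referencing matters in curved or undulating patches.
Depth distributions get a histogram (default bin 0.05 nm), mean ± sd and a
modality call from 1- vs 2-component Gaussian mixtures compared by BIC
(via mclust) — the statistic that separates a composition-adapted anchor
(narrow, unimodal) from unspecific anchoring (broad, bimodal).

**Per-residue membrane distances** use the proximal (upper) leaflet mean
phosphate plane as reference and the mass-weighted residue centre of mass;
using local phosphates instead would mix anchor-proximal undulations into
every residue's trace.

**Orientation descriptors.** With A the anchor-carbon centroid, G the
G-domain centre of mass, S the switch-regions centre of mass and
M = A − ẑ a probe point displaced into the membrane: θ is the angle
between G − A and +z (θ = 90° ⇔ G domain parallel to the bilayer), and ω
is the torsion M–A–G–S mapped to [0, 360). Frames are labelled 'exo' when
ω is within ±45° of 80°, 'endo' within ±45° of 190°, else intermediate.
The A/G/S/M construction is this package's own self-consistent definition:
it satisfies every constraint the descriptors must have (parallelism at
θ = 90°, a torsion that separates membrane-facing from solvent-facing
switch regions) but the internal reference atoms are not guaranteed to
match other tools' choices — absolute ω values should be compared only
within memanchor analyses. The same quantity appears in the literature
under both φ and ω; ω is used throughout here.

**RMSF** superposes each frame's fit selection (typically G-domain Cα)
onto the first frame by weighted Kabsch superposition (SVD with a
determinant guard against reflections) and reports per-atom fluctuations
about the mean structure. The superposition is validated against an
independent quaternion-method (Horn/Kearsley) RMSD oracle to 1e-8, and
RMSF is reference-frame independent within 2% on jittered fixtures.

## Synthetic generators: what is emulated, what is not

The generators exist because the analyses need data with knowable answers.
They emulate exactly the observables the analyses measure, with planted
values chosen from the magnitudes reported for comparable all-atom systems
(pure-POPC thickness ≈ 3.87 nm with order ≈ 0.176; sterol-rich membranes
≈ 4.5–4.6 nm with order ≈ 0.30–0.33; lipid D ≈ 0.4–1.6 × 10⁻⁷ cm² s⁻¹;
anchor depths ≈ 0.9–1.8 nm):

* **Bilayers** place pseudo-lipids on a lateral grid: phosphate planes at
  ±thickness/2 with per-frame Gaussian z jitter (default sd 0.05 nm, a
  typical per-lipid vertical fluctuation scale), a box sized exactly to
  n · APL, and all-trans zigzag chains whose axes are drawn per frame from
  a polar-cap distribution calibrated in closed form so the chain-averaged
  |S_CD| equals the target; hydrogens are placed tetrahedrally from the
  skeleton, which makes the explicit and reconstruction routes agree
  exactly and pins ⟨P2⟩ analytically. Chain lateral centroids are pinned at
  the grid site so per-lipid planted order is recovered by lateral
  assignment. The six-component composition uses a plausible early-endosome
  mimic (POPC .30 / CHOL .25 / PSM .15 / POPE .15 / POPS .10 / PI3P .05);
  the exact experimental ratios are not critical because species identity
  only routes selections.
* **Tracks** are exact 2D Gaussian random walks (per-axis step variance
  2DΔt) wrapped into the box; the unwrapped truth is returned alongside.
  Generation refuses step sds above L/4, where unwrapping becomes
  ambiguous.
* **Anchored proteins** are rigid CA-only templates (215 residues, G domain
  15–185, switch regions 50–60 and 75–92 as offset sub-blobs, an HVR tail,
  1 or 2 twenty-carbon anchor chains) posed per frame so the planted depth,
  θ and ω hold exactly under the package's own measurement rules.

Not emulated: chemistry (no force field, no excluded volume), membrane
undulations and curvature, anomalous or correlated diffusion,
protein-induced lipid perturbations beyond the planted order deficit, and
any coupling between observables (depth does not influence order, θ does
not influence diffusion). Passing tests therefore demonstrate that the
estimators recover what they claim to measure under their stated model —
not that the model captures every feature of real bilayers. The cone-band
C–H distribution used for calibration (uniform cos θ within a band around
the membrane plane) spans the full physical range 0 < |⟨P2⟩| ≤ 0.5, with
the half-angle found by bisection against numerical quadrature and
cross-checked by closed form (|⟨P2⟩| = cos²α/2) and Monte Carlo.

## Numerical choices and degenerate inputs

* EM for the jump-distance mixture runs deterministic quantile-based
  multi-starts, converges on relative log-likelihood 1e-10, and errors on
  non-convergence; an all-zero jump set short-circuits to D = 0.
* `superpose()` rejects collinear point sets (second singular value ~ 0).
* `cone_halfangle_for_order()` errors outside (0, 0.5]; the planar target
  0.5 converges to half-angle 0, the isotropy limit to π/2.
* Histogram edges align to multiples of the bin width so bin counts are
  reproducible across series with different ranges.
* Generators draw through a private RNG state (seed in the spec), so they
  are bit-reproducible and do not disturb the caller's stream; pipeline
  seeds derive deterministically from the config seed.
* Problem sizes in the tests and drivers (tens of lipids, 150–2000 frames,
   up to ~200 × 2000-step track sets) are chosen so every planted recovery
  has sampling error comfortably inside its asserted tolerance.

## Known limitations

Orthorhombic boxes only; no triclinic cells, curved membranes, Voronoi
areas, electron-density thickness, anomalous-diffusion exponents,
finite-size hydrodynamic corrections, secondary structure, contacts or
H-bonds. The selection grammar is deliberately small (name/resname/resid/
element/segid with boolean algebra); it covers every selection the analyses
need without becoming a query language.
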