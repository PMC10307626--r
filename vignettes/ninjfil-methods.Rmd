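---
title: "Models and methods behind ninjfil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ninjfil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ninjfil)
```

ninjfil implements the quantitative analyses surrounding the NINJ1
filament mechanism of plasma membrane rupture: screw-symmetric filament
and ring assembly with parameter estimation, intra- versus
inter-protomer classification of evolutionary couplings, amphipathic
face and hydrophobic belt quantification, single-molecule localization
(SMLM) cluster morphometrics, and the membrane-assay normalization
formulas. This vignette explains the models, the tunable parameters and
the numerical choices, and what the synthetic-data generators do and do
not emulate.

## Screw-symmetric assembly

A helical filament is generated by repeated application of a screw
operator: subunit $i$ carries the protomer coordinates rotated by
$i\,\theta$ about the filament axis and translated by $i\,d$ along it,
where $d$ is the **rise** (Å per subunit) and $\theta$ the signed
**twist** (degrees per subunit). For the NINJ1 filament the refined
helical symmetry is $d = 20.95$ Å and $\theta = -1.05^\circ$; those are
the package-wide example parameters.

```{r}
p <- synth_protomer(seed = 1)
fil <- build_filament(p, screw_symmetry(rise = 20.95, twist = -1.05), n = 20)
glance(estimate_screw(fil))
```

`estimate_screw()` inverts the construction: for every consecutive
subunit pair it computes the least-squares rigid transform (Kabsch
superposition over the singular value decomposition of the cross
covariance of CA coordinates), then decomposes that transform into a
rotation angle about and translation along the screw axis. The axis
direction comes from the antisymmetric part of the rotation matrix; the
axis point solves $(I - R)\,p = t_\perp$ in closed form. Per-pair
estimates are averaged, using the circular mean for the twist.

Numerical conventions:

* the axis is oriented so the rise is positive; the twist sign then
  follows the right-hand rule about that axis. The sign of the NINJ1
  twist is reproduced under this convention.
* pure translations (rotation angle below $10^{-9}$ rad) return twist 0
  with the axis along the translation.
* rotations of exactly 180° leave the angle sign undefined; the fit
  stops with a "degenerate" error rather than guessing.

**Ring closure.** A membrane pore model is built by *rearranging* the
filament into a ring rather than propagating the screw: $n$ subunits are
placed at angles $2\pi i/n$ on a circle of radius $R = n d / (2\pi)$ in
the plane normal to the membrane normal, each rotated so its propagation
direction is tangential. The intrinsic $-1.05^\circ$ filament twist is
dropped on closure; the accumulated residual ($n\theta$, the closure
mismatch) is reported as a diagnostic attribute. Subunit *centroids* are
placed exactly on the circle, which makes the consecutive-centroid chord
exactly $2R\sin(\pi/n)$ and keeps centroids coplanar; for a 45-mer at
the NINJ1 rise, $R \approx 150$ Å.

**Double filaments.** The soluble form of the filament is a pair of
identical filaments packed antiparallel via their hydrophobic faces.
`stack_double_filament()` duplicates a filament, rotates the copy 180°
about the axis perpendicular to both the filament axis and the
hydrophobic-face normal (through the filament centroid, so the copy
overlays the same span with its hydrophobic face turned inward), and
translates it by a user-chosen separation along the face normal. Any
resulting interatomic contact below 1.5 Å raises an error naming the
worst pair; no energetics or packing optimization is attempted.

## Evolutionary-coupling contact classification

Coupling tables (residue $i$, residue $j$, coupling score) are consumed,
not inferred. The analysis protocol keeps the top 100 pairs with score
above 0.5, measures on the assembly the intra-subunit CA–CA distance and
the minimum inter-subunit CA–CA distance over *all* ordered subunit
pairs, and labels each pair:

* `excluded` if both distances exceed 12 Å (contacts above 12 Å between
  CA atoms are not considered);
* `inter_dominant` if the intermolecular distance is strictly shorter
  than the intramolecular one;
* `intra_dominant` otherwise — exact ties count as intra, because the
  defining relation ("shorter than") is strict.

The 12 Å rule is applied to the *minimum* of the two distances: a pair
that touches neither within nor between subunits carries no contact
information, while a pair with a short intermolecular distance is
informative regardless of its intramolecular separation. The intra
distance is measured on the first subunit only; all subunits are rigid
copies, so the choice is immaterial (asserted to $10^{-6}$ in tests).
An `offset` argument maps alignment-column numbering to author
numbering when the two differ.

## Amphipathic faces, hydrophobic belt, hydrophobic moment

`assign_faces()` projects each residue's side-chain centroid (all
non-backbone heavy atoms; CA for glycine or CA-only models) into
cylindrical coordinates about the filament axis, and splits the azimuth
circle into two half-planes by a single planar cut through the axis. The
cut is found by a 1° grid search maximizing the difference in mean
hydrophobicity between the halves — the simplest model of a filament
with "one hydrophobic and one hydrophilic face". If the best achievable
difference is below a tolerance (default 0.2 scale units) the assignment
is flagged degenerate, as for a compositionally uniform filament.

The **hydrophobic belt** is the membrane-facing band of hydrophobic side
chains; its height is the axial extent ($z_{max} - z_{min}$) of
hydrophobic-face side-chain centroids with hydrophobicity at or above a
threshold, after trimming 2.5% of z-values at each end as an outlier
guard (set `trim = 0` for exact constructions). On the NINJ1 filament
this belt measures around 26 Å, matching the average plasma-membrane
thickness; the measurement protocol behind that figure is not fully
specified at the source, so the package treats ±3 Å as the relevant
agreement band and exposes both the threshold and the trim.

Two hydrophobicity scales ship with the package: Kyte–Doolittle
(default) and the Wimley–White interface scale (negated so larger =
more hydrophobic). The facial analyses only use differences and
rankings, so any affine rescaling of a scale leaves face assignment
unchanged.

The **hydrophobic moment** of a sequence segment is the helical-wheel
vector sum $\mu_H = |\sum_k (H_k - \bar H)\,e^{ik\delta}| / N$ with
$\delta = 100^\circ$ per residue for an ideal α-helix.
Hydrophobicities are mean-centred before summation. The classic
(uncentred) Eisenberg sum acquires a spurious length-dependent ripple
from the uniform component of the sequence — it vanishes only at
special lengths — whereas the centred moment is exactly zero for any
homopolymer and measures periodic facial segregation only. For
comparisons against composition-matched shuffles the two definitions
rank identically.

## SMLM cluster morphometrics

Localization tables (x, y in nm) are clustered with DBSCAN. No
maintained DBSCAN implementation is available among the package's
dependencies, so the algorithm is implemented here with standard
semantics, documented precisely for oracle parity:

* a point is a core point when at least `min_pts` points (counting the
  point itself) lie within `eps`;
* clusters grow from core points in scan (row) order with FIFO seed
  queues, neighbours appended in row order;
* non-core points within `eps` of a core point are border points,
  assigned to the first core cluster reaching them in scan order;
* everything else is noise (label −1).

Neighbour queries use an eps-sized grid and are exact. The test suite
checks label-for-label equality against an independent $O(n^2)$
brute-force implementation on randomized fields. The parameters are not
reported in the source study; the package defaults (`eps = 50` nm,
`min_pts = 10`) are package defaults chosen for nanobody-labelled STORM
data at ~15 nm precision, not reproduced values.

Cluster shape comes from the 2×2 gyration tensor (second-moment matrix
about the centroid) with eigenvalues $\lambda_1 \ge \lambda_2$:
$R_g = \sqrt{\lambda_1 + \lambda_2}$ and eccentricity
$Ecc = \sqrt{\lambda_1/\lambda_2}$ (1 = isotropic, larger = more
elongated). Collinear clusters ($\lambda_2 = 0$) report `Inf` with a
flag. The alternative flattening definition
$\sqrt{1 - \lambda_2/\lambda_1}$ is available via `ecc_def`; only the
direction "less spherical ⇒ larger" is fixed by the source material, so
the axis-ratio form is a package choice.

Condition comparisons run Student's unpaired two-sided t-test on
*per-experiment medians* — one median per independent experiment, never
pooled localizations — mirroring the study's statistical design. Groups
with zero pooled variance are handled in closed form.

## Assay normalizations

All formulas are linear rescalings between controls, implemented exactly
as stated by their protocols:

* percent of controls (LDH lysis, PI uptake):
  $100\,(S - N)/(F - N)$ with negative control $N$ and full control $F$;
  out-of-range values are flagged, never clamped — a value of 130% is
  quality-control information.
* dithionite-quench permeability:
  $100 - 200\,(F_{dit} - F_{triton})/(F_{initial} - F_{triton})$. The
  factor 200 reflects leaflet topology: in a sealed liposome dithionite
  quenches only the outer-leaflet NBD (half the signal), so the
  midpoint plateau maps to 0% and full quenching to 100%. Plateaus are
  estimated as the median of the final 20% of each phase — the protocol
  records "until plateau" without an estimator, so this robust choice is
  a package decision exposed via `tail_frac`.
* dye release: $100\,(S - D)/(T - D)$ against the Triton endpoint.
* DRAQ7 influx: normalized as $(F_t - F_i)/F_i$; the onset of membrane
  permeabilization (time zero) is the first time point strictly
  exceeding 1.
* distribution inhomogeneity: baselined by subtraction, $D_t - D_i$.
  The figure legends of the source describe this as "normalized to" the
  initial value, but its Methods give the difference form, which is what
  the package implements.

## Synthetic-data generators

Every analysis stage is testable without downloads because the
generators return ground truth alongside the data:

* `synth_protomer()` builds an idealized four-helix protomer with the
  NINJ1 helix annotations (α1 44–55, α2 58–74, α3 79–103, α4 114–138 in
  author numbering): ideal α-helices (1.5 Å rise, 100°/residue),
  antiparallel packing on a square lattice, CA plus a pseudo-CB side
  chain, and a default Leu/Ser sequence with 100° periodicity so each
  helix is amphipathic. A small seeded coordinate jitter (0.05 Å)
  distinguishes realizations.
* `synth_localizations()` plants dots, round Gaussian clusters, and
  branched filamentous clusters (branching, directionally persistent
  random walks: 20 nm steps, 0.02 branch probability per step, 10°
  heading noise, per-branch contour length set by `size_nm`), decorated
  with blinking — a geometric number of localizations per site (minimal
  over-counting model, no photophysics) displaced by the localization
  precision. The condition presets give fields whose branched clusters
  span the 0.5–5 µm extent range and whose cluster counts per field are
  in the tens, so per-experiment medians are stable; they emulate
  morphology and over-counting only, not camera noise, drift, or
  label-density artefacts, so passing tests show the *pipeline* is
  correct, not that real data would be this clean.
* `synth_ec_table()` plants coupling pairs of known class by exhaustive
  distance enumeration on an assembly; classifier recovery is exact by
  construction at zero noise.
* `synth_trace()` produces the three-phase quench protocol (180 s
  baseline, 500 s post-dithionite, 60 s post-Triton) with exponential
  transitions (τ = 20 s and 5 s) and seeded Gaussian noise, returning
  the noiseless planted permeability.

All generators take a single seed, derive everything from it, and
restore the caller's random stream.

## Problem sizes and test design

The test suite uses 20-subunit filaments for screw round trips (the
fitted rise and twist recover the generating values to $10^{-6}$),
45-mers for ring geometry, fields of a few thousand localizations for
clustering, and 10 seeds for each stochastic recovery claim. The
condition-comparison check simulates 4 independent experiments per
condition, each pooling the clusters of 3 imaged fields — more
simulated experiments than the study's three, chosen so the
per-experiment-median t-test is decisively powered at α = 0.01 for
every seed.

## Known limitations

* The deposited cryo-EM model and the published coupling-score table
  are not redistributable inside the package; the workflows that
  consume them (`read_structure()`, `split_filaments()`,
  `classify_pairs()`) are validated on synthetic assemblies, and the
  checks against the deposited numbers run only when those files are
  supplied under `inst/extdata/`.
* Ring closure is purely geometric; no relaxation of the subunit
  interfaces is attempted, and how the original in-silico pore handled
  intrinsic twist is not stated at the source — dropping it is this
  package's documented choice.
* The hydrophobic belt height depends on the scale and threshold; both
  are exposed because the source protocol is underdetermined.
* DBSCAN parameters are package defaults; absolute cluster counts and
  morphometrics from real data depend on them and on localization
  precision, so only planted-truth recoveries and direction-of-effect
  claims are tested.
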