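# ninjfil

Quantitative analyses around the NINJ1 filament mechanism of plasma
membrane rupture (PMR), for structural biologists and cell biologists
working on lytic cell death.

NINJ1 is a 16-kDa plasma-membrane protein that polymerizes during
pyroptosis and other lytic deaths into long filaments that rupture the
membrane. The filament is a screw-symmetric stack of four-helix
protomers — a rise of 20.95 Å and a twist of −1.05° per subunit — with
one hydrophilic and one hydrophobic face, a membrane-matching
hydrophobic belt, and amphipathic helices (α1 44–55, α2 58–74) that
interlink subunits. `ninjfil` implements the computations that surround
this model:

* **Helical assembly** — build linear filaments, closed rings
  (radius `R = n·rise/2π`; ~150 Å for a 45-mer) and antiparallel double
  filaments from a protomer plus a screw symmetry, and estimate
  `(rise, twist)` from coordinates by least-squares (Kabsch) screw-axis
  fitting; subunit stoichiometry from polymer/monomer mass.
* **Coupling mapping** — classify evolutionary-coupling residue pairs
  as intra- versus inter-protomer contacts on an assembly (top 100
  pairs with score > 0.5; 12 Å Cα cutoff; ties are intra).
* **Surface amphipathicity** — hydrophobic/hydrophilic face assignment
  in cylindrical coordinates, hydrophobic belt height, and
  mean-centred Eisenberg hydrophobic moments (δ = 100°).
* **SMLM morphometrics** — DBSCAN clustering of single-molecule
  localizations, gyration-tensor radius of gyration
  `Rg = √(λ₁+λ₂)` and eccentricity `Ecc = √(λ₁/λ₂)`, field summaries,
  and Student's t comparisons on per-experiment medians.
* **Assay quantification** — LDH lysis % and PI uptake %
  (percent-of-controls), dithionite-quench permeability
  `100 − 200(F_dit − F_triton)/(F_initial − F_triton)`, liposome dye
  release %, DRAQ7 normalization `(F_t − F_i)/F_i` with strict onset
  at > 1, and inhomogeneity baselining `D_t − D_i`.
* **Synthetic data** — seeded generators with ground truth for every
  stage: toy four-helix protomers, SMLM fields (dots, round and
  branched filamentous clusters with blinking), planted coupling
  tables, and three-phase quench traces.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods and results have `autoplot()`/`plot_*()`
views.

## Worked example

```r
library(ninjfil)

p <- synth_protomer(seed = 1)                        # toy four-helix protomer
fil <- build_filament(p, screw_symmetry(rise = 20.95, twist = -1.05), n = 20)
glance(estimate_screw(fil))
#> # A tibble: 1 × 4
#>    rise twist     rmsd n_pairs
#>   <dbl> <dbl>    <dbl>   <int>
#> 1  21.0 -1.05 1.59e-14      19
```

The screw fit recovers the generating rise (20.95 Å; printed rounded)
and twist (−1.05°) with numerically zero superposition error — the
round trip that validates both the builder and the estimator.

```r
ring <- close_ring(p, screw_symmetry(20.95, -1.05), n = 45)
attr(ring, "ring_radius")
#> [1] 150.0433            # Å, = 45 × 20.95 / 2π

subunit_count_from_mass(1.3e6, 1.6e4)
#> # A tibble: 1 × 2
#>   ratio n_subunits
#>   <dbl>      <int>
#> 1  81.2         81          # ~1.3 MDa polymer of 16 kDa subunits
```

Coupling classification on a filament with a planted coupling table —
nine inter-protomer pairs planted, nine recovered:

```r
asm <- build_filament(p, screw_symmetry(20.95, -1.05), 4)
tab <- synth_ec_table(asm, n_intra = 15, n_inter = 9, n_far = 8, seed = 2)
cls <- classify_pairs(asm, tab, top_n = 100, score_min = 0.5, max_dist = 12)
coupling_summary(cls)
#> # A tibble: 1 × 4
#>   n_analysed n_inter n_intra n_excluded
#>        <int>   <int>   <int>      <int>
#> 1         32       9      15          8
```

A noisy dithionite-quench trace with 40% planted permeability:

```r
tr <- synth_trace(permeability = 40, noise_sd = 0.02, seed = 3)
liposome_permeability(tr)
#> # A tibble: 1 × 4
#>   f_initial f_dit f_triton permeability
#>       <dbl> <dbl>    <dbl>        <dbl>
#> 1      1.01 0.309   0.0233         41.9
```

And SMLM morphometrics of a simulated pyroptotic field (large,
branched, elongated clusters):

```r
locs <- synth_localizations(field_components("pyroptotic"), seed = 4)
cl <- cluster_localizations(locs, eps = 50, min_pts = 10)
glance(summarize_field(cl, field_area = 100))
#> # A tibble: 1 × 7
#>   n_clusters clusters_per_area noise_fraction n_locs median_rg median_ecc ...
#> 1         21              0.21         0.0200   8562      299.       3.31
```

Median cluster Rg of ~300 nm and Ecc of ~3.3 are what the branched
micrometre-scale morphology produces, versus ~55 nm and ~1.2 for the
untreated preset (`field_components("untreated")`).

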