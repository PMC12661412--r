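# idkit — nanodosimetric ionization detail and cluster dose

`idkit` is an R toolkit for computational radiobiology research on
ion-beam radiotherapy. It implements the chain of quantities that connects
nanoscale ionization clustering to millimetre-scale treatment-planning
voxels:

* **Nanoscale scoring.** Ionization events from a primary particle history
  are grouped inside a dense lattice of cylindrical sampling volumes
  (2.3 nm × 3.4 nm, the size of a 10-base-pair DNA segment) packed into a
  100 nm water cube. The event count per occupied cylinder is the ionization
  cluster size ν; accumulated per unit primary track length this gives the
  frequency ionization cluster size distribution *f(ν)* (nm⁻¹).
* **Ionization parameters.** The tail sums
  *F_k = Σ_{ν≥k} f(ν)* — clusters of *k* or more ionizations per unit track
  length — collapse *f(ν)* into the scalars used downstream (*k* = 1…10).
* **Adaptive lookup database.** *F_k(E)* records per particle class
  (species from electrons and protons up to Ar ions, energies in MeV or
  MeV/u) on an adaptively spaced energy grid: adjacent grid energies differ
  by at most 5% in *F₅…F₇*, which keeps linear-interpolation errors at
  intermediate energies below 1%.
* **Macroscale scoring.** Condensed-history step logs are converted into
  voxel-averaged *I_p = Σ t·I_p / Σ t* and cluster dose
  *g = φ · I_p / ρ₀* (pg⁻¹) by dividing each step into substeps at the
  midpoints between database energies — so parameter variation along a step
  (largest near the end of range) is captured instead of being frozen at
  the prestep energy.
* **Survival association.** Cluster-dose survival data are fitted jointly
  with one linear-quadratic curve *ln S = −αg − βg²* per candidate *F_k*;
  the definition with the lowest RMS ln-survival residual is the preferred
  ionization parameter.

Because real inputs come from track-structure and condensed-history Monte
Carlo engines, the package ships two first-class synthetic modules — an
analytically tractable toy track generator and a 1D power-law Bragg/SOBP
phantom — so the entire pipeline runs and is testable without any external
code.

## Worked example

```r
library(idkit)

# Nanoscale geometry: maximal packing of DNA-segment-sized cylinders
lat <- build_cylinder_lattice(100, 2.3, 3.4, 1.15)
lat
#> <cylinder lattice> 53621 cylinders (43 x 43 x 29 grid)
#>   cube 100 nm, cylinders 2.3 nm diameter x 3.4 nm, row shift 1.15 nm
#>   fill fraction 75.7%

mean_source_path(radius = 17)        # mean path inside the 34 nm source sphere
#> [1] 12.75
primary_termination_budget(15, 10)   # allowed energy loss, 15 MeV over a 10 MeV gap
#> [1] 0.05

# Database on adaptive 5% grids from synthetic parameter curves
db <- build_id_database(synthetic_ip_curves(c("p", "C", "O")))
db
#> <id database> 3 species, nu_max 10
#>   p   301 energies in [0.1, 230] MeV
#>   C   307 energies in [0.5, 425] MeV/u
#>   O   309 energies in [0.5, 510] MeV/u

# Macroscale: carbon pencil beam through a 1D water phantom
steps <- transport_1d(beam_spec("C", 180, 1, n_histories = 10),
                      stopping_model(), n_voxels = 60, voxel_mm = 1)
g <- cluster_dose(score_steps(steps, db, mode = "substep"))
peak <- which.max(g$g_F5)
g$g_F5[peak]                         # cluster dose at the Bragg peak, pg^-1
#> [1] 2.442003e-07
```

The peak F₅ cluster dose exceeds the plateau value (4.6 × 10⁻⁸ pg⁻¹ at
5 mm) about five-fold, and scoring the same steps with the legacy
single-prestep lookup (`mode = "prestep"`) gives a 5% lower peak — the
substep decomposition picks up the parameter growth across each step's
energy span. The absolute numbers are tied to the synthetic curves and the
10-history fluence; the ratios are the physics.

The command-line wrapper exposes the same pipeline
(`system.file("cli", "idkit", package = "idkit")`): subcommands `pack`,
`gen-tracks`, `score-nano`, `build-db`, `db-validate`, `phantom`,
`score-macro`, `fit-survival`.

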