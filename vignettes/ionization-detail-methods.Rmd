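---
title: "Ionization detail from nanoscale clusters to voxel cluster dose: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionization detail from nanoscale clusters to voxel cluster dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idkit)
```

# The quantities

Nanodosimetry characterizes a radiation field by where its ionizations fall,
not only by how much energy it deposits. When ionizations are scored inside
volumes the size of a short DNA segment, the *ionization cluster size* $\nu$
— the number of ionizations one primary particle and its descendants produce
inside one sampling volume — correlates with the complexity of the DNA
damage the track can cause. Accumulated over many primaries and normalized
per unit primary track length, the cluster sizes form the frequency
ionization cluster size distribution $f(\nu)$ (units nm$^{-1}$), an
intensive quantity independent of fluence.

Scalar *ionization parameters* collapse $f(\nu)$ for use at the macroscale.
The family used throughout this package is the tail sum

$$F_k = \sum_{\nu \ge k} f(\nu), \qquad k = 1, \dots, 10,$$

the number of clusters of $k$ or more ionizations per unit track length.
$F_k$ is non-increasing in $k$ by construction; `compute_Fk()` implements the
operator and every stored or interpolated record is checked against this
invariant.

Two macroscopic quantities connect the nanoscale database to
treatment-planning voxels. The voxel-averaged parameter is the
track-length-weighted mean over all charged-particle classes $c$ seen in
voxel $j$,

$$ I_p^{\varphi_j} = \frac{\sum_c t_j^c\, I_p^c}{\sum_c t_j^c}, $$

and the *cluster dose* is its fluence-weighted, mass-normalized form

$$ g_j^{(I_p)} = \phi_j\, I_p^{\varphi_j} / \rho_0 , $$

with units of inverse mass (pg$^{-1}$): the number of clusters of $\ge k$
ionizations produced per picogram of tissue in the voxel. Cluster dose
scales linearly with fluence; the voxel average does not. Both behaviours
are asserted as properties in the test suite.

# Nanoscale geometry

The simulation volume is a 100 nm water cube densely packed with Z-aligned
cylinders of 2.3 nm diameter and 3.4 nm length (the size and shape of a
10-base-pair DNA segment). The packing is deterministic: layers along Z at
pitch equal to the cylinder length, rows along X stacked along Y at pitch
equal to the diameter, and every other row offset by one radius along X.
With the first centre at $(-50 + 1.15,\ -50 + 1.15,\ -50 + 1.7)$ nm this
gives $\lfloor 100/2.3\rfloor = 43$ columns, 43 rows and
$\lfloor 100/3.4 \rfloor = 29$ layers — $43 \times 43 \times 29 = 53\,621$
cylinders occupying 75.7% of the cube.

One subtlety is worth stating explicitly. A full 43-column shifted row needs
$42 \times 2.3 + 1.15 + 2.3 = 100.05$ nm of width, 0.05 nm more than the
cube provides. The package keeps the full column count in shifted rows —
the only registration consistent with the printed count above — and
documents that shifted-row cylinders may protrude beyond one face by at most
`row_shift` minus the axial margin (0.05 nm here, i.e. 2% of a radius).
The alternative (dropping the last cylinder of every shifted row) changes
the count by more than 1% and was rejected. The exhaustive placement oracle
in the test suite uses the same acceptance rule and independently verifies
the pairwise no-overlap invariant.

Containment is closed ($\le$) on both the radial and axial boundary.
Cylinders in the same row touch, so the tangent point between two
neighbours belongs to both under this convention; `locate_event()` resolves
such measure-zero ties to the lower cylinder index, and the linear-scan
oracle in the tests uses the same rule, so index-structure lookups and brute
force agree point for point.

The particle source is a 34 nm vacuum sphere at the centre of the cube (ten
times the largest sampling-volume dimension). Sampling volumes intersecting
it are removed (`exclude_source_overlap()`, conservative solid-distance
test) *after* the packing count is taken. The mean path from a uniform
interior point of the sphere to its surface along an isotropic direction is
$3R/4 = 12.75$ nm; `mean_source_path()` provides both the closed form and a
Monte Carlo estimate, and track lengths inside the source sphere are always
excluded from the $f(\nu)$ normalization.

# Transport bookkeeping rules

Three rules keep database entries mutually consistent:

* **Primary termination.** A database entry must be nearly monoenergetic.
  A primary is dropped once its cumulative energy loss exceeds 1% of the gap
  to the next lower database energy (`primary_termination_budget()`;
  0.05 MeV for a 15 MeV primary above a 10 MeV neighbour). This prevents a
  single primary from contributing clusters to the energy range covered by
  the neighbouring entry.
* **Secondary cutoffs.** Secondaries below the condensed-history production
  threshold (0.054 MeV electrons, 1.56 MeV protons) are transported and
  scored here, because a macroscale code would never create them
  explicitly. Secondaries at or above the threshold are terminated here:
  they carry their own database class at macroscale, and scoring them twice
  would double-count. Secondaries heavier than protons are always terminated
  (their transport below 0.5 MeV/u belongs to the macroscale code).
* **Boundaries.** Periodic re-entry of escaping secondaries
  (`apply_pbc()`: reflection of the exit point through the cube centre,
  direction and energy unchanged) is implemented but off by default; for
  histories contained in the cube it provably changes nothing, which the
  suite asserts on contained toy tracks.

# The toy track generator

`generate_history()` is **not** a physics model and is documented as such.
Primaries start uniformly in the source sphere with isotropic directions;
primary ionizations are a Poisson process along the ray; secondaries branch
at Poisson points and deposit a shifted-geometric number of ionizations at
exponential distances; positions can be jittered. Every piece is chosen for
tractability: the Poisson-thinning closed form
$F_1 = (1 - e^{-\lambda L})/L$ for an axial track (`closed_form_f1()`) is an
exact oracle for the whole scoring chain, and the suite checks the Monte
Carlo tally against it within three standard errors. The default rate
$\lambda_p(E) \propto 1/E$ reproduces the qualitative LET trend (slower
particles ionize more densely), and a dense-track configuration reproduces
the drop/plateau shape of high-LET cluster-size distributions. What passing
these tests shows is that *scoring* is correct — not that the generator
resembles any real track structure: there is no straggling, no realistic
delta-ray spectrum, no chemistry.

# The database: adaptive binning and interpolation

Database energies per species span the ranges in `id_species_table()`
(1 keV–1 MeV electrons, 0.1–230 MeV protons, 0.5 MeV/u up to species-specific
maxima for ions). The grid constructor marches upward from the minimum
energy: the next grid energy is the largest energy at which none of
$F_5, F_6, F_7$ has changed by more than 5% relative to the previous grid
point (maximum over the three; the spec of the criterion does not fix the
denominator, and this package measures change against the previous,
lower-energy grid value). The boundary is found by bisection to relative
tolerance $10^{-6}$ and nudged below the criterion so the accepted pair
satisfies it with $\le$. For a pure power law $c/E$ this yields adjacent
energies in ratio $1/0.95$, a closed form the tests pin down.

Interpolation between grid records is linear in energy, not log-energy: on
a 5% grid the difference between the two conventions is below the
interpolation error itself ($\sim 0.1\%$), and linear is what a
condensed-history code does cheaply. Queries outside the grid clamp to the
boundary record — particles below the lowest database energy still
contribute with the boundary parameter rather than disappearing. On the
synthetic curves, the measured interpolation error at $10^4$ random
energies per species stays below 0.1%, comfortably inside the 1% design
bound.

Isotopes are not stored: `resolve_isotope()` maps any $(Z, A)$ to the
stable-ion record for that $Z$. Because ion energies are keyed per nucleon,
no energy rescaling is applied. `isotope_relative_difference()` implements
the percentage comparison used to justify the policy.

The on-disk format is a flat CSV (`species,Z,A,energy,unit,nu,f_per_nm,
se_per_nm`) with a `#`-prefixed YAML header — diffable, greppable, and
lossless (numbers at 17 significant digits); `read_db()` validates
monotone grids and non-negative frequencies and names the offending row.

# Substep scoring at the macroscale

A condensed-history step from $E_{\rm pre}$ down to $E_{\rm post}$ may span
several database energies, and the parameter can change substantially over
it, especially near the end of range. The substep rule:

1. Take the midpoints of all *adjacent database energy pairs* and keep those
   that fall strictly inside $(E_{\rm post}, E_{\rm pre})$ — including
   midpoints formed with the grid neighbours just outside the step. These
   midpoints are the substep boundaries.
2. Every interior substep encloses exactly one database energy; its
   parameter is the stored value there, no interpolation.
3. The first and last substeps interpolate at their own midpoint energies,
   $(E_{\rm pre} + E_{a'})/2$ and $(E_{z'} + E_{\rm post})/2$ — even when
   their interval happens to contain a database energy. With three database
   energies inside a step this single rule produces five substeps when the
   exterior midpoints fall inside the step and three when they do not.
4. Track lengths are proportional to the energy spanned (constant energy
   loss per unit track length within the step), with the last length set by
   subtraction so the total equals the step length exactly.

Degenerate steps ($E_{\rm pre} = E_{\rm post}$, e.g. purely elastic) form a
single substep at the prestep energy. The legacy method — one lookup at the
prestep energy for the whole step — is retained as `mode = "prestep"` purely
for differencing; since the parameter grows toward low energy, the substep
method scores more clusters at the end of range, and the suite asserts both
the sign of that difference on the fixture and quantitative agreement of
substep scoring with a fine-sampling integrator (a $10^4$-point mean of the
interpolated parameter over the step's energy interval) within the 1%
interpolation bound.

Fluence is estimated with the standard track-length estimator
$\phi_j = \sum t / V_j$ (the defining operation is never stated alongside
the formalism, so the package commits to this standard choice); all charged
particles in the step log count toward it, with sub-range energies clamped
rather than dropped. Track lengths scale with local density relative to the
database reference density $\rho_0$. Unit bookkeeping for cluster dose:
$t\,[\mathrm{mm}] \times I_p\,[\mathrm{nm^{-1}}]$ gives $10^6$ clusters, a
1 mm$^3$ voxel of unit density weighs $10^9$ pg, hence
$g = \Sigma t I_p / (V \rho_0) \times 10^{-3}$ pg$^{-1}$.

# The 1D phantom fixture

`transport_1d()` is a constant-stopping-power-per-step marcher on a
power-law range-energy relation $R = \alpha (A/Z^2) E^{p}$
(Bragg-Kleeman form; $\alpha = 0.022$ mm, $p = 1.77$ approximates protons
in water, and the $A/Z^2$ scaling gives carbon a third of the proton range
at equal energy per nucleon). Steps are capped at 1 mm and at voxel
boundaries; transport stops below 0.5 MeV(/u) with the residual deposited in
place. There is no straggling or scattering, so a track at a given energy is
deterministic; histories at the same energy share one simulated track, and
spread-out peaks are built from a weighted energy spectrum
(`sobp_weights()` computes flat-plateau weights by non-negative least
squares on the per-energy deposition profiles; range spacing of one voxel
keeps plateau ripple below a few per mill on the fixture). The fixture's
job is end-of-range step structure, not dosimetry: no nuclear
fragmentation, no lateral transport, primaries only.

The synthetic parameter curves that stand in for a simulated database
(`synthetic_ip_curves()`) are labelled synthetic throughout:
$F_k(E) = N(E)\, q(E)^{k-1}$ with $N = c_0 |Z|^{1.6} E^{-0.85}$ and
$q = 0.15 + 0.75\, x/(x + 5)$, $x = Z^2/E$. They are positive, smooth,
monotone decreasing in energy, increasing with atomic number, and
non-increasing in $k$ — the qualitative structure the method needs — but
their absolute values are arbitrary, which is why the package's acceptance
checks on macroscale differences are sign and invariance tests, not
magnitude reproductions. One consequence of strict monotonicity worth
noting: toward the very bottom of the proton range the synthetic curves are
much steeper than physical ones, so the fixture's substep-vs-prestep
enhancement at the distal edge is far larger than anything a real database
would produce; only its sign and its growth toward the end of range are
meaningful.

# Survival association

For each candidate definition $F_k$, all points of a dataset are fitted
jointly with one linear-quadratic curve through the origin,
$\ln S = -\alpha g - \beta g^2$, by least squares in $\ln S$ space
(optional inverse-variance weights; $\beta$ constrained non-negative,
$\alpha$ free). "Mean residual" is not defined precisely in the tradition
this follows, so the package reports both the RMS and the mean absolute
ln-survival residual and uses the RMS — differentiable and
variance-interpretable — to drive selection; `select_preferred_ip()`
returns the argmin and reports ties rather than breaking them silently.
Rescaling all doses by a constant rescales $\alpha, \beta$ and leaves every
residual unchanged, so the global fluence calibration of a dataset cannot
influence which $k$ wins.

The synthetic validation study mirrors how the underlying experiments are
run: cell samples at six depths along five pristine beams (p 150, p 80,
C 250, C 120, O 300 MeV(/u)), each position irradiated at four fluence
levels set so that its *absorbed dose* — an energy-deposition proxy the
experimenter can measure without knowing any $F_k$ — reaches fixed targets.
This matters: sampling one fluence per position leaves most points at
negligible dose, where all candidate definitions fit equally well and noise
decides the argmin. With dose-controlled levels every point is informative,
and with survival generated from $F_5$ plus 2% lognormal noise the true
definition is recovered in 100 of 100 seeded datasets (the acceptance
criterion requires 95%). The noiseless wrong-$k$ residuals (0.05–0.58)
against the 0.02 noise floor quantify the margin.

# Problem sizes and numerical choices

The test suite builds all fixtures in code at run time. Sizes were chosen
so the full suite runs in about a minute: packing oracles on 10–20 nm
cubes, $2 \times 10^3$–$10^4$ points for lookup-equivalence checks,
$2 \times 10^4$ axial histories for the Poisson oracle ($10^6$ samples for
the mean-path Monte Carlo), $10^5$ random steps for the track-length
conservation sweep, 100 seeded survival datasets. Statistical assertions
use three-standard-error bands from the tally's own batch uncertainties
(ten batches, mirroring the ten-independent-simulations recipe) or
chi-square goodness-of-fit at $p > 10^{-3}$, so they are stable across
seeds while retaining power.

Known limitations, beyond those already flagged: the package contains no
track-structure physics, so absolute database values are out of reach by
design; cluster-size distributions from the toy generator have no claim to
realism; the phantom is one-dimensional and primary-only; and the
survival module assumes the LQ form that it fits.
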