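---
title: "Methods: integral-equation hydration analysis with rismhydra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integral-equation hydration analysis with rismhydra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the
known limitations.

## The model

RISM (Reference Interaction Site Model) theory describes a molecular
liquid through site–site correlation functions. The package implements
both stages of the standard two-stage scheme for solvation of a rigid
solute at infinite dilution:

1. **Bulk solvent (1D, XRISM).** For a rigid n-site water model the
   matrix Ornstein–Zernike equation
   `h = ω c ω + ω c ρ h` (distinct-site form, molecular density ρ on
   the diagonal) is closed with the Kovalenko–Hirata (KH) or HNC
   relation and iterated to a fixed point in the short-range direct
   correlations. The product is the solvent susceptibility
   `χ_αβ(k) = ω_αβ(k) + ρ h_αβ(k)` per distinct site-type pair, with
   `ω_αβ(k) = sin(k l_αβ)/(k l_αβ)` the rigid-molecule intramolecular
   correlation. Site-type symmetry (the two water hydrogens) is
   collapsed: the 3D stage convolves
   `h_β(k) = Σ_α m_α c_α(k) χ_αβ(k)` with the multiplicities `m_α`.
2. **Solute in solvent (3D).** On a Cartesian grid around the fixed,
   fully parameterized solute (coordinates, partial charges,
   Lennard-Jones terms), the 3D OZ equation above is closed with the KH
   relation `g = exp(d)` for `d ≤ 0`, `g = 1 + d` for `d > 0`,
   `d = −u/kT + h − c`. The branches meet at `d = 0` with matching
   value and slope, and `g ≥ 0` by construction.

Assumptions inherited from this framework: the solute is rigid (no
conformational response), the solvent is at equilibrium and infinite
dilution, and all structure is expressed as site densities — there are
no discrete water molecules, only distribution functions.

### Electrostatics

Site–site and solute–site Coulomb interactions are Ng-split with an
`erf`/`erfc` pair at splitting parameter η (default 1.0 Å⁻¹ in 1D,
0.5 Å⁻¹ in 3D): the short-range `erfc` part joins the LJ term on the
grid, while the long-range part of the direct correlation,
`ĉ_l(k) ∝ −q q 4π e^{−k²/4η²}/k²`, is carried analytically in k-space.
The `k = 0` mode is dropped, which for a net-charged solute is
equivalent to a uniform neutralizing background — relevant for
proteins, which typically carry net charge at physiological pH; this
convention is recorded in the run parameters. The solvent stage is
plain XRISM without a dielectric-consistency correction, so the bulk
dielectric constant of the model is an outcome, not an imposed value;
the catalogue stores the experimental value for provenance only.

### Water models

The catalogue ships SPC/E and `mspce`, SPC/E with small hydrogen LJ
cores (σ_H = 1.0 Å, ε_H = 0.0545 kcal/mol). Bare-charge hydrogens make
the site–site closure singular at the O–H contact; the small hydrogen
core is the conventional regularization in site–site integral-equation
work, and those are the hydrogen parameters long used with this family
of models. Ambient conditions are fixed at T = 298.15 K and
0.997 g/cm³ (0.03332 molecules/Å³).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| 1D radial grid | 2¹³ points, dr = 0.01 | Å | resolves the O–H contact peak; k-range (≈314 Å⁻¹) far exceeds any 3D lattice Nyquist |
| 1D tolerance | 10⁻⁸ | max residual | tighter than the 3D stage so susceptibility error never dominates |
| 3D spacing | 0.25 | Å | resolves the first hydration shell; coarser values are accepted for desk-scale runs and recorded in provenance |
| buffer | 12 | Å | solvent becomes bulk-like well inside the box; boundary mean |g−1| < 10⁻² |
| MDIIS vectors | 5 | — | standard subspace size; 1 gives damped Picard |
| damping | 0.7 (3D), 0.5 (1D) | — | stable for the shipped models and toy solutes |
| 3D tolerance | 10⁻⁶ | max residual on c | suffices for ~10⁻³ accuracy in derived quantities |
| core cap | 40 | kT | `exp(−40)` underflows gracefully; avoids inf−inf inside hard cores |
| shell bin | grid spacing | Å | finer bins would alias the n′ derivative |
| H-bond radii | 2.6 (acceptor···Hw), 3.5 (donor···Ow) | Å | standard H-bond contact geometry; configurable |
| SASA | probe 1.4 Å, 960 points/atom | | water-sized probe; doubling the point count moves totals by < 0.3% |

## The shell-boundary criterion

Cutting the shell at a fixed distance makes hydration numbers depend
strongly on the cutoff choice and the protein's shape. Instead the
boundary is read off the density itself: with
`n(r_cut) = ρ_Ow Σ_{d ≤ r_cut} g_Ow ΔV` the cumulative water count and
`n′` its central finite difference on bins no finer than the grid
spacing, the *shell density* is `n′` normalized by the measured volume
of each distance shell (voxel count per bin × voxel volume per bin
width). This normalization makes a bulk field give exactly 1 and
cancels box-shape artifacts. The boundary is the first local minimum of
the shell density after its first local maximum above 1, refined by a
parabolic fit through the three bracketing bins; a minimum that does
not dip below 1 is flagged as a weak shell, and a featureless profile
raises a no-boundary condition rather than returning a number.

"Distance to the solute" defaults to nearest atom *center*; a
vdW-surface variant (center distance minus atom radius) is selectable
and recorded per run. Center-based first-minimum distances are the ones
consistent with single-water-layer shell thicknesses of 3–4 Å.

Pocket water counts attribute every first-shell voxel to its nearest
solute residue (Voronoi-style). This is parameter-free and partitions
the shell exactly, so counts over a full residue partition sum to the
total hydration number to machine precision. The shipped pocket
catalogue defines the two Sudlow drug-binding sites of serum albumin by
their literature residue lists.

The H-bonded fraction integrates `ρ_Hw g_Hw` over spheres around solute
N/O acceptors and `ρ_Ow g_Ow` over spheres around donor heavy atoms
(N/O carrying a hydrogen within 1.25 Å), divided by the total hydration
number and clamped to [0, 1] with a warning. The criterion is
geometric and configurable; equilibrium site densities cannot resolve
individual bond topologies, so this is a density-weighted estimate, not
a bond count.

## Synthetic-data generator

The generator exists so every stage is testable without downloads:

* **toy solutes** — a neutral LJ sphere, a charged ion, a rigid water
  treated as solute, and seeded random polyatomics (zero net charge by
  construction, one residue per atom so residue partitions are
  non-trivial); byte-reproducible from (recipe, seed);
* **painted fields** — analytic radial profiles evaluated on the same
  distance field the analysis uses, giving integrals with known 1D
  quadrature values;
* **synthetic shell profiles** — two-Gaussian profiles (enhanced first
  shell, depleted trough — the physical signature the boundary
  criterion expects) with analytic extrema for recovery tests.

What it does *not* emulate: protein-scale heterogeneity, rugged
molecular surfaces, buried cavities, or any specific protein. Passing
the toy-scale tests demonstrates the correctness of the operators
(transforms, closures, integrals, boundary detection), not the accuracy
of RISM for any particular biomolecule. Protein-scale runs require an
externally prepared, complete, hydrogenated structure (PQR, or PDB plus
a parameter table and an explicit per-residue protonation file — the
package deliberately calls no web service, for reproducibility) and are
hours-scale at 0.25 Å spacing.

## Numerical choices

* Radial transforms via a type-I fast sine transform on grids that
  exclude the origin; the k → 0 Coulomb divergence never appears on a
  grid point and is carried analytically.
* 1D iteration starts from the Mayer function `e^{−βu} − 1`; 3D from
  `c = −u_long` (short-range part zero), removing the dominant slow
  mode.
* MDIIS minimizes the residual norm in the subspace of recent iterates
  with a Σa = 1 constraint, restarts from the best iterate when the
  residual grows 10× beyond the best seen, and falls back to a damped
  step when the subspace becomes ill-conditioned.
* 3D grid shapes are rounded up to even 7-smooth sizes for the FFT; the
  box covers solute extents plus buffer, and a configurable memory
  ceiling turns oversized requests into an explicit error stating the
  required bytes.
* Shell bins are right-closed (`d ≤ j·bin`), matching the `d ≤ r_cut`
  convention of the hydration-number integral exactly.
* Hard cores are capped at 40 kT before exponentiation; grid points
  coincident with atom centers are floored, never NaN.
* Ties and degenerate profiles: parabolic refinement of the boundary is
  clamped to one bin; profiles with fewer than three usable bins, no
  peak above 1, or no subsequent minimum raise typed conditions.

Verification problem sizes: the reference 3D checks run a single LJ
sphere on a 64³ box at 0.5 Å spacing against the production-quality
water susceptibility (2¹³ points, dr = 0.01 Å); oracle-equivalence
checks use 8³ grids (direct O(N²) convolution), 20³–64³ grids
(distance and quadrature oracles), and 50 seeded profiles for boundary
recovery. These sizes make the full suite and the acceptance script
minutes-scale on one core while leaving every operator exercised at
production settings except the grid extent.

## Design decisions on open points

* **Solvent stage closure:** the low-density Mayer-limit check uses
  HNC, which is exact in that limit; KH linearizes the attractive well
  and leaves an O((βu)²) residual there by construction.
* **Hydrogen LJ parameters of the modified water model:** taken as the
  conventional σ_H = 1.0 Å, ε_H = 0.0545 kcal/mol regularization (see
  above).
* **Chain selection for multi-copy crystal structures:** the PDB reader
  takes an explicit `chain` argument (serum albumin's 1AO6 contains two
  copies; chain A is the conventional choice) and the selection is part
  of run provenance.
* **Protonation:** an explicit per-residue protonation file redirects
  parameter-table lookups (e.g. HIS → HID); no pKa computation.
* **Disulfides:** SSBOND records (or an explicit pair list) retype
  bridged cysteines to the CYX entry before lookup.
* **Units:** Å and kcal/mol internally; configs accept `nm`/`A`
  suffixes; reports print thickness in both Å and nm.

## Limitations

* No solvation free energies, partial molar volumes, or energy
  decompositions; no water dynamics (residence times are outside
  equilibrium theory); no discrete water placement.
* Plain XRISM solvent: the model's dielectric constant is not imposed,
  so long-range dielectric response is approximate.
* The KH closure's linearized enhancement branch systematically softens
  high-density peaks relative to HNC where HNC converges.
* Periodic FFT images contribute small long-range artifacts; the
  buffer default keeps the boundary deviation of g below 10⁻², but
  strongly charged solutes in small boxes deserve a larger buffer.
* Pure-R FFT solves are minutes-scale for 64³–128³ grids;
  protein-scale production grids (≥ 256³) are feasible but slow — this
  package prioritizes transparency and testability of the method over
  raw throughput.
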