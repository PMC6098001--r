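# lamellaR

Structural analysis of amyloid-peptide aggregation in oriented lipid
membranes, from x-ray diffraction, scanning transmission x-ray microscopy
(STXM) and head-group coordinate surfaces.

## The scientific problem

Short amyloid-β fragments partition into anionic lipid bilayers and, at
high concentration, condense into nanoscale clusters with the cross-β
motif: extended peptide strands 4.7 Å apart (reflection at
q ≈ 1.35 Å⁻¹), stacked into sheets ~9–10 Å apart (q ≈ 0.7 Å⁻¹).
Membrane-active small molecules change bilayer thickness and stiffness,
and thereby the *hydrophobic mismatch* between cluster and bilayer — which
in turn sets the size and amount of the aggregates. Quantifying that chain
of effects requires several measurements on one sample series:

* **Out-of-plane diffraction** — lamellar period d_z = 2π/Δq_z from the
  Bragg series; electron density ρ(z) ∝ Σ ν_n |F_n| cos(2πnz/d_z) with
  |F_n| = (I_n·q_n)^½ (Lorentz correction for oriented stacks); head-head
  distance d_HH and hydration-water layer d_W = d_z − d_HH.
* **In-plane diffraction** — area per acyl tail A_T = 8π²/(√3 q_T²) from
  the chain-correlation peak; rectangular head-group cell (a = 4π/q₂,
  b = 4π/q₁); cross-β domain size from Scherrer broadening
  L = 2πK_s/Δq_FWHM (K_s = 0.9); cluster volume fraction φ from the
  peptide/lipid signal ratio.
* **Orientation** — lipid tilt from the azimuthal chain-arc offset;
  membrane alignment via the Hermans function f = (3⟨cos²δ⟩ − 1)/2
  (f = 1 aligned, f = 0.25 random).
* **STXM** — OD = −ln(I/I₀), two-component spectral unmixing of the C 1s
  stack (lipid vs peptide π\* separated by 0.3 eV), and cluster
  morphometry (equivalent-circle diameters).
* **Mismatch model** — ΔG(R) = −πR²g₀ + 2πRσ with line tension
  σ = ½Ku², u = w − w₀, K = √2·(K_t³K_b/w⁶)^¼; the stationary radius is
  R\* = σ/g₀, so thinner/softer membranes (smaller σ) mean smaller
  clusters.
* **Monge curvature** — K = −∇·(∇δ/√(1+|∇δ|²)) ≈ −∇²δ of the head-group
  height field; depressions carry negative curvature.

A synthetic-data module generates every input class (1D scans, 2D
reciprocal-space maps, STXM stacks, surfaces) with the ground truth
embedded, so the entire pipeline is testable without instrument data.

## Worked example

Analyse two synthetic conditions — a pure membrane and one loaded with
20 mol% peptide — generated at the published reference parameters:

```r
library(lamellaR)
cfg <- list(seed = 1, samples = list(
  list(name = "membrane",        molecule = "none", abeta_mol_pct = 0),
  list(name = "membrane+abeta",  molecule = "none", abeta_mol_pct = 20)))
res <- run_pipeline(cfg)
res$table
```

```
         sample  d_z   A_T lipid_tilt     H   d_W  d_HH     L   phi
       membrane 69.5 22.54      21.03 96.79 27.75 41.75    NA    NA
 membrane+abeta 55.2 23.53      18.18 75.30 16.28 38.92 21.29 0.137
```

Reading the rows: adding the peptide collapses the lamellar period from
69.5 to 55.2 Å (thinner hydration layer d_W), dilates the chain lattice
(A_T up ~1 Å²), and degrades stack alignment (H from ~97 to ~75). The
peptide rows gain two cross-β columns: 21 nm coherent domains occupying
~14% of the scattering signal — with 20 mol% peptide added, that is
`aggregated_fraction ≈ 0.7`, i.e. about 3/4 of the peptide sits in
clusters. Every number is a fit to the synthetic data; the generator's
ground truth mirrors the published reference table
(`reference_structure_table()`).

Ranking drug conditions by mismatch line tension (bilayer thicknesses
from the peptide-loaded reference rows, any common cluster thickness
`w0`):

```r
rank_conditions(c(curcumin = 36.9, melatonin = 37.6, ASA = 41.0), w0 = 30)
```

```
 condition    w sigma
  curcumin 36.9 0.150
 melatonin 37.6 0.177
       ASA 41.0 0.326
```

σ_curcumin < σ_melatonin < σ_ASA: the thinnest membrane has the cheapest
cluster boundary, consistent with curcumin shrinking/dissolving clusters
and ASA growing them.

There is also a command-line front end
(`inst/scripts/lamellar-cli`) with `generate`, `integrate`, `analyze`,
`stxm`, `curvature`, `model` and `report` subcommands.

## Layout

* `R/` — implementation (reciprocal-space reductions, lamellar/in-plane/
  orientation analyses, STXM mapping, mismatch model, Monge curvature,
  synthetic generators, pipeline + CLI)
* `tests/testthat/` — unit, property and acceptance suites
* `vignettes/lamellaR-methods.Rmd` — the methods vignette (models,
  conventions, tolerances, limitations)
* `scripts/acceptance.R` — the acceptance report
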