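---
title: "Methods: models, conventions and numerical choices in lamellaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and numerical choices in lamellaR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

lamellaR quantifies the structure of oriented lipid multibilayers and of
the cross-β peptide clusters that form inside them. This vignette is the
package's own account of the science it implements: the models and their
assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical decisions taken
where the underlying protocols leave freedom.

## Reciprocal-space geometry

All reductions share one coordinate convention. A two-dimensional map
stores intensity over in-plane momentum transfer $q_\parallel$ and
out-of-plane $q_z$ (both Å⁻¹). Derived per pixel:
$Q = (q_z^2 + q_\parallel^2)^{1/2}$, the azimuthal angle $\gamma$
measured from the $q_\parallel$ axis (equator), and the meridional angle
$\delta = 90^\circ - \gamma$ from the $q_z$ axis. Interfaces take
degrees; radians are internal only. Real-space spacings are always
$d = 2\pi/Q$, with `q_to_d()`/`d_to_q()` the single source of truth. We
note the well-known bookkeeping wrinkle that the inter-sheet reflection
at 0.7 Å⁻¹ converts to 8.98 Å although it is conventionally quoted as
"~10 Å"; the package reports the exact conversion.

**Wedge integration** bins pixels with $\gamma$ in a half-open wedge by
$Q$ and divides each bin by its pixel count. Because bins partition the
selected pixels, the pixel-count-weighted recombination of disjoint
wedges equals the full-map integral exactly; this conservation is a test
invariant. The default analysis wedge is 30–90°, excluding low-angle
pixels that suffer strong absorption in reflection geometry.

**Azimuthal profiles** sum pixels in a $Q$ annulus into half-open
angular bins (ties on bin edges go to the lower bin). Two knobs matter
in practice and are worth stating:

* `normalize = "count"` returns the mean rather than the sum per bin.
  Where the annulus leaves the map (large $Q$, high $\gamma$), summed
  bins shrink artificially; the mean does not.
* `drop_incomplete` removes bins with fewer than 80% of the median pixel
  count — bins that sample only part of the annulus would otherwise bias
  any fit through them.

**Peak fitting** uses least squares of a Lorentzian (fluid-phase
features, following the standard treatment of disordered chain
scattering) or Gaussian (finite-size features: Bragg orders, gel
doublet, cross-β) plus a *linear* background per window — the simplest
defensible background model, since none of the protocols specify one.
Intensities are normalised to the window maximum before optimisation
(the Levenberg-style `port` optimiser is poorly scaled otherwise), and a
Gauss–Newton polish is applied when `port` ends with a questionable
stop code, which happens routinely at the optimum of nearly noiseless
data. Areas are computed analytically from the fitted parameters.
Non-convergence is never silent: fits carry a `converged` flag and the
optimiser message. Overlapping features (the cross-β strand at
1.35 Å⁻¹, the broad chain peak near 1.4 Å⁻¹, the gel doublet at
1.43/1.50 Å⁻¹, and the water correlation at 1.85 Å⁻¹) are fit
simultaneously in one window; co-fitting the water feature is what keeps
the chain-peak parameters unbiased by its tail.

## Out-of-plane analysis

The lamellar period follows Bragg's law, $d_z = 2\pi/\Delta q_z$,
estimated as $2\pi$ over the slope of the zero-intercept regression of
peak position on integer order. The regression is over-determined, so
dropping any single interior order leaves $d_z$ unchanged; residuals
beyond 0.005 Å⁻¹ flag a non-equidistant series.

Electron density is synthesised as
$\rho(z) \propto \sum_n \nu_n |F_n| \cos(2\pi n z/d_z)$ with
$|F_n| = (I_n q_n)^{1/2}$. The Lorentz exponent (1 for oriented stacks)
is configurable. The phase problem is *not* solved: signs default to the
alternating set $(-,-,+,-,+,-,+)$ characteristic of phosphatidylcholine
bilayers and can be overridden; synthetic data carry their model-derived
signs so round trips are phase-consistent.

The head-head distance $d_{HH}$ is the separation of the two dominant
density maxima (parabolic sub-grid interpolation; asymmetry beyond
1.5 Å is an error), and $d_W = d_z - d_{HH}$, so the identity
$d_z = d_{HH} + d_W$ holds *exactly by construction* on every output
row. Note that with a handful of Fourier orders, $d_{HH}$ from a
truncated synthesis carries an intrinsic truncation bias; with the
generator's density model (below) this bias stays within the package's
0.8 Å recovery tolerance for all reference geometries.

## In-plane analysis

Hexagonal chain packing gives $a_T = 4\pi/(\sqrt3\,q_T)$ and
$A_T = 8\pi^2/(\sqrt3\,q_T^2)$ (so $A_T = \tfrac{\sqrt3}{2}a_T^2$
identically). The gel head-group doublet is indexed as second-order
axial reflections of a rectangular cell, $b = 4\pi/q_1$, $a = 4\pi/q_2$.

Scherrer sizing uses $L = 2\pi K_s/(\Delta q_{FWHM} - \Delta q_{instr})$
with the shape factor fixed package-wide at $K_s = 0.9$ (the common
near-spherical-domain value; the source protocols do not state one).
Generator and analyser share the constant, so synthetic round trips are
exact up to fit noise. The instrumental width defaults to 0 and is
subtracted linearly in $q$ when supplied. The Kapton window feature at
0.35–0.45 Å⁻¹ is never inside a fit window.

The cluster volume fraction is, by default, the peptide share of the
*total* (peptide + chain) integrated signal,
$\phi = \Sigma_{pep}/(\Sigma_{pep} + A_{lipid})$: this is the
convention under which a fully aggregated 20 mol% peptide load would
contribute 20% of the signal, which is how the published accounting
(3/4 aggregated at $\phi = 15\%$) works. The plain ratio to the lipid
peak is exposed as `denominator = "lipid"` because the source figure
caption describes that normalisation; the two read identically only for
small $\phi$. The aggregated fraction is $100\phi$ divided by the added
mol%, capped at 1 with a 0.02 tolerance before the input is declared
inconsistent.

## Orientation

Lipid tilt is the offset of the chain-correlation arc from the equator:
a Gaussian plus constant is fit to $I(\gamma)$ over the 30–90° protocol
range and the absolute fitted centre is reported. Since the arc centre
(17–25°) lies below the 30° absorption cut-off, this is a tail fit; it
is exact on noiseless data but is the noisiest estimator in the
pipeline (see tolerances below). The underlying protocols never define
the $I(\gamma)\to$ tilt mapping explicitly; this convention is shared
with the generator and validated by round trip.

The Hermans orientation parameter is
$f = (3\langle\cos^2\delta\rangle - 1)/2$, with
$\langle\cos^2\delta\rangle$ the *intensity-weighted, unweighted-angle*
average over $[0^\circ, 90^\circ]$ — no solid-angle $\sin\delta$
factor. That choice is forced by the stated limits: flat
$I(\delta)$ must give $f = 0.25$ (a $\sin$-weighted average would give
$1/3$, i.e. $f = 0$). The pipeline fits a Gaussian centred at
$\delta = 0$ to the meridional profile around the *second* lamellar
order (weaker diffuse background than the first) and evaluates the
average of the fitted Gaussian by quadrature. Degenerate profiles
(delta-like or flat, or fewer than 5 bins) fall back to the direct
average of the raw profile, which reproduces the two limits exactly.
The protocol window starts at $\delta = 18^\circ$ (diffuse scattering
below); the pipeline extends the upper limit from the printed 40° to
60° — on a window that ends at 40° the Gaussian width and the constant
background are nearly degenerate for mid-width mosaics, and the
extension pins the background down without touching the protocol's
physical exclusion at low $\delta$.

## STXM mapping

Transmission converts to optical density per pixel and energy as
$OD = -\ln(I/I_0)$ (non-positive intensities are masked and counted,
never silently dropped). Two printed variants of this formula circulate
in the source material; the Beer–Lambert form above is the physically
meaningful one and is what the package implements.

Unmixing solves, per pixel, a two-component non-negative least-squares
problem against lipid and peptide reference spectra. For two components
the NNLS solution is closed-form: the unconstrained $2\times2$ solve
where it is feasible, otherwise the better of the two single-component
solutions. Weights are physical thicknesses, hence the non-negativity;
the number of clipped pixels is reported. Collinear references are
rejected by a condition-number check. The model reference spectra place
the peptide amide $\pi^*$ resonance 0.3 eV *below* the lipid ester
peak at 288.8 eV — the source states only the magnitude of the shift;
the sign follows the usual ordering of amide vs ester $\pi^*$ energies.

Morphometry binarises the peptide map (Otsu's threshold by default;
when the between-class variance has a plateau the split is taken at its
middle), labels 8-connected components with a two-pass union-find,
excludes border-touching components (their widths are censored), and
reports equivalent-circle diameters $2\sqrt{A/\pi}$ in nm. An empty map
is a valid result, not an error.

## Hydrophobic-mismatch model

Clusters are circular phase-separated domains:
$\Delta G(R) = -\pi R^2 g_0 + 2\pi R\sigma$, concave with stationary
point $R^* = \sigma/g_0$ and barrier $\pi\sigma^2/g_0$. The line
tension is the thickness-deformation cost
$\sigma = \tfrac12 K u^2$, $u = w - w_0$, with the membrane spring
constant $K = \sqrt2\,(K_t^3 K_b/w^6)^{1/4}$. Units are consistent
arbitrary units ($K_t$, $K_b$, $g_0$ are never quantified in the source
material); the module exists to *order* conditions, and the ranking is
invariant under common rescaling of the moduli. The alternative scaling
form $\sigma \propto (w-w_0)^2/w^{3/2}$ is exposed via
`formula = "scaling"`; it produces the same ordering. Because the
cluster hydrophobic length $w_0$ is never given numerically, ranking
tests assert the ordering for a grid of admissible $w_0$ below the
smallest bilayer thickness rather than for one value.

## Monge-gauge curvature

Head-group surfaces are height fields $\delta(x,y) = z - d_0$ over the
bilayer centre $d_0$ (default: the mean of the per-leaflet mean
heights; configurable). The field curvature is
$K = -\nabla\cdot(\nabla\delta/\sqrt{1+|\nabla\delta|^2})$, computed on
a regular grid by finite differences; the default small-gradient method
is the negative compact 5-point Laplacian, and the full divergence form
uses a staggered face-centred flux scheme chosen so that it reduces to
the *same* compact stencil as gradients vanish — the two methods then
differ only by the nonlinear slope correction (cubic in amplitude), not
by stencil width.

**Sign convention.** The curvature carries the sign of the central
deformation: a depression ($\delta < 0$ at its centre) has negative
curvature, matching the physical statement that peptide partitioning
imprints negative curvature on both leaflets. Consequently a Gaussian
deformation $A e^{-r^2/2w^2}$ has centre curvature $2A/w^2$, and a
quadratic section $f(x) = ax^2+bx+c$ has $K = -2a$ with touching-circle
radius $\rho = 1/|K|$. The printed section-curvature relation in the
source material ($K = f'/\sqrt{1+f'^2} \approx f''$) is typographically
garbled — the standard plane-curve curvature is
$f''/(1+f'^2)^{3/2}$ — and the package implements the standard form's
small-slope limit under the sign convention above. The quadratic is fit
to the section through the point of maximum deformation along the axis
of larger local curvature, within the contiguous half-maximum region of
a lightly smoothed copy of the section (the window must depend on the
deformation's shape, not its noise realisation, for curvature ratios
between conditions to be meaningful); a fit with $|a|$ below tolerance
reports zero curvature and infinite $\rho$ rather than failing.

## The synthetic world

The generator's defaults are the published reference conditions: each
of the eight (molecule × peptide) assays maps to a `ground_truth` whose
lamellar period, head-head distance, chain-peak position (inverted from
the printed area per tail), tilt, mosaic width (inverted numerically
from the printed Hermans parameter), domain size and volume fraction
equal the printed values. Choices the source material does not state,
fixed once:

* **Bragg orders.** Drug-free membranes carry 7 orders; peptide-loaded
  membranes 4 (the source reports that peptide strongly suppresses the
  higher orders without counting them).
* **Density model.** One period is two head-group Gaussians
  (σ = 4.5 Å) at $\pm d_{HH}/2$ minus a central methyl trough
  (σ = 6 Å, 0.8 relative amplitude). Form factors (with signs) come
  from this profile by quadrature; the widths were chosen so that the
  4–7-order truncated resynthesis locates the head maxima within the
  0.8 Å recovery tolerance for all eight reference geometries — fluid
  unsaturated bilayers genuinely have broad head-group distributions.
* **Peak shapes and widths.** Chain and water features are Lorentzian
  (half widths 0.13 and 0.15 Å⁻¹), finite-size features Gaussian;
  lamellar radial width σ = 0.0035 Å⁻¹ (floored at one grid step on 2D
  maps so peaks stay resolvable); chain-arc azimuthal width 12°.
* **Intensity and noise.** A constant plus weak power-law diffuse
  background; Poisson counting noise on scaled counts
  (`noise_scale = 0` disables it). The default count scale gives
  percent-level relative noise at the peaks, comparable to a rotating-
  anode measurement of an oriented stack.
* **Cross-β amplitude accounting.** The two cross-β Gaussians share
  (50/50) a total area of $\phi/(1-\phi)$ times the chain-peak area, so
  the recovered total-share volume fraction equals $\phi$ by
  construction. On 2D maps the chain-arc amplitude is normalised by the
  wedge-average azimuthal factor so the same accounting survives wedge
  integration.
* **STXM.** Reference spectra are an ionisation edge step plus the
  π\* Gaussian (peptide 0.3 eV below lipid). Clusters are disks with
  sub-pixel edge coverage (so half-coverage thresholding recovers the
  true diameter), placed without overlap on a jittered cell grid away
  from the border, with diameters from a normal distribution truncated
  at 3 pixels; the default energy grid samples 0.1 eV across 284–290 eV
  and coarser outside, spanning 280–340 eV.
* **Surfaces.** Both leaflets on a regular grid with a mirrored
  Gaussian deformation and independent z-noise (σ = 0.3 Å).

What the generator does **not** emulate — and hence what a green round
trip does not establish: detector geometry corrections (flat field,
polarisation, absorption), mosaic-dependent Lorentz factors, rigorous
slab form factors with roughness, stack misregistration in STXM,
radiation damage, and any real sample-to-sample biology. Round trips
validate the *inference machinery* against a world whose parameters are
the published ones, not the instruments.

## Stated recovery tolerances

The full-pipeline acceptance test regenerates all eight conditions over
20 seeds and requires, per seed: d_z within 0.1 Å, A_T within 0.2 Å²,
tilt within 3°, H within 1.5, d_HH within 0.8 Å, L within 20% and φ
within 0.025 — each sized at roughly three noise standard deviations of
the corresponding estimator at the default counting statistics, with
the tail-fit tilt the widest. Across-seed means must additionally be
unbiased at tighter bounds (tilt 0.5°, L 10%, φ 0.01). The identity
$d_z = d_{HH} + d_W$ must hold exactly on every row. Curvature and
mismatch properties are checked analytically; the absolute MD-derived
curvature and diffusivity values of the source work require hundreds of
nanoseconds of simulation and are deliberately out of scope — the
curvature module is validated against its analytic oracle instead.

## Known limitations

* The phase set for the Fourier synthesis is an assumption (alternating
  PC-type signs); real samples with unusual density profiles need
  user-supplied phases.
* The tilt estimator fits only the $\gamma > 30^\circ$ tail of the
  chain arc; its per-seed scatter (~1°) dominates the pipeline's noise
  budget.
* Scherrer sizing saturates once the peak width approaches the grid or
  instrumental resolution; sizes much above ~200 nm are not resolvable
  at the default grids.
* Two-component unmixing assumes exactly two chromophores; a third
  component (e.g. substrate contamination) aliases into the residual
  map, which is reported but not decomposed.
* The mismatch model is dimensionless by convention; it ranks
  conditions and cannot produce absolute energies without measured
  moduli.
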