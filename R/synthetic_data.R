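# Synthetic-data generators.
#
# Every generator embeds its ground truth in the output metadata; recovery
# tests compare against that embedded truth, never against hard-coded
# numbers.  All randomness is Poisson counting noise (plus positional noise
# for surfaces) under a user-supplied seed; with the seed fixed, outputs are
# bit-identical across runs.

# -- model bilayer electron density and its form factors -----------------

#' Model relative electron density of one bilayer period
#'
#' Two head-group Gaussians at `+/- d_hh/2` minus a methyl trough at the
#' bilayer centre; water-subtracted, arbitrary units.  This parametric
#' profile supplies the generator's per-order form factors (with signs) and
#' defines the ground-truth head-head distance.
#'
#' @param z positions (Angstrom), one period centred on the bilayer.
#' @param d_hh head-head distance (Angstrom).
#' @param sigma_head,sigma_core Gaussian widths of head peaks and methyl
#'   trough (Angstrom).
#' @param trough trough amplitude relative to the head peaks.
#' @return Numeric vector of relative electron density.
#' @export
bilayer_density_model <- function(z, d_hh, sigma_head = 4.5, sigma_core = 6,
                                  trough = 0.8) {
  zh <- d_hh / 2
  exp(-(z - zh)^2 / (2 * sigma_head^2)) +
    exp(-(z + zh)^2 / (2 * sigma_head^2)) -
    trough * exp(-z^2 / (2 * sigma_core^2))
}

#' Form factors of the model bilayer density
#'
#' \eqn{F_n = \int \rho(z) \cos(2\pi n z / d_z) dz} over one period, by
#' trapezoidal quadrature.  Signs are retained; the generator stores them so
#' that the Fourier synthesis round trip is phase-consistent.
#'
#' @param d_z lamellar period (Angstrom).
#' @param d_hh head-head distance (Angstrom).
#' @param n_orders number of orders.
#' @param ... passed to [bilayer_density_model()].
#' @return Numeric vector `F[1..n_orders]` (signed).
#' @export
bilayer_form_factors <- function(d_z, d_hh, n_orders, ...) {
  z <- seq(-d_z / 2, d_z / 2, length.out = 4001)
  rho <- bilayer_density_model(z, d_hh, ...)
  h <- z[2] - z[1]
  vapply(seq_len(n_orders), function(n) {
    f <- rho * cos(2 * pi * n * z / d_z)
    sum((f[-1] + f[-length(f)]) / 2) * h
  }, numeric(1))
}

# -- Hermans <-> mosaic width mapping ------------------------------------

#' Hermans order parameter of a Gaussian mosaic distribution
#'
#' For a meridional intensity distribution
#' \eqn{I(\delta) \propto \exp(-\delta^2/2\sigma^2)} on `[0, 90]` degrees,
#' computes \eqn{f = (3\langle\cos^2\delta\rangle - 1)/2} where the average
#' is intensity-weighted with no solid-angle weighting (so that a flat
#' distribution gives exactly f = 0.25).  `mosaic_from_hermans()` is the
#' numerical inverse.
#'
#' @param sigma_deg Gaussian width in degrees.
#' @return Order parameter `f` in `(0.25, 1)`.
#' @export
hermans_from_mosaic <- function(sigma_deg) {
  if (sigma_deg <= 0) return(1)
  # substitute t = delta / sigma so the quadrature stays well-scaled for
  # arbitrarily narrow distributions
  upper <- min(90 / sigma_deg, 40)
  num <- integrate(function(t) exp(-t^2 / 2) *
                     cos(deg2rad(t * sigma_deg))^2, 0, upper,
                   rel.tol = 1e-10)$value
  den <- integrate(function(t) exp(-t^2 / 2), 0, upper,
                   rel.tol = 1e-10)$value
  (3 * num / den - 1) / 2
}

#' @rdname hermans_from_mosaic
#' @param f Hermans order parameter, in `(0.25, 1)`.
#' @export
mosaic_from_hermans <- function(f) {
  if (f >= 1) return(0)
  if (f <= 0.25) stop_domain("f must exceed the isotropic limit 0.25")
  uniroot(function(s) hermans_from_mosaic(s) - f, c(0.02, 500),
          tol = 1e-8)$root
}

# -- ground-truth records ------------------------------------------------

#' Ground truth for diffraction generators
#'
#' Holds every structural parameter the generators emulate and the analysis
#' pipeline recovers.  Defaults correspond to the 20 mol% peptide,
#' drug-free condition of the reference assays (see
#' [reference_structure_table()]); [condition_ground_truth()] builds the
#' record for any published condition.
#'
#' @param d_z lamellar period (Angstrom), `> 0`.
#' @param n_orders number of Bragg orders (`>= 2`).
#' @param d_hh head-head distance (Angstrom); sets the form factors via
#'   [bilayer_form_factors()].
#' @param chain_q fluid chain-correlation peak centre (1/Angstrom).
#' @param chain_hwhm Lorentzian half width of the chain peak (1/Angstrom).
#' @param gel_peaks list of `c(q, amplitude)` gel head-group reflections
#'   (empty when absent).
#' @param water_q,kapton_q water-correlation and Kapton-window feature
#'   positions (1/Angstrom).
#' @param crossbeta_qs inter-sheet and inter-strand reflection positions
#'   (1/Angstrom).
#' @param domain_length cross-beta domain size L (nm); sets peptide peak
#'   widths through the package Scherrer convention.
#' @param peptide_area_fraction cluster volume fraction phi in `[0, 1]`:
#'   the peptide share of the total (peptide + chain) integrated signal.
#' @param mosaic_sigma meridional Gaussian spread of the membrane normals
#'   (deg).
#' @param tilt_angle mean chain tilt: offset of the chain-correlation arc
#'   from the equator (deg).
#' @param tilt_width azimuthal Gaussian width of the chain arc (deg).
#' @param bragg_sigma radial Gaussian width of lamellar peaks (1/Angstrom).
#' @param noise_scale Poisson exposure scaling; `0` disables noise.
#' @param intensity_scale overall count scale (sets counting statistics).
#' @param seed RNG seed for this ground truth's realisations.
#' @return An object of class `ground_truth` (a validated list; signed form
#'   factors in `$form_factors`, their signs in `$phases`).
#' @export
ground_truth <- function(d_z = 55.2, n_orders = 4, d_hh = 39,
                         chain_q = 1.393, chain_hwhm = 0.13,
                         gel_peaks = list(),
                         water_q = 1.85, kapton_q = 0.4,
                         crossbeta_qs = c(0.7, 1.35),
                         domain_length = 21, peptide_area_fraction = 0.14,
                         mosaic_sigma = 25.8, tilt_angle = 18.3,
                         tilt_width = 12, bragg_sigma = 0.0035,
                         noise_scale = 1, intensity_scale = 2000,
                         seed = 1L) {
  if (d_z <= 0) stop_domain("d_z must be positive")
  if (n_orders < 2) stop_domain("need at least 2 Bragg orders")
  qs <- c(chain_q, water_q, kapton_q, crossbeta_qs,
          vapply(gel_peaks, `[`, numeric(1), 1))
  if (any(qs <= 0)) stop_domain("all q positions must be positive")
  if (peptide_area_fraction < 0 || peptide_area_fraction > 1)
    stop_domain("peptide_area_fraction must lie in [0, 1]")
  if (domain_length <= 0) stop_domain("domain_length must be positive")
  if (chain_hwhm <= 0 || bragg_sigma <= 0 || tilt_width <= 0 ||
      mosaic_sigma <= 0)
    stop_domain("all widths must be positive")
  ff <- bilayer_form_factors(d_z, d_hh, n_orders)
  structure(list(
    d_z = d_z, n_orders = n_orders, d_hh = d_hh,
    form_factors = ff, phases = sign(ff),
    chain_q = chain_q, chain_hwhm = chain_hwhm, gel_peaks = gel_peaks,
    water_q = water_q, kapton_q = kapton_q, crossbeta_qs = crossbeta_qs,
    domain_length = domain_length,
    peptide_area_fraction = peptide_area_fraction,
    mosaic_sigma = mosaic_sigma, hermans_f = hermans_from_mosaic(mosaic_sigma),
    tilt_angle = tilt_angle, tilt_width = tilt_width,
    bragg_sigma = bragg_sigma, noise_scale = noise_scale,
    intensity_scale = intensity_scale, seed = as.integer(seed)),
    class = "ground_truth")
}

#' Ground truth matching one published reference condition
#'
#' Builds a [ground_truth()] whose parameters reproduce one row of
#' [reference_structure_table()]: the lamellar period, head-head distance,
#' chain peak position (inverted from the published area per tail), tilt,
#' mosaic width (inverted from the published Hermans parameter), cluster
#' size and volume fraction.  Drug-free membranes keep 7 Bragg orders and,
#' without peptide, the gel head-group doublet at 1.43/1.50 1/Angstrom;
#' peptide-loaded membranes are limited to 4 orders (increased bending
#' suppresses the high orders).
#'
#' @param molecule one of `"none"`, `"curcumin"`, `"ASA"`, `"melatonin"`.
#' @param abeta_mol_pct 0 or 20.
#' @param seed RNG seed.
#' @param ... overrides passed on to [ground_truth()].
#' @return A `ground_truth` object.
#' @export
condition_ground_truth <- function(molecule = "none", abeta_mol_pct = 20,
                                   seed = 1L, ...) {
  tab <- reference_structure_table()
  row <- tab[tab$molecule == molecule & tab$abeta_mol_pct == abeta_mol_pct, ]
  if (nrow(row) != 1)
    stop_domain("unknown condition: ", molecule, " / ", abeta_mol_pct)
  has_pep <- row$abeta_mol_pct > 0
  args <- list(
    d_z = row$d_z, d_hh = row$d_HH,
    n_orders = if (has_pep) 4 else 7,
    chain_q = sqrt(8 * pi^2 / (sqrt(3) * row$A_T)),
    tilt_angle = row$lipid_tilt,
    mosaic_sigma = mosaic_from_hermans(row$H / 100),
    domain_length = if (has_pep) row$L else 21,
    peptide_area_fraction = if (has_pep) row$phi else 0,
    gel_peaks = if (!has_pep && molecule == "none")
      list(c(1.43, 6), c(1.50, 8)) else list(),
    seed = seed)
  do.call(ground_truth, modifyList(args, list(...)))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> d_z = %.1f A (%d orders), d_HH = %.1f A,",
                     " tilt = %.1f deg, H = %.1f, L = %g nm, phi = %.2f\n"),
              x$d_z, x$n_orders, x$d_hh, x$tilt_angle, 100 * x$hermans_f,
              x$domain_length, x$peptide_area_fraction))
  invisible(x)
}

# Poisson counting noise on scaled intensities; scale 0 disables noise.
apply_poisson <- function(intensity, noise_scale) {
  if (is.null(noise_scale) || noise_scale <= 0) return(intensity)
  rpois(length(intensity), pmax(intensity, 0) * noise_scale) / noise_scale
}

# package Scherrer convention: FWHM in q for a domain of L nm
scherrer_fwhm <- function(L_nm) 2 * pi * .ks_shape / (L_nm * 10)

# -- 1D generators -------------------------------------------------------

#' Generate a synthetic out-of-plane (lamellar) line scan
#'
#' Produces I(q_z) on a uniform grid: Gaussian Bragg peaks at
#' \eqn{q_n = n 2\pi/d_z} whose integrated areas are
#' \eqn{F_n^2 / q_n} (form factor squared with the Lorentz correction for
#' oriented stacks), a constant-plus-power-law diffuse background, and
#' optional Poisson noise.  The ground truth is embedded in
#' `metadata$ground_truth`.
#'
#' @param gt a [ground_truth()].
#' @param q_min,q_max,q_step grid (1/Angstrom); `q_max` defaults to half an
#'   order beyond the last Bragg peak.
#' @return A [line_scan()].
#' @export
gen_lamellar_scan <- function(gt, q_min = 0.03, q_max = NULL,
                              q_step = 2.5e-4) {
  stopifnot(inherits(gt, "ground_truth"))
  if (q_step <= 0) stop_domain("q_step must be positive")
  if (is.null(q_max)) q_max <- (gt$n_orders + 0.5) * 2 * pi / gt$d_z
  q <- seq(q_min, q_max, by = q_step)
  qn <- seq_len(gt$n_orders) * 2 * pi / gt$d_z
  areas <- gt$intensity_scale * gt$form_factors^2 / qn
  I <- 5 + 0.02 * q^-1.5   # diffuse background
  for (n in seq_len(gt$n_orders))
    I <- I + areas[n] * dnorm(q, qn[n], gt$bragg_sigma)
  if (!is.null(gt$seed)) set.seed(gt$seed)
  line_scan(q, apply_poisson(I, gt$noise_scale),
            metadata = list(ground_truth = unclass(gt), kind = "lamellar"))
}

#' Generate a synthetic in-plane line scan
#'
#' Produces I(q_par) with the fluid chain-correlation peak (Lorentzian),
#' optional gel head-group doublet (narrow Gaussians), the broad water
#' correlation feature, the Kapton window feature, and - when the peptide
#' area fraction is positive - the two cross-beta reflections as Gaussians
#' whose FWHM follows the package Scherrer convention for the ground-truth
#' domain size.  The total cross-beta area is `phi/(1-phi)` times the chain
#' peak area, so that the peptide share of the (peptide + chain) signal is
#' exactly `phi`.
#'
#' @param gt a [ground_truth()].
#' @param q_min,q_max,q_step grid (1/Angstrom).
#' @return A [line_scan()].
#' @export
gen_inplane_scan <- function(gt, q_min = 0.2, q_max = 2.2, q_step = 5e-4) {
  stopifnot(inherits(gt, "ground_truth"))
  if (q_step <= 0) stop_domain("q_step must be positive")
  q <- seq(q_min, q_max, by = q_step)
  s <- gt$intensity_scale / 20        # chain peak amplitude scale
  chain_area <- s * pi * (2 * gt$chain_hwhm) / 2
  I <- 3 + 0.05 * q^-1.5
  I <- I + s * .peak_lor(q, gt$chain_q, 2 * gt$chain_hwhm)
  I <- I + 0.35 * s * .peak_lor(q, gt$water_q, 0.3)
  I <- I + 0.15 * s * .peak_gau(q, gt$kapton_q, 0.08)
  for (g in gt$gel_peaks)
    I <- I + g[2] * s / 10 * .peak_gau(q, g[1], 0.015)
  phi <- gt$peptide_area_fraction
  if (phi > 0) {
    pep_area <- phi / (1 - phi) * chain_area
    fw <- scherrer_fwhm(gt$domain_length)
    split <- c(0.5, 0.5)
    for (k in 1:2) {
      amp <- split[k] * pep_area /
        (fw / (2 * sqrt(2 * log(2))) * sqrt(2 * pi))
      I <- I + amp * .peak_gau(q, gt$crossbeta_qs[k], fw)
    }
  }
  if (!is.null(gt$seed)) set.seed(gt$seed + 1L)
  line_scan(q, apply_poisson(I, gt$noise_scale),
            metadata = list(ground_truth = unclass(gt), kind = "inplane",
                            chain_area = chain_area))
}

# -- 2D map generator ----------------------------------------------------

#' Generate a synthetic 2D reciprocal-space map
#'
#' Builds the full \eqn{(q_\parallel, q_z)} intensity map: lamellar Bragg
#' peaks along q_z with a meridional Gaussian mosaic spread, the chain
#' correlation arc offset from the equator by the ground-truth tilt angle,
#' gel doublet arcs, isotropic water and Kapton rings, isotropic cross-beta
#' rings with Scherrer finite-size widths, a diffuse background and
#' optional Poisson noise.  The chain arc amplitude is normalised so that
#' wedge integration over the default 30-90 degree wedge reproduces the
#' chain/cross-beta area ratio implied by the ground-truth volume fraction.
#'
#' @param gt a [ground_truth()].
#' @param q_par_max,q_z_range,q_step grid extent and step (1/Angstrom); the
#'   defaults cover the protocol window `0 <= q_par <= 3.1`,
#'   `0.03 <= q_z <= 1.1`.
#' @return A [reciprocal_map()].
#' @export
gen_map2d <- function(gt, q_par_max = 3.1, q_z_range = c(0.03, 1.1),
                      q_step = 0.005) {
  stopifnot(inherits(gt, "ground_truth"))
  if (q_step <= 0) stop_domain("q_step must be positive")
  if (q_par_max <= q_step || diff(q_z_range) <= q_step)
    stop_domain("grids of zero extent are not allowed")
  q_par <- seq(q_step, q_par_max, by = q_step)
  q_z <- seq(q_z_range[1], q_z_range[2], by = q_step)
  np <- length(q_par); nz <- length(q_z)
  QP <- matrix(q_par, np, nz)
  QZ <- matrix(q_z, np, nz, byrow = TRUE)
  Q <- sqrt(QP^2 + QZ^2)
  gamma <- rad2deg(atan2(QZ, QP))
  delta <- 90 - gamma
  s <- gt$intensity_scale / 20

  I <- 2 + 0.05 * Q^-1.5
  # lamellar orders: radial Gaussian x meridional mosaic Gaussian; the
  # radial width is floored at one grid step to stay resolvable on the map
  qn <- seq_len(gt$n_orders) * 2 * pi / gt$d_z
  areas <- gt$intensity_scale * gt$form_factors^2 / qn
  sig_r <- max(gt$bragg_sigma, q_step)
  mos <- exp(-delta^2 / (2 * gt$mosaic_sigma^2))
  for (n in seq_len(gt$n_orders))
    I <- I + areas[n] * dnorm(Q, qn[n], sig_r) * mos

  # chain arc: Lorentzian radial, Gaussian azimuthal centred at the tilt.
  # Scale by the wedge-average azimuthal factor so that the 30-90 deg wedge
  # integral reproduces the intended chain area.
  gfill <- integrate(function(g) exp(-(g - gt$tilt_angle)^2 /
                                       (2 * gt$tilt_width^2)),
                     30, 90)$value / 60
  az_chain <- exp(-(gamma - gt$tilt_angle)^2 / (2 * gt$tilt_width^2))
  I <- I + s / gfill * .peak_lor(Q, gt$chain_q, 2 * gt$chain_hwhm) * az_chain
  chain_area <- s * pi * (2 * gt$chain_hwhm) / 2

  for (g in gt$gel_peaks)
    I <- I + g[2] * s / (10 * gfill) * .peak_gau(Q, g[1], 0.015) * az_chain

  I <- I + 0.35 * s * .peak_lor(Q, gt$water_q, 0.3)
  I <- I + 0.15 * s * .peak_gau(Q, gt$kapton_q, 0.08)

  phi <- gt$peptide_area_fraction
  if (phi > 0) {
    pep_area <- phi / (1 - phi) * chain_area
    fw <- scherrer_fwhm(gt$domain_length)
    for (k in 1:2) {
      amp <- 0.5 * pep_area / (fw / (2 * sqrt(2 * log(2))) * sqrt(2 * pi))
      I <- I + amp * .peak_gau(Q, gt$crossbeta_qs[k], fw)
    }
  }
  if (!is.null(gt$seed)) set.seed(gt$seed + 2L)
  Iobs <- apply_poisson(I, gt$noise_scale)
  reciprocal_map(q_par, q_z, matrix(Iobs, np, nz),
                 metadata = list(ground_truth = unclass(gt),
                                 chain_area = chain_area))
}

# -- surfaces ------------------------------------------------------------

#' Ground truth for synthetic head-group surfaces
#'
#' Describes a bilayer whose two head-group sheets carry a localised
#' Gaussian deformation, emulating the depression a partitioned peptide
#' imprints on both leaflets.  Sign convention: `amplitude < 0` is a
#' depression of the upper leaflet (mirrored on the lower leaflet), and
#' yields negative curvature at the centre under the package convention
#' `K = -laplacian(delta)`; the analytic centre curvature recorded as
#' ground truth is `2 * amplitude / width^2`.
#'
#' @param box lateral extent of the square patch (Angstrom).
#' @param depression_amplitude extremal height change (Angstrom); negative
#'   for a depression.
#' @param depression_width lateral Gaussian width (Angstrom), `> 0`.
#' @param center `c(x, y)` position of the deformation (Angstrom).
#' @param baseline_z distance of each undisturbed leaflet from the bilayer
#'   centre (Angstrom).
#' @param noise_sigma Gaussian z-noise per head group (Angstrom).
#' @param n_side grid points per side and leaflet (`n_side^2 >= 64`).
#' @param seed RNG seed.
#' @return An object of class `surface_ground_truth`.
#' @export
surface_ground_truth <- function(box = 200, depression_amplitude = -6,
                                 depression_width = 30, center = c(100, 100),
                                 baseline_z = 20, noise_sigma = 0.3,
                                 n_side = 32, seed = 1L) {
  if (depression_width <= 0) stop_domain("depression width must be positive")
  if (n_side^2 < 64) stop_domain("need at least 64 points per leaflet")
  structure(list(box = box, depression_amplitude = depression_amplitude,
                 depression_width = depression_width, center = center,
                 baseline_z = baseline_z, noise_sigma = noise_sigma,
                 n_side = as.integer(n_side), seed = as.integer(seed),
                 curvature_center = 2 * depression_amplitude /
                   depression_width^2),
            class = "surface_ground_truth")
}

#' Generate a synthetic head-group surface point cloud
#'
#' Samples both leaflets on a regular lateral grid:
#' `z = +/-(baseline_z) +/- amplitude * exp(-r^2 / (2 width^2)) + noise`,
#' with the deformation mirrored on the lower leaflet (negative curvature
#' on both sides of the membrane).  The analytic centre curvature
#' `2 * amplitude / width^2` is recorded in the ground truth.
#'
#' @param sgt a [surface_ground_truth()].
#' @return A [surface_point_cloud()] with the ground truth in its metadata.
#' @export
gen_surface <- function(sgt) {
  stopifnot(inherits(sgt, "surface_ground_truth"))
  g <- seq(0, sgt$box, length.out = sgt$n_side)
  pts <- expand.grid(x = g, y = g)
  r2 <- (pts$x - sgt$center[1])^2 + (pts$y - sgt$center[2])^2
  bump <- sgt$depression_amplitude *
    exp(-r2 / (2 * sgt$depression_width^2))
  if (!is.null(sgt$seed)) set.seed(sgt$seed)
  noise <- function() if (sgt$noise_sigma > 0)
    rnorm(nrow(pts), 0, sgt$noise_sigma) else 0
  upper <- data.frame(leaflet = 1L, x = pts$x, y = pts$y,
                      z = sgt$baseline_z + bump + noise())
  lower <- data.frame(leaflet = 2L, x = pts$x, y = pts$y,
                      z = -sgt$baseline_z - bump + noise())
  surface_point_cloud(rbind(upper, lower),
                      metadata = list(ground_truth = unclass(sgt)))
}

# -- STXM ----------------------------------------------------------------

#' Default C 1s photon-energy grid for STXM stacks
#'
#' Fine 0.25 eV sampling across the pi* region (284-290 eV), coarser
#' outside, spanning the 280-340 eV carbon edge sequence.
#' @return Numeric vector of energies (eV), strictly increasing.
#' @export
stxm_default_energies <- function() {
  unique(c(seq(280, 283.5, by = 1), seq(284, 290, by = 0.1),
           seq(290.5, 305, by = 1.5), seq(310, 340, by = 5)))
}

#' Model lipid and peptide C 1s reference spectra
#'
#' Optical density per unit component thickness: an ionisation edge step
#' (logistic) plus a Gaussian C 1s -> pi* (C=O) resonance.  The lipid ester
#' pi* sits at 288.8 eV; the peptide amide pi* is shifted by `pi_shift`
#' (default -0.3 eV, i.e. 288.5 eV - the amide resonance lies below the
#' ester one), which is the spectroscopic handle that makes the two
#' components separable.
#'
#' @param energies photon energies (eV).
#' @param pi_shift peptide pi* shift relative to the lipid 288.8 eV peak
#'   (eV).
#' @return Matrix with columns `lipid`, `peptide` (OD per unit thickness).
#' @export
stxm_reference_spectra <- function(energies, pi_shift = -0.3) {
  edge <- function(E, E0, w) 1 / (1 + exp(-(E - E0) / w))
  lipid <- 0.8 * edge(energies, 290.5, 1.2) +
    1.0 * .peak_gau(energies, 288.8, 1.0)
  peptide <- 1.0 * edge(energies, 289.8, 1.2) +
    0.9 * .peak_gau(energies, 288.8 + pi_shift, 1.0)
  cbind(lipid = lipid, peptide = peptide)
}

#' Generate a synthetic STXM transmission stack
#'
#' Scatters non-overlapping disk-shaped peptide clusters (widths drawn from
#' a truncated normal distribution) on a uniform lipid background; cluster
#' edges carry sub-pixel coverage so that thresholding at half coverage
#' recovers the true diameter.  Per pixel and energy the transmitted flux
#' is `i0 * exp(-OD)` with `OD = t_lipid * s_lipid(E) + t_pep * s_pep(E)`,
#' plus Poisson counting noise when `noise_scale > 0`.
#'
#' @param energies photon energies (eV), strictly increasing within
#'   280-340 eV.
#' @param cluster_mean,cluster_sd cluster width distribution (nm); the
#'   reference imaging assays give 74 and 18 nm.
#' @param pixel_nm pixel size (nm), `> 0`.
#' @param i0 incident flux (counts), `> 0`.
#' @param noise_scale Poisson exposure scaling; `0` disables noise.
#' @param seed RNG seed.
#' @param n_clusters number of clusters to place.
#' @param lipid_thickness,peptide_thickness component thicknesses in the
#'   units of the reference spectra.
#' @return An [stxm_stack()]; `metadata$ground_truth` holds the placed
#'   cluster table and all parameters, `metadata$ref` the reference
#'   spectra used.
#' @export
gen_stxm_stack <- function(energies = stxm_default_energies(),
                           cluster_mean = 74, cluster_sd = 18,
                           pixel_nm = 10, i0 = 5000, noise_scale = 1,
                           seed = 1L, n_clusters = 120,
                           lipid_thickness = 1, peptide_thickness = 1.2) {
  if (any(diff(energies) <= 0))
    stop_domain("energies must be strictly increasing")
  if (min(energies) < 280 || max(energies) > 340)
    stop_domain("energies must lie within the 280-340 eV C 1s sequence")
  if (pixel_nm <= 0) stop_domain("pixel_nm must be positive")
  if (any(i0 <= 0)) stop_domain("i0 must be positive")
  set.seed(seed)
  d_min <- 3 * pixel_nm
  d_max <- cluster_mean + 4 * cluster_sd
  widths <- rnorm(n_clusters, cluster_mean, cluster_sd)
  widths <- pmin(pmax(widths, d_min), d_max)
  # non-overlapping placement on a jittered cell grid, clear of the border
  cell_px <- ceiling(d_max / pixel_nm) + 6
  ncx <- ceiling(sqrt(n_clusters * 1.2))
  ncy <- ceiling(n_clusters / ncx)
  nx <- ncx * cell_px + 4; ny <- ncy * cell_px + 4
  cells <- expand.grid(cx = seq_len(ncx), cy = seq_len(ncy))
  cells <- cells[sample(nrow(cells), n_clusters), ]
  jit <- (cell_px - ceiling(widths / pixel_nm)) / 2 - 1
  x0 <- 2 + (cells$cx - 0.5) * cell_px + runif(n_clusters, -1, 1) * jit
  y0 <- 2 + (cells$cy - 0.5) * cell_px + runif(n_clusters, -1, 1) * jit
  px <- matrix(seq_len(nx), nx, ny)
  py <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  t_pep <- matrix(0, nx, ny)
  for (k in seq_len(n_clusters)) {
    r <- widths[k] / 2 / pixel_nm
    dist <- sqrt((px - x0[k])^2 + (py - y0[k])^2)
    cov <- pmin(pmax(r - dist + 0.5, 0), 1)    # sub-pixel edge coverage
    t_pep <- t_pep + peptide_thickness * cov
  }
  ref <- stxm_reference_spectra(energies)
  od <- outer(as.vector(t_pep) * 0 + lipid_thickness, ref[, "lipid"]) +
    outer(as.vector(t_pep), ref[, "peptide"])
  trans <- i0 * exp(-od)
  if (noise_scale > 0)
    trans <- matrix(rpois(length(trans), trans * noise_scale) / noise_scale,
                    nrow(trans), ncol(trans))
  imgs <- array(trans, dim = c(nx, ny, length(energies)))
  stxm_stack(energies, imgs, i0 = i0, pixel_nm = pixel_nm,
             metadata = list(
               ground_truth = list(cluster_mean = cluster_mean,
                                   cluster_sd = cluster_sd,
                                   widths = widths, x = x0, y = y0,
                                   pixel_nm = pixel_nm,
                                   lipid_thickness = lipid_thickness,
                                   peptide_thickness = peptide_thickness,
                                   noise_scale = noise_scale, seed = seed),
               ref = ref))
}
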