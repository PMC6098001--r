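# In-plane analysis: chain packing, head-group lattice, cross-beta
# quantification, Scherrer domain size, volume fractions.

#' Area per acyl tail from the chain-correlation peak
#'
#' For hexagonally packed chains the tail-tail distance and area per tail
#' follow from the peak position:
#' \deqn{a_T = 4\pi/(\sqrt{3} q_T), \qquad A_T = 8\pi^2/(\sqrt{3} q_T^2)}
#' (so \eqn{A_T = \sqrt{3}/2\, a_T^2}, the hexagonal cell identity).
#'
#' @param q_T chain-correlation peak centre (1/Angstrom), `> 0`.
#' @return A list with `q_T`, `a_T` (Angstrom), `A_T` (Angstrom^2), of
#'   class `chain_packing`.
#' @export
area_per_tail <- function(q_T) {
  if (any(!is.finite(q_T)) || any(q_T <= 0))
    stop_domain("q_T must be positive")
  structure(list(q_T = q_T,
                 a_T = 4 * pi / (sqrt(3) * q_T),
                 A_T = 8 * pi^2 / (sqrt(3) * q_T^2)),
            class = "chain_packing")
}

#' Index the gel head-group doublet on a rectangular lattice
#'
#' Treats the two reflections as second-order axial reflections (0,2)/(2,0)
#' of a rectangular head-group cell: `b = 4*pi/q1`, `a = 4*pi/q2` with
#' `q1 < q2`, so `a <= b` by convention.
#'
#' @param q1,q2 reflection positions (1/Angstrom), `0 < q1 < q2`.
#' @return A list with cell edges `a`, `b` (Angstrom), class
#'   `headgroup_cell`.
#' @export
index_headgroup_cell <- function(q1, q2) {
  if (!(q1 > 0 && q2 > q1))
    stop_domain("require 0 < q1 < q2 (equal reflections are degenerate)")
  structure(list(a = 4 * pi / q2, b = 4 * pi / q1),
            class = "headgroup_cell")
}

#' Predicted reflection positions of a rectangular head-group cell
#'
#' Inverse of [index_headgroup_cell()]: returns `c(q1, q2) = (4*pi/b,
#' 4*pi/a)`.
#' @param cell a `headgroup_cell`.
#' @return Numeric vector `c(q1, q2)`.
#' @export
predict_headgroup_q <- function(cell) {
  stopifnot(inherits(cell, "headgroup_cell"))
  c(4 * pi / cell$b, 4 * pi / cell$a)
}

#' Scherrer domain size from peak broadening
#'
#' \deqn{L = 2\pi K_s / (\Delta q_{FWHM} - \Delta q_{instr})} with the
#' package-wide shape factor \eqn{K_s = 0.9}, converted to nm.  The
#' generator shares the same convention, so synthetic round trips are
#' exact.
#'
#' @param fwhm_q peak FWHM in q (1/Angstrom); must exceed the instrumental
#'   width.
#' @param instrumental instrumental FWHM contribution (1/Angstrom),
#'   subtracted in q.
#' @return Domain size L in nm.
#' @export
scherrer_size <- function(fwhm_q, instrumental = 0) {
  if (any(fwhm_q <= instrumental))
    stop_domain("peak width does not exceed the instrumental width: ",
                "domain size unresolvable")
  2 * pi * .ks_shape / (fwhm_q - instrumental) / 10
}

#' Cross-beta cluster volume fraction from integrated peak areas
#'
#' The peptide share of the scattering signal.  With
#' `denominator = "total"` (default),
#' \eqn{\phi = \Sigma_{pep} / (\Sigma_{pep} + A_{lipid})}: the share of the
#' combined peptide + lipid signal, the convention under which 20 mol%
#' fully aggregated peptide contributes 20% of the signal.
#' `denominator = "lipid"` gives the plain ratio to the lipid peak instead.
#'
#' @param peptide_areas integrated cross-beta peak areas (non-negative).
#' @param lipid_area integrated lipid (chain) peak area, `> 0`.
#' @param denominator `"total"` or `"lipid"`.
#' @return Volume fraction `phi`.
#' @export
crossbeta_volume_fraction <- function(peptide_areas, lipid_area,
                                      denominator = c("total", "lipid")) {
  denominator <- match.arg(denominator)
  if (any(peptide_areas < 0)) stop_domain("peak areas must be non-negative")
  if (lipid_area <= 0) stop_domain("lipid area must be positive")
  p <- sum(peptide_areas)
  switch(denominator,
         total = p / (p + lipid_area),
         lipid = p / lipid_area)
}

#' Fraction of added peptide found in aggregates
#'
#' The diffraction signal only reports aggregated peptide, so the measured
#' volume fraction divided by the nominal added amount gives the aggregated
#' share: `100 * phi / peptide_mol_pct`.  A 15% signal from 20 mol% added
#' peptide means 3/4 of the peptide sits in clusters.
#'
#' @param phi measured cluster volume fraction, `[0, 1]`.
#' @param peptide_mol_pct added peptide concentration (mol%), `(0, 100]`.
#' @param tol tolerance on `phi` exceeding the added amount before the
#'   result is rejected as inconsistent.
#' @return Aggregated fraction in `[0, 1]`.
#' @export
aggregated_fraction <- function(phi, peptide_mol_pct, tol = 0.02) {
  if (peptide_mol_pct <= 0 || peptide_mol_pct > 100)
    stop_domain("peptide_mol_pct must lie in (0, 100]")
  if (phi < 0) stop_domain("phi must be non-negative")
  frac <- 100 * phi / peptide_mol_pct
  if (frac > 1 + tol)
    stop_domain(sprintf(
      "inconsistent: measured phi = %.3f exceeds the added %g mol%%",
      phi, peptide_mol_pct))
  min(frac, 1)
}
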