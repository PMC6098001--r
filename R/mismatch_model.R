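# Hydrophobic-mismatch free-energy model for peptide cluster size.
#
# A cross-beta cluster is treated as a circular phase-separated domain of
# radius R with bulk free-energy gain g0 per unit area and line tension
# sigma at the lipid boundary.  The line tension is dominated by the
# thickness-deformation energy of the surrounding bilayer and grows
# quadratically with the hydrophobic mismatch u = w - w0.  Units are
# consistent-but-arbitrary: the model is used for ordering conditions, not
# for absolute energies.

#' Membrane deformation spring constant
#'
#' \deqn{K = \sqrt{2}\,(K_t^3 K_b / w^6)^{1/4}} - the effective spring
#' constant of the thickness deformation around a hydrophobic inclusion,
#' combining the thickness-compression modulus `K_t`, the bending modulus
#' `K_b` and the bilayer hydrophobic thickness `w`.
#'
#' @param K_t thickness-compression modulus (energy/length^4), `> 0`.
#' @param K_b bending modulus (energy), `> 0`.
#' @param w bilayer hydrophobic thickness (length), `> 0`.
#' @return Spring constant (energy/length^4). Vectorised.
#' @export
spring_constant <- function(K_t, K_b, w) {
  if (any(K_t <= 0) || any(K_b <= 0) || any(w <= 0))
    stop_domain("K_t, K_b and w must be positive")
  sqrt(2) * (K_t^3 * K_b / w^6)^(1 / 4)
}

#' Line tension from hydrophobic mismatch
#'
#' \deqn{\sigma = \tfrac{1}{2} K u^2, \quad u = w - w_0} where `w` is the
#' bilayer hydrophobic thickness and `w0` the (sample-independent)
#' hydrophobic length of the peptide cluster.  Zero mismatch means zero
#' line tension; the cost grows quadratically with the mismatch.
#'
#' @param K_spring spring constant from [spring_constant()].
#' @param w,w0 bilayer and cluster hydrophobic thicknesses (length).
#' @return Line tension (energy/length). Vectorised.
#' @export
line_tension <- function(K_spring, w, w0) {
  if (any(!is.finite(c(K_spring, w, w0))))
    stop_domain("inputs must be finite")
  0.5 * K_spring * (w - w0)^2
}

#' Domain free energy versus radius
#'
#' \deqn{\Delta G(R) = -\pi R^2 g_0 + 2\pi R \sigma}: bulk gain plus
#' boundary cost of a circular domain.  Strictly concave in R; positive
#' for small R, negative beyond the root `R = 2 sigma / g0`.
#'
#' @param R domain radius (length), `>= 0`; vectorised.
#' @param g0 bulk free-energy density (energy/area), `> 0`.
#' @param sigma line tension (energy/length), `>= 0`.
#' @return Free energy change (energy).
#' @export
free_energy <- function(R, g0, sigma) {
  if (any(R < 0)) stop_domain("R must be non-negative")
  if (g0 <= 0) stop_domain("g0 must be positive")
  if (sigma < 0) stop_domain("sigma must be non-negative")
  -pi * R^2 * g0 + 2 * pi * R * sigma
}

#' Critical (stationary) radius of the domain free energy
#'
#' The stationary point of \eqn{\Delta G(R)}: `R* = sigma / g0`, with
#' barrier height `dG* = pi sigma^2 / g0`.  Smaller line tension means a
#' smaller critical domain size.
#'
#' @param g0 bulk free-energy density, `> 0`.
#' @param sigma line tension, `>= 0`.
#' @return List with `R_star` and `deltaG_star`.
#' @export
critical_radius <- function(g0, sigma) {
  if (g0 <= 0) stop_domain("g0 must be positive")
  if (sigma < 0) stop_domain("sigma must be non-negative")
  list(R_star = sigma / g0, deltaG_star = pi * sigma^2 / g0)
}

#' Rank conditions by line tension
#'
#' Computes the line tension for each named condition from its bilayer
#' thickness (shared `w0`, `K_t`, `K_b`) and returns the conditions sorted
#' by increasing sigma.  With `formula = "spring"` (default)
#' `sigma = 0.5 * K(w) * (w - w0)^2`; `formula = "scaling"` uses the
#' thin-deformation scaling form `sigma ~ (w - w0)^2 / w^(3/2)` (identical
#' ordering, arbitrary prefactor).  Ties are reported in the `ties`
#' attribute.
#'
#' @param conditions named numeric vector of bilayer thicknesses `w`
#'   (e.g. head-head distances), at least 2, unique names.
#' @param w0 cluster hydrophobic length (same units as `w`).
#' @param K_t,K_b moduli passed to [spring_constant()] (defaults 1: only
#'   the ordering is meaningful).
#' @param formula `"spring"` or `"scaling"`.
#' @return A data.frame (`condition`, `w`, `sigma`) sorted ascending by
#'   sigma, with attribute `ties` (list of tied name groups, empty when
#'   none).
#' @export
rank_conditions <- function(conditions, w0, K_t = 1, K_b = 1,
                            formula = c("spring", "scaling")) {
  formula <- match.arg(formula)
  if (length(conditions) < 2)
    stop_domain("need at least 2 conditions to rank")
  nm <- names(conditions)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop_domain("conditions must have unique, non-empty names")
  w <- as.numeric(conditions)
  sigma <- switch(formula,
                  spring = line_tension(spring_constant(K_t, K_b, w), w, w0),
                  scaling = (w - w0)^2 / w^(3 / 2))
  ord <- order(sigma)
  out <- data.frame(condition = nm[ord], w = w[ord], sigma = sigma[ord],
                    stringsAsFactors = FALSE)
  grp <- split(out$condition, factor(signif(out$sigma, 12)))
  ties <- grp[lengths(grp) > 1]
  if (length(ties))
    message("tied line tensions: ",
            paste(vapply(ties, paste, "", collapse = " = "),
                  collapse = "; "))
  attr(out, "ties") <- unname(ties)
  out
}
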