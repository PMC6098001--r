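# Orientation analysis: lipid tilt from the azimuthal chain-peak profile,
# membrane orientational order via the Hermans function.

#' Lipid tilt from an azimuthal (gamma) chain-peak profile
#'
#' Fits a Gaussian plus constant background to I(gamma).  The tilt is the
#' absolute offset of the chain-correlation arc from the equator (the
#' fitted centre); the width is the fitted Gaussian sigma.  A flat profile
#' (no arc) is rejected: there is no preferred tilt to report.
#'
#' @param profile an [angular_profile()] of kind `"gamma"`, extracted
#'   around the chain-correlation |Q|.
#' @param flat_tol minimum peak-to-base contrast (relative) below which the
#'   profile is considered flat.
#' @return A list with `tilt` (deg), `tilt_width` (deg, Gaussian sigma) and
#'   the fit object.
#' @export
tilt_angle <- function(profile, flat_tol = 0.05) {
  stopifnot(inherits(profile, "angular_profile"))
  if (profile$kind != "gamma")
    stop_domain("tilt analysis needs a gamma-kind profile")
  g <- profile$angle; y <- profile$intensity
  if ((max(y) - min(y)) <= flat_tol * max(max(y), .Machine$double.eps))
    stop_domain("no preferred tilt: azimuthal profile is flat")
  st <- list(b0 = min(y), A = max(y) - min(y), c0 = g[which.max(y)], s = 10)
  dat <- data.frame(g = g, y = y)
  fit <- tryCatch(
    nls(y ~ b0 + A * exp(-(g - c0)^2 / (2 * s^2)), data = dat, start = st,
        algorithm = "port",
        lower = c(0, 0, -30, 1), upper = c(Inf, Inf, 90, 90),
        control = nls.control(maxiter = 200, scaleOffset = 1,
                              warnOnly = TRUE)),
    error = function(e) stop_domain("tilt fit failed: ",
                                    conditionMessage(e)))
  p <- coef(fit)
  list(tilt = abs(unname(p["c0"])), tilt_width = unname(p["s"]), fit = fit)
}

#' Hermans orientation parameter from a meridional (delta) profile
#'
#' \deqn{f = (3\langle\cos^2\delta\rangle - 1)/2.}
#' The average is intensity-weighted with a plain (unweighted) angle
#' measure over `[0, 90]` degrees - no solid-angle `sin(delta)` factor -
#' so a flat distribution gives exactly `f = 0.25` and perfect alignment
#' `f = 1`.
#'
#' Methods: `"fit"` fits a Gaussian centred at delta = 0 (amplitude, width
#' and constant background free; the protocol form for profiles measured
#' over a restricted window such as 18-40 deg) and evaluates
#' \eqn{\langle\cos^2\delta\rangle} of the fitted Gaussian by quadrature
#' over `[0, 90]`; `"direct"` averages the raw profile; `"auto"` uses the
#' fit and falls back to the direct average when the fit is degenerate
#' (flat or delta-like profiles).
#'
#' @param profile an [angular_profile()] of kind `"delta"`.
#' @param method `"auto"`, `"fit"` or `"direct"`.
#' @param center_tol fitted centres are constrained to 0; kept for
#'   interface compatibility of misalignment flagging.
#' @return A list with `f`, `H_pct = 100 f`, `cos2` and, for fits, `sigma`
#'   (deg) and the fit object.
#' @export
hermans <- function(profile, method = c("auto", "fit", "direct"),
                    center_tol = 2) {
  stopifnot(inherits(profile, "angular_profile"))
  if (profile$kind != "delta")
    stop_domain("Hermans analysis needs a delta-kind profile")
  method <- match.arg(method)
  d <- profile$angle; y <- profile$intensity

  direct <- function() {
    cos2 <- sum(y * cos(deg2rad(d))^2) / sum(y)
    list(f = (3 * cos2 - 1) / 2, H_pct = 100 * (3 * cos2 - 1) / 2,
         cos2 = cos2, method = "direct")
  }
  if (method == "direct") return(direct())
  if (length(d) < 5) {
    # too few bins for a 3-parameter fit (e.g. a delta-like profile)
    if (method == "fit")
      stop_domain("Hermans Gaussian fit needs at least 5 angular bins")
    return(direct())
  }

  fitted <- tryCatch({
    st <- list(b0 = min(y), A = max(y) - min(y),
               s = max(d[which.min(abs(y - (min(y) + (max(y) - min(y)) / 2)))],
                       5))
    dat <- data.frame(d = d, y = y)
    fit <- nls(y ~ b0 + A * exp(-d^2 / (2 * s^2)), data = dat, start = st,
               algorithm = "port", lower = c(0, 0, 0.5),
               upper = c(Inf, Inf, 1000),
               control = nls.control(maxiter = 200, scaleOffset = 1,
                                     warnOnly = TRUE))
    p <- coef(fit)
    if (p["A"] <= 1e-6 * max(y) || p["s"] >= 500)
      stop("degenerate Gaussian fit")
    f <- hermans_from_mosaic(unname(p["s"]))
    list(f = f, H_pct = 100 * f, cos2 = (2 * f + 1) / 3,
         sigma = unname(p["s"]), method = "fit", fit = fit)
  }, error = function(e) e)
  if (inherits(fitted, "error")) {
    if (method == "fit")
      stop_domain("Hermans Gaussian fit failed: ", conditionMessage(fitted))
    return(direct())
  }
  fitted
}
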