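# Reciprocal-space containers and geometric reductions.
#
# Angular conventions (fixed package-wide):
#   Q     = sqrt(q_z^2 + q_par^2)        total momentum transfer (1/A)
#   gamma = angle from the q_par axis    (deg, 0 = equator)
#   delta = 90 - gamma                   meridional angle from the q_z axis
# All interfaces take angles in degrees; radians are internal only.

#' One-dimensional intensity scan I(q)
#'
#' @param q strictly increasing grid of momentum transfer (1/Angstrom).
#' @param intensity non-negative intensities, same length as `q`.
#' @param metadata free-form named list (generator ground truth travels here).
#' @return An object of class `line_scan`.
#' @export
line_scan <- function(q, intensity, metadata = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop_domain("q and intensity must have the same length")
  if (any(!is.finite(q)) || any(diff(q) <= 0))
    stop_domain("q must be a finite, strictly increasing grid")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_domain("intensity must be finite and non-negative")
  structure(list(q = q, intensity = intensity, metadata = metadata),
            class = "line_scan")
}

#' @export
print.line_scan <- function(x, ...) {
  cat(sprintf("<line_scan> %d points, q in [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Two-dimensional reciprocal-space intensity map
#'
#' @param q_par strictly increasing in-plane grid (1/Angstrom).
#' @param q_z strictly increasing out-of-plane grid (1/Angstrom).
#' @param intensity matrix of non-negative intensities with
#'   `dim = c(length(q_par), length(q_z))` (rows index `q_par`).
#' @param metadata free-form named list.
#' @return An object of class `reciprocal_map`.
#' @export
reciprocal_map <- function(q_par, q_z, intensity, metadata = list()) {
  q_par <- as.numeric(q_par); q_z <- as.numeric(q_z)
  if (length(q_par) < 2 || length(q_z) < 2)
    stop_domain("reciprocal_map grids must have extent (>= 2 points each)")
  if (any(diff(q_par) <= 0) || any(diff(q_z) <= 0))
    stop_domain("q_par and q_z must be strictly increasing")
  intensity <- as.matrix(intensity)
  if (!all(dim(intensity) == c(length(q_par), length(q_z))))
    stop_domain("intensity must be a length(q_par) x length(q_z) matrix")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_domain("intensity must be finite and non-negative")
  structure(list(q_par = q_par, q_z = q_z, intensity = intensity,
                 metadata = metadata),
            class = "reciprocal_map")
}

#' @export
print.reciprocal_map <- function(x, ...) {
  cat(sprintf("<reciprocal_map> %d x %d, q_par [%.3g, %.3g], q_z [%.3g, %.3g] 1/A\n",
              length(x$q_par), length(x$q_z),
              min(x$q_par), max(x$q_par), min(x$q_z), max(x$q_z)))
  invisible(x)
}

# per-pixel polar coordinates of a map
map_polar <- function(map) {
  QP <- matrix(map$q_par, length(map$q_par), length(map$q_z))
  QZ <- matrix(map$q_z, length(map$q_par), length(map$q_z), byrow = TRUE)
  Q <- sqrt(QP^2 + QZ^2)
  gamma <- rad2deg(atan2(QZ, QP))
  list(Q = Q, gamma = gamma, delta = 90 - gamma)
}

#' Azimuthal intensity profile
#'
#' @param angle angle grid in degrees, within `[0, 90]`.
#' @param intensity summed intensities per angular bin.
#' @param kind `"gamma"` (from the equator / q_par axis) or `"delta"`
#'   (meridional, from the q_z axis).
#' @param q_center,q_width centre and full width of the Q annulus the
#'   profile was extracted from (1/Angstrom).
#' @param counts optional pixel counts per bin.
#' @return An object of class `angular_profile`.
#' @export
angular_profile <- function(angle, intensity, kind = c("gamma", "delta"),
                            q_center = NA_real_, q_width = NA_real_,
                            counts = NULL) {
  kind <- match.arg(kind)
  angle <- as.numeric(angle); intensity <- as.numeric(intensity)
  if (length(angle) != length(intensity))
    stop_domain("angle and intensity must have the same length")
  if (any(angle < 0 | angle > 90))
    stop_domain("angles must lie within [0, 90] degrees")
  structure(list(angle = angle, intensity = intensity, kind = kind,
                 q_center = q_center, q_width = q_width, counts = counts),
            class = "angular_profile")
}

# Conversions ------------------------------------------------------------

#' Convert momentum transfer to real-space distance (and back)
#'
#' `q_to_d()` returns \eqn{d = 2\pi/q}; `d_to_q()` is its inverse.  The pair
#' is the single source of truth for all spacing conversions in the package
#' (inter-strand, inter-sheet, water correlation, lamellar period).
#'
#' @param q momentum transfer (1/Angstrom), `> 0`; vectorised.
#' @return Distance in Angstrom.
#' @examples
#' q_to_d(1.85)  # ~3.4 A water correlation
#' q_to_d(1.35)  # ~4.7 A inter-strand spacing
#' @export
q_to_d <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop_domain("q must be positive")
  2 * pi / q
}

#' @rdname q_to_d
#' @param d real-space distance (Angstrom), `> 0`.
#' @export
d_to_q <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop_domain("d must be positive")
  2 * pi / d
}

# Wedge integration ------------------------------------------------------

#' Integrate a reciprocal-space map over an angular wedge
#'
#' Pixels with `gamma_lo <= gamma < gamma_hi` (the upper edge is inclusive
#' when `gamma_hi == 90`) are binned by total momentum transfer Q; each Q
#' bin is normalised by its pixel count, i.e. the returned intensity is the
#' mean pixel intensity in the bin.  Pixel counts per bin are stored in the
#' result metadata so that a pixel-count-weighted recombination of disjoint
#' wedges reproduces the full-map integral exactly.
#'
#' The default analysis wedge is 30--90 degrees: low-angle pixels suffer
#' from high absorption in reflection geometry and are excluded.
#'
#' @param map a [reciprocal_map()].
#' @param gamma_lo,gamma_hi wedge limits in degrees, `0 <= lo < hi <= 90`.
#' @param q_step Q bin width (1/Angstrom); defaults to the median `q_par`
#'   grid step.
#' @return A [line_scan()] of I(Q) with `metadata$counts` (pixels per bin)
#'   and `metadata$wedge`.
#' @export
wedge_integrate <- function(map, gamma_lo = 30, gamma_hi = 90, q_step = NULL) {
  stopifnot(inherits(map, "reciprocal_map"))
  if (!(gamma_lo >= 0 && gamma_lo < gamma_hi && gamma_hi <= 90))
    stop_domain("require 0 <= gamma_lo < gamma_hi <= 90")
  if (is.null(q_step)) q_step <- median(diff(map$q_par))
  if (q_step <= 0) stop_domain("q_step must be positive")
  pol <- map_polar(map)
  sel <- pol$gamma >= gamma_lo &
    (pol$gamma < gamma_hi | (gamma_hi == 90 & pol$gamma <= 90))
  if (!any(sel))
    stop_domain(sprintf("empty wedge [%g, %g) deg: no pixels selected",
                        gamma_lo, gamma_hi))
  Q <- pol$Q[sel]; I <- map$intensity[sel]
  bin <- floor(Q / q_step)            # half-open [a, a + q_step)
  tot <- tapply(I, bin, sum)
  cnt <- tapply(I, bin, length)
  qc <- (as.numeric(names(tot)) + 0.5) * q_step
  ord <- order(qc)
  line_scan(qc[ord], as.numeric(tot / cnt)[ord],
            metadata = list(counts = as.numeric(cnt)[ord],
                            wedge = c(gamma_lo, gamma_hi), q_step = q_step))
}

#' Azimuthal profile around a Q annulus
#'
#' Direct summation of pixels with `|Q - q_center| <= q_width/2`, binned by
#' angle in half-open bins `[a, a + step)`.  For `kind = "delta"` the
#' default angular range is 18--40 degrees (the protocol window around the
#' second lamellar order, chosen to avoid diffuse scattering below 18
#' degrees); for `kind = "gamma"` it is 30--90 degrees (low-angle pixels
#' excluded for absorption).
#'
#' @param map a [reciprocal_map()].
#' @param q_center,q_width annulus centre and full width (1/Angstrom);
#'   `q_center - q_width/2` must be positive.
#' @param kind `"gamma"` or `"delta"`.
#' @param step angular bin width in degrees (protocol value: 2).
#' @param angle_range length-2 numeric or `NULL` for the kind-dependent
#'   protocol default.
#' @param normalize `"sum"` (direct summation, the protocol form) or
#'   `"count"` (mean pixel intensity per bin; insensitive to annulus
#'   clipping at the map edge).
#' @param drop_incomplete drop angular bins whose pixel count falls below
#'   80% of the median bin count (bins where the annulus leaves the map).
#' @return An [angular_profile()].
#' @export
azimuthal_profile <- function(map, q_center, q_width,
                              kind = c("gamma", "delta"), step = 2,
                              angle_range = NULL,
                              normalize = c("sum", "count"),
                              drop_incomplete = TRUE) {
  stopifnot(inherits(map, "reciprocal_map"))
  kind <- match.arg(kind)
  if (q_center - q_width / 2 <= 0)
    stop_domain("annulus must be strictly positive in Q")
  if (is.null(angle_range))
    angle_range <- if (kind == "delta") c(18, 40) else c(30, 90)
  pol <- map_polar(map)
  ang <- if (kind == "gamma") pol$gamma else pol$delta
  sel <- abs(pol$Q - q_center) <= q_width / 2
  if (!any(sel))
    stop_domain(sprintf("annulus Q = %g +/- %g lies outside the map extent",
                        q_center, q_width / 2))
  sel <- sel & ang >= angle_range[1] &
    (ang < angle_range[2] | (angle_range[2] == 90 & ang <= 90))
  if (!any(sel))
    stop_domain("no pixels in the requested annulus/angle range")
  normalize <- match.arg(normalize)
  a <- ang[sel]; I <- map$intensity[sel]
  bin <- floor((a - angle_range[1]) / step)
  tot <- tapply(I, bin, sum)
  cnt <- tapply(I, bin, length)
  centres <- angle_range[1] + (as.numeric(names(tot)) + 0.5) * step
  ord <- order(centres)
  centres <- centres[ord]
  tot <- as.numeric(tot)[ord]; cnt <- as.numeric(cnt)[ord]
  if (drop_incomplete) {
    keep <- cnt >= 0.8 * median(cnt)
    centres <- centres[keep]; tot <- tot[keep]; cnt <- cnt[keep]
  }
  val <- if (normalize == "count") tot / cnt else tot
  angular_profile(centres, val, kind = kind,
                  q_center = q_center, q_width = q_width, counts = cnt)
}

# Peak models ------------------------------------------------------------

.peak_lor <- function(q, c0, fw) (fw / 2)^2 / ((q - c0)^2 + (fw / 2)^2)
.peak_gau <- function(q, c0, fw) {
  s <- fw / (2 * sqrt(2 * log(2)))
  exp(-(q - c0)^2 / (2 * s^2))
}
.peak_area <- function(model, amplitude, fwhm) {
  switch(model,
         lorentzian = pi * amplitude * fwhm / 2,
         gaussian = amplitude * fwhm / (2 * sqrt(2 * log(2))) * sqrt(2 * pi))
}

peak_fit_obj <- function(center, fwhm, amplitude, model, window,
                         goodness = NA_real_, converged = TRUE, se = NULL) {
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 area = .peak_area(model, amplitude, fwhm), model = model,
                 window = window, goodness = goodness, converged = converged,
                 se = se),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit %s> q0 = %.5g, FWHM = %.4g, area = %.4g%s\n",
              x$model, x$center, x$fwhm, x$area,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

# bounded port fit with an unbounded Gauss-Newton polish when port stops
# with a questionable code (7/8 can occur at the optimum on
# nearly-noiseless data); helper objects (peak functions) live in the
# formula environment, not in `data`.
.nls_refit <- function(formula, data, env, start, lower, upper) {
  e <- list2env(c(as.list(data), env), parent = environment())
  environment(formula) <- e
  # warnOnly: convergence is judged from convInfo below, so the port
  # warnings are informational only and suppressed
  fit <- suppressWarnings(
    nls(formula, data = e, start = start, algorithm = "port",
        lower = lower, upper = upper,
        control = nls.control(maxiter = 500, scaleOffset = 1,
                              warnOnly = TRUE)))
  if (!.nls_converged(fit)) {
    polish <- tryCatch(
      suppressWarnings(
        nls(formula, data = e, start = as.list(coef(fit)),
            control = nls.control(maxiter = 200, scaleOffset = 1,
                                  warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(polish) && .nls_converged(polish)) fit <- polish
  }
  fit
}

.nls_converged <- function(fit) {
  ci <- fit$convInfo
  isTRUE(ci$isConv) || isTRUE(ci$stopCode %in% 3:6)
}

# crude initial guesses within a window
.peak_start <- function(q, y) {
  b0 <- min(y); yc <- y - b0
  i <- which.max(yc)
  half <- yc >= yc[i] / 2
  runs <- rle(half)
  # width of the run containing the maximum
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  k <- which(starts <= i & ends >= i)
  fw <- max(q[ends[k]] - q[starts[k]], 2 * median(diff(q)))
  list(center = q[i], fwhm = fw, amplitude = yc[i], b0 = b0)
}

#' Fit peaks with a linear background in q windows
#'
#' Each window is fit independently by least squares with
#' `model(q; center, fwhm, amplitude) + b0 + b1*q`.  Fluid-phase membrane
#' features are conventionally Lorentzian; finite-size (cross-beta, gel,
#' Bragg) features Gaussian.  Areas are computed analytically from the
#' fitted parameters.  Non-convergence never fails silently: the returned
#' `peak_fit` carries `converged = FALSE` and the optimiser diagnostics.
#'
#' @param scan a [line_scan()].
#' @param windows list of `c(q_lo, q_hi)` windows, each containing at least
#'   5 grid points.
#' @param model `"lorentzian"` or `"gaussian"`, recycled over windows.
#' @return A list of `peak_fit` objects (fields: center, fwhm, amplitude,
#'   area, model, goodness, converged, se).
#' @export
fit_peaks <- function(scan, windows, model = "lorentzian") {
  stopifnot(inherits(scan, "line_scan"))
  if (!is.list(windows)) windows <- list(windows)
  model <- rep_len(model, length(windows))
  lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    sel <- scan$q >= w[1] & scan$q <= w[2]
    if (sum(sel) < 5)
      stop_domain(sprintf("window [%g, %g] contains fewer than 5 points",
                          w[1], w[2]))
    fit_one_peak(scan$q[sel], scan$intensity[sel], model[i], w)
  })
}

fit_one_peak <- function(q, y, model, window) {
  ys <- max(y)                     # normalise: keeps port well-conditioned
  yn <- y / ys
  st <- .peak_start(q, yn)
  fun <- if (model == "lorentzian") .peak_lor else .peak_gau
  dat <- data.frame(q = q, yn = yn)
  fit <- tryCatch(
    .nls_refit(yn ~ b0 + b1 * q + A * fun(q, c0, fw), data = dat,
               env = list(fun = fun),
               start = list(b0 = st$b0, b1 = 0, A = st$amplitude,
                            c0 = st$center, fw = st$fwhm),
               lower = c(-Inf, -Inf, 0, window[1], 1e-6 * diff(window)),
               upper = c(Inf, Inf, Inf, window[2], 10 * diff(window))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    pf <- peak_fit_obj(st$center, st$fwhm, ys * st$amplitude, model, window,
                       converged = FALSE)
    pf$diagnostics <- conditionMessage(fit)
    return(pf)
  }
  p <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
  if (!is.null(se)) se[c("b0", "b1", "A")] <- ys * se[c("b0", "b1", "A")]
  conv <- .nls_converged(fit)
  pf <- peak_fit_obj(unname(p["c0"]), unname(p["fw"]), ys * unname(p["A"]),
                     model, window,
                     goodness = ys * sqrt(mean(residuals(fit)^2)),
                     converged = conv, se = se)
  pf$background <- ys * unname(p[c("b0", "b1")])
  pf
}

#' Fit several overlapping peaks in one window
#'
#' Simultaneous least-squares fit of a shared linear background plus one
#' component per entry of `centers` (used e.g. to separate the narrow
#' cross-beta strand reflection at ~1.35 1/A and the gel head-group doublet
#' at 1.43/1.50 1/A from the broad fluid chain peak at ~1.4 1/A).
#'
#' @param scan a [line_scan()].
#' @param window `c(q_lo, q_hi)`.
#' @param centers starting peak positions (1/Angstrom).
#' @param model per-peak model, `"lorentzian"` or `"gaussian"`, recycled.
#' @param fwhm_init optional starting FWHM per peak.
#' @return A list of `peak_fit` objects, in the order of `centers`.
#' @export
fit_multipeak <- function(scan, window, centers, model = "lorentzian",
                          fwhm_init = NULL) {
  stopifnot(inherits(scan, "line_scan"))
  sel <- scan$q >= window[1] & scan$q <= window[2]
  q <- scan$q[sel]; y <- scan$intensity[sel]
  k <- length(centers)
  if (sum(sel) < 3 * k + 2)
    stop_domain("window too small for the requested number of peaks")
  model <- rep_len(model, k)
  if (is.null(fwhm_init)) fwhm_init <- rep(diff(window) / (4 * k), k)
  fwhm_init <- rep_len(fwhm_init, k)
  ys <- max(y)
  y <- y / ys
  b0 <- min(y)
  amp0 <- vapply(centers, function(cc) {
    max(y[which.min(abs(q - cc))] - b0, 1e-3 * (max(y) - b0 + 1e-12))
  }, numeric(1))
  funs <- lapply(model, function(m)
    if (m == "lorentzian") .peak_lor else .peak_gau)
  # build the model expression A1*f1(q,c1,w1) + ... dynamically
  terms <- paste0("A", seq_len(k), " * funs[[", seq_len(k),
                  "]](q, c", seq_len(k), ", w", seq_len(k), ")",
                  collapse = " + ")
  form <- stats::as.formula(paste("y ~ b0 + b1 * q +", terms))
  start <- c(list(b0 = b0, b1 = 0),
             setNames(as.list(amp0), paste0("A", seq_len(k))),
             setNames(as.list(centers), paste0("c", seq_len(k))),
             setNames(as.list(fwhm_init), paste0("w", seq_len(k))))
  lower <- c(-Inf, -Inf, rep(0, k), rep(window[1], k),
             rep(1e-6 * diff(window), k))
  upper <- c(Inf, Inf, rep(Inf, k), rep(window[2], k),
             rep(5 * diff(window), k))
  # port expects bounds in start order
  ord <- names(start)
  names(lower) <- names(upper) <- c("b0", "b1", paste0("A", seq_len(k)),
                                    paste0("c", seq_len(k)),
                                    paste0("w", seq_len(k)))
  fit <- tryCatch(
    .nls_refit(form, data = data.frame(q = q, y = y), env = list(funs = funs),
               start = start, lower = lower[ord], upper = upper[ord]),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- lapply(seq_len(k), function(i) {
      pf <- peak_fit_obj(centers[i], fwhm_init[i], ys * amp0[i], model[i],
                         window, converged = FALSE)
      pf$diagnostics <- conditionMessage(fit)
      pf
    })
    return(out)
  }
  p <- coef(fit)
  gof <- ys * sqrt(mean(residuals(fit)^2))
  conv <- .nls_converged(fit)
  lapply(seq_len(k), function(i) {
    pf <- peak_fit_obj(unname(p[paste0("c", i)]), unname(p[paste0("w", i)]),
                       ys * unname(p[paste0("A", i)]), model[i], window,
                       goodness = gof, converged = conv)
    pf$background <- ys * unname(p[c("b0", "b1")])
    pf
  })
}

# simple local-maximum peak finder used by the pipeline to seed windows
find_scan_peaks <- function(scan, min_prominence = 0.02, min_sep = 0) {
  y <- scan$intensity; q <- scan$q
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(i)) return(numeric(0))
  base <- stats::quantile(y, 0.1)
  keep <- (y[i] - base) >= min_prominence * (max(y) - base)
  i <- i[keep]
  if (min_sep > 0 && length(i) > 1) {
    i <- i[order(-y[i])]
    picked <- integer(0)
    for (j in i) if (!length(picked) || all(abs(q[j] - q[picked]) >= min_sep))
      picked <- c(picked, j)
    i <- sort(picked)
  }
  q[i]
}
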