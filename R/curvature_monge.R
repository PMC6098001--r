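# Monge-gauge curvature of head-group surfaces.
#
# The surface is a height field delta(x, y) = z - d0 over the bilayer
# centre plane d0.  Curvature is computed in the divergence form
#   K = -div( grad(delta) / sqrt(1 + |grad(delta)|^2) )
# which reduces to -laplacian(delta) in the small-gradient limit.
#
# Sign convention (fixed package-wide): the curvature carries the sign of
# the central deformation - a depression (delta < 0 at its centre) has
# negative curvature there, matching the physical statement that peptide
# partitioning imprints negative curvature on both leaflets.  For a
# Gaussian deformation A*exp(-r^2/2w^2) the centre curvature is 2A/w^2;
# for a quadratic section f(x) = a x^2 + b x + c the section curvature is
# K = -2a (so an upward-opening parabola, a local depression, is
# negative).

#' Head-group surface point cloud
#'
#' @param points data.frame with columns `leaflet` (1 = upper, 2 = lower),
#'   `x`, `y`, `z` (Angstrom); at least 16 points per leaflet.
#' @param d0 bilayer-centre reference height (Angstrom); default: mean of
#'   the per-leaflet mean heights.
#' @param metadata free-form named list.
#' @return An object of class `surface_point_cloud`.
#' @export
surface_point_cloud <- function(points, d0 = NULL, metadata = list()) {
  req <- c("leaflet", "x", "y", "z")
  if (!all(req %in% names(points)))
    stop_domain("points needs columns leaflet, x, y, z")
  if (any(!is.finite(as.matrix(points[req]))))
    stop_domain("coordinates must be finite")
  cnt <- table(points$leaflet)
  if (any(cnt < 16))
    stop_domain("need at least 16 points per leaflet")
  if (is.null(d0))
    d0 <- mean(tapply(points$z, points$leaflet, mean))
  structure(list(points = points[req], d0 = d0, metadata = metadata),
            class = "surface_point_cloud")
}

#' @export
print.surface_point_cloud <- function(x, ...) {
  cat(sprintf("<surface_point_cloud> %d points, %d leaflets, d0 = %.2f A\n",
              nrow(x$points), length(unique(x$points$leaflet)), x$d0))
  invisible(x)
}

# grid one leaflet: returns list(x, y, z matrix [nx, ny], h spacing)
grid_leaflet <- function(surface, leaflet = 1, grid_spacing = NULL) {
  p <- surface$points[surface$points$leaflet == leaflet, ]
  if (!nrow(p)) stop_domain("no points in leaflet ", leaflet)
  if (is.null(grid_spacing)) {
    xs <- sort(unique(round(p$x, 6))); ys <- sort(unique(round(p$y, 6)))
    hx <- median(diff(xs)); hy <- median(diff(ys))
  } else {
    hx <- hy <- grid_spacing
    xs <- seq(min(p$x), max(p$x) + hx / 2, by = hx)
    ys <- seq(min(p$y), max(p$y) + hy / 2, by = hy)
  }
  if (abs(hx - hy) > 1e-6 * hx)
    stop_domain("anisotropic grids are not supported")
  ix <- round((p$x - xs[1]) / hx) + 1L
  iy <- round((p$y - ys[1]) / hy) + 1L
  nx <- max(ix); ny <- max(iy)
  zsum <- matrix(0, nx, ny); cnt <- matrix(0L, nx, ny)
  for (k in seq_len(nrow(p))) {
    zsum[ix[k], iy[k]] <- zsum[ix[k], iy[k]] + p$z[k]
    cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1L
  }
  if (any(cnt == 0L)) {
    holes <- which(cnt == 0L, arr.ind = TRUE)
    stop_domain("surface has grid holes at ",
                paste(sprintf("(%d,%d)", holes[, 1], holes[, 2])[
                  seq_len(min(5, nrow(holes)))], collapse = ", "),
                if (nrow(holes) > 5) " ..." else "")
  }
  list(x = xs[seq_len(nx)], y = ys[seq_len(ny)], z = zsum / cnt, h = hx)
}

#' Monge-gauge curvature field of a head-group surface
#'
#' Grids the leaflet height field, forms `delta = z - d0` and evaluates
#' \deqn{K = -\nabla\cdot(\nabla\delta / \sqrt{1 + |\nabla\delta|^2})}
#' by central finite differences (`method = "divergence"`), or its
#' small-gradient limit, the negative Laplacian (`method = "laplacian"`,
#' default - the regime the analysis is intended for).  Border cells,
#' where no central stencil exists, are `NA`.
#'
#' @param surface a [surface_point_cloud()].
#' @param grid_spacing target grid spacing (Angstrom); `NULL` to use the
#'   native point grid.
#' @param leaflet which leaflet to analyse (default 1, upper).
#' @param method `"laplacian"` or `"divergence"`.
#' @return A list of class `curvature_field`: `x`, `y`, `K` (matrix,
#'   1/Angstrom), `delta`, `h`.
#' @export
monge_curvature_field <- function(surface, grid_spacing = NULL, leaflet = 1,
                                  method = c("laplacian", "divergence")) {
  stopifnot(inherits(surface, "surface_point_cloud"))
  method <- match.arg(method)
  g <- grid_leaflet(surface, leaflet, grid_spacing)
  delta <- g$z - surface$d0
  h <- g$h
  nx <- nrow(delta); ny <- ncol(delta)
  K <- matrix(NA_real_, nx, ny)
  ii <- 2:(nx - 1); jj <- 2:(ny - 1)
  if (method == "laplacian") {
    lap <- (delta[ii - 1, jj] + delta[ii + 1, jj] +
              delta[ii, jj - 1] + delta[ii, jj + 1] -
              4 * delta[ii, jj]) / h^2
    K[ii, jj] <- -lap
  } else {
    # staggered (face-centred) flux scheme: reduces exactly to the compact
    # 5-point Laplacian when the gradient normalisation tends to 1, so the
    # divergence and Laplacian forms differ only by the nonlinear slope
    # correction, not by stencil width
    gyn <- matrix(0, nx, ny)               # nodal d(delta)/dy
    gyn[, jj] <- (delta[, jj + 1] - delta[, jj - 1]) / (2 * h)
    gyn[, c(1, ny)] <- gyn[, c(2, ny - 1)]
    gxn <- matrix(0, nx, ny)               # nodal d(delta)/dx
    gxn[ii, ] <- (delta[ii + 1, ] - delta[ii - 1, ]) / (2 * h)
    gxn[c(1, nx), ] <- gxn[c(2, nx - 1), ]
    # x-faces between rows i and i+1
    gxf <- (delta[-1, ] - delta[-nx, ]) / h
    gyf_x <- (gyn[-1, ] + gyn[-nx, ]) / 2
    Fx <- gxf / sqrt(1 + gxf^2 + gyf_x^2)
    # y-faces between columns j and j+1
    gyf <- (delta[, -1] - delta[, -ny]) / h
    gxf_y <- (gxn[, -1] + gxn[, -ny]) / 2
    Fy <- gyf / sqrt(1 + gyf^2 + gxf_y^2)
    div <- (Fx[ii, jj] - Fx[ii - 1, jj]) / h +
      (Fy[ii, jj] - Fy[ii, jj - 1]) / h
    K[ii, jj] <- -div
  }
  structure(list(x = g$x, y = g$y, K = K, delta = delta, h = h),
            class = "curvature_field")
}

#' Curvature at the point of maximum deformation
#'
#' Extracts a 1D section through the grid point of maximum |deformation|
#' (deformation = height minus the leaflet median plane), along the
#' lateral axis of larger local curvature, fits
#' `f(x) = a x^2 + b x + c` to the section within its half-maximum
#' region, and reports the small-slope section curvature `K = -2a` (sign
#' convention above) together with the touching-circle radius
#' `rho = 1/|K|`.  A degenerate fit (`|a|` below `tol`) reports zero
#' curvature and infinite rho rather than failing.
#'
#' @param surface a [surface_point_cloud()].
#' @param leaflet leaflet to analyse.
#' @param grid_spacing optional regridding spacing (Angstrom).
#' @param tol curvature magnitude below which the section is considered
#'   flat (1/Angstrom).
#' @return A list with `K_max` (1/Angstrom), `rho` (Angstrom),
#'   `quad_coeffs` (`a`, `b`, `c`), `section` (data.frame `x`, `delta`).
#' @export
max_deformation_curvature <- function(surface, leaflet = 1,
                                      grid_spacing = NULL, tol = 1e-10) {
  stopifnot(inherits(surface, "surface_point_cloud"))
  g <- grid_leaflet(surface, leaflet, grid_spacing)
  dev <- g$z - median(g$z)
  idx <- which(abs(dev) == max(abs(dev)), arr.ind = TRUE)[1, ]
  # pick the section axis with the larger |second difference| at the peak
  i <- idx[1]; j <- idx[2]
  d2x <- if (i > 1 && i < nrow(dev))
    abs(dev[i - 1, j] - 2 * dev[i, j] + dev[i + 1, j]) else -Inf
  d2y <- if (j > 1 && j < ncol(dev))
    abs(dev[i, j - 1] - 2 * dev[i, j] + dev[i, j + 1]) else -Inf
  if (d2x >= d2y) {
    xs <- g$x; sec <- dev[, j]; at <- i
  } else {
    xs <- g$y; sec <- dev[i, ]; at <- j
  }
  # contiguous half-maximum window through the extremum (>= 7 points).
  # The run is found on a 3-point moving average so that point noise does
  # not truncate it - the window must depend on the deformation shape, not
  # its noise realisation, for curvature ratios between surfaces to be
  # meaningful.
  n <- length(sec)
  sm <- sec
  sm[2:(n - 1)] <- (sec[1:(n - 2)] + sec[2:(n - 1)] + sec[3:n]) / 3
  peak <- abs(sm[at])
  keep <- abs(sm) >= peak / 2
  lo <- at; while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- at; while (hi < n && keep[hi + 1]) hi <- hi + 1
  while (hi - lo + 1 < 7) {
    if (lo > 1) lo <- lo - 1
    if (hi < n) hi <- hi + 1
    if (lo == 1 && hi == n) break
  }
  if (hi - lo + 1 < 5)
    stop_domain("section too short for a quadratic fit")
  xw <- xs[lo:hi] - xs[at]; yw <- sec[lo:hi]
  co <- coef(lm(yw ~ xw + I(xw^2)))
  a <- unname(co[3]); b <- unname(co[2]); cc <- unname(co[1])
  K <- -2 * a
  if (abs(K) < tol) {
    K <- 0; rho <- Inf
  } else rho <- 1 / abs(K)
  list(K_max = K, rho = rho, quad_coeffs = c(a = a, b = b, c = cc),
       section = data.frame(x = xs[lo:hi], delta = yw))
}
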