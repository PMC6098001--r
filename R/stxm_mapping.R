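# STXM stack processing: Beer-Lambert optical density, two-component
# spectral unmixing, peptide-cluster morphometry.

#' STXM transmission stack
#'
#' @param energies photon energies (eV), strictly increasing; one image
#'   per energy.
#' @param images 3D array `[nx, ny, n_energies]` of transmitted flux, or a
#'   list of matrices.
#' @param i0 incident flux: scalar or an `nx x ny` matrix, `> 0`.
#' @param pixel_nm pixel size (nm).
#' @param metadata free-form named list.
#' @return An object of class `stxm_stack`.
#' @export
stxm_stack <- function(energies, images, i0, pixel_nm, metadata = list()) {
  energies <- as.numeric(energies)
  if (any(diff(energies) <= 0))
    stop_domain("energies must be strictly increasing")
  if (is.list(images)) images <- simplify2array(images)
  if (length(dim(images)) != 3 || dim(images)[3] != length(energies))
    stop_domain("need one image per energy ([nx, ny, n_energies] array)")
  if (any(i0 <= 0)) stop_domain("i0 must be positive")
  if (pixel_nm <= 0) stop_domain("pixel_nm must be positive")
  structure(list(energies = energies, images = images, i0 = i0,
                 pixel_nm = pixel_nm, metadata = metadata),
            class = "stxm_stack")
}

#' @export
print.stxm_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<stxm_stack> %d x %d px (%g nm), %d energies %.5g-%.5g eV\n",
              d[1], d[2], x$pixel_nm, d[3], min(x$energies), max(x$energies)))
  invisible(x)
}

#' Convert transmitted flux to optical density
#'
#' Beer-Lambert law, per pixel and energy: `OD = -ln(I / I0)`.  Pixels
#' with non-positive transmitted flux (or `i0`) are masked to `NA`; the
#' masked-pixel count is reported in the attribute `n_masked`.
#'
#' @param stack an [stxm_stack()].
#' @return A 3D array of OD with attributes `energies`, `pixel_nm`,
#'   `n_masked`.
#' @export
to_optical_density <- function(stack) {
  stopifnot(inherits(stack, "stxm_stack"))
  I <- stack$images
  bad <- I <= 0
  I[bad] <- NA_real_
  od <- -log(sweep(I, c(1, 2), array(stack$i0, dim(I)[1:2]), "/"))
  structure(od, energies = stack$energies, pixel_nm = stack$pixel_nm,
            n_masked = sum(bad))
}

# exact non-negative least squares for two components, vectorised over
# pixels: unconstrained 2x2 solve, then the better of the two clamped
# single-component solutions wherever a weight goes negative.
nnls2 <- function(R, B) {
  G <- crossprod(R)                  # 2 x 2
  gb <- crossprod(R, B)              # 2 x P
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  w1 <- (G[2, 2] * gb[1, ] - G[1, 2] * gb[2, ]) / det
  w2 <- (G[1, 1] * gb[2, ] - G[1, 2] * gb[1, ]) / det
  neg <- w1 < 0 | w2 < 0
  if (any(neg)) {
    a1 <- pmax(gb[1, neg] / G[1, 1], 0)      # component-1-only solution
    a2 <- pmax(gb[2, neg] / G[2, 2], 0)
    # residual^2 = const - 2 w.gb + w.G.w ; compare the data-dependent part
    s1 <- -2 * a1 * gb[1, neg] + a1^2 * G[1, 1]
    s2 <- -2 * a2 * gb[2, neg] + a2^2 * G[2, 2]
    use1 <- s1 <= s2
    w1[neg] <- ifelse(use1, a1, 0)
    w2[neg] <- ifelse(use1, 0, a2)
  }
  rbind(w1, w2)
}

#' Unmix an optical-density stack into lipid and peptide component maps
#'
#' Per-pixel non-negative least squares of OD(E) against the two reference
#' spectra.  Weights are physical component thicknesses, hence the
#' non-negativity constraint (the unconstrained SVD projection is used as
#' the interior solution and clamped on the boundary where it goes
#' negative).  Collinear references are rejected by a condition-number
#' check.
#'
#' @param od_stack OD array from [to_optical_density()] (energies in its
#'   attributes), or a plain 3D array plus `energies`.
#' @param ref matrix with columns `lipid`, `peptide`: reference OD per
#'   unit thickness sampled on the stack's energies.
#' @param energies photon energies; defaults to the attribute of
#'   `od_stack`.
#' @param max_condition maximum allowed condition number of the normal
#'   matrix.
#' @return A list of class `component_maps`: matrices `lipid`, `peptide`,
#'   `residual` (per-pixel residual norm) and `n_clipped`, the number of
#'   pixels where negativity was clipped.
#' @export
unmix_components <- function(od_stack, ref, energies = NULL,
                             max_condition = 1e10) {
  energies <- energies %||% attr(od_stack, "energies")
  if (is.null(energies)) stop_domain("energies are required")
  ref <- as.matrix(ref)
  if (nrow(ref) != length(energies) || ncol(ref) != 2)
    stop_domain("ref must sample 2 component spectra on the stack energies")
  if (kappa(crossprod(ref), exact = TRUE) > max_condition)
    stop_domain("reference spectra are collinear (condition number above ",
                "threshold): unmixing is ill-posed")
  d <- dim(od_stack)
  B <- t(matrix(od_stack, d[1] * d[2], d[3]))   # energies x pixels
  ok <- colSums(is.na(B)) == 0
  W <- matrix(NA_real_, 2, ncol(B))
  res <- rep(NA_real_, ncol(B))
  if (any(ok)) {
    W[, ok] <- nnls2(ref, B[, ok, drop = FALSE])
    res[ok] <- sqrt(colSums((ref %*% W[, ok, drop = FALSE] -
                               B[, ok, drop = FALSE])^2))
  }
  interior <- nnls_interior_count(ref, B[, ok, drop = FALSE])
  structure(list(lipid = matrix(W[1, ], d[1], d[2]),
                 peptide = matrix(W[2, ], d[1], d[2]),
                 residual = matrix(res, d[1], d[2]),
                 n_clipped = interior),
            class = "component_maps")
}

nnls_interior_count <- function(R, B) {
  if (!ncol(B)) return(0L)
  G <- crossprod(R); gb <- crossprod(R, B)
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  w1 <- (G[2, 2] * gb[1, ] - G[1, 2] * gb[2, ]) / det
  w2 <- (G[1, 1] * gb[2, ] - G[1, 2] * gb[1, ]) / det
  sum(w1 < 0 | w2 < 0)
}

#' Otsu automatic threshold
#'
#' Histogram split maximising the between-class variance; the default
#' threshold for [cluster_morphometry()].
#'
#' @param x numeric values (NAs dropped).
#' @param n_bins histogram resolution.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (!length(x)) stop_domain("no finite values to threshold")
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(floor((x - r[1]) / diff(r) * n_bins) + 1L, n_bins),
                n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # the maximum is a plateau when the histogram has an empty gap; split in
  # the middle of it
  k <- round(median(which(sigma_b >= max(sigma_b) - 1e-12)))
  r[1] + k / n_bins * diff(r)
}

# two-pass 8/4-connected component labelling with union-find
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(2 + sum(mask) %/% 2)
  nlab <- 0L
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1L && mask[i - 1L, j]) nb <- lab[i - 1L, j]
      if (j > 1L) {
        if (mask[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
        if (connectivity == 8) {
          if (i > 1L && mask[i - 1L, j - 1L]) nb <- c(nb, lab[i - 1L, j - 1L])
          if (i < nr && mask[i + 1L, j - 1L]) nb <- c(nb, lab[i + 1L, j - 1L])
        }
      }
      if (!length(nb)) {
        nlab <- nlab + 1L
        if (nlab > length(parent)) parent <- c(parent, integer(nlab))
        parent[nlab] <- nlab
        lab[i, j] <- nlab
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        m <- min(roots)
        lab[i, j] <- m
        for (r in roots) parent[r] <- m
      }
    }
  }
  if (nlab == 0L) return(lab)
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  idx <- lab > 0L
  lab[idx] <- relab[lab[idx]]
  lab
}

#' Morphometry of peptide clusters in a component map
#'
#' Binarises the map at `threshold` (Otsu by default), labels connected
#' components (8-connected), excludes components touching the image border
#' (their widths are censored), and reports per-cluster equivalent-circle
#' diameters \eqn{2\sqrt{A/\pi}} in nm.
#'
#' @param peptide_map matrix of peptide component weights.
#' @param pixel_nm pixel size (nm).
#' @param threshold binarisation threshold; `NULL` for Otsu.
#' @param exclude_border drop clusters touching the border (default TRUE).
#' @param connectivity 8 (default) or 4.
#' @return A list of class `cluster_stats`: `count`, `mean_width`,
#'   `sd_width`, `widths` (nm), `threshold`, `labels` (label matrix).
#'   An empty map yields `count = 0`, not an error.
#' @export
cluster_morphometry <- function(peptide_map, pixel_nm, threshold = NULL,
                                exclude_border = TRUE, connectivity = 8) {
  if (pixel_nm <= 0) stop_domain("pixel_nm must be positive")
  if (is.null(threshold)) threshold <- otsu_threshold(peptide_map)
  rng <- range(peptide_map, na.rm = TRUE)
  if (threshold < rng[1] || threshold > rng[2])
    stop_domain("threshold lies outside the map's value range")
  mask <- !is.na(peptide_map) & peptide_map >= threshold
  lab <- label_components(mask, connectivity)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (exclude_border && length(ids)) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    ids <- setdiff(ids, border)
  }
  if (!length(ids)) {
    return(structure(list(count = 0L, mean_width = NA_real_,
                          sd_width = NA_real_, widths = numeric(0),
                          threshold = threshold, labels = lab),
                     class = "cluster_stats"))
  }
  areas <- tabulate(lab[lab %in% ids], max(ids))[ids]
  widths <- 2 * sqrt(areas / pi) * pixel_nm
  structure(list(count = length(ids), mean_width = mean(widths),
                 sd_width = if (length(widths) > 1) sd(widths) else 0,
                 widths = widths, threshold = threshold, labels = lab),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("<cluster_stats> %d clusters, width %.1f +/- %.1f nm\n",
              x$count, x$mean_width, x$sd_width))
  invisible(x)
}
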