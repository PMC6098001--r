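# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (direct summation, grid search, closed forms).

# trapezoidal quadrature
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# Hermans f of an intensity profile by trapezoidal quadrature on a dense
# grid (independent of hermans_from_mosaic's integrate() path)
hermans_quadrature_oracle <- function(intensity_fun) {
  d <- seq(0, 90, length.out = 20001)
  w <- intensity_fun(d)
  cos2 <- trapz(d, w * cos(d * pi / 180)^2) / trapz(d, w)
  (3 * cos2 - 1) / 2
}

# brute-force non-negative least squares for two components: coarse grid
# plus iterative refinement
nnls2_bruteforce <- function(R, b, w_max = 10) {
  obj <- function(w) sum((R %*% w - b)^2)
  lo <- c(0, 0); hi <- c(w_max, w_max)
  best <- c(0, 0)
  for (iter in 1:12) {
    g1 <- seq(lo[1], hi[1], length.out = 21)
    g2 <- seq(lo[2], hi[2], length.out = 21)
    vals <- outer(g1, g2, Vectorize(function(a, b2) obj(c(a, b2))))
    k <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(g1[k[1]], g2[k[2]])
    span1 <- (hi[1] - lo[1]) / 10; span2 <- (hi[2] - lo[2]) / 10
    lo <- pmax(c(best[1] - span1, best[2] - span2), 0)
    hi <- c(best[1] + span1, best[2] + span2)
  }
  best
}

# a small isotropic test map whose intensity depends only on Q
isotropic_map <- function(fun, q_step = 0.01, q_par_max = 2,
                          q_z_range = c(0.03, 1)) {
  q_par <- seq(q_step, q_par_max, by = q_step)
  q_z <- seq(q_z_range[1], q_z_range[2], by = q_step)
  Q <- sqrt(outer(q_par^2, q_z^2, "+"))
  reciprocal_map(q_par, q_z, fun(Q))
}

# quick ground truth with mild noise for round-trip tests
quick_gt <- function(seed = 1, ...) {
  condition_ground_truth("none", 20, seed = seed, ...)
}
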