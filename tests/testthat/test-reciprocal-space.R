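# Containers, conversions, wedge/azimuthal reductions, peak fitting.

test_that("q_to_d / d_to_q reproduce printed spacings and invert", {
  expect_equal(q_to_d(1.85), 3.40, tolerance = 0.005 / 3.40)
  expect_equal(q_to_d(2 * pi), 1.0)
  expect_equal(q_to_d(0.7), 8.98, tolerance = 0.005 / 8.98)
  x <- c(0.01, 0.7, 1.35, 1.85, 10)
  expect_equal(q_to_d(d_to_q(x)), x)
  expect_equal(d_to_q(q_to_d(x)), x)
  expect_error(q_to_d(0), "positive")
  expect_error(d_to_q(-1), "positive")
})

test_that("container validation rejects malformed inputs", {
  expect_error(line_scan(c(1, 2, 2), c(1, 1, 1)), "strictly increasing")
  expect_error(line_scan(1:3, c(1, -1, 1)), "non-negative")
  expect_error(line_scan(1:3, 1:2), "same length")
  expect_error(reciprocal_map(1:3, 1:3, matrix(1, 2, 3)), "matrix")
  expect_error(reciprocal_map(1, 1:3, matrix(1, 1, 3)), "extent")
  expect_error(angular_profile(c(-5, 10), c(1, 1)), "within")
})

test_that("wedge integration is isotropy-consistent and conserves counts", {
  map <- isotropic_map(function(Q) exp(-(Q - 0.8)^2 / 0.02) + 0.1)
  w1 <- wedge_integrate(map, 30, 60)
  w2 <- wedge_integrate(map, 60, 90)
  shared <- intersect(round(w1$q, 9), round(w2$q, 9))
  i1 <- match(shared, round(w1$q, 9)); i2 <- match(shared, round(w2$q, 9))
  # identical I(Q) in equal-width wedges of an isotropic map (bin tolerance)
  expect_lt(median(abs(w1$intensity[i1] - w2$intensity[i2]) /
                     w2$intensity[i2]), 0.02)

  # pixel-count-weighted recombination of disjoint wedges == full integral
  wedges <- list(c(0, 30), c(30, 60), c(60, 90))
  tot <- sum(vapply(wedges, function(w) {
    s <- wedge_integrate(map, w[1], w[2])
    sum(s$intensity * s$metadata$counts)
  }, numeric(1)))
  expect_equal(tot, sum(map$intensity))
})

test_that("wedge integration rejects bad wedges and excludes low angles", {
  map <- isotropic_map(function(Q) Q * 0 + 1)
  expect_error(wedge_integrate(map, 50, 40), "gamma_lo")
  # a map with intensity only below 30 deg yields a flat-zero default wedge
  pol <- lamellaR:::map_polar(map)
  I <- ifelse(pol$gamma < 30, 5, 0)
  map2 <- reciprocal_map(map$q_par, map$q_z,
                         matrix(I, length(map$q_par)))
  w <- wedge_integrate(map2)   # default 30-90 deg
  expect_true(all(w$intensity == 0))
  # narrow wedge far outside the grid's angular span errors
  tiny <- reciprocal_map(c(1, 1.01), c(0.001, 0.002), matrix(1, 2, 2))
  expect_error(wedge_integrate(tiny, 80, 90), "empty wedge")
})

test_that("azimuthal profiles locate equatorial arcs and validate annuli", {
  map <- isotropic_map(function(Q) Q * 0 + 1)
  pol <- lamellaR:::map_polar(map)
  I <- exp(-pol$gamma^2 / (2 * 8^2)) * exp(-(pol$Q - 1.4)^2 / 0.005)
  arc <- reciprocal_map(map$q_par, map$q_z, matrix(I, length(map$q_par)))
  pr <- azimuthal_profile(arc, 1.4, 0.1, kind = "gamma",
                          angle_range = c(0, 90))
  expect_equal(pr$angle[which.max(pr$intensity)], min(pr$angle))
  expect_error(azimuthal_profile(arc, 0.05, 0.2, kind = "gamma"),
               "positive")
  expect_error(azimuthal_profile(arc, 5, 0.1, kind = "delta"),
               "outside the map")
})

test_that("single-peak fits recover exact parameters on noiseless data", {
  q <- seq(1.0, 1.8, by = 1e-3)
  for (model in c("lorentzian", "gaussian")) {
    fun <- if (model == "lorentzian") lamellaR:::.peak_lor else
      lamellaR:::.peak_gau
    y <- 2 + 0.5 * q + 7 * fun(q, 1.4, 0.1)
    fit <- fit_peaks(line_scan(q, y), list(c(1.1, 1.7)), model = model)[[1]]
    expect_true(fit$converged)
    expect_equal(fit$center, 1.4, tolerance = 1e-6)
    expect_equal(fit$fwhm, 0.1, tolerance = 1e-6)
    expect_equal(fit$amplitude, 7, tolerance = 1e-6)
  }
})

test_that("fitted areas agree with quadrature and scale linearly", {
  q <- seq(0.8, 2.0, by = 5e-4)
  y <- 1 + 4 * lamellaR:::.peak_gau(q, 1.4, 0.08)
  scan <- line_scan(q, y)
  fit <- fit_peaks(scan, list(c(1.1, 1.7)), model = "gaussian")[[1]]
  bgsub <- y - (fit$background[1] + fit$background[2] * q)
  expect_equal(fit$area, trapz(q, bgsub), tolerance = 0.01)
  # linearity: rescaling intensity rescales the area by the same factor
  fit5 <- fit_peaks(line_scan(q, 5 * y), list(c(1.1, 1.7)),
                    model = "gaussian")[[1]]
  expect_equal(fit5$area / fit$area, 5, tolerance = 1e-6)
})

test_that("overlapping gel doublet at 1.43/1.50 is resolved", {
  q <- seq(1.2, 1.8, by = 5e-4)
  y <- 3 + 6 * lamellaR:::.peak_gau(q, 1.43, 0.02) +
    8 * lamellaR:::.peak_gau(q, 1.50, 0.02) +
    2 * lamellaR:::.peak_lor(q, 1.40, 0.25)
  fits <- fit_multipeak(line_scan(q, y), c(1.25, 1.75),
                        centers = c(1.40, 1.43, 1.50),
                        model = c("lorentzian", "gaussian", "gaussian"),
                        fwhm_init = c(0.2, 0.02, 0.02))
  expect_true(all(vapply(fits, function(p) p$converged, logical(1))))
  expect_equal(fits[[2]]$center, 1.43, tolerance = 1e-4)
  expect_equal(fits[[3]]$center, 1.50, tolerance = 1e-4)
  cell <- index_headgroup_cell(fits[[2]]$center, fits[[3]]$center)
  expect_equal(round(cell$a, 1), 8.4)
  expect_equal(round(cell$b, 1), 8.8)
})

test_that("fit windows must contain enough points", {
  scan <- line_scan(seq(1, 2, 0.1), rep(1, 11))
  expect_error(fit_peaks(scan, list(c(1.0, 1.2))), "fewer than 5")
})
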