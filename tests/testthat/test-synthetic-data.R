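# Generators: placement accuracy, ground-truth embedding, invariants.

test_that("ground_truth validates its invariants", {
  expect_error(ground_truth(d_z = -1), "d_z")
  expect_error(ground_truth(n_orders = 1), "orders")
  expect_error(ground_truth(peptide_area_fraction = 1.2), "\\[0, 1\\]")
  expect_error(ground_truth(domain_length = 0), "domain_length")
  expect_error(ground_truth(chain_hwhm = -0.1), "widths")
  gt <- ground_truth()
  expect_s3_class(gt, "ground_truth")
  expect_equal(gt$phases, sign(gt$form_factors))
})

test_that("lamellar scans place Bragg peaks at n*2pi/d_z", {
  gt <- ground_truth(d_z = 69.5, n_orders = 7, d_hh = 41.8,
                     noise_scale = 0)
  sc <- gen_lamellar_scan(gt)
  # argmax at the first order, grid-resolution limited
  i <- which.max(sc$intensity)
  expect_lt(abs(sc$q[i] - 2 * pi / 69.5), 2.6e-4)
  # fitted centres sit at n*2pi/d_z for all orders
  qn <- (1:7) * 2 * pi / 69.5
  fits <- fit_peaks(sc, lapply(qn, function(q0) c(q0 - 0.012, q0 + 0.012)),
                    model = "gaussian")
  expect_equal(vapply(fits, `[[`, numeric(1), "center"), qn,
               tolerance = 1e-5)
  expect_identical(sc$metadata$ground_truth$d_z, 69.5)
  expect_error(gen_lamellar_scan(gt, q_step = 0), "q_step")
})

test_that("lamellar round trip recovers d_z within 0.1 A across seeds", {
  for (s in c(2, 17, 301)) {
    gt <- quick_gt(seed = s)
    rl <- analyze_lamellar(gen_lamellar_scan(gt))
    expect_lt(abs(rl$d_z - gt$d_z), 0.1)
  }
})

test_that("maps omit cross-beta features when phi = 0 and are symmetric at tilt 0", {
  gt0 <- condition_ground_truth("none", 0, noise_scale = 0)
  expect_identical(gt0$peptide_area_fraction, 0)
  mp <- gen_map2d(gt0)
  pol <- lamellaR:::map_polar(mp)
  ring <- abs(pol$Q - 0.7) < 0.02
  near <- abs(pol$Q - 0.7) >= 0.03 & abs(pol$Q - 0.7) < 0.06
  # no excess intensity at the sheet position over the local background
  expect_lt(mean(mp$intensity[ring]), 1.02 * mean(mp$intensity[near]))

  gt_flat <- ground_truth(tilt_angle = 1e-9, noise_scale = 0)
  mpf <- gen_map2d(gt_flat)
  pr <- azimuthal_profile(mpf, gt_flat$chain_q, 0.08, kind = "gamma",
                          angle_range = c(0, 90), normalize = "count")
  expect_equal(pr$angle[which.max(pr$intensity)], min(pr$angle))
  expect_error(gen_map2d(gt_flat, q_par_max = 0.001), "zero extent")
})

test_that("generated intensities are non-negative and seed-deterministic", {
  gt <- quick_gt(seed = 11)
  s1 <- gen_lamellar_scan(gt); s2 <- gen_lamellar_scan(gt)
  expect_identical(s1$intensity, s2$intensity)
  expect_true(all(s1$intensity >= 0))
  i1 <- gen_inplane_scan(gt); i2 <- gen_inplane_scan(gt)
  expect_identical(i1$intensity, i2$intensity)
  m1 <- gen_map2d(gt); m2 <- gen_map2d(gt)
  expect_identical(m1$intensity, m2$intensity)
  expect_true(all(m1$intensity >= 0))
  x1 <- gen_stxm_stack(seed = 4, n_clusters = 20)
  x2 <- gen_stxm_stack(seed = 4, n_clusters = 20)
  expect_identical(x1$images, x2$images)
})

test_that("surfaces carry the analytic centre curvature as ground truth", {
  # flat surface
  s0 <- surface_ground_truth(depression_amplitude = 0, noise_sigma = 0)
  expect_identical(s0$curvature_center, 0)
  # negative amplitude -> negative centre curvature, = 2A/w^2
  sg <- surface_ground_truth(depression_amplitude = -6,
                             depression_width = 30, noise_sigma = 0,
                             n_side = 81)
  expect_equal(sg$curvature_center, 2 * (-6) / 30^2)
  srf <- gen_surface(sg)
  # oracle: centred second differences of the generated upper leaflet
  p <- srf$points[srf$points$leaflet == 1, ]
  xs <- sort(unique(p$x)); h <- xs[2] - xs[1]
  zmat <- matrix(p$z, length(xs))
  ic <- which.min(abs(xs - sg$center[1]))
  lap <- (zmat[ic - 1, ic] + zmat[ic + 1, ic] + zmat[ic, ic - 1] +
            zmat[ic, ic + 1] - 4 * zmat[ic, ic]) / h^2
  expect_equal(-lap, sg$curvature_center, tolerance = 0.01)
  expect_error(surface_ground_truth(depression_width = 0), "width")
  expect_error(surface_ground_truth(n_side = 7), "64 points")
})

test_that("STXM stacks follow the Beer-Lambert forward model exactly", {
  st <- gen_stxm_stack(seed = 3, noise_scale = 0, n_clusters = 12)
  gt <- st$metadata$ground_truth
  ref <- st$metadata$ref
  # a corner pixel is pure lipid: I = i0 * exp(-OD_lipid)
  expect_equal(st$images[1, 1, ],
               unname(st$i0 * exp(-gt$lipid_thickness * ref[, "lipid"])))
  expect_error(gen_stxm_stack(i0 = 0), "i0")
  expect_error(gen_stxm_stack(energies = c(300, 290)), "increasing")
  expect_error(gen_stxm_stack(energies = c(100, 200)), "280-340")
  expect_error(gen_stxm_stack(pixel_nm = -1), "pixel_nm")
})

test_that("reference spectra separate by the 0.3 eV pi* shift", {
  E <- stxm_default_energies()
  ref <- stxm_reference_spectra(E)
  i_lip <- which.max(lamellaR:::.peak_gau(E, 288.8, 1))
  expect_gt(kappa(crossprod(ref), exact = TRUE), 1)   # well-defined
  expect_lt(kappa(crossprod(ref), exact = TRUE), 1e6) # and well-conditioned
  expect_equal(E[i_lip], 288.8)
})
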