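# Monge-gauge curvature.  Sign convention: K = -laplacian(delta), so a
# depression (delta < 0 at centre) carries negative curvature.

flat_surface <- function(n = 9, z = 5) {
  g <- expand.grid(x = seq(0, 80, length.out = n),
                   y = seq(0, 80, length.out = n))
  surface_point_cloud(rbind(
    data.frame(leaflet = 1, x = g$x, y = g$y, z = z),
    data.frame(leaflet = 2, x = g$x, y = g$y, z = -z)))
}

test_that("flat and quadratic surfaces have closed-form curvature", {
  expect_true(all(abs(na.omit(as.vector(
    monge_curvature_field(flat_surface())$K))) < 1e-12))
  # delta = a (x^2 + y^2): |laplacian| = 4a at interior points
  a <- 0.01
  g <- expand.grid(x = seq(-20, 20, length.out = 21),
                   y = seq(-20, 20, length.out = 21))
  srf <- surface_point_cloud(rbind(
    data.frame(leaflet = 1, x = g$x, y = g$y, z = 5 + a * (g$x^2 + g$y^2)),
    data.frame(leaflet = 2, x = g$x, y = g$y, z = -5)))
  K <- monge_curvature_field(srf, leaflet = 1)$K
  Kin <- K[!is.na(K)]
  expect_equal(Kin, rep(-4 * a, length(Kin)), tolerance = 1e-8)
  # section curvature of the exact parabola: |K| = 2a, rho = 1/(2a)
  mx <- max_deformation_curvature(srf, leaflet = 1)
  expect_equal(abs(mx$K_max), 2 * a, tolerance = 1e-8)
  expect_equal(mx$rho, 1 / (2 * a), tolerance = 1e-6)
  expect_equal(mx$rho * abs(mx$K_max), 1)
})

test_that("Gaussian depressions match the analytic Laplacian under refinement", {
  sgt <- surface_ground_truth(depression_amplitude = -6,
                              depression_width = 30, noise_sigma = 0,
                              n_side = 101)
  srf <- gen_surface(sgt)
  fld <- monge_curvature_field(srf)
  ic <- which.min(abs(fld$x - sgt$center[1]))
  jc <- which.min(abs(fld$y - sgt$center[2]))
  expect_equal(fld$K[ic, jc], sgt$curvature_center, tolerance = 0.01)
  expect_lt(fld$K[ic, jc], 0)                 # depression -> negative K
  # 4x refinement stays within 1% of the analytic value
  sgt4 <- surface_ground_truth(depression_amplitude = -6,
                               depression_width = 30, noise_sigma = 0,
                               n_side = 401)
  fld4 <- monge_curvature_field(gen_surface(sgt4))
  i4 <- which.min(abs(fld4$x - 100)); j4 <- which.min(abs(fld4$y - 100))
  expect_equal(fld4$K[i4, j4], sgt4$curvature_center, tolerance = 0.01)
})

test_that("small-gradient linearity and divergence-form convergence hold", {
  base <- surface_ground_truth(depression_amplitude = -2,
                               depression_width = 40, noise_sigma = 0,
                               n_side = 81)
  f1 <- monge_curvature_field(gen_surface(base))
  twice <- surface_ground_truth(depression_amplitude = -4,
                                depression_width = 40, noise_sigma = 0,
                                n_side = 81)
  f2 <- monge_curvature_field(gen_surface(twice))
  sel <- !is.na(f1$K) & abs(f1$K) > 1e-5
  expect_lt(max(abs(f2$K[sel] / f1$K[sel] - 2)), 0.01)
  # divergence form -> Laplacian form quadratically as amplitude -> 0
  dev_at <- function(amp) {
    s <- gen_surface(surface_ground_truth(depression_amplitude = amp,
                                          depression_width = 40,
                                          noise_sigma = 0, n_side = 81))
    a <- monge_curvature_field(s, method = "laplacian")$K
    b <- monge_curvature_field(s, method = "divergence")$K
    max(abs(a - b), na.rm = TRUE)
  }
  d4 <- dev_at(-4); d2 <- dev_at(-2)
  expect_lt(d2, d4 / 3)   # ~quartic in slope ~ quadratic in amplitude^2
})

test_that("deformation-section curvature mirrors the drug effect direction", {
  # single-section quadratic fits on noisy surfaces are noisy; the
  # proportionality is a property of the estimator's mean over seeds
  ks <- vapply(1:10, function(s) c(
    deep = max_deformation_curvature(gen_surface(
      surface_ground_truth(depression_amplitude = -6, seed = s)))$K_max,
    shallow = max_deformation_curvature(gen_surface(
      surface_ground_truth(depression_amplitude = -2.4, seed = s)))$K_max),
    numeric(2))
  expect_true(all(ks["deep", ] < 0))          # depressions: negative K
  expect_true(all(ks["shallow", ] < 0))
  # 60% shallower depression -> ~60% smaller mean |K|
  expect_equal(mean(ks["shallow", ]) / mean(ks["deep", ]), 0.4,
               tolerance = 0.12)
})

test_that("surface validation and gridding reject bad inputs", {
  g <- expand.grid(x = 1:3, y = 1:3)
  expect_error(surface_point_cloud(
    data.frame(leaflet = 1, x = g$x, y = g$y, z = 1)), "16 points")
  srf <- flat_surface()
  p <- srf$points[-40, ]                     # punch a hole in leaflet 1
  holed <- surface_point_cloud(p)
  expect_error(monge_curvature_field(holed), "holes")
  expect_error(surface_point_cloud(data.frame(leaflet = 1, x = 1, y = 1,
                                              z = NaN)), "leaflet|finite")
})

test_that("reference plane defaults to the bilayer centre", {
  srf <- flat_surface(z = 7)
  expect_equal(srf$d0, 0)
  fld <- monge_curvature_field(srf, leaflet = 1)
  expect_equal(unique(as.vector(fld$delta)), 7)
})
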