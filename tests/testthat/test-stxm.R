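# Optical density, spectral unmixing, cluster morphometry.

test_that("Beer-Lambert conversion is exact and masks bad pixels", {
  E <- c(285, 288, 292)
  imgs <- array(100, dim = c(2, 2, 3))
  st <- stxm_stack(E, imgs, i0 = 100, pixel_nm = 10)
  od <- to_optical_density(st)
  expect_equal(as.vector(od), rep(0, 12))           # I = I0 -> OD = 0
  st2 <- stxm_stack(E, imgs * exp(-1), i0 = 100, pixel_nm = 10)
  expect_equal(as.vector(to_optical_density(st2)), rep(1, 12))
  imgs[1, 1, 2] <- 0
  st3 <- stxm_stack(E, imgs, i0 = 100, pixel_nm = 10)
  od3 <- to_optical_density(st3)
  expect_identical(attr(od3, "n_masked"), 1L)
  expect_true(is.na(od3[1, 1, 2]))
})

test_that("OD conversion inverts the generator forward model at zero noise", {
  st <- gen_stxm_stack(seed = 9, noise_scale = 0, n_clusters = 10)
  od <- to_optical_density(st)
  gt <- st$metadata$ground_truth
  ref <- st$metadata$ref
  maps <- unmix_components(od, ref)
  # weights equal the generating thicknesses everywhere
  expect_equal(max(abs(maps$lipid - gt$lipid_thickness)), 0,
               tolerance = 1e-10)
  expect_true(all(maps$peptide >= 0))
  # a pure-lipid pixel has exactly zero peptide weight
  expect_equal(maps$peptide[1, 1], 0, tolerance = 1e-12)
})

test_that("two-component NNLS matches a brute-force oracle", {
  E <- stxm_default_energies()
  R <- stxm_reference_spectra(E)
  w_true <- c(0.7, 0.3)
  b <- R %*% w_true
  od <- array(b, dim = c(1, 1, length(E)))
  maps <- unmix_components(od, R, energies = E)
  expect_equal(c(maps$lipid[1, 1], maps$peptide[1, 1]), w_true,
               tolerance = 1e-8)
  w_bf <- nnls2_bruteforce(R, b, w_max = 2)
  expect_equal(c(maps$lipid[1, 1], maps$peptide[1, 1]), w_bf,
               tolerance = 1e-6)
  # negative-weight case: clamped solution beats naive projection
  b2 <- R %*% c(1, 0) - 0.3 * R[, 2]
  w_bf2 <- nnls2_bruteforce(R, b2, w_max = 2)
  od2 <- array(b2, dim = c(1, 1, length(E)))
  maps2 <- unmix_components(od2, R, energies = E)
  expect_equal(c(maps2$lipid[1, 1], maps2$peptide[1, 1]), w_bf2,
               tolerance = 1e-5)
  expect_gte(maps2$peptide[1, 1], 0)
})

test_that("unmixing is homogeneous and rejects collinear references", {
  E <- stxm_default_energies()
  R <- stxm_reference_spectra(E)
  b <- R %*% c(0.4, 0.6)
  od1 <- array(b, dim = c(1, 1, length(E)))
  od5 <- array(5 * b, dim = c(1, 1, length(E)))
  m1 <- unmix_components(od1, R, energies = E)
  m5 <- unmix_components(od5, R, energies = E)
  expect_equal(m5$lipid[1, 1] / m1$lipid[1, 1], 5, tolerance = 1e-10)
  Rcol <- cbind(R[, 1], R[, 1] * (1 + 1e-14))
  expect_error(unmix_components(od1, Rcol, energies = E), "collinear")
})

test_that("morphometry measures widths in closed form and scales", {
  m <- matrix(0, 30, 30)
  m[10:19, 10:19] <- 1                       # 10 x 10 px square
  st <- cluster_morphometry(m, pixel_nm = 10, threshold = 0.5)
  expect_identical(st$count, 1L)
  expect_equal(st$mean_width, 2 * sqrt(100 / pi) * 10, tolerance = 1e-10)
  expect_identical(st$sd_width, 0)
  st2 <- cluster_morphometry(m, pixel_nm = 20, threshold = 0.5)
  expect_equal(st2$mean_width / st$mean_width, 2)
  # equivalent diameter is rotation-insensitive (within discretisation)
  n <- 101
  g <- expand.grid(x = 1:n, y = 1:n)
  sq <- matrix(as.numeric(abs(g$x - 51) + abs(g$y - 51) <= 21), n, n)
  st3 <- cluster_morphometry(sq, pixel_nm = 1, threshold = 0.5)
  rot <- matrix(as.numeric(pmax(abs(g$x - 51), abs(g$y - 51)) <= 15), n, n)
  st4 <- cluster_morphometry(rot, pixel_nm = 1, threshold = 0.5)
  expect_equal(st3$mean_width / st4$mean_width, 1, tolerance = 0.05)
})

test_that("morphometry excludes border clusters and tolerates empty maps", {
  m <- matrix(0, 20, 20)
  m[1:5, 1:5] <- 1          # touches the border
  m[10:12, 10:12] <- 1      # interior
  st <- cluster_morphometry(m, pixel_nm = 10, threshold = 0.5)
  expect_identical(st$count, 1L)
  expect_equal(st$widths, 2 * sqrt(9 / pi) * 10)
  stb <- cluster_morphometry(m, pixel_nm = 10, threshold = 0.5,
                             exclude_border = FALSE)
  expect_identical(stb$count, 2L)
  empty <- cluster_morphometry(matrix(0:1, 4, 4), pixel_nm = 1,
                               threshold = 1)
  expect_gte(empty$count, 0L)
  expect_error(cluster_morphometry(m, pixel_nm = 10, threshold = 7),
               "value range")
  expect_error(cluster_morphometry(m, pixel_nm = 0), "pixel_nm")
})

test_that("full STXM round trip recovers the cluster width distribution", {
  st <- gen_stxm_stack(seed = 21)
  od <- to_optical_density(st)
  maps <- unmix_components(od, st$metadata$ref)
  cs <- cluster_morphometry(maps$peptide, st$pixel_nm)
  gt <- st$metadata$ground_truth
  expect_identical(cs$count, length(gt$widths))
  expect_lt(abs(cs$mean_width - mean(gt$widths)), 3)
  expect_lt(abs(cs$sd_width - sd(gt$widths)), 3)
})

test_that("Otsu threshold splits a bimodal map", {
  set.seed(1)
  x <- c(rnorm(500, 0, 0.05), rnorm(200, 1, 0.05))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
})
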