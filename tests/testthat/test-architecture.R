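test_that("orientation field recovers analytic orientations", {
  # horizontal stripes: intensity varies only along y -> angle 0
  stripes <- matrix(rep(sin(seq(0, 6 * pi, length.out = 64)), 64), 64, 64)
  of <- orientation_field(stripes, window = 4, pixel_size = 0.108,
                          energy_rel = 0)
  th <- of$theta[of$valid]
  expect_true(all(pmin(th, pi - th) < 0.02))
  expect_gt(sum(of$valid), 100)

  # grating at 30 degrees
  g <- grating_image(96, angle_rad = pi / 6, period_px = 12)
  of2 <- orientation_field(g, 4, 0.108, energy_rel = 0)
  err <- abs(of2$theta[of2$valid] - pi / 6)
  expect_lt(stats::median(err), 1 * pi / 180)

  # constant image: everything invalid
  expect_warning(of3 <- orientation_field(matrix(5, 64, 64), 4, 0.108),
                 "no valid windows")
  expect_false(any(of3$valid))
})

test_that("curvature map is zero for uniform fields and unwraps the seam", {
  g <- grating_image(64, angle_rad = 0.4, period_px = 10)
  of <- orientation_field(g, 4, 0.108, energy_rel = 0)
  cm <- curvature_map(of)
  # uniformly oriented pattern: curvature is zero up to discretization
  # residue (evaluated on interior windows; edge windows carry the
  # replicated-gradient boundary residue)
  k_int <- cm$k[3:14, 3:14]
  expect_lt(stats::median(k_int, na.rm = TRUE), 0.01)
  expect_lt(stats::quantile(k_int, 0.9, na.rm = TRUE), 0.05)

  # synthetic theta field with a nematic pi-jump seam: eps, not pi/spacing
  of2 <- of
  eps <- 0.05
  th <- matrix(pi - eps, 16, 16); th[, 9:16] <- 0
  of2$theta <- th; of2$valid <- matrix(TRUE, 16, 16)
  of2$spacing_um <- 0.432
  k2 <- curvature_map(of2)$k
  # centered difference across the seam reads ~eps/(2 spacing), far from
  # the pi/spacing a naive (unwrapped) difference would give
  expect_lt(max(k2, na.rm = TRUE), 1.2 * eps / 0.432)
  expect_gt(max(k2, na.rm = TRUE), 0)
})

test_that("curvature on rings matches 1/R within 15%", {
  img <- ring_image(128, 0.108, period_um = 0.86)
  of <- orientation_field(img, 4, 0.108, energy_rel = 0)
  cm <- curvature_map(of)
  ctr <- (64 - 0.5) * 4 * 0.108 / 4  # field center in um
  cx <- mean(of$x_um); cy <- mean(of$y_um)
  rad <- sqrt(outer(of$y_um - cy, of$x_um - cx, function(a, b) a^2 + b^2))
  for (R in c(1, 2, 4)) {
    sel <- abs(rad - R) < 0.2 & is.finite(cm$k)
    expect_lt(abs(mean(cm$k[sel]) - 1 / R) / (1 / R), 0.15)
  }
})

test_that("exponential curvature fit is the sample mean", {
  expect_equal(fit_curvature_distribution(c(1, 2, 3), min_samples = 3)$k_um_inv,
               2)
  withr::with_seed(30, {
    x <- stats::rexp(1e4, rate = 1 / 0.3)
  })
  f <- fit_curvature_distribution(x)
  expect_lt(abs(f$k_um_inv - 0.3), 0.01)
  expect_warning(fit_curvature_distribution(c(1, 2)), "too few")
})

test_that("spatial correlation equals brute-force pair enumeration", {
  withr::with_seed(31, {
    th <- matrix(runif(16 * 16, 0, pi), 16, 16)
  })
  of <- orientation_field(matrix(runif(64 * 64), 64, 64), 4, 0.108,
                          energy_rel = 0, coherence_min = 0)
  of$theta <- th
  of$valid <- matrix(TRUE, 16, 16)
  suppressWarnings(sc <- spatial_correlation(of, bin = 0.432, r_max = 2))
  x <- rep(of$x_um, each = 16); y <- rep(of$y_um, times = 16)
  # orientation_field grids are indexed [row = y, col = x]
  idx <- which(of$valid, arr.ind = TRUE)
  bf <- brute_spatial_corr(of$x_um[idx[, 2]], of$y_um[idx[, 1]], th[idx],
                           bin = 0.432, r_max = 2)
  expect_equal(sc$S[-1], bf, tolerance = 1e-12)
  expect_equal(sc$S[1], 1)
})

test_that("spatial correlation of uniform and random fields behaves", {
  of <- orientation_field(grating_image(128, 0.3, 16), 4, 0.108,
                          energy_rel = 0)
  sc <- spatial_correlation(of)
  expect_true(all(sc$S[sc$reliable] > 0.95))
  expect_true(attr(sc, "censored"))

  withr::with_seed(32, {
    th <- matrix(runif(32 * 32, 0, pi), 32, 32)
  })
  off <- orientation_field(matrix(runif(128 * 128), 128, 128), 4, 0.108,
                           energy_rel = 0, coherence_min = 0)
  off$theta <- th; off$valid <- matrix(TRUE, 32, 32)
  scr <- spatial_correlation(off)
  lim <- 3 / sqrt(scr$n_pairs[-1])
  expect_true(all(abs(scr$S[-1]) < pmax(lim, 0.2)))
})

test_that("rotating the image by 90 degrees rotates theta and not k or S", {
  p <- network_params(duration = 4, field_size = 128 * 0.108)
  g <- generate_network_movie(p, seed = 33)
  fr <- g$movie$frames[, , 1]
  rot90 <- t(fr)[, nrow(fr):1]  # 90 degree rotation
  of1 <- orientation_field(fr, 4, 0.108)
  of2 <- orientation_field(rot90, 4, 0.108)
  k1 <- fit_curvature_distribution(curvature_map(of1))$k_um_inv
  k2 <- fit_curvature_distribution(curvature_map(of2))$k_um_inv
  expect_lt(abs(k1 - k2) / k1, 0.05)
  s1 <- spatial_correlation(of1); s2 <- spatial_correlation(of2)
  expect_lt(abs(attr(s1, "rho_um") - attr(s2, "rho_um")) /
              attr(s1, "rho_um"), 0.05)
  # angles rotate by pi/2 (mod pi): compare circular means of 2*theta
  m1 <- Arg(mean(exp(2i * of1$theta[of1$valid])))
  m2 <- Arg(mean(exp(2i * of2$theta[of2$valid])))
  expect_lt(abs(abs(((m2 - m1) / 2) %% pi) - pi / 2), 0.2)
})

test_that("alignment-length recovery tracks the generated director order", {
  rho <- vapply(c(0.9, 1.8), function(al) {
    p <- network_params(n_filaments = 150, alignment_length = al,
                        duration = 60, field_size = 128 * 0.108,
                        frame_interval = 6, reorganization_time = 15)
    g <- generate_network_movie(p, seed = 34)
    as <- architecture_series(g$movie)
    mean(as$rho_um)
  }, numeric(1))
  expect_gt(rho[2], rho[1])
  # the better-aligned condition reads out near its target
  expect_lt(abs(rho[2] - 1.8) / 1.8, 0.35)
})
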