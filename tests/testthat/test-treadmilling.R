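test_that("differential movie separates appearing and vanishing intensity", {
  f <- array(rep(matrix(runif(32 * 32, 50, 60), 32, 32), 5), c(32, 32, 5))
  dm <- differential_movie(movie(f))
  expect_equal(max(dm$growth), 0, tolerance = 1e-9)
  expect_equal(max(dm$shrink), 0, tolerance = 1e-9)

  # spot stepping +3 px in x: growth leads, shrinkage trails
  H <- 48
  f2 <- array(10, c(H, H, 6))
  for (t in 1:6) f2[, , t] <- gaussian_spot_frame(H, cbind(24, 6 + 3 * t),
                                                  amplitude = 100)
  dm2 <- differential_movie(movie(f2))
  for (t in 2:4) {
    gmax <- arrayInd(which.max(dm2$growth[, , t]), c(H, H))
    smax <- arrayInd(which.max(dm2$shrink[, , t]), c(H, H))
    expect_gt(gmax[2], smax[2])  # growth ahead in x
  }

  # recombination is exact: growth - shrink == filtered difference
  withr::with_seed(50, {
    f3 <- array(runif(24 * 24 * 5, 0, 100), c(24, 24, 5))
  })
  mv3 <- movie(f3)
  dm3 <- differential_movie(mv3, sigma_xy = 1, sigma_t = 1)
  fs <- f3
  for (t in 1:5) fs[, , t] <- filnet:::blur2d(f3[, , t], 1)
  fs <- filnet:::blur_time(fs, 1)
  D <- fs[, , 2:5] - fs[, , 1:4]
  expect_equal(dm3$growth - dm3$shrink, D, tolerance = 1e-12)
  expect_error(differential_movie(movie(f3[, , 1:2])), "3 frames")
})

test_that("differential movie is linear in the input intensities", {
  withr::with_seed(51, {
    f <- array(runif(24 * 24 * 4, 0, 50), c(24, 24, 4))
  })
  d1 <- differential_movie(movie(f))
  d2 <- differential_movie(movie(2 * f))
  expect_equal(d2$growth, 2 * d1$growth, tolerance = 1e-12)
  expect_equal(d2$shrink, 2 * d1$shrink, tolerance = 1e-12)
})

test_that("spot detection finds separated Gaussian spots at SNR 5", {
  withr::with_seed(52, {
    H <- 96
    pos <- cbind(runif(20, 10, H - 10), runif(20, 10, H - 10))
    repeat {
      d <- as.matrix(stats::dist(pos)); diag(d) <- Inf
      if (min(d) > 8) break
      i <- which(d == min(d), arr.ind = TRUE)[1, 1]
      pos[i, ] <- c(runif(1, 10, H - 10), runif(1, 10, H - 10))
    }
    fr <- gaussian_spot_frame(H, pos, amplitude = 50, sigma = 2) +
      matrix(rnorm(H * H, 0, 10), H, H)  # SNR 5
  })
  mv <- movie(array(pmax(fr, 0), c(H, H, 2)), 0.108, 1)
  sp <- detect_spots(mv, diameter = 0.5, quality_percentile = 0)
  sp1 <- sp[sp$frame == 0, ]
  dm <- sqrt(outer(sp1$y_um / 0.108 + 1, pos[, 1], `-`)^2 +
               outer(sp1$x_um / 0.108 + 1, pos[, 2], `-`)^2)
  recall <- mean(apply(dm, 2, min) < 2)
  precision <- mean(apply(dm, 1, min) < 2)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("quality filtering separates bright from dim spots", {
  H <- 64
  fr <- gaussian_spot_frame(H, rbind(c(20, 20), c(44, 44)),
                            amplitude = c(100, 10), sigma = 2)
  mv <- movie(array(fr, c(H, H, 2)), 0.108, 1)
  sp <- detect_spots(mv, quality_percentile = 60)
  sp1 <- sp[sp$frame == 0, ]
  expect_equal(nrow(sp1), 1L)
  expect_lt(abs(sp1$y_um / 0.108 + 1 - 20), 2)
  blank <- movie(array(5, c(32, 32, 3)))
  expect_equal(nrow(detect_spots(blank)), 0L)
})

test_that("linking matches exhaustive assignment on small instances", {
  withr::with_seed(53, {
    for (rep in 1:10) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      p1 <- matrix(runif(2 * n1, 0, 3), ncol = 2)
      p2 <- matrix(runif(2 * n2, 0, 3), ncol = 2)
      cost <- sqrt(outer(p1[, 1], p2[, 1], `-`)^2 +
                     outer(p1[, 2], p2[, 2], `-`)^2)
      cost[cost > 0.8] <- Inf
      got <- filnet:::assign_links(cost)
      want <- brute_assignment(cost)
      n_got <- sum(!is.na(got))
      c_got <- sum(cost[cbind(which(!is.na(got)), got[!is.na(got)])])
      expect_equal(n_got, want$n)
      expect_equal(c_got, want$cost, tolerance = 1e-9)
    }
  })
})

test_that("linking respects radius, gaps, and never swaps parallel tracks", {
  mk <- function(frame, x, y) tibble::tibble(frame = frame, x_um = x,
                                             y_um = y, intensity = 1,
                                             quality = 1,
                                             channel = "growth")
  # two parallel lines 2 um apart
  spots <- dplyr::bind_rows(lapply(0:9, function(f)
    mk(f, c(0.1 * f, 0.1 * f), c(0, 2))))
  tr <- link_trajectories(spots, link_max = 0.5)
  expect_equal(dplyr::n_distinct(tr$track_id), 2L)
  ys <- tapply(tr$y_um, tr$track_id, function(v) length(unique(v)))
  expect_true(all(ys == 1))

  # gap of 2 frames is closed
  spots2 <- dplyr::bind_rows(lapply(c(0:3, 6:9), function(f)
    mk(f, 0.05 * f, 1)))
  tr2 <- link_trajectories(spots2, link_max = 0.5, gap_max = 2)
  expect_equal(dplyr::n_distinct(tr2$track_id), 1L)

  # jump beyond the radius starts a new track
  spots3 <- dplyr::bind_rows(mk(0, 0, 0), mk(1, 0.05, 0), mk(2, 1.2, 0),
                             mk(3, 1.25, 0))
  tr3 <- link_trajectories(spots3, link_max = 0.5)
  expect_equal(dplyr::n_distinct(tr3$track_id), 2L)
})

test_that("track speed is exact on a constant-velocity track", {
  spots <- dplyr::bind_rows(lapply(0:9, function(f)
    tibble::tibble(frame = f, x_um = 0.1 * f, y_um = 0, intensity = 1,
                   quality = 1, channel = "growth")))
  tr <- link_trajectories(spots)
  vel <- track_velocities(tr, frame_interval = 2)
  expect_equal(vel$by_channel$mean_nm_s, 50)
  vel2 <- track_velocities(tr, frame_interval = 2, method = "path")
  expect_equal(vel2$by_channel$mean_nm_s, 50)
})

test_that("treadmilling speed is recovered from rendered movies", {
  # sampling matched so each frame advances ~100 nm along the path
  res <- lapply(c(25, 100), function(v) {
    fi <- 100 / v
    p <- network_params(n_filaments = 10, treadmill_speed = v,
                        duration = 99 * fi, field_size = 128 * 0.108,
                        frame_interval = fi, path_length = 6,
                        filament_spacing = 1.5)
    g <- generate_network_movie(p, seed = 54)
    tr <- link_trajectories(detect_spots(differential_movie(g$movie)),
                            link_max = 0.3, min_len = 6)
    track_velocities(tr, fi, min_len = 6)$by_channel
  })
  for (i in 1:2) {
    v_true <- c(25, 100)[i]
    expect_true(all(abs(res[[i]]$mean_nm_s - v_true) / v_true < 0.1))
  }
})

test_that("directional autocorrelation separates straight, random and persistent walks", {
  mk_walk <- function(n, kappa_sd, seed) {
    withr::with_seed(seed, {
      th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 1, 0, kappa_sd)))
    })
    tibble::tibble(frame = 0:(n - 1), x_um = cumsum(0.2 * cos(th)),
                   y_um = cumsum(0.2 * sin(th)), intensity = 1,
                   quality = 1, channel = "growth")
  }
  straight <- dplyr::bind_rows(lapply(1:5, function(k) {
    d <- mk_walk(20, 0, 60 + k); d$x_um <- d$x_um + 10 * k; d
  }))
  tr <- link_trajectories(straight, link_max = 0.5)
  dc <- directional_autocorrelation(tr, frame_interval = 1, max_lag = 5)
  expect_true(all(abs(dc$C - 1) < 1e-9))

  # persistent walk dominates a more diffusive one pointwise
  dcs <- lapply(c(0.3, 1.2), function(ks) {
    walks <- dplyr::bind_rows(lapply(1:40, function(k) {
      d <- mk_walk(15, ks, 700 + k); d$track_id <- k; d
    }))
    walks$n_frames <- 15L; walks$len_ok <- TRUE
    directional_autocorrelation(walks, frame_interval = 1, max_lag = 8)
  })
  expect_true(all(dcs[[1]]$C[-1] > dcs[[2]]$C[-1]))

  # isotropic random walk: C near zero
  iso <- dplyr::bind_rows(lapply(1:60, function(k) {
    withr::with_seed(800 + k, {
      tibble::tibble(frame = 0:14,
                     x_um = cumsum(0.2 * cos(runif(15, 0, 2 * pi))),
                     y_um = cumsum(0.2 * sin(runif(15, 0, 2 * pi))),
                     track_id = k)
    })
  }))
  dci <- directional_autocorrelation(iso, frame_interval = 1, max_lag = 5)
  expect_true(all(abs(dci$C[-1]) < 3 / sqrt(dci$n_pairs[-1])))
})

test_that("polarity diagnostics distinguish parallel from antiparallel bundles", {
  rates <- vapply(c(0, 0.5), function(af) {
    p <- network_params(n_filaments = 16, treadmill_speed = 50,
                        duration = 178, field_size = 128 * 0.108,
                        path_length = 6, filament_spacing = 1.5,
                        antiparallel_fraction = af)
    g <- generate_network_movie(p, seed = 55)
    tr <- link_trajectories(detect_spots(differential_movie(g$movie)),
                            link_max = 0.35, min_len = 4)
    pr <- spot_intensity_profile(tr)
    w <- pr$by_channel$n_spots
    sum(pr$by_channel$excursion_rate * w) / sum(w)
  }, numeric(1))
  expect_gt(rates[2], rates[1])

  # parallel case: growth/shrink intensity ratio near 1, flat profile
  p0 <- network_params(n_filaments = 16, treadmill_speed = 50,
                       duration = 118, field_size = 128 * 0.108,
                       path_length = 6, filament_spacing = 1.5)
  g0 <- generate_network_movie(p0, seed = 56)
  tr0 <- link_trajectories(detect_spots(differential_movie(g0$movie)),
                           link_max = 0.35, min_len = 4)
  pr0 <- spot_intensity_profile(tr0)
  expect_lt(abs(pr0$intensity_ratio - 1), 0.15)
  expect_true(all(abs(pr0$profile$mean_norm - 1) < 0.2))
})

test_that("single constant-intensity track has a flat normalized profile", {
  spots <- dplyr::bind_rows(lapply(0:9, function(f)
    tibble::tibble(frame = f, x_um = 0.1 * f, y_um = 0, intensity = 7,
                   quality = 1, channel = "growth")))
  tr <- link_trajectories(spots)
  pr <- spot_intensity_profile(tr)
  expect_true(all(abs(pr$samples$norm_intensity - 1) < 1e-12))
  expect_equal(pr$by_channel$excursion_rate, 0)
})

test_that("bundle length from spot pairs tracks the filament length", {
  lens <- vapply(1:3, function(s) {
    p <- network_params(n_filaments = 1, mean_length = 0.5,
                        treadmill_speed = 50, duration = 60,
                        field_size = 128 * 0.108, path_length = 8,
                        curvature_scale = 0.1, photons_per_pixel = 400,
                        bundle_width = 0.3, psf_sigma = 0.1)
    g <- generate_network_movie(p, seed = s)
    tr <- link_trajectories(detect_spots(differential_movie(g$movie),
                                         quality_percentile = 80),
                            link_max = 0.35, min_len = 6)
    bundle_length_from_spot_pairs(tr, min_len = 6)$length_um
  }, numeric(1))
  est <- mean(lens, na.rm = TRUE)
  # within the resolution-limited broadening of the two difference lobes
  expect_lt(abs(est - 0.5), 0.2)

  # well-separated filaments: pairing never crosses filaments
  p2 <- network_params(n_filaments = 2, mean_length = 0.5,
                       treadmill_speed = 50, duration = 60,
                       field_size = 128 * 0.108, path_length = 8,
                       filament_spacing = 8, curvature_scale = 0.1,
                       photons_per_pixel = 400, bundle_width = 0.3,
                       psf_sigma = 0.1)
  for (s in 1:3) {
    g2 <- generate_network_movie(p2, seed = 60 + s)
    tr2 <- link_trajectories(detect_spots(differential_movie(g2$movie),
                                          quality_percentile = 80),
                             link_max = 0.35, min_len = 6)
    bl <- bundle_length_from_spot_pairs(tr2, min_len = 6)
    if (bl$n_pairs > 0) expect_true(all(bl$pairs$separation_um < 2))
  }

  # empty input flagged undefined
  empty <- link_trajectories(tibble::tibble(
    frame = integer(), x_um = numeric(), y_um = numeric(),
    intensity = numeric(), quality = numeric(), channel = character()))
  expect_true(is.na(bundle_length_from_spot_pairs(empty)$length_um))
})

test_that("kymograph ridges move at the spot velocity", {
  H <- 48; T <- 10
  f <- array(10, c(H, H, T))
  ii <- seq_len(H)
  for (t in seq_len(T)) {
    f[, , t] <- f[, , t] + 100 * outer(exp(-(ii - 24)^2 / 8),
                                       exp(-(ii - (5 + 2 * t))^2 / 8))
  }
  mv <- movie(f, 0.108, 2)
  ky <- kymograph(mv, rbind(c(0, 24 * 0.108), c(47 * 0.108, 24 * 0.108)),
                  width_um = 0.4)
  peaks <- ky |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(s_peak = .data$s_um[which.max(.data$intensity)])
  slope <- stats::coef(stats::lm(s_peak ~ I(frame * 2), data = peaks))[2]
  expect_equal(unname(slope) * 1000, 108, tolerance = 0.05)
})
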