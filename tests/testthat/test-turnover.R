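test_that("frap_trace normalizes pre-bleach to 1 and bleach frame to 0", {
  p <- network_params(duration = 30, frame_interval = 0.5,
                      field_size = 64 * 0.108, n_filaments = 20,
                      path_length = 3)
  g <- generate_frap_movie(p, bleach_roi = c(1.5, 1.5, 5, 5),
                           bleach_frame = 15, recovery_rate = 0.1,
                           seed = 70, noise = FALSE)
  tr <- frap_trace(g$movie, roi = c(1.5, 1.5, 5, 5))
  expect_equal(attr(tr, "bleach_frame"), 15)
  pre <- tr$intensity_norm[tr$frame < 15]
  expect_true(all(abs(pre - 1) < 1e-9))
  expect_equal(tr$intensity_norm[tr$frame == 15], 0)
  # noiseless trace follows a(1 - exp(-bt)) exactly
  post <- tr[!is.na(tr$t_post_s) & tr$t_post_s > 0, ]
  expect_equal(post$intensity_norm, 0.9 * (1 - exp(-0.1 * post$t_post_s)),
               tolerance = 1e-9)
  expect_error(roi_err <- frap_trace(g$movie, roi = c(50, 50, 60, 60)),
               "ROI outside field")
})

test_that("reference-ROI correction flattens acquisition photobleaching", {
  # flat true recovery, reference decaying 10% linearly
  H <- 32; T <- 40
  f <- array(0, c(H, H, T))
  for (t in seq_len(T)) {
    decay <- 1 - 0.1 * (t - 1) / (T - 1)
    fr <- matrix(100 * decay, H, H)
    fr[1:10, 1:10] <- ifelse(t - 1 >= 10, 20 * decay, 100 * decay)
    f[, , t] <- fr
  }
  mv <- movie(f, 0.108, 1)
  roi <- c(0, 0, 9 * 0.108, 9 * 0.108)
  ref <- c(15 * 0.108, 15 * 0.108, 30 * 0.108, 30 * 0.108)
  tr <- frap_trace(mv, roi, bleach_frame = 10, reference_roi = ref)
  post <- tr$intensity_norm[!is.na(tr$t_post_s) & tr$t_post_s > 0]
  fitl <- stats::lm(post ~ seq_along(post))
  ci <- stats::confint(fitl)[2, ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)  # slope CI contains 0
})

test_that("fit_frap matches the closed form and rejects empty traces", {
  t <- seq(0.5, 30, by = 0.5)
  ff <- fit_frap(0.9 * (1 - exp(-0.1386 * t)), t)
  expect_equal(ff$a, 0.9, tolerance = 1e-6)
  expect_equal(ff$half_time_s, log(2) / 0.1386, tolerance = 1e-6)
  expect_error(fit_frap(rep(0, 20), seq_len(20)), "no recovery")
  expect_error(fit_frap(c(0.1, 0.2), c(1, 2)), "at least 6")
})

test_that("fit_frap recovers a noisy 7.63 s half-time within 10%", {
  t <- seq(0.114, 40, by = 0.114)
  b <- log(2) / 7.63
  est <- vapply(1:20, function(s) {
    withr::with_seed(900 + s, {
      y <- 0.9 * (1 - exp(-b * t)) + rnorm(length(t), 0, 0.05)
    })
    fit_frap(y, t)$half_time_s
  }, numeric(1))
  expect_lt(abs(mean(est) - 7.63) / 7.63, 0.1)
})

test_that("end-to-end FRAP: movie -> trace -> fit recovers the rate", {
  p <- network_params(duration = 40, frame_interval = 0.25,
                      field_size = 64 * 0.108, n_filaments = 20,
                      path_length = 3)
  g <- generate_frap_movie(p, bleach_roi = c(1.5, 1.5, 5, 5),
                           bleach_frame = 20,
                           recovery_rate = log(2) / 7.63, seed = 71)
  ff <- fit_frap(frap_trace(g$movie, roi = c(1.5, 1.5, 5, 5)))
  expect_lt(abs(ff$half_time_s - 7.63) / 7.63, 0.15)
})

test_that("single molecules are counted and timed correctly", {
  p <- network_params(duration = 30, field_size = 128 * 0.108,
                      background = 40, photons_per_pixel = 200)
  sm <- generate_single_molecule_movie(p, label_density = 50 / 191,
                                       k_off = 0, p_bleach_per_exposure = 0,
                                       acquisition_interval = 1, seed = 72)
  n_true <- nrow(sm$truth$molecules)
  tk <- track_single_molecules(sm$movie)
  n_tracks <- dplyr::n_distinct(tk$track_id)
  expect_lt(abs(n_tracks - n_true) / n_true, 0.1)
  # permanent binding: tracks span the whole movie
  lens <- tapply(tk$frame, tk$track_id, function(f) max(f) - min(f))
  expect_gt(stats::median(lens), 0.9 * (n_frames(sm$movie) - 1))
  # empty movie: empty table
  blank <- movie(array(40, c(64, 64, 3)), 0.108, 1)
  expect_equal(nrow(track_single_molecules(blank)), 0L)
})

test_that("track duration follows the (n-1) x interval definition", {
  spots <- dplyr::bind_rows(lapply(0:4, function(f)
    tibble::tibble(frame = f, x_um = 1, y_um = 1, intensity = 5,
                   quality = 1, channel = "raw")))
  tr <- link_trajectories(spots, min_len = 2)
  d <- tapply(tr$frame, tr$track_id, function(f) (max(f) - min(f)) * 1)
  expect_equal(as.numeric(d), 4)
})

test_that("truncated lifetime MLE is unbiased", {
  withr::with_seed(73, {
    dur <- stats::rexp(1e4, 1 / 6.59)
  })
  dur <- dur[dur >= 0.228]
  lf <- lifetime_fit(dur, acquisition_interval = 0.114, truncation = 0.228)
  expect_lt(abs(lf$mean_lifetime_s - 6.59) / 6.59, 0.03)

  withr::with_seed(74, {
    dur2 <- stats::rexp(1e4, 1 / 0.95)
  })
  lf2 <- lifetime_fit(dur2[dur2 >= 0.228], 0.114, truncation = 0.228)
  expect_lt(abs(lf2$mean_lifetime_s - 0.95) / 0.95, 0.05)

  expect_error(lifetime_fit(rep(2, 100), 1), "all durations equal")
  # unbiasedness across means, within Monte-Carlo error
  for (m in c(1, 3, 6.6)) {
    withr::with_seed(75 + round(m), {
      d3 <- stats::rexp(5e3, 1 / m)
    })
    d3 <- d3[d3 >= 0.2]
    lf3 <- lifetime_fit(d3, 0.1, truncation = 0.2)
    expect_lt(abs(lf3$mean_lifetime_s - m), 2 * m / sqrt(length(d3)) * 2)
  }
})

test_that("ground-truth residence times have the configured mean", {
  p <- network_params(duration = 200, field_size = 64 * 0.108)
  sm <- suppressWarnings(
    generate_single_molecule_movie(p, label_density = 2, k_off = 1 / 6.59,
                                   acquisition_interval = 1, seed = 76,
                                   render = FALSE))
  res <- sm$truth$molecules$residence_s
  expect_gt(length(res), 500)
  expect_lt(abs(mean(res) - 6.59) / 6.59, 0.05)
})

test_that("observed decay accelerates as the interval shrinks under bleaching", {
  p <- network_params(duration = 600, field_size = 64 * 0.108)
  rates <- vapply(c(0.114, 0.5, 1.0), function(iv) {
    sm <- generate_single_molecule_movie(p, label_density = 0.5,
                                         k_off = 1 / 6.59,
                                         p_bleach_per_exposure = 0.1,
                                         acquisition_interval = iv,
                                         seed = 77, render = FALSE)
    mol <- sm$truth$molecules[sm$truth$molecules$n_frames_visible >= 2, ]
    lifetime_fit((mol$n_frames_visible - 1) * iv, iv)$k_obs_per_s
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("bleach correction separates unbinding from photobleaching", {
  p <- network_params(duration = 2400, field_size = 64 * 0.108)
  fits <- lapply(c(0.114, 0.25, 0.5, 1.0), function(iv) {
    sm <- generate_single_molecule_movie(p, label_density = 0.3,
                                         k_off = 0.15,
                                         p_bleach_per_exposure = 0.1,
                                         acquisition_interval = iv,
                                         seed = 78, render = FALSE)
    mol <- sm$truth$molecules[sm$truth$molecules$n_frames_visible >= 2, ]
    lifetime_fit((mol$n_frames_visible - 1) * iv, iv)
  })
  bc <- bleach_correction(fits)
  expect_lt(abs(bc$k_off_per_s - 0.15) / 0.15, 0.1)
  expect_lt(abs(bc$p_bleach - 0.1), 0.03)
  expect_error(bleach_correction(fits[1:2]), "3 distinct")

  # no bleaching: k_off equals the common k_obs
  fits0 <- lapply(c(0.25, 0.5, 1.0), function(iv) {
    sm <- generate_single_molecule_movie(p, label_density = 0.3,
                                         k_off = 0.15,
                                         p_bleach_per_exposure = 0,
                                         acquisition_interval = iv,
                                         seed = 79, render = FALSE)
    mol <- sm$truth$molecules[sm$truth$molecules$n_frames_visible >= 2, ]
    lifetime_fit((mol$n_frames_visible - 1) * iv, iv)
  })
  bc0 <- bleach_correction(fits0)
  expect_lt(abs(bc0$k_off_per_s - 0.15) / 0.15, 0.1)
  expect_lt(bc0$p_bleach, 0.02)
})
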