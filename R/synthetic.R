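#' Parameters of the synthetic filament-network generator
#'
#' Defaults emulate the reconstituted FtsZ/FtsA system at steady state on a
#' supported bilayer imaged by TIRF: treadmilling speed ~50 nm/s, subunit
#' lifetime ~6.6 s, mean curvature ~0.33 um^-1, bundle width below the
#' micron, micron-scale orientational order, 0.108 um pixels and 2 s frames.
#'
#' @param n_filaments Number of treadmilling filaments.
#' @param mean_length Filament length (um); every filament has exactly this
#'   contour length, and the growth/shrink end separation equals it.
#' @param curvature_scale Mean of the exponential distribution from which
#'   per-segment centerline curvature magnitudes are drawn (um^-1).
#' @param alignment_length Target orientational (nematic) correlation length
#'   of the filament field (um); imposed by calibrating the smoothness of the
#'   random director field from which filament paths are seeded.
#' @param bundle_width Ribbon FWHM before PSF convolution (um).
#' @param treadmill_speed Treadmilling speed (nm/s); the visible arc of each
#'   filament translates along its path at this speed.
#' @param monomer_lifetime Mean subunit residence time (s); used by the
#'   single-molecule mode.
#' @param antiparallel_fraction Fraction of filaments running opposite to
#'   their bundle partner along the same path, in `[0, 1]`.
#' @param psf_sigma Gaussian PSF sd (um).
#' @param background Background level (counts).
#' @param photons_per_pixel Peak signal of one bundle above background
#'   (counts).
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param duration Movie duration (s).
#' @param field_size Field of view (um, square); `field_size / pixel_size`
#'   must be >= 64 px.
#' @param pixel_size,frame_interval Calibration (um/px, s).
#' @param path_length Contour length of each bundle path (um) along which
#'   filaments are tiled.
#' @param filament_spacing Tiling pitch of filaments along a path (um);
#'   default `1.3 * mean_length`.
#' @param reorganization_time Mean lifetime of a bundle path (s); paths die
#'   and are replaced by fresh ones at stationary rate, so the network
#'   reorganizes on this time scale. `Inf` (default) freezes the geometry.
#' @param fade_time Intensity ramp at path birth/death (s), default 2.
#' @return A validated list of class `network_params`.
#' @export
network_params <- function(n_filaments = 72, mean_length = 0.5,
                           curvature_scale = 0.33, alignment_length = 1.0,
                           bundle_width = 0.6, treadmill_speed = 50,
                           monomer_lifetime = 6.59,
                           antiparallel_fraction = 0, psf_sigma = 0.12,
                           background = 80, photons_per_pixel = 150,
                           read_noise_sd = 2, duration = 120,
                           field_size = 13.824, pixel_size = 0.108,
                           frame_interval = 2, path_length = 4,
                           filament_spacing = 1.3 * mean_length,
                           reorganization_time = Inf, fade_time = 2) {
  p <- as.list(environment())
  with(p, stopifnot(
    n_filaments >= 1, mean_length > 0, curvature_scale >= 0,
    alignment_length > 0, bundle_width > 0, treadmill_speed >= 0,
    monomer_lifetime > 0, antiparallel_fraction >= 0,
    antiparallel_fraction <= 1, psf_sigma >= 0, background >= 0,
    photons_per_pixel > 0, read_noise_sd >= 0, duration > 0,
    field_size / pixel_size >= 64, path_length >= mean_length,
    filament_spacing > 0, reorganization_time > 0, fade_time >= 0))
  structure(p, class = "network_params")
}

# total blur sd (px) of ribbon cross-section + PSF
ribbon_sigma_px <- function(p) {
  sqrt((p$bundle_width / 2.3548)^2 + p$psf_sigma^2) / p$pixel_size
}

# Worm-like path: per-segment curvature magnitude ~ Exp(mean =
# curvature_scale), integrated at ds = 0.1 um. The bending sign is random
# with persistence (flip probability 0.15 per segment) while the tangent
# stays within `band` rad of the local director, and steers back toward the
# director beyond it -- so curvature magnitudes keep their exact exponential
# distribution while the director field imposes large-scale orientational
# order.
make_path <- function(x0, y0, theta0, length_um, curvature_scale,
                      director = NULL, ds = 0.1, seg_len = 0.2,
                      band = 0.3, field_size = NULL, margin = 0.6) {
  n <- max(2L, ceiling(length_um / ds))
  steps_per_seg <- as.integer(seg_len / ds)
  nseg <- ceiling(n / steps_per_seg)
  kappa_seg <- if (curvature_scale > 0)
    stats::rexp(nseg, rate = 1 / curvature_scale) else rep(0, nseg)
  flip <- stats::runif(nseg) < 0.15
  sgn0 <- sample(c(-1, 1), 1)
  x <- y <- theta <- kappa <- numeric(n)
  x[1] <- x0; y[1] <- y0; theta[1] <- theta0
  k <- 1; sgn <- sgn0
  for (sg in seq_len(nseg)) {
    if (sg > 1 && flip[sg]) sgn <- -sgn
    if (!is.null(director)) {
      dev <- wrap_nematic(theta[k] - director(x[k], y[k]))
      if (abs(dev) > band) sgn <- -sign(dev)
    }
    if (!is.null(field_size)) {
      # steer back toward the field center when close to the border, so
      # the rendered scene has no mass flux across the image edge
      near <- min(x[k], y[k], field_size - x[k], field_size - y[k])
      if (near < margin) {
        want <- atan2(field_size / 2 - y[k], field_size / 2 - x[k])
        dev2 <- (theta[k] - want + pi) %% (2 * pi) - pi
        if (abs(dev2) > pi / 3) sgn <- -sign(dev2)
      }
    }
    for (j in seq_len(steps_per_seg)) {
      if (k >= n) break
      kappa[k] <- kappa_seg[sg] * sgn
      theta[k + 1] <- theta[k] + kappa[k] * ds
      x[k + 1] <- x[k] + cos(theta[k]) * ds
      y[k + 1] <- y[k] + sin(theta[k]) * ds
      k <- k + 1
    }
  }
  kappa[n] <- kappa[n - 1]
  list(x = x, y = y, theta = theta, s = (seq_len(n) - 1) * ds, ds = ds,
       kappa = kappa)
}

# Smooth random director field sampled at grid pitch dg; sigma_um controls
# its correlation length.
make_director <- function(field_size, sigma_um, dg = 0.25) {
  n <- ceiling(field_size / dg) + 1
  ang <- matrix(stats::runif(n * n, 0, pi), n, n)
  z <- blur2d(cos(2 * ang), sigma_um / dg) +
    1i * blur2d(sin(2 * ang), sigma_um / dg)
  th <- (Arg(z) / 2) %% pi
  function(x, y) {
    i <- pmin(pmax(round(y / dg) + 1, 1), n)
    j <- pmin(pmax(round(x / dg) + 1, 1), n)
    th[cbind(i, j)]
  }
}

# Nematic pair-correlation length of sampled tangent points, by the same
# S(r) = 0.5 crossing definition as the image analysis.
tangent_rho <- function(x, y, theta, r_max, bin = 0.25, n_max = 1500) {
  if (length(x) > n_max) {
    idx <- sample.int(length(x), n_max)
    x <- x[idx]; y <- y[idx]; theta <- theta[idx]
  }
  dx <- outer(x, x, `-`); dy <- outer(y, y, `-`)
  dth <- outer(theta, theta, `-`)
  up <- upper.tri(dx)
  r <- sqrt(dx[up]^2 + dy[up]^2); cc <- cos(2 * dth[up])
  keep <- r > 0 & r <= r_max
  b <- ceiling(r[keep] / bin)
  S <- vapply(seq_len(max(b)), function(i) mean(cc[keep][b == i]), numeric(1))
  cr <- crossing_point(c(0, (seq_len(max(b)) - 0.5) * bin), c(1, S), 0.5)
  if (is.na(cr)) r_max else cr
}

# Generate the full network geometry for one seed and director smoothness.
# With finite reorganization_time, paths carry stationary birth/death times:
# the initial population dies with residual-exponential lifetimes and new
# paths are born at the matching Poisson rate, keeping the live count
# stationary while the geometry decorrelates.
make_geometry <- function(p, sigma_um) {
  director <- make_director(p$field_size, sigma_um)
  fil_per_path <- max(1L, floor(p$path_length / p$filament_spacing))
  n_paths <- ceiling(p$n_filaments / fil_per_path)
  margin <- 0.5
  if (is.finite(p$reorganization_time)) {
    birth <- rep(0, n_paths)
    n_new <- stats::rpois(1, n_paths * p$duration / p$reorganization_time)
    birth <- c(birth, sort(stats::runif(n_new, 0, p$duration)))
    death <- birth + stats::rexp(length(birth), 1 / p$reorganization_time)
  } else {
    birth <- rep(0, n_paths); death <- rep(Inf, n_paths)
  }
  paths <- lapply(seq_along(birth), function(i) {
    x0 <- stats::runif(1, margin, p$field_size - margin)
    y0 <- stats::runif(1, margin, p$field_size - margin)
    th0 <- director(x0, y0) + sample(c(0, pi), 1)
    pa <- make_path(x0, y0, th0, p$path_length, p$curvature_scale,
                    director = director, field_size = p$field_size)
    pa$birth <- birth[i]; pa$death <- death[i]
    pa
  })
  path_of <- rep(seq_along(paths), each = fil_per_path)
  if (!is.finite(p$reorganization_time)) {
    # static geometry: exactly n_filaments in total
    path_of <- path_of[seq_len(p$n_filaments)]
  }
  fil <- tibble::tibble(id = seq_along(path_of), path = path_of)
  fil <- fil |>
    dplyr::group_by(.data$path) |>
    dplyr::mutate(
      s0 = (dplyr::row_number() - 1) * (p$path_length /
                                          max(dplyr::n(), 1)) +
        stats::runif(dplyr::n(), 0, 0.2 * p$filament_spacing),
      direction = ifelse(stats::runif(dplyr::n()) <
                           p$antiparallel_fraction, -1, 1)) |>
    dplyr::ungroup()
  list(paths = paths, filaments = fil)
}

# Visible arc [s_tail, s_head] of filament f at time t (um, modulo path).
filament_arc <- function(fil_row, t, p) {
  v <- p$treadmill_speed / 1000
  if (fil_row$direction > 0) {
    head <- fil_row$s0 + p$mean_length + v * t
    c(head - p$mean_length, head)
  } else {
    head <- fil_row$s0 - v * t
    c(head, head + p$mean_length)
  }
}

# Intensity weight of a path at time t: ramps over fade_time at birth and
# death, 1 while fully alive, 0 outside.
path_alive_factor <- function(path, t, fade_time) {
  b <- path$birth %||% 0; d <- path$death %||% Inf
  if (t < b || t > d) return(0)
  if (fade_time <= 0) return(1)
  # paths alive at t = 0 are pre-existing and do not fade in
  min(1, if (b > 0) (t - b) / fade_time else 1,
      if (is.finite(d)) (d - t) / fade_time else 1)
}

path_point <- function(path, s) {
  s <- s %% max(path$s)
  list(x = stats::approx(path$s, path$x, s, rule = 2)$y,
       y = stats::approx(path$s, path$y, s, rule = 2)$y,
       theta = stats::approx(path$s, path$theta, s, rule = 2)$y)
}

render_scene <- function(geom, t, p) {
  npx <- round(p$field_size / p$pixel_size)
  dep <- numeric(npx * npx)
  ds_r <- 0.25 * p$pixel_size
  for (k in seq_len(nrow(geom$filaments))) {
    fr <- geom$filaments[k, ]
    pa <- geom$paths[[fr$path]]
    amp <- path_alive_factor(pa, t, p$fade_time)
    if (amp <= 0) next
    arc <- filament_arc(fr, t - pa$birth, p)
    s <- seq(arc[1], arc[2], by = ds_r)
    pt <- path_point(pa, s)
    # bilinear (subpixel) deposition avoids aliasing flicker as arcs
    # translate between frames
    fi <- pt$y / p$pixel_size + 1
    fj <- pt$x / p$pixel_size + 1
    i0 <- floor(fi); j0 <- floor(fj)
    wi <- fi - i0; wj <- fj - j0
    for (q in 1:4) {
      i <- i0 + (q == 2 | q == 4)
      j <- j0 + (q == 3 | q == 4)
      wgt <- (if (q %% 2 == 1) 1 - wi else wi) *
        (if (q <= 2) 1 - wj else wj)
      ok <- i >= 1 & i <= npx & j >= 1 & j <= npx & wgt > 0
      if (any(ok)) {
        lin <- i[ok] + (j[ok] - 1) * npx
        w_acc <- rep(0, npx * npx)
        sums <- rowsum(amp * wgt[ok], lin)
        dep[as.integer(rownames(sums))] <-
          dep[as.integer(rownames(sums))] + sums[, 1]
      }
    }
  }
  sig_px <- ribbon_sigma_px(p)
  sc <- blur2d(matrix(dep, npx, npx), sig_px)
  # deposited linear density is 1 point per ds_r of arc; rescale so one
  # straight ribbon peaks at ~photons_per_pixel above background
  p$background + p$photons_per_pixel * sqrt(2 * pi) * sig_px *
    (ds_r / p$pixel_size) * sc
}

add_camera_noise <- function(scene, p) {
  n <- length(scene)
  out <- stats::rpois(n, pmax(scene, 0)) +
    stats::rnorm(n, 0, p$read_noise_sd)
  matrix(pmax(out, 0), nrow(scene), ncol(scene))
}

#' Synthetic treadmilling-network movie with ground truth
#'
#' Renders a seeded movie of curved treadmilling filament bundles: worm-like
#' paths with exponentially distributed local curvature (mean
#' `curvature_scale`), filament orientations spatially correlated at the
#' target `alignment_length` (imposed by seeding paths on a calibrated
#' smooth director field), constant-speed treadmilling (the visible arc of
#' fixed contour length translates along the path; the leading end grows,
#' the trailing end shrinks), Gaussian-PSF rendering, Poisson shot noise,
#' additive background, and Gaussian read noise. The returned ground truth
#' records every estimand of the downstream analyses.
#'
#' @param params A [network_params()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(params, seed)`.
#' @param noise Disable to obtain the expected (noiseless) scenes.
#' @return List with `movie` (a [movie()]) and `truth` (class
#'   `ground_truth`): the bundle paths and filament kinematics (head/tail
#'   arc positions per frame are recoverable via [filament_ends()]), the
#'   realized alignment length, and all true parameter values.
#' @export
generate_network_movie <- function(params = network_params(), seed = 1L,
                                   noise = TRUE) {
  p <- params
  if (2.3548 * ribbon_sigma_px(p) < 1)
    stop("degenerate parameters: rendered filament width below 1 px")
  withr::with_seed(seed, {
    # calibrate director smoothness so the realized tangent correlation
    # length matches alignment_length
    sigma <- p$alignment_length
    geom <- NULL; rho <- NA_real_
    r_max <- p$field_size / 2
    measure <- function(geom) {
      pts <- do.call(rbind, lapply(geom$paths, function(pa)
        cbind(pa$x, pa$y, pa$theta)))
      inside <- pts[, 1] > 0 & pts[, 1] < p$field_size &
        pts[, 2] > 0 & pts[, 2] < p$field_size
      tangent_rho(pts[inside, 1], pts[inside, 2], pts[inside, 3], r_max)
    }
    for (it in 1:5) {
      geom <- withr::with_seed(seed + 1000L, make_geometry(p, sigma))
      rho <- measure(geom)
      ratio <- min(max(p$alignment_length / rho, 1 / 3), 3)
      if (abs(ratio - 1) < 0.05) break
      # damped multiplicative update; re-measured on a fresh realization
      # each iteration, so convergence is stochastic-approximation style
      sigma <- min(max(sigma * ratio^0.7, 0.1), 6)
    }
    T <- max(2L, floor(p$duration / p$frame_interval) + 1L)
    npx <- round(p$field_size / p$pixel_size)
    frames <- array(0, c(npx, npx, T))
    for (t in seq_len(T)) {
      sc <- render_scene(geom, (t - 1) * p$frame_interval, p)
      frames[, , t] <- if (noise) add_camera_noise(sc, p) else sc
    }
    truth <- structure(list(
      seed = seed, params = p, paths = geom$paths,
      filaments = geom$filaments,
      realized_alignment_um = rho,
      treadmill_speed_nm_s = p$treadmill_speed,
      curvature_scale_um_inv = p$curvature_scale,
      filament_length_um = p$mean_length,
      monomer_lifetime_s = p$monomer_lifetime), class = "ground_truth")
    list(movie = movie(frames, p$pixel_size, p$frame_interval),
         truth = truth)
  })
}

#' Ground-truth filament end positions
#'
#' Head (growing) and tail (shrinking) end coordinates of every filament at
#' a set of frame times, from the generator's ground truth.
#'
#' @param truth `ground_truth` from [generate_network_movie()].
#' @param times Times (s) at which to evaluate.
#' @return Tibble: `time_s`, `filament`, `head_x_um`, `head_y_um`,
#'   `tail_x_um`, `tail_y_um`.
#' @export
filament_ends <- function(truth, times) {
  p <- truth$params
  purrr::map_dfr(times, function(t) {
    purrr::map_dfr(seq_len(nrow(truth$filaments)), function(k) {
      fr <- truth$filaments[k, ]
      pa <- truth$paths[[fr$path]]
      arc <- filament_arc(fr, t - (pa$birth %||% 0), p)
      head_s <- if (fr$direction > 0) arc[2] else arc[1]
      tail_s <- if (fr$direction > 0) arc[1] else arc[2]
      h <- path_point(pa, head_s); tl <- path_point(pa, tail_s)
      tibble::tibble(time_s = t, filament = fr$id,
                     head_x_um = h$x, head_y_um = h$y,
                     tail_x_um = tl$x, tail_y_um = tl$y)
    })
  })
}

#' Synthetic FRAP movie
#'
#' A static realization of the filament network whose fluorophores inside
#' `bleach_roi` are bleached to `residual` at `bleach_frame` and recover in
#' expectation as `residual + (1 - residual) * plateau * (1 - exp(-b t))`
#' with `b = recovery_rate`; the [frap_trace()] normalization therefore
#' recovers exactly `plateau * (1 - exp(-b t))`. Background counts are not
#' bleached (they cancel in the normalization). Camera noise as in
#' [generate_network_movie()].
#'
#' @param params A [network_params()]; `duration` and `frame_interval` set
#'   the movie length.
#' @param bleach_roi Rectangle `c(x0, y0, x1, y1)` in um.
#' @param bleach_frame 0-based frame of the bleach event.
#' @param recovery_rate Recovery rate b (s^-1).
#' @param seed Integer seed.
#' @param residual Post-bleach residual fraction (default 0.05).
#' @param plateau Mobile fraction a (default 0.9).
#' @param noise Disable for noiseless expectation movies.
#' @return List with `movie` and `truth` (recovery parameters + roi + seed).
#' @export
generate_frap_movie <- function(params = network_params(), bleach_roi,
                                bleach_frame, recovery_rate, seed = 1L,
                                residual = 0.05, plateau = 0.9,
                                noise = TRUE) {
  p <- params
  T <- max(2L, floor(p$duration / p$frame_interval) + 1L)
  if (bleach_frame < 1 || bleach_frame >= T - 1)
    stop("bleach_frame outside movie duration")
  withr::with_seed(seed, {
    geom <- make_geometry(p, p$alignment_length)
    scene <- render_scene(geom, 0, p)
    npx <- nrow(scene)
    ix <- roi_indices(bleach_roi, p$pixel_size, c(npx, npx))
    sig <- scene - p$background
    frames <- array(0, c(npx, npx, T))
    for (t in seq_len(T)) {
      fac <- matrix(1, npx, npx)
      if (t - 1 >= bleach_frame) {
        dt <- (t - 1 - bleach_frame) * p$frame_interval
        fac[ix$i, ix$j] <- residual + (1 - residual) * plateau *
          (1 - exp(-recovery_rate * dt))
      }
      sc <- p$background + sig * fac
      frames[, , t] <- if (noise) add_camera_noise(sc, p) else sc
    }
    list(movie = movie(frames, p$pixel_size, p$frame_interval),
         truth = structure(list(
           seed = seed, recovery_rate_per_s = recovery_rate,
           half_time_s = log(2) / recovery_rate, plateau = plateau,
           residual = residual, bleach_roi = bleach_roi,
           bleach_frame = bleach_frame), class = "ground_truth"))
  })
}

#' Synthetic single-molecule movie
#'
#' Sparse diffraction-limited spots at static positions (treadmilling
#' subunits are stationary): molecules bind as a steady-state Poisson
#' process at surface density `label_density`, stay for exponential
#' residence times with rate `k_off`, and each exposure bleaches a visible
#' molecule with probability `p_bleach_per_exposure` (the molecule is still
#' seen in the bleaching frame). Ground truth stores per-molecule positions
#' and on/off times.
#'
#' @param params A [network_params()] (`duration`, `field_size`,
#'   `psf_sigma`, `photons_per_pixel`, `background`, `read_noise_sd` used).
#' @param label_density Mean visible molecules per um^2.
#' @param k_off Unbinding rate (s^-1); 0 means permanent binding.
#' @param p_bleach_per_exposure Bleaching probability per exposure.
#' @param acquisition_interval Seconds per frame; must be >= the 0.05 s
#'   exposure.
#' @param seed Integer seed.
#' @param noise Disable for noiseless movies.
#' @param render Set to `FALSE` to skip rendering and return only the
#'   ground truth (`movie = NULL`); useful for large-sample studies of the
#'   residence-time estimators where only the visibility record matters.
#' @return List with `movie` and `truth` (`molecules` tibble: `x_um`,
#'   `y_um`, `t_on_s`, `residence_s`, `first_frame` (0-based),
#'   `n_frames_visible`; plus rates and seed).
#' @export
generate_single_molecule_movie <- function(params = network_params(),
                                           label_density = 0.5,
                                           k_off = 1 / 6.59,
                                           p_bleach_per_exposure = 0,
                                           acquisition_interval = 1,
                                           seed = 1L, noise = TRUE,
                                           render = TRUE) {
  p <- params
  if (acquisition_interval < 0.05)
    stop("acquisition_interval must be >= the 0.05 s exposure")
  area <- p$field_size^2
  if (0.5 / sqrt(max(label_density, 1e-12)) < 4 * p$psf_sigma)
    warning("label density so high that spots overlap; tracking unreliable")
  withr::with_seed(seed, {
    T <- max(2L, floor(p$duration / acquisition_interval) + 1L)
    times <- (seq_len(T) - 1) * acquisition_interval
    n0 <- stats::rpois(1, label_density * area)
    t_on <- rep(0, n0)
    if (k_off > 0) {
      n_arr <- stats::rpois(1, label_density * area * k_off * p$duration)
      t_on <- c(t_on, sort(stats::runif(n_arr, 0, p$duration)))
    }
    n <- length(t_on)
    res <- if (k_off > 0) stats::rexp(n, k_off) else rep(Inf, n)
    x <- stats::runif(n, 0, p$field_size)
    y <- stats::runif(n, 0, p$field_size)
    max_vis <- if (p_bleach_per_exposure > 0)
      1 + stats::rgeom(n, p_bleach_per_exposure) else rep(Inf, n)
    # analytic visibility: frame i (1-based) shows the molecule iff
    # t_on <= (i-1)*dt < t_on + residence, truncated by bleaching
    i_min <- ceiling(t_on / acquisition_interval - 1e-12) + 1
    u <- (t_on + res) / acquisition_interval
    i_max <- floor(u - 1e-12) + 1
    i_max[!is.finite(res)] <- T
    i_max <- pmin(i_max, T)
    n_win <- pmax(0, i_max - i_min + 1)
    n_vis <- pmin(n_win, max_vis)
    i_end <- i_min + n_vis - 1

    frames <- NULL
    if (render) {
      npx <- round(p$field_size / p$pixel_size)
      frames <- array(0, c(npx, npx, T))
      sig_px <- p$psf_sigma / p$pixel_size
      w <- ceiling(4 * sig_px)
      for (t in seq_len(T)) {
        sc <- matrix(p$background, npx, npx)
        for (m in which(i_min <= t & t <= i_end)) {
          cj <- x[m] / p$pixel_size + 1; ci <- y[m] / p$pixel_size + 1
          ii <- max(1, floor(ci - w)):min(npx, ceiling(ci + w))
          jj <- max(1, floor(cj - w)):min(npx, ceiling(cj + w))
          g <- outer(exp(-(ii - ci)^2 / (2 * sig_px^2)),
                     exp(-(jj - cj)^2 / (2 * sig_px^2)))
          sc[ii, jj] <- sc[ii, jj] + p$photons_per_pixel * g
        }
        frames[, , t] <- if (noise) add_camera_noise(sc, p) else sc
      }
    }
    molecules <- tibble::tibble(
      x_um = x, y_um = y, t_on_s = t_on, residence_s = res,
      first_frame = as.integer(i_min) - 1L,
      n_frames_visible = as.integer(pmax(n_vis, 0)))
    mv <- if (render) movie(frames, p$pixel_size, acquisition_interval)
          else NULL
    list(movie = mv,
         truth = structure(list(
           seed = seed, molecules = molecules, k_off_per_s = k_off,
           p_bleach_per_exposure = p_bleach_per_exposure,
           acquisition_interval_s = acquisition_interval),
           class = "ground_truth"))
  })
}

#' Synthetic Hill titration table
#'
#' Replicate responses `y(c) = y0 + (ymax - y0) c^n / (EC50^n + c^n)` plus
#' Gaussian noise, in the long CSV layout consumed by [fit_hill()].
#'
#' @param hill Numeric `c(y0, ymax, n_h, ec50)`.
#' @param concentrations Concentrations (uM); 0 allowed.
#' @param noise_sd Gaussian noise sd.
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return Tibble: `concentration_uM`, `replicate`, `response`.
#' @export
generate_titration_table <- function(hill, concentrations, noise_sd = 0.02,
                                     replicates = 3, seed = 1L) {
  stopifnot(length(hill) == 4, hill[4] > 0, hill[3] > 0)
  withr::with_seed(seed, {
    tidyr::expand_grid(concentration_uM = concentrations,
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(response = hill_curve(.data$concentration_uM, hill[1],
                                          hill[2], hill[3], hill[4]) +
                      stats::rnorm(dplyr::n(), 0, noise_sd))
  })
}
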