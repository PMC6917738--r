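#' Differential movie: growth and shrinkage channels
#'
#' Applies a spatiotemporal Gaussian low-pass (sd `sigma_xy` px in x and y,
#' `sigma_t` frames in t) to the stack and takes differences of consecutive
#' filtered frames, `D(t) = F(t+1) - F(t)`. The positive part is the growth
#' channel (intensity appearing: polymerizing ends), the negative part the
#' shrinkage channel (intensity disappearing: depolymerizing ends);
#' `growth - shrinkage` reconstructs the filtered difference exactly. The
#' operation is linear in the input intensities.
#'
#' @param mv A [movie()] with at least 3 frames.
#' @param sigma_xy,sigma_t Low-pass scales (px, frames); defaults 1 and 1,
#'   the diffraction/sampling scale.
#' @return A `differential_movie`: list with `growth` and `shrink`
#'   (`H x W x (T-1)` arrays, >= 0), `pixel_size`, `frame_interval`,
#'   `origin_time` (time of difference `t` is the time of source frame `t`).
#' @export
differential_movie <- function(mv, sigma_xy = 1, sigma_t = 1) {
  stopifnot(inherits(mv, "filnet_movie"))
  T <- n_frames(mv)
  if (T < 3) stop("differential movie needs at least 3 frames")
  f <- mv$frames
  if (sigma_xy > 0)
    for (t in seq_len(T)) f[, , t] <- blur2d(f[, , t], sigma_xy)
  f <- blur_time(f, sigma_t)
  D <- f[, , 2:T, drop = FALSE] - f[, , 1:(T - 1), drop = FALSE]
  structure(list(growth = pmax(D, 0), shrink = pmax(-D, 0),
                 pixel_size = mv$pixel_size,
                 frame_interval = mv$frame_interval,
                 origin_time = mv$origin_time),
            class = "differential_movie")
}

# Difference-of-Gaussians blob response at blob radius r_px; approximates the
# scale-normalized Laplacian of Gaussian.
dog_response <- function(frame, r_px) {
  s1 <- max(0.6, r_px / sqrt(2))
  blur2d(frame, s1) - blur2d(frame, 1.6 * s1)
}

# Local maxima of m (>= all 8 neighbors and > floor), with candidates closer
# than min_sep px merged keeping the higher response.
local_maxima <- function(m, min_sep, floor = 0) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(-Inf, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  sh <- function(dy, dx) p[seq_len(H) + 1 + dy, seq_len(W) + 1 + dx]
  is_max <- m > floor
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & m >= sh(dy, dx)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(idx)
  ord <- order(m[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1):nrow(idx)
      d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
      keep[j][d2 < min_sep^2] <- FALSE
    }
  }
  idx[keep, , drop = FALSE]
}

#' Detect diffraction-limited spots
#'
#' Laplacian-of-Gaussian style blob detection (difference of Gaussians at the
#' blob scale `diameter / 2`) with sub-pixel localization by centroid
#' refinement of the response in a small window. The per-movie quality
#' (response) distribution is thresholded either at an absolute value
#' (`quality_threshold`) or at a percentile of all candidates
#' (`quality_percentile`, default 90).
#'
#' @param x A `differential_movie` (both channels are processed) or a
#'   [movie()] (single channel `"raw"`).
#' @param diameter Expected spot diameter (um), default 0.5.
#' @param quality_percentile Percentile cut on candidate quality (0-100).
#' @param quality_threshold Absolute quality cut; overrides the percentile.
#' @return A `tibble` with columns `frame` (0-based difference/frame index),
#'   `x_um`, `y_um`, `intensity` (3x3 sum of the channel), `quality`,
#'   `channel`.
#' @export
detect_spots <- function(x, diameter = 0.5, quality_percentile = 90,
                         quality_threshold = NULL) {
  UseMethod("detect_spots")
}

detect_channel <- function(arr, pixel_size, channel, diameter,
                           quality_percentile, quality_threshold) {
  r_px <- (diameter / 2) / pixel_size
  w <- max(1L, round(r_px))
  T <- dim(arr)[3]
  H <- dim(arr)[1]; W <- dim(arr)[2]
  offs <- expand.grid(dy = -w:w, dx = -w:w)
  cand <- purrr::map(seq_len(T), function(t) {
    fr <- arr[, , t]
    resp <- dog_response(fr, r_px)
    # noise floor: candidates must clear 3 robust sds of the response
    # (with an absolute epsilon so constant frames yield no candidates)
    floor_t <- max(3 * stats::mad(resp), 1e-9 * (mean(abs(fr)) + 1))
    idx <- local_maxima(resp, min_sep = max(2, r_px), floor = floor_t)
    if (nrow(idx) == 0) return(NULL)
    # vectorized centroid refinement on the positive response in a
    # (2w+1)^2 window (indices clamped at borders)
    sw <- swi <- swj <- int <- numeric(nrow(idx))
    for (k in seq_len(nrow(offs))) {
      ii <- pmin(pmax(idx[, 1] + offs$dy[k], 1), H)
      jj <- pmin(pmax(idx[, 2] + offs$dx[k], 1), W)
      v <- pmax(resp[cbind(ii, jj)], 0)
      sw <- sw + v; swi <- swi + v * ii; swj <- swj + v * jj
      if (abs(offs$dy[k]) <= 1 && abs(offs$dx[k]) <= 1)
        int <- int + fr[cbind(ii, jj)]
    }
    ci <- ifelse(sw > 0, swi / sw, idx[, 1])
    cj <- ifelse(sw > 0, swj / sw, idx[, 2])
    tibble::tibble(frame = t - 1L,
                   x_um = (cj - 1) * pixel_size,
                   y_um = (ci - 1) * pixel_size,
                   intensity = int,
                   quality = resp[idx])
  })
  out <- dplyr::bind_rows(cand)
  if (nrow(out) == 0)
    return(tibble::tibble(frame = integer(), x_um = numeric(),
                          y_um = numeric(), intensity = numeric(),
                          quality = numeric(), channel = character()))
  thr <- quality_threshold %||%
    stats::quantile(out$quality, quality_percentile / 100, names = FALSE)
  out <- dplyr::filter(out, .data$quality >= thr, .data$intensity > 0)
  out$channel <- channel
  out
}

#' @rdname detect_spots
#' @export
detect_spots.differential_movie <- function(x, diameter = 0.5,
                                            quality_percentile = 90,
                                            quality_threshold = NULL) {
  dplyr::bind_rows(
    detect_channel(x$growth, x$pixel_size, "growth", diameter,
                   quality_percentile, quality_threshold),
    detect_channel(x$shrink, x$pixel_size, "shrink", diameter,
                   quality_percentile, quality_threshold))
}

#' @rdname detect_spots
#' @export
detect_spots.filnet_movie <- function(x, diameter = 0.5,
                                      quality_percentile = 90,
                                      quality_threshold = NULL) {
  detect_channel(x$frames, x$pixel_size, "raw", diameter,
                 quality_percentile, quality_threshold)
}

# Minimum-cost maximum-cardinality assignment between rows (tracks) and
# columns (spots) given a finite-cost edge list. Solved exactly per
# connected component by depth-first enumeration (components here are small
# because the link radius is short); components larger than `cap` tracks
# fall back to greedy nearest-first. Ties broken by lower spot index.
assign_links <- function(cost, cap = 10L) {
  nt <- nrow(cost); ns <- ncol(cost)
  match_t <- rep(NA_integer_, nt)
  if (nt == 0 || ns == 0) return(match_t)
  edges <- which(is.finite(cost), arr.ind = TRUE)
  if (nrow(edges) == 0) return(match_t)
  # connected components over the bipartite edge graph
  comp_t <- rep(0L, nt); comp_s <- rep(0L, ns); nc <- 0L
  for (e in seq_len(nrow(edges))) {
    t0 <- edges[e, 1]; s0 <- edges[e, 2]
    if (comp_t[t0] == 0 && comp_s[s0] == 0) {
      nc <- nc + 1L; comp_t[t0] <- nc; comp_s[s0] <- nc
    } else if (comp_t[t0] == 0) comp_t[t0] <- comp_s[s0]
    else if (comp_s[s0] == 0) comp_s[s0] <- comp_t[t0]
    else if (comp_t[t0] != comp_s[s0]) {
      old <- comp_s[s0]; new <- comp_t[t0]
      comp_t[comp_t == old] <- new; comp_s[comp_s == old] <- new
    }
  }
  for (cid in unique(comp_t[comp_t > 0])) {
    ts <- which(comp_t == cid); ss <- which(comp_s == cid)
    sub <- cost[ts, ss, drop = FALSE]
    if (length(ts) <= cap) {
      best <- list(n = -1L, cost = Inf, asg = NULL)
      asg <- rep(NA_integer_, length(ts))
      rec <- function(i, used, n, cst) {
        if (i > length(ts)) {
          if (n > best$n || (n == best$n && cst < best$cost - 1e-12)) {
            best <<- list(n = n, cost = cst, asg = asg)
          }
          return(invisible())
        }
        # upper bound prune
        if (n + (length(ts) - i + 1) < best$n) return(invisible())
        opts <- which(is.finite(sub[i, ]) & !used)
        if (length(opts)) {
          opts <- opts[order(sub[i, opts], opts)]
          for (s in opts) {
            asg[i] <<- s; used[s] <- TRUE
            rec(i + 1, used, n + 1L, cst + sub[i, s])
            used[s] <- FALSE; asg[i] <<- NA_integer_
          }
        }
        rec(i + 1, used, n, cst)
      }
      rec(1L, rep(FALSE, length(ss)), 0L, 0)
      match_t[ts] <- ss[best$asg]
    } else {
      sube <- which(is.finite(sub), arr.ind = TRUE)
      ord <- order(sub[sube], sube[, 2])
      used_t <- rep(FALSE, length(ts)); used_s <- rep(FALSE, length(ss))
      for (e in ord) {
        i <- sube[e, 1]; s <- sube[e, 2]
        if (!used_t[i] && !used_s[s]) {
          match_t[ts[i]] <- ss[s]; used_t[i] <- TRUE; used_s[s] <- TRUE
        }
      }
    }
  }
  match_t
}

#' Link detected spots into trajectories
#'
#' Frame-to-frame assignment minimizing the total displacement (exact
#' minimum-cost maximum-cardinality matching per connected component of the
#' candidate graph; ties broken by lower spot index), with a hard linking
#' radius and gap closing: a track whose last spot is up to `gap_max` frames
#' in the past may still capture a new spot within `link_max`. Channels are
#' linked independently.
#'
#' @param spots Spot table from [detect_spots()] (sorted by frame).
#' @param link_max Maximum displacement between linked spots (um).
#' @param gap_max Maximum number of missed frames closed (frames).
#' @param min_len Tracks with fewer localizations are flagged
#'   (`len_ok = FALSE`) and excluded from velocity statistics, but kept.
#' @return Tibble of class `trajectory_table`: `track_id`, `frame`, `x_um`,
#'   `y_um`, `intensity`, `channel`, `n_frames`, `len_ok`.
#' @export
link_trajectories <- function(spots, link_max = 0.5, gap_max = 2L,
                              min_len = 4L) {
  stopifnot(all(c("frame", "x_um", "y_um", "channel") %in% names(spots)))
  out <- spots |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(function(df, key)
      link_one_channel(df, link_max, gap_max)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$channel, .data$track_id) |>
    dplyr::mutate(n_frames = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(len_ok = .data$n_frames >= min_len) |>
    dplyr::arrange(.data$channel, .data$track_id, .data$frame)
  # globally unique ids across channels
  out <- out |>
    dplyr::mutate(track_id = as.integer(factor(
      paste(.data$channel, .data$track_id, sep = ":"),
      levels = unique(paste(.data$channel, .data$track_id, sep = ":")))))
  class(out) <- c("trajectory_table", class(out))
  out
}

link_one_channel <- function(df, link_max, gap_max) {
  df <- dplyr::arrange(df, .data$frame, .data$x_um, .data$y_um)
  frames <- sort(unique(df$frame))
  # active track state
  tid <- integer(0); tx <- numeric(0); ty <- numeric(0); tf <- integer(0)
  next_id <- 1L
  df$track_id <- NA_integer_
  rows_by_frame <- split(seq_len(nrow(df)), df$frame)
  for (f in frames) {
    rows <- rows_by_frame[[as.character(f)]]
    sx <- df$x_um[rows]; sy <- df$y_um[rows]
    alive <- which(f - tf >= 1 & f - tf <= gap_max + 1)
    if (length(alive) && length(rows)) {
      cost <- outer(tx[alive], sx, function(a, b) (a - b)^2) +
        outer(ty[alive], sy, function(a, b) (a - b)^2)
      cost <- sqrt(cost)
      cost[cost > link_max] <- Inf
      m <- assign_links(cost)
    } else m <- rep(NA_integer_, length(alive))
    taken <- rep(FALSE, length(rows))
    if (length(alive)) for (i in seq_along(alive)) {
      if (!is.na(m[i])) {
        k <- alive[i]; r <- rows[m[i]]
        df$track_id[r] <- tid[k]
        tx[k] <- df$x_um[r]; ty[k] <- df$y_um[r]; tf[k] <- f
        taken[m[i]] <- TRUE
      }
    }
    for (r in rows[!taken]) {
      tid <- c(tid, next_id); tx <- c(tx, df$x_um[r])
      ty <- c(ty, df$y_um[r]); tf <- c(tf, f)
      df$track_id[r] <- next_id
      next_id <- next_id + 1L
    }
    # retire stale tracks
    live <- f - tf <= gap_max
    tid <- tid[live]; tx <- tx[live]; ty <- ty[live]; tf <- tf[live]
  }
  df
}

#' Per-track treadmilling velocities
#'
#' Per-track speed is a path length divided by the elapsed time
#' `(last frame - first frame) x frame_interval`. The default
#' `method = "coarse_path"` sums displacements over a polyline decimated to
#' every `coarse_step`-th localization: summing raw frame-to-frame steps
#' (`method = "path"`) is robust to curvature but systematically inflated by
#' localization noise (each step adds the jitter in quadrature), while pure
#' end-to-end displacement (`method = "end_to_end"`) underestimates strongly
#' curved trajectories; the coarse polyline keeps both biases at the percent
#' level for treadmilling-scale motion (see the methods vignette).
#' Channel-wise mean and sd are reported per spot track and, when a
#' `movie_id` column is present, additionally as mean of per-experiment
#' means.
#'
#' @param tracks A [link_trajectories()] result.
#' @param frame_interval Seconds per frame.
#' @param min_len Minimum track length (frames) for inclusion (default 4).
#' @param method Speed estimator (see above).
#' @param coarse_step Decimation step (localizations) for `"coarse_path"`,
#'   default 5.
#' @return List of class `velocity_stats`: `by_channel` tibble (`channel`,
#'   `n_tracks`, `mean_nm_s`, `sd_nm_s`), `per_track` tibble, and
#'   `by_experiment` (or NULL).
#' @export
track_velocities <- function(tracks, frame_interval, min_len = 4L,
                             method = c("coarse_path", "path",
                                        "end_to_end"),
                             coarse_step = 5L) {
  method <- match.arg(method)
  track_path <- function(x, y) {
    n <- length(x)
    idx <- switch(method,
      path = seq_len(n),
      end_to_end = c(1L, n),
      coarse_path = unique(c(seq(1L, n, by = coarse_step), n)))
    sum(sqrt(diff(x[idx])^2 + diff(y[idx])^2))
  }
  per_track <- tracks |>
    dplyr::filter(.data$n_frames >= min_len) |>
    dplyr::group_by(.data$channel, .data$track_id,
                    dplyr::across(dplyr::any_of("movie_id"))) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      path_um = track_path(.data$x_um, .data$y_um),
      elapsed_s = (max(.data$frame) - min(.data$frame)) * frame_interval,
      duration_s = elapsed_s,
      speed_nm_s = 1000 * .data$path_um / .data$elapsed_s,
      .groups = "drop")
  if (nrow(per_track) == 0) {
    warning("no qualifying tracks for velocity statistics")
    return(structure(list(
      by_channel = tibble::tibble(channel = character(), n_tracks = integer(),
                                  mean_nm_s = numeric(), sd_nm_s = numeric()),
      per_track = per_track, by_experiment = NULL),
      class = "velocity_stats"))
  }
  by_channel <- per_track |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(n_tracks = dplyr::n(),
                     mean_nm_s = mean(.data$speed_nm_s),
                     sd_nm_s = stats::sd(.data$speed_nm_s),
                     .groups = "drop")
  by_exp <- NULL
  if ("movie_id" %in% names(per_track)) {
    by_exp <- per_track |>
      dplyr::group_by(.data$channel, .data$movie_id) |>
      dplyr::summarise(mean_nm_s = mean(.data$speed_nm_s),
                       .groups = "drop_last") |>
      dplyr::summarise(n_experiments = dplyr::n(),
                       mean_nm_s = mean(.data$mean_nm_s),
                       sd_nm_s = stats::sd(.data$mean_nm_s),
                       .groups = "drop")
  }
  structure(list(by_channel = by_channel, per_track = per_track,
                 by_experiment = by_exp),
            class = "velocity_stats")
}

#' @export
print.velocity_stats <- function(x, ...) {
  cat("Treadmilling velocities (per spot track):\n")
  print(x$by_channel)
  if (!is.null(x$by_experiment)) {
    cat("Per experiment (mean of per-movie means):\n")
    print(x$by_experiment)
  }
  invisible(x)
}

#' Directional autocorrelation of trajectories
#'
#' `C(D)` is the mean cosine of the angle between displacement vectors of the
#' same track separated by `D` steps; `C(0) = 1`. Steps shorter than
#' `min_step_um` (localization-noise floor) are excluded.
#'
#' @param tracks A [link_trajectories()] result.
#' @param frame_interval Seconds per frame (for the lag axis in seconds).
#' @param max_lag Maximum step lag (default 10).
#' @param min_step_um Noise floor (default 0.054 um = 0.5 px at 0.108 um/px).
#' @return Tibble of class `directional_autocorr`: `lag_steps`, `lag_s`,
#'   `C`, `n_pairs`.
#' @export
directional_autocorrelation <- function(tracks, frame_interval,
                                        max_lag = 10L,
                                        min_step_um = 0.054) {
  steps <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe(dx = diff(.data$x_um), dy = diff(.data$y_um),
                   step = seq_len(dplyr::n() - 1)) |>
    dplyr::mutate(len = sqrt(.data$dx^2 + .data$dy^2)) |>
    dplyr::filter(.data$len >= min_step_um)
  rows <- purrr::map(seq_len(max_lag), function(l) {
    prs <- steps |>
      dplyr::group_by(.data$track_id) |>
      dplyr::reframe(cosang = {
        i <- match(.data$step + l, .data$step)
        ok <- !is.na(i)
        (.data$dx[ok] * .data$dx[i[ok]] + .data$dy[ok] * .data$dy[i[ok]]) /
          (.data$len[ok] * .data$len[i[ok]])
      })
    tibble::tibble(lag_steps = l, lag_s = l * frame_interval,
                   C = if (nrow(prs)) mean(prs$cosang) else NA_real_,
                   n_pairs = nrow(prs))
  })
  out <- dplyr::bind_rows(
    tibble::tibble(lag_steps = 0L, lag_s = 0, C = 1, n_pairs = nrow(steps)),
    rows)
  class(out) <- c("directional_autocorr", class(out))
  out
}

#' Spot intensity distributions and along-track intensity profile
#'
#' For each channel: the distribution of spot intensities, the mean intensity
#' (and the growth/shrink mean-intensity ratio), and the per-track intensity
#' normalized to its own track mean, averaged as a function of fractional
#' position along the trajectory. For parallel (polar) bundles the normalized
#' profile is flat near 1; antiparallel bundles produce transient excursions
#' when growth and shrinkage spots cross. The excursion rate is the fraction
#' of samples with `|I/mean - 1| > excursion_threshold`.
#'
#' @param tracks A [link_trajectories()] result with intensities.
#' @param n_bins Number of fractional-position bins (default 10).
#' @param excursion_threshold Relative deviation from the track mean counted
#'   as an excursion (default 0.25, about 2.5 robust sds of the
#'   noise-driven intensity scatter of a stable differential spot).
#' @param min_len Minimum track length used (default 4).
#' @return List of class `spot_intensity_profile`: `by_channel` (mean
#'   intensity, excursion_rate, n), `profile` tibble (channel, position bin
#'   center, mean normalized intensity, sd, n), `intensity_ratio`
#'   (growth/shrink), `samples` tibble.
#' @export
spot_intensity_profile <- function(tracks, n_bins = 10,
                                   excursion_threshold = 0.25,
                                   min_len = 4L) {
  samples <- tracks |>
    dplyr::filter(.data$n_frames >= min_len) |>
    dplyr::group_by(.data$channel, .data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(norm_intensity = .data$intensity / mean(.data$intensity),
                  position = (dplyr::row_number() - 1) /
                    pmax(dplyr::n() - 1, 1)) |>
    dplyr::ungroup()
  by_channel <- samples |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      n_tracks = dplyr::n_distinct(.data$track_id),
      mean_intensity = mean(.data$intensity),
      excursion_rate = mean(abs(.data$norm_intensity - 1) >
                              excursion_threshold),
      .groups = "drop")
  profile <- samples |>
    dplyr::mutate(bin = pmin(floor(.data$position * n_bins), n_bins - 1)) |>
    dplyr::group_by(.data$channel, .data$bin) |>
    dplyr::summarise(position = (.data$bin[1] + 0.5) / n_bins,
                     mean_norm = mean(.data$norm_intensity),
                     sd_norm = stats::sd(.data$norm_intensity),
                     n = dplyr::n(), .groups = "drop")
  mg <- by_channel$mean_intensity[by_channel$channel == "growth"]
  ms <- by_channel$mean_intensity[by_channel$channel == "shrink"]
  ratio <- if (length(mg) && length(ms)) mg / ms else NA_real_
  structure(list(by_channel = by_channel, profile = profile,
                 intensity_ratio = ratio, samples = samples),
            class = "spot_intensity_profile")
}

#' Bundle length from concurrent growth/shrink spot pairs
#'
#' The growing and shrinking ends of a treadmilling filament travel along the
#' same path separated by the filament length. For each growth track the
#' concurrent shrink track with the smallest time-averaged perpendicular
#' offset to its path (below `max_perp_offset_um`) is paired one-to-one, and
#' the mean separation of the paired spots over their common frames is the
#' length estimate.
#'
#' @param tracks A [link_trajectories()] result with both channels.
#' @param max_perp_offset_um Maximum admissible path offset (um), default
#'   0.25.
#' @param min_overlap Minimum number of common frames (default 3).
#' @param min_len Minimum track length used (default 4).
#' @return List of class `bundle_length`: `length_um` (NA when undefined),
#'   `n_pairs`, `pairs` tibble (growth id, shrink id, perpendicular offset,
#'   separation).
#' @export
bundle_length_from_spot_pairs <- function(tracks, max_perp_offset_um = 0.25,
                                          min_overlap = 3L, min_len = 4L) {
  tk <- dplyr::filter(tracks, .data$n_frames >= min_len)
  gs <- split(tk[tk$channel == "growth", ], tk$track_id[tk$channel == "growth"])
  ss <- split(tk[tk$channel == "shrink", ], tk$track_id[tk$channel == "shrink"])
  if (length(gs) == 0 || length(ss) == 0)
    return(structure(list(length_um = NA_real_, n_pairs = 0L,
                          pairs = NULL), class = "bundle_length"))
  cand <- list()
  for (gi in names(gs)) for (si in names(ss)) {
    g <- gs[[gi]]; s <- ss[[si]]
    common <- intersect(g$frame, s$frame)
    if (length(common) < min_overlap) next
    gi_rows <- match(common, g$frame); si_rows <- match(common, s$frame)
    off <- mean(vapply(si_rows, function(r)
      point_to_polyline(s$x_um[r], s$y_um[r], g$x_um, g$y_um), numeric(1)))
    sep <- mean(sqrt((g$x_um[gi_rows] - s$x_um[si_rows])^2 +
                       (g$y_um[gi_rows] - s$y_um[si_rows])^2))
    cand[[length(cand) + 1]] <- tibble::tibble(
      growth_id = as.integer(gi), shrink_id = as.integer(si),
      perp_offset_um = off, separation_um = sep)
  }
  if (length(cand) == 0)
    return(structure(list(length_um = NA_real_, n_pairs = 0L, pairs = NULL),
                     class = "bundle_length"))
  cand <- dplyr::bind_rows(cand) |>
    dplyr::filter(.data$perp_offset_um <= max_perp_offset_um) |>
    dplyr::arrange(.data$perp_offset_um)
  used_g <- integer(0); used_s <- integer(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$growth_id[i] %in% used_g || cand$shrink_id[i] %in% used_s) next
    keep[i] <- TRUE
    used_g <- c(used_g, cand$growth_id[i])
    used_s <- c(used_s, cand$shrink_id[i])
  }
  pairs <- cand[keep, ]
  if (nrow(pairs) == 0)
    return(structure(list(length_um = NA_real_, n_pairs = 0L, pairs = pairs),
                     class = "bundle_length"))
  structure(list(length_um = mean(pairs$separation_um),
                 n_pairs = nrow(pairs), pairs = pairs),
            class = "bundle_length")
}

# Shortest distance from point (px, py) to the polyline (xs, ys).
point_to_polyline <- function(px, py, xs, ys) {
  if (length(xs) == 1) return(sqrt((px - xs)^2 + (py - ys)^2))
  ax <- xs[-length(xs)]; ay <- ys[-length(ys)]
  bx <- xs[-1]; by <- ys[-1]
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- ifelse(L2 > 0, ((px - ax) * vx + (py - ay) * vy) / L2, 0)
  t <- pmin(pmax(t, 0), 1)
  min(sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
}
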