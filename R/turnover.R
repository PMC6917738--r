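# ROI helpers: rectangles are c(x0, y0, x1, y1) in um from the top-left
# pixel center (0-based pixel coordinates).
roi_indices <- function(roi, pixel_size, dims) {
  stopifnot(length(roi) == 4)
  if (roi[1] > roi[3] || roi[2] > roi[4] ||
      roi[3] < 0 || roi[1] > (dims[2] - 1) * pixel_size ||
      roi[4] < 0 || roi[2] > (dims[1] - 1) * pixel_size)
    stop("ROI outside field")
  j <- max(1, round(roi[1] / pixel_size) + 1):min(dims[2],
                                                  round(roi[3] / pixel_size) + 1)
  i <- max(1, round(roi[2] / pixel_size) + 1):min(dims[1],
                                                  round(roi[4] / pixel_size) + 1)
  list(i = i, j = j)
}

roi_means <- function(mv, roi) {
  ix <- roi_indices(roi, mv$pixel_size, dim(mv$frames)[1:2])
  apply(mv$frames[ix$i, ix$j, , drop = FALSE], 3, mean)
}

#' Normalized FRAP recovery trace
#'
#' Computes the ROI mean per frame, optionally background-subtracts and
#' divides by a reference-ROI mean (normalized to its own pre-bleach level)
#' to correct for acquisition photobleaching, then rescales so that the
#' pre-bleach mean is 1 and the bleach frame is 0. The bleach frame can be
#' supplied or auto-detected as the largest single-frame drop of the ROI
#' mean.
#'
#' @param mv A [movie()].
#' @param roi Bleached rectangle `c(x0, y0, x1, y1)` in um.
#' @param bleach_frame 0-based index of the first bleached frame, or NULL to
#'   auto-detect.
#' @param reference_roi Optional unbleached rectangle for photobleaching
#'   correction.
#' @param background_roi Optional protein-free rectangle whose mean is
#'   subtracted.
#' @return Tibble of class `frap_trace` with columns `frame`, `time_s`,
#'   `t_post_s` (time since the bleach frame; NA before it),
#'   `intensity_norm`; attribute `bleach_frame`.
#' @export
frap_trace <- function(mv, roi, bleach_frame = NULL, reference_roi = NULL,
                       background_roi = NULL) {
  stopifnot(inherits(mv, "filnet_movie"))
  I <- roi_means(mv, roi)
  if (!is.null(background_roi)) I <- I - roi_means(mv, background_roi)
  if (!is.null(reference_roi)) {
    R <- roi_means(mv, reference_roi)
    if (!is.null(background_roi)) R <- R - roi_means(mv, background_roi)
    if (any(R <= 0)) stop("reference ROI has non-positive intensity")
    I <- I / R
  }
  if (is.null(bleach_frame)) {
    drops <- -diff(I)
    bf <- which.max(drops)  # frame index (1-based) of first bleached frame + 1
    pre_level <- mean(I[seq_len(bf)])
    if (drops[bf] < 0.2 * pre_level) {
      stop("no detectable bleach drop (max drop ", signif(drops[bf], 3),
           " vs pre-bleach level ", signif(pre_level, 3), "); drop profile: ",
           paste(signif(drops, 3), collapse = ", "))
    }
    bleach_frame <- bf  # 0-based index of the bleached frame
  }
  bf1 <- bleach_frame + 1L  # 1-based
  if (bf1 < 2 || bf1 > length(I)) stop("bleach_frame outside movie")
  if (!is.null(reference_roi)) {
    pre <- mean(I[seq_len(bf1 - 1)])
    I <- I / pre
  }
  pre <- mean(I[seq_len(bf1 - 1)])
  I0 <- I[bf1]
  if (pre <= I0) stop("pre-bleach level not above bleach level")
  times <- frame_times(mv)
  out <- tibble::tibble(
    frame = seq_along(I) - 1L,
    time_s = times,
    t_post_s = ifelse(seq_along(I) >= bf1, times - times[bf1], NA_real_),
    intensity_norm = (I - I0) / (pre - I0))
  attr(out, "bleach_frame") <- bleach_frame
  class(out) <- c("frap_trace", class(out))
  out
}

#' Fit a FRAP recovery curve
#'
#' Nonlinear least squares for `I(t) = a (1 - exp(-b t))` with multi-start
#' over `b` in `{0.01, 0.1, 1}` per second; the reported half-time is
#' `ln(2)/b`. Time is measured from the bleach event (`t = 0` at the bleach
#' frame, which itself is excluded from the fit since the model fixes
#' `I(0) = 0`).
#'
#' @param trace A [frap_trace()] tibble, or a numeric vector of normalized
#'   intensities (then `times` is required).
#' @param times Seconds since bleach for each element of `trace` (vector
#'   input only). At least 6 post-bleach points are required.
#' @return List of class `frap_fit`: `a`, `b_per_s`, `half_time_s`, `sigma`
#'   (residual sd), `n`.
#' @export
fit_frap <- function(trace, times = NULL) {
  if (inherits(trace, "frap_trace") || is.data.frame(trace)) {
    d <- dplyr::filter(trace, !is.na(.data$t_post_s), .data$t_post_s > 0)
    y <- d$intensity_norm; t <- d$t_post_s
  } else {
    y <- trace; t <- times
  }
  stopifnot(length(y) == length(t))
  if (length(y) < 6) stop("fit_frap needs at least 6 post-bleach points")
  if (all(y <= 0) || stats::sd(y) == 0)
    stop("no recovery detected in the trace")
  df <- data.frame(t = t, y = y)
  a0 <- max(stats::quantile(y, 0.9), 0.1)
  fits <- purrr::map(c(0.01, 0.1, 1), function(b0) {
    tryCatch(minpack.lm::nlsLM(y ~ a * (1 - exp(-b * t)), data = df,
                               start = list(a = a0, b = b0),
                               lower = c(1e-8, 1e-8),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0)
    stop("FRAP fit failed to converge from all starts; n = ", length(y),
         ", range = [", signif(min(y), 3), ", ", signif(max(y), 3), "]")
  rss <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  structure(list(a = unname(cf["a"]), b_per_s = unname(cf["b"]),
                 half_time_s = log(2) / unname(cf["b"]),
                 sigma = sqrt(min(rss) / max(1, length(y) - 2)),
                 n = length(y)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP fit: a = %.4g, b = %.4g /s, half-time = %.4g s (n = %d)\n",
    x$a, x$b_per_s, x$half_time_s, x$n))
  invisible(x)
}

#' Track single molecules
#'
#' Detection and linking tuned to sparse single-molecule movies: spot size
#' 0.5 um, linking and gap-closing radius 0.5 um, gaps up to 2 frames,
#' particles localized for at least 2 frames kept. The quality cut is an
#' absolute response threshold at `threshold_mads` robust standard
#' deviations of the blob response (default 6).
#'
#' @param mv A sparse-spot [movie()].
#' @param diameter,link_max,gap_max As in [detect_spots()] /
#'   [link_trajectories()].
#' @param threshold_mads Detection threshold in MADs of the response.
#' @return A [link_trajectories()] trajectory table (min 2 localizations).
#' @export
track_single_molecules <- function(mv, diameter = 0.5, link_max = 0.5,
                                   gap_max = 2L, threshold_mads = 6) {
  stopifnot(inherits(mv, "filnet_movie"))
  r_px <- (diameter / 2) / mv$pixel_size
  resp1 <- dog_response(mv$frames[, , 1], r_px)
  thr <- threshold_mads * stats::mad(resp1)
  spots <- detect_spots(mv, diameter = diameter, quality_threshold = thr)
  if (nrow(spots) == 0)
    return(link_trajectories(spots, link_max, gap_max, min_len = 2L))
  per_frame <- nrow(spots) / n_frames(mv)
  area <- prod(dim(mv$frames)[1:2]) * mv$pixel_size^2
  if (per_frame > 0 && sqrt(area / per_frame) / 2 < 4 * (diameter / 4))
    warning("spot density high; single-molecule tracking may be unreliable")
  link_trajectories(spots, link_max = link_max, gap_max = gap_max,
                    min_len = 2L)
}

#' Mono-exponential residence-time fit at one acquisition interval
#'
#' Track durations are `(n_frames - 1) x interval`. Durations below the
#' detection truncation (default two acquisition intervals) are discarded
#' and the exponential mean is the truncated maximum-likelihood estimate
#' `mean(d - truncation)` (memorylessness makes it independent of the
#' truncation point). The per-interval observed decay rate `k_obs` is
#' reported on the per-frame geometric hazard scale,
#' `k_obs = ln(1 + interval / mean) / interval`, which removes the
#' frame-quantization bias so that `k_obs(interval) = k_off +
#' (-ln(1 - p_bleach)) / interval` holds exactly in expectation (see the
#' methods vignette).
#'
#' @param tracks A trajectory table (or any data frame with one row per
#'   localization and columns `track_id`, `frame`), or a numeric vector of
#'   durations in seconds.
#' @param acquisition_interval Seconds per frame.
#' @param truncation Left-truncation point (s); default
#'   `2 * acquisition_interval`.
#' @param min_tracks Below this the fit is flagged low-confidence (50).
#' @return List of class `lifetime_fit`: `mean_lifetime_s`, `k_obs_per_s`,
#'   `n`, `interval_s`, `truncation_s`, `low_confidence`.
#' @export
lifetime_fit <- function(tracks, acquisition_interval,
                         truncation = 2 * acquisition_interval,
                         min_tracks = 50) {
  d <- if (is.numeric(tracks)) tracks else {
    tracks |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(dur = (max(.data$frame) - min(.data$frame)) *
                         acquisition_interval, .groups = "drop") |>
      dplyr::pull(.data$dur)
  }
  d <- d[d >= truncation]
  if (length(d) == 0) stop("no track durations at or above the truncation")
  if (stats::sd(d) == 0)
    stop("degenerate lifetime distribution: all durations equal (",
         d[1], " s)")
  low <- length(d) < min_tracks
  if (low) warning("only ", length(d), " tracks; lifetime fit is ",
                   "low-confidence")
  m <- mean(d - truncation)
  if (m <= 0) stop("degenerate lifetime distribution")
  k_obs <- log(1 + acquisition_interval / m) / acquisition_interval
  structure(list(mean_lifetime_s = m, k_obs_per_s = k_obs,
                 n = length(d), interval_s = acquisition_interval,
                 truncation_s = truncation, low_confidence = low),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf(
    "lifetime fit: mean = %.4g s, k_obs = %.4g /s (n = %d, interval %.3g s)%s\n",
    x$mean_lifetime_s, x$k_obs_per_s, x$n, x$interval_s,
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Photobleaching correction across acquisition intervals
#'
#' With a fixed exposure per frame, the observed single-molecule decay rate
#' at acquisition interval `D` is `k_obs(D) = k_off + c / D` where
#' `c = -ln(1 - p_bleach)` is the per-exposure bleaching log-survival.
#' Fitting `k_obs` against `1/D` by weighted linear regression (weights =
#' number of tracks) separates unbinding from bleaching: the intercept is
#' `k_off`, the slope gives `p_bleach`.
#'
#' @param fits List of [lifetime_fit()] objects at >= 3 distinct intervals.
#' @return List of class `bleach_correction`: `k_off_per_s` (negative
#'   intercepts clipped to 0 with a warning), `p_bleach`, `slope`,
#'   `intercept_se`, `per_interval` tibble.
#' @export
bleach_correction <- function(fits) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1),
                                      "lifetime_fit")))
  tab <- dplyr::bind_rows(lapply(fits, function(f)
    tibble::tibble(interval_s = f$interval_s, k_obs = f$k_obs_per_s,
                   n = f$n)))
  if (dplyr::n_distinct(tab$interval_s) < 3)
    stop("bleach correction needs fits at >= 3 distinct intervals")
  fit <- stats::lm(k_obs ~ I(1 / interval_s), data = tab, weights = n)
  co <- stats::coef(fit)
  k_off <- unname(co[1])
  if (k_off < 0) {
    warning("negative k_off intercept (", signif(k_off, 3),
            ") clipped to 0")
    k_off <- 0
  }
  structure(list(k_off_per_s = k_off,
                 p_bleach = 1 - exp(-max(unname(co[2]), 0)),
                 slope = unname(co[2]),
                 intercept_se = summary(fit)$coefficients[1, 2],
                 per_interval = tab),
            class = "bleach_correction")
}

#' @export
print.bleach_correction <- function(x, ...) {
  cat(sprintf(
    "bleach correction: k_off = %.4g /s, p_bleach = %.3g per exposure (%d intervals)\n",
    x$k_off_per_s, x$p_bleach, nrow(x$per_interval)))
  invisible(x)
}
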