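#' Structure-tensor orientation field
#'
#' Computes the local nematic orientation of line features from the gradient
#' squared tensor. The frame is smoothed with a Gaussian (sd
#' `smooth_sigma` px), intensity gradients are taken by centered differences,
#' and the tensor components are accumulated over non-overlapping
#' `window x window` blocks. The reported angle is the orientation of the
#' eigenvector of the smaller eigenvalue -- perpendicular to the dominant
#' gradient, i.e. along the filament -- in `[0, pi)` measured from the +x
#' axis (y pointing down). The accumulated tensor grid is additionally
#' smoothed with a Gaussian of sd `tensor_sigma` windows before the
#' eigen-decomposition (nematic tensors average correctly where raw angles
#' would wrap), which suppresses window-scale angle noise. Coherence is the
#' eigenvalue contrast `(l1 - l2)/(l1 + l2)`. Windows are invalid when their
#' gradient energy falls below `energy_rel` times the frame's mean window
#' energy (or at or below the absolute `energy_floor`) or their coherence is
#' below `coherence_min`: such windows are background or isotropic regions that
#' carry no filament orientation and are excluded from curvature and
#' spatial-order statistics.
#'
#' @param frame Numeric matrix; must be at least `4 * window` in each
#'   dimension.
#' @param window Analysis window in px (default 4, i.e. 432 nm at
#'   0.108 um/px -- roughly the bundle feature size).
#' @param pixel_size um per px.
#' @param smooth_sigma Gaussian smoothing before gradients (px).
#' @param tensor_sigma Tensor-grid smoothing (windows), default 1.
#' @param coherence_min,energy_floor,energy_rel Validity thresholds (see
#'   above).
#' @return An `orientation_field`: list with matrices `theta` (rad),
#'   `coherence`, `valid`, plus `window_px`, `spacing_um` (= window x
#'   pixel_size), `pixel_size`, and window-center coordinates `x_um`, `y_um`.
#' @export
orientation_field <- function(frame, window = 4L, pixel_size = 0.108,
                              smooth_sigma = 1, tensor_sigma = 1,
                              coherence_min = 0.1, energy_floor = 0,
                              energy_rel = 0.25) {
  stopifnot(is.matrix(frame))
  if (any(dim(frame) < 4 * window))
    stop("frame must be at least 4 x window in each dimension")
  g <- gradients(blur2d(frame, smooth_sigma))
  Jxx <- block_sum(g$gx * g$gx, window)
  Jyy <- block_sum(g$gy * g$gy, window)
  Jxy <- block_sum(g$gx * g$gy, window)
  energy <- Jxx + Jyy
  if (tensor_sigma > 0) {
    Jxx <- blur2d(Jxx, tensor_sigma)
    Jyy <- blur2d(Jyy, tensor_sigma)
    Jxy <- blur2d(Jxy, tensor_sigma)
  }
  # orientation of the dominant gradient, rotated by pi/2 onto the feature
  theta <- (0.5 * atan2(2 * Jxy, Jxx - Jyy) + pi / 2) %% pi
  coh <- ifelse(energy > 0, sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / energy, 0)
  # absolute floor guards against pure floating-point residue on
  # (near-)constant frames, where the relative floor would be meaningless
  efloor <- max(energy_floor, energy_rel * mean(energy),
                1e-12 * (mean(abs(frame)) + 1)^2)
  valid <- energy > efloor & coh >= coherence_min
  if (!any(valid)) warning("orientation field has no valid windows ",
                           "(degenerate or constant frame)")
  bh <- nrow(Jxx); bw <- ncol(Jxx)
  structure(list(
    theta = theta, coherence = coh, valid = valid,
    window_px = window, spacing_um = window * pixel_size,
    pixel_size = pixel_size,
    x_um = (seq_len(bw) - 0.5) * window * pixel_size - pixel_size / 2,
    y_um = (seq_len(bh) - 0.5) * window * pixel_size - pixel_size / 2
  ), class = "orientation_field")
}

#' Curvature map of an orientation field
#'
#' Curvature is the magnitude of the spatial rate of change of the local
#' orientation, `k = |grad theta|`, computed on the window grid by centered
#' differences with nematic unwrapping (every pairwise angle difference is
#' mapped to `(-pi/2, pi/2]`) and expressed in um^-1 (rad treated as
#' dimensionless). Undefined (NA) wherever any stencil neighbor is invalid.
#'
#' @param field An [orientation_field()].
#' @return A `curvature_map`: list with matrix `k` (um^-1, NA where
#'   undefined) and `spacing_um`.
#' @export
curvature_map <- function(field) {
  stopifnot(inherits(field, "orientation_field"))
  th <- field$theta
  ok <- field$valid
  H <- nrow(th); W <- ncol(th)
  k <- matrix(NA_real_, H, W)
  if (H >= 3 && W >= 3) {
    i <- 2:(H - 1); j <- 2:(W - 1)
    dx <- wrap_nematic(th[i, j + 1] - th[i, j - 1]) / (2 * field$spacing_um)
    dy <- wrap_nematic(th[i + 1, j] - th[i - 1, j]) / (2 * field$spacing_um)
    def <- ok[i, j] & ok[i, j + 1] & ok[i, j - 1] & ok[i + 1, j] & ok[i - 1, j]
    kk <- sqrt(dx^2 + dy^2)
    kk[!def] <- NA_real_
    k[i, j] <- kk
  }
  if (!any(is.finite(k))) warning("curvature map is empty (no valid stencil)")
  structure(list(k = k, spacing_um = field$spacing_um),
            class = "curvature_map")
}

#' Mean curvature from an exponential fit to the curvature distribution
#'
#' The per-frame curvature values are modeled as exponentially distributed;
#' the characteristic scale (the maximum-likelihood estimate, i.e. the sample
#' mean) is reported as the frame's mean curvature `k`.
#'
#' @param cmap A [curvature_map()] (or a numeric vector of curvature samples).
#' @param min_samples Frames with fewer defined samples are skipped with a
#'   warning (default 50).
#' @return List with `k_um_inv`, `n`, `loglik`; `k_um_inv` is `NA` when the
#'   frame is skipped.
#' @export
fit_curvature_distribution <- function(cmap, min_samples = 50) {
  x <- if (inherits(cmap, "curvature_map")) as.vector(cmap$k) else cmap
  x <- x[is.finite(x)]
  if (length(x) < min_samples) {
    warning("too few curvature samples (", length(x), " < ", min_samples,
            "); frame skipped")
    return(list(k_um_inv = NA_real_, n = length(x), loglik = NA_real_))
  }
  m <- mean(x)
  list(k_um_inv = m, n = length(x),
       loglik = if (m > 0) sum(stats::dexp(x, rate = 1 / m, log = TRUE))
                else NA_real_)
}

#' Nematic spatial correlation of an orientation field
#'
#' `S(r)` is the mean of `cos(2 * (theta_i - theta_j))` over all pairs of
#' valid windows whose distance falls in each radial bin; the `r = 0` bin is
#' 1 by definition. The correlation length `rho` is the abscissa of the first
#' downward crossing of `S(r) = 0.5`, found by linear interpolation; when
#' `S` never crosses 0.5 within `r_max`, `rho = r_max` and the result is
#' flagged censored.
#'
#' @param field An [orientation_field()].
#' @param r_max Maximum pair distance (um); default half the smaller field
#'   extent.
#' @param bin Radial bin width (um); default one window spacing. Bin `b`
#'   covers `((b-1) bin, b bin]` and is centered at `(b - 0.5) bin`.
#' @param min_pairs Bins with fewer pairs are flagged unreliable (default 10).
#' @return A tibble of class `spatial_correlation` with columns `r_um`, `S`,
#'   `n_pairs`, `reliable`, and attributes `rho_um`, `censored`.
#' @export
spatial_correlation <- function(field, r_max = NULL, bin = NULL,
                                min_pairs = 10) {
  stopifnot(inherits(field, "orientation_field"))
  bin <- bin %||% field$spacing_um
  ext <- c(max(field$x_um) - min(field$x_um),
           max(field$y_um) - min(field$y_um))
  r_max <- r_max %||% (min(ext) / 2)
  idx <- which(field$valid, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 100) warning("only ", n, " valid windows; S(r) may be unreliable")
  if (n < 2) stop("spatial correlation needs at least 2 valid windows")
  x <- field$x_um[idx[, 2]]; y <- field$y_um[idx[, 1]]
  th <- field$theta[idx]
  dx <- outer(x, x, `-`); dy <- outer(y, y, `-`)
  dth <- outer(th, th, `-`)
  up <- upper.tri(dx)
  r <- sqrt(dx[up]^2 + dy[up]^2)
  cc <- cos(2 * dth[up])
  keep <- r <= r_max & r > 0
  b <- ceiling(r[keep] / bin)
  nb <- max(b)
  S <- vapply(seq_len(nb), function(i) mean(cc[keep][b == i]), numeric(1))
  np <- tabulate(b, nbins = nb)
  out <- tibble::tibble(
    r_um = c(0, (seq_len(nb) - 0.5) * bin),
    S = c(1, S),
    n_pairs = c(n, np),
    reliable = c(TRUE, np >= min_pairs))
  cross <- crossing_point(out$r_um, out$S, level = 0.5)
  attr(out, "rho_um") <- if (is.na(cross)) r_max else cross
  attr(out, "censored") <- is.na(cross)
  class(out) <- c("spatial_correlation", class(out))
  out
}

# First downward crossing of `level` by linear interpolation along (x, y).
crossing_point <- function(x, y, level) {
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  for (i in seq_len(length(y) - 1)) {
    if (y[i] >= level && y[i + 1] < level) {
      return(x[i] + (y[i] - level) / (y[i] - y[i + 1]) * (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

#' Restrict an orientation field to segmented foreground
#'
#' Marks windows invalid unless at least `min_frac` of their pixels belong
#' to the foreground mask. Background windows carry gradient structure from
#' noise and bundle tails, not filament orientation; restricting curvature
#' and spatial-order statistics to segmented foreground removes that
#' contamination.
#'
#' @param field An [orientation_field()].
#' @param mask Logical foreground mask at pixel resolution (e.g. from
#'   [adaptive_threshold()] + [despeckle()]).
#' @param min_frac Minimum foreground fraction per window (default 0.2).
#' @return The field with its `valid` matrix updated.
#' @export
restrict_to_foreground <- function(field, mask, min_frac = 0.2) {
  stopifnot(inherits(field, "orientation_field"), is.matrix(mask))
  w <- field$window_px
  frac <- block_sum(mask * 1, w) / w^2
  bh <- nrow(field$theta); bw <- ncol(field$theta)
  field$valid <- field$valid & (frac[seq_len(bh), seq_len(bw)] >= min_frac)
  field
}

#' Architecture time series: curvature and spatial order
#'
#' Per frame of the (normalized) movie: orientation field (restricted to
#' segmented foreground windows by default), exponential fit of
#' the curvature distribution, and nematic spatial correlation with its
#' correlation length. Steady-state values `k_ss` and `rho_ss` average the
#' same window as [width_series()].
#'
#' @param mv A [movie()].
#' @param config An [analysis_config()].
#' @param r_max,bin Passed to [spatial_correlation()].
#' @return Tibble of class `architecture_series` with columns `frame`,
#'   `time_s`, `k_um_inv`, `n_curv`, `rho_um`, `rho_censored`; attributes
#'   `k_ss_um_inv`, `rho_ss_um`, `ss_frames`.
#' @export
architecture_series <- function(mv, config = analysis_config(),
                                r_max = NULL, bin = NULL) {
  stopifnot(inherits(mv, "filnet_movie"))
  nm <- normalize_intensity(mv)
  times <- frame_times(nm)
  rows <- purrr::map(seq_len(n_frames(nm)), function(t) {
    of <- orientation_field(nm$frames[, , t],
                            window = config$orientation_window,
                            pixel_size = nm$pixel_size,
                            smooth_sigma = config$orientation_sigma,
                            tensor_sigma = config$tensor_sigma,
                            coherence_min = config$coherence_min,
                            energy_floor = config$energy_floor,
                            energy_rel = config$energy_rel)
    if (config$foreground_only) {
      mask <- segment_frame(nm$frames[, , t], config)
      of <- restrict_to_foreground(of, mask, config$foreground_min_frac)
    }
    kf <- fit_curvature_distribution(curvature_map(of))
    sc <- spatial_correlation(of, r_max = r_max, bin = bin)
    tibble::tibble(frame = t - 1L, time_s = times[t],
                   k_um_inv = kf$k_um_inv, n_curv = kf$n,
                   rho_um = attr(sc, "rho_um"),
                   rho_censored = attr(sc, "censored"))
  })
  out <- dplyr::bind_rows(rows)
  sel <- steady_frames(times, config)
  attr(out, "k_ss_um_inv") <- mean(out$k_um_inv[sel], na.rm = TRUE)
  attr(out, "rho_ss_um") <- mean(out$rho_um[sel], na.rm = TRUE)
  attr(out, "ss_frames") <- sel
  class(out) <- c("architecture_series", class(out))
  out
}

#' @export
autoplot.spatial_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_um, y = .data$S)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$reliable),
                        show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = attr(object, "rho_um"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(r ~ (mu * m)), y = "S(r)",
                  title = sprintf("Spatial order (rho = %.2f um%s)",
                                  attr(object, "rho_um"),
                                  if (attr(object, "censored"))
                                    ", censored" else "")) +
    ggplot2::theme_minimal()
}
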