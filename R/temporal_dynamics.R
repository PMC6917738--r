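#' Temporal image autocorrelation
#'
#' Quantifies network reorganization: each frame is reduced to its grid of
#' non-overlapping `block x block` pixel means, and for every lag `l` the
#' Pearson correlation between the block grids of all frame pairs `(t, t+l)`
#' is averaged. `Theta(0) = 1` by definition. Pairs involving a zero-variance
#' frame are skipped with a warning. Because it is built on Pearson
#' correlations, Theta is invariant under per-stack affine intensity
#' rescaling.
#'
#' @param mv A [movie()].
#' @param block Block size in px (default 3).
#' @param max_lag Maximum lag in frames (default `min(T - 2, 40)`); requires
#'   `T >= max_lag + 2`.
#' @return Tibble of class `temporal_autocorr` with columns `lag_s`, `theta`,
#'   `n_pairs`, and attribute `frame_interval`.
#' @export
temporal_autocorrelation <- function(mv, block = 3L, max_lag = NULL) {
  stopifnot(inherits(mv, "filnet_movie"))
  T <- n_frames(mv)
  max_lag <- max_lag %||% min(T - 2L, 40L)
  if (T < max_lag + 2) stop("movie too short: need T >= max_lag + 2")
  grids <- lapply(seq_len(T), function(t)
    as.vector(block_sum(mv$frames[, , t], block)) / block^2)
  sds <- vapply(grids, stats::sd, numeric(1))
  if (any(sds == 0)) warning("zero-variance frame(s) skipped: ",
                             paste(which(sds == 0), collapse = ", "))
  rows <- purrr::map(seq_len(max_lag), function(l) {
    ts <- seq_len(T - l)
    ok <- sds[ts] > 0 & sds[ts + l] > 0
    cors <- vapply(ts[ok], function(t) stats::cor(grids[[t]], grids[[t + l]]),
                   numeric(1))
    tibble::tibble(lag_s = l * mv$frame_interval,
                   theta = mean(cors), n_pairs = sum(ok))
  })
  out <- dplyr::bind_rows(
    tibble::tibble(lag_s = 0, theta = 1, n_pairs = T), rows)
  attr(out, "frame_interval") <- mv$frame_interval
  class(out) <- c("temporal_autocorr", class(out))
  out
}

#' Correlation time from a mono-exponential decay fit
#'
#' Fits `Theta(dt) = exp(-lambda dt)` by least squares (anchored at
#' `Theta(0) = 1`, no offset term) and reports the half-time
#' `tau = ln(2) / lambda`. When the fitted decay rate is not positive the
#' result is censored at the maximum lag.
#'
#' @param curve A [temporal_autocorrelation()] result, or any data frame with
#'   columns `lag_s` and `theta` (at least 4 lag points).
#' @return List of class `correlation_time`: `tau_s`, `lambda_per_s`,
#'   `censored`, `rss`.
#' @export
correlation_time <- function(curve) {
  stopifnot(all(c("lag_s", "theta") %in% names(curve)))
  lag <- curve$lag_s; th <- curve$theta
  ok <- is.finite(th)
  lag <- lag[ok]; th <- th[ok]
  if (length(lag) < 4) stop("correlation_time needs at least 4 lag points")
  obj <- function(lam) sum((th - exp(-lam * lag))^2)
  # coarse scan then local refinement; lambda = 0 included to detect
  # non-decaying curves
  span <- max(lag)
  lams <- c(0, exp(seq(log(1e-4 / span), log(200 / span), length.out = 60)))
  vals <- vapply(lams, obj, numeric(1))
  i <- which.min(vals)
  lo <- lams[max(1, i - 1)]; hi <- lams[min(length(lams), i + 1)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
  lam <- opt$minimum
  censored <- lam <= 1e-4 / span
  list2 <- structure(list(
    tau_s = if (censored) max(lag) else log(2) / lam,
    lambda_per_s = if (censored) 0 else lam,
    censored = censored, rss = opt$objective
  ), class = "correlation_time")
  list2
}

#' @export
print.correlation_time <- function(x, ...) {
  cat(sprintf("correlation time tau = %.4g s%s (lambda = %.4g /s)\n",
              x$tau_s, if (x$censored) " [censored]" else "",
              x$lambda_per_s))
  invisible(x)
}

#' @export
autoplot.temporal_autocorr <- function(object, ...) {
  ct <- correlation_time(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$theta)) +
    ggplot2::geom_point() +
    ggplot2::stat_function(fun = function(t) exp(-ct$lambda_per_s * t),
                           colour = "grey40") +
    ggplot2::labs(x = expression(Delta * t ~ (s)),
                  y = expression(Theta(Delta * t)),
                  title = sprintf("Temporal autocorrelation (tau = %.3g s%s)",
                                  ct$tau_s,
                                  if (ct$censored) ", censored" else "")) +
    ggplot2::theme_minimal()
}
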