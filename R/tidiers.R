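#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Hill fit
#'
#' @param x A [fit_hill()] result.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, and bootstrap CI
#'   bounds where available.
#' @export
tidy.hill_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("y0", "ymax", "n_h", "ec50_um"),
    estimate = c(x$y0, x$ymax, x$n_h, x$ec50_um),
    conf.low = NA_real_, conf.high = NA_real_)
  if (!is.null(x$ci)) {
    out$conf.low[3:4] <- c(x$ci$n_h[1], x$ci$ec50_um[1])
    out$conf.high[3:4] <- c(x$ci$n_h[2], x$ci$ec50_um[2])
  }
  out
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, n_obs = x$n_obs, fittable = x$fittable,
                 n_boot = if (is.null(x$ci)) NA_integer_ else x$ci$n_boot)
}

#' Tidy a FRAP fit
#'
#' @param x A [fit_frap()] result.
#' @param ... Unused.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b_per_s", "half_time_s"),
                 estimate = c(x$a, x$b_per_s, x$half_time_s))
}

#' @rdname tidy.frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, n = x$n)
}

#' Tidy a lifetime fit
#'
#' @param x A [lifetime_fit()] result.
#' @param ... Unused.
#' @export
tidy.lifetime_fit <- function(x, ...) {
  tibble::tibble(term = c("mean_lifetime_s", "k_obs_per_s"),
                 estimate = c(x$mean_lifetime_s, x$k_obs_per_s))
}

#' @rdname tidy.lifetime_fit
#' @export
glance.lifetime_fit <- function(x, ...) {
  tibble::tibble(n = x$n, interval_s = x$interval_s,
                 truncation_s = x$truncation_s,
                 low_confidence = x$low_confidence)
}

#' Tidy velocity statistics
#'
#' @param x A [track_velocities()] result.
#' @param ... Unused.
#' @export
tidy.velocity_stats <- function(x, ...) x$by_channel

#' @rdname tidy.velocity_stats
#' @export
glance.velocity_stats <- function(x, ...) {
  tibble::tibble(n_tracks = sum(x$by_channel$n_tracks),
                 n_channels = nrow(x$by_channel))
}
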