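#' Kymograph along a polyline path
#'
#' Samples the movie's intensity along a user-supplied polyline (e.g. drawn
#' along a treadmilling bundle) for every frame, averaging over a band of
#' `width_um` perpendicular to the path. In the resulting position-time
#' image, treadmilling ends appear as diagonal ridges whose slope is the
#' treadmilling velocity.
#'
#' @param mv A [movie()] (or a `differential_movie`; then `channel` selects
#'   `"growth"` or `"shrink"`).
#' @param path_xy Two-column matrix or data frame of polyline vertices
#'   (x_um, y_um).
#' @param width_um Averaging band width perpendicular to the path (um).
#' @param step_um Sampling step along the path (default one pixel).
#' @param channel Channel for differential movies.
#' @return Tibble of class `kymograph` with columns `s_um` (arc length),
#'   `frame`, `time_s`, `intensity`; use `autoplot()` to render it, or
#'   write it as CSV.
#' @export
kymograph <- function(mv, path_xy, width_um = 0.324, step_um = NULL,
                      channel = c("growth", "shrink")) {
  if (inherits(mv, "differential_movie")) {
    channel <- match.arg(channel)
    frames <- mv[[if (channel == "growth") "growth" else "shrink"]]
    ps <- mv$pixel_size; fi <- mv$frame_interval; ot <- mv$origin_time
  } else {
    stopifnot(inherits(mv, "filnet_movie"))
    frames <- mv$frames; ps <- mv$pixel_size; fi <- mv$frame_interval
    ot <- mv$origin_time
  }
  path_xy <- as.matrix(path_xy)
  stopifnot(ncol(path_xy) == 2, nrow(path_xy) >= 2)
  step_um <- step_um %||% ps
  # resample the polyline at constant arc length and get unit normals
  seg <- diff(path_xy)
  seg_len <- sqrt(rowSums(seg^2))
  s_knots <- c(0, cumsum(seg_len))
  s <- seq(0, s_knots[length(s_knots)], by = step_um)
  px <- stats::approx(s_knots, path_xy[, 1], s)$y
  py <- stats::approx(s_knots, path_xy[, 2], s)$y
  tx <- c(diff(px), utils::tail(diff(px), 1))
  ty <- c(diff(py), utils::tail(diff(py), 1))
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nx <- -ty / tl; ny <- tx / tl
  offs <- seq(-width_um / 2, width_um / 2, by = ps)
  H <- dim(frames)[1]; W <- dim(frames)[2]; T <- dim(frames)[3]
  # nearest-pixel sampling over the band
  idx <- lapply(offs, function(o) {
    i <- round((py + o * ny) / ps) + 1
    j <- round((px + o * nx) / ps) + 1
    ok <- i >= 1 & i <= H & j >= 1 & j <= W
    list(i = i, j = j, ok = ok)
  })
  rows <- purrr::map(seq_len(T), function(t) {
    fr <- frames[, , t]
    acc <- numeric(length(s)); cnt <- numeric(length(s))
    for (b in idx) {
      v <- rep(NA_real_, length(s))
      v[b$ok] <- fr[cbind(b$i[b$ok], b$j[b$ok])]
      acc <- acc + ifelse(is.na(v), 0, v)
      cnt <- cnt + !is.na(v)
    }
    tibble::tibble(s_um = s, frame = t - 1L, time_s = ot + (t - 1) * fi,
                   intensity = ifelse(cnt > 0, acc / cnt, NA_real_))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kymograph", class(out))
  out
}

#' @export
autoplot.kymograph <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$s_um,
                                       fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "counts") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "position along path (um)",
                  title = "Kymograph") +
    ggplot2::theme_minimal()
}
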