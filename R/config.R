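#' Analysis configuration
#'
#' Collects every tunable parameter of the analysis stages with its default.
#' The object is a named list; [write_config()] / [read_config()] round-trip
#' it through a JSON document.
#'
#' @param ... Named overrides of the defaults listed below.
#'
#' @details Defaults (units in parentheses):
#' \describe{
#'   \item{threshold_window}{adaptive-threshold neighborhood (px), 20}
#'   \item{min_peak_px}{EDM peaks strictly below this are dropped (px), 0
#'     (i.e. single-pixel peaks of value 1 are retained)}
#'   \item{orientation_window}{structure-tensor window (px), 4}
#'   \item{orientation_sigma}{pre-gradient Gaussian smoothing (px), 1}
#'   \item{tensor_sigma}{structure-tensor grid smoothing (windows), 1}
#'   \item{coherence_min}{windows below this coherence are invalid, 0.1}
#'   \item{energy_rel}{windows below this fraction of the frame's mean
#'     window energy are invalid, 0.25}
#'   \item{foreground_only}{restrict curvature and S(r) statistics to
#'     windows overlapping the segmentation mask, TRUE}
#'   \item{foreground_min_frac}{minimum foreground pixel fraction of a
#'     window under `foreground_only`, 0.2}
#'   \item{energy_floor}{windows with total gradient energy at or below this
#'     are invalid, 0}
#'   \item{autocorr_block}{block size for temporal autocorrelation (px), 3}
#'   \item{autocorr_max_lag}{maximum lag (frames), NULL = min(T - 2, 40)}
#'   \item{diff_sigma_xy, diff_sigma_t}{spatiotemporal low-pass of the
#'     differential movie (px, frames), 1 and 1}
#'   \item{spot_diameter}{blob detection scale (um), 0.5}
#'   \item{quality_percentile}{spot quality cut (percentile), 90}
#'   \item{link_max}{maximum linking / gap-closing displacement (um), 0.5}
#'   \item{gap_max}{maximum gap closed (frames), 2}
#'   \item{min_track_len}{minimum track length for velocity stats (frames), 4}
#'   \item{dircorr_min_step_um}{steps below this noise floor are excluded from
#'     directional autocorrelation (um), 0.054 (= 0.5 px at 0.108 um/px)}
#'   \item{ss_window_min}{steady-state averaging window (min of
#'     origin-referenced time), c(15, 20); when the movie does not reach it,
#'     the last 25 percent of frames are used instead}
#'   \item{n_boot}{bootstrap iterations for Hill CIs, 1000}
#'   \item{seed}{RNG seed used by stochastic stages, 1}
#' }
#' @return A named list of class `filnet_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    threshold_window = 20L,
    min_peak_px = 0,
    orientation_window = 4L,
    orientation_sigma = 1,
    tensor_sigma = 1,
    coherence_min = 0.1,
    energy_floor = 0,
    energy_rel = 0.25,
    foreground_only = TRUE,
    foreground_min_frac = 0.2,
    autocorr_block = 3L,
    autocorr_max_lag = NULL,
    diff_sigma_xy = 1,
    diff_sigma_t = 1,
    spot_diameter = 0.5,
    quality_percentile = 90,
    link_max = 0.5,
    gap_max = 2L,
    min_track_len = 4L,
    dircorr_min_step_um = 0.054,
    ss_window_min = c(15, 20),
    n_boot = 1000L,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "filnet_config"))
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(threshold_window >= 3, orientation_window >= 1,
              orientation_sigma >= 0, coherence_min >= 0, coherence_min <= 1,
              autocorr_block >= 1, spot_diameter > 0,
              quality_percentile >= 0, quality_percentile <= 100,
              link_max > 0, gap_max >= 0, min_track_len >= 1,
              length(ss_window_min) == 2, ss_window_min[1] < ss_window_min[2],
              n_boot >= 1)
  })
  cfg
}

#' @rdname analysis_config
#' @param cfg A `filnet_config`.
#' @param path File path of the JSON config document.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$autocorr_max_lag) && length(raw$autocorr_max_lag) == 0)
    raw$autocorr_max_lag <- NULL
  do.call(analysis_config, raw)
}

# Steady-state frame selection shared by width and architecture series:
# frames whose origin-referenced time falls in cfg$ss_window_min, or the last
# 25% of frames when fewer than 2 frames fall there.
steady_frames <- function(times_s, cfg) {
  win <- cfg$ss_window_min * 60
  sel <- which(times_s >= win[1] & times_s <= win[2])
  if (length(sel) < 2) {
    n <- length(times_s)
    sel <- seq.int(max(1L, n - ceiling(n / 4) + 1L), n)
  }
  sel
}
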