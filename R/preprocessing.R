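#' Normalize a movie to constant overall intensity
#'
#' Rescales every frame so that its mean equals the mean of the whole stack,
#' compensating for the slow intensity increase caused by ongoing protein
#' binding to the membrane. Within-frame contrast is preserved (each frame is
#' multiplied by a single factor).
#'
#' @param mv A [movie()]; every frame must have mean > 0.
#' @return A [movie()] with constant frame means.
#' @export
normalize_intensity <- function(mv) {
  stopifnot(inherits(mv, "filnet_movie"))
  means <- apply(mv$frames, 3, mean)
  if (any(means == 0))
    stop("cannot normalize: frame(s) with zero mean intensity: ",
         paste(which(means == 0), collapse = ", "))
  target <- mean(mv$frames)
  out <- sweep(mv$frames, 3, target / means, `*`)
  movie(out, mv$pixel_size, mv$frame_interval, mv$origin_time)
}

#' Adaptive (local-mean) threshold
#'
#' A pixel is foreground iff its value is strictly greater than the mean
#' intensity of the `window x window` neighborhood centered on it, with no
#' further offset. Neighborhoods are truncated at the image borders (the mean
#' is taken over the in-image part of the window), so constant regions never
#' segment and the result is invariant under affine intensity rescaling with
#' positive gain.
#'
#' @param frame Numeric matrix (one movie frame).
#' @param window Neighborhood size in pixels (default 20, roughly three bundle
#'   widths at 0.108 um/px); must be >= 3 and no larger than the image.
#' @return Logical `H x W` mask, `TRUE` = foreground.
#' @export
adaptive_threshold <- function(frame, window = 20L) {
  stopifnot(is.matrix(frame))
  if (window < 3) stop("threshold window must be >= 3 px")
  if (window > min(dim(frame)))
    stop("threshold window (", window, " px) larger than image")
  # strict inequality up to floating-point rounding of the window means,
  # so exactly constant regions never segment
  tol <- 1e-9 * (max(frame) - min(frame) + 1)
  frame > local_mean(frame, window) + tol
}

#' Despeckle (3x3 median) filter
#'
#' Removes isolated bright or dark single pixels while preserving solid
#' shapes of at least 2 px extent exactly. Borders are handled by edge
#' replication. Logical masks stay logical.
#'
#' @param x Numeric or logical matrix.
#' @return Filtered matrix of the same type.
#' @export
despeckle <- function(x) {
  stopifnot(is.matrix(x))
  logical_in <- is.logical(x)
  out <- median3x3(x * 1)
  if (logical_in) out > 0.5 else out
}

# Shared per-frame segmentation: normalize is applied at the movie level by
# callers; this runs threshold -> despeckle on one frame.
segment_frame <- function(frame, cfg) {
  despeckle(adaptive_threshold(frame, cfg$threshold_window))
}
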