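#' Calibrated time-lapse movie
#'
#' A `filnet_movie` bundles a grayscale image stack with its spatial and
#' temporal calibration. Frames are stored as an `H x W x T` numeric array of
#' non-negative intensities (camera counts or photons). Pixel coordinates are
#' 0-based with x rightward (columns) and y downward (rows); positions are
#' reported in micrometers from the top-left pixel center, and frame `t`
#' (0-based) maps to time `origin_time + t * frame_interval` seconds.
#'
#' @param frames Numeric `H x W x T` array (a matrix is treated as `T = 1`).
#'   All values must be finite and `>= 0`; `H` and `W` must be at least 2.
#' @param pixel_size Pixel size in micrometers per pixel (default 0.108, the
#'   calibration of a 100x TIRF objective on a 512 x 512 EMCCD).
#' @param frame_interval Time between frames in seconds (default 2).
#' @param origin_time Time of the first frame in seconds relative to the start
#'   of the experiment (default 0).
#'
#' @return A `filnet_movie` object.
#' @examples
#' mv <- movie(array(runif(32 * 32 * 4), c(32, 32, 4)), pixel_size = 0.1,
#'             frame_interval = 1)
#' n_frames(mv)
#' frame_times(mv)
#' @export
movie <- function(frames, pixel_size = 0.108, frame_interval = 2,
                  origin_time = 0) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  d <- dim(frames)
  if (d[1] < 2 || d[2] < 2 || d[3] < 1)
    stop("movie frames must be at least 2 x 2 pixels and 1 frame")
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("movie intensities must be finite and non-negative")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  storage.mode(frames) <- "double"
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, origin_time = origin_time),
    class = "filnet_movie"
  )
}

#' @rdname movie
#' @param x A `filnet_movie`.
#' @export
n_frames <- function(x) dim(x$frames)[3]

#' @rdname movie
#' @export
frame_times <- function(x) {
  x$origin_time + (seq_len(n_frames(x)) - 1) * x$frame_interval
}

#' @export
print.filnet_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<filnet_movie> %d x %d px, %d frames | %.4g um/px, %.4g s/frame, t0 = %.4g s\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval, x$origin_time))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.[Tt][Ii][Ff]{1,2}$", "", path) |> paste0(".json")
}

#' Read a calibrated movie from a multi-page TIFF
#'
#' Reads an 8- or 16-bit grayscale multi-page TIFF plus its calibration. The
#' calibration is looked up, in order of precedence, from the explicit
#' arguments, from a sidecar JSON (same path with extension `.json`, fields
#' `pixel_size_um`, `frame_interval_s`, `origin_time_s`, `intensity_scale`),
#' and finally from the defaults (0.108 um/px, 2 s/frame) with a warning.
#'
#' @param path Path to a multi-page TIFF file.
#' @param pixel_size,frame_interval,origin_time Optional explicit calibration
#'   overriding the sidecar.
#' @return A [movie()].
#' @seealso [write_movie()]
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL,
                       origin_time = NULL) {
  if (!file.exists(path)) stop("cannot read movie: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) == 3, logical(1))))
    stop("unsupported format: RGB or multi-channel TIFF pages; ",
         "filnet movies must be single-channel grayscale")
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16
  frames <- vapply(pages, function(p) round(p * (2^bits - 1)),
                   matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))

  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  scale <- meta$intensity_scale %||% 1
  frames <- frames / scale
  ps <- pixel_size %||% meta$pixel_size_um
  fi <- frame_interval %||% meta$frame_interval_s
  ot <- origin_time %||% meta$origin_time_s %||% 0
  if (is.null(ps) || is.null(fi)) {
    warning("no calibration supplied or found in sidecar; ",
            "using defaults 0.108 um/px and 2 s/frame")
    ps <- ps %||% 0.108
    fi <- fi %||% 2
  }
  movie(frames, pixel_size = ps, frame_interval = fi, origin_time = ot)
}

#' Write a movie as a 16-bit multi-page TIFF with sidecar metadata
#'
#' Integer movies with a maximum of at most 65535 are written losslessly.
#' Other movies are rescaled to the 16-bit range; the applied scale factor is
#' recorded in the sidecar (`intensity_scale`) so that [read_movie()] can
#' reverse it to within one part in 2^16.
#'
#' @param mv A [movie()].
#' @param path Output TIFF path; the sidecar JSON is written next to it.
#' @return `path`, invisibly.
#' @export
write_movie <- function(mv, path) {
  stopifnot(inherits(mv, "filnet_movie"))
  f <- mv$frames
  mx <- max(f)
  lossless <- mx <= 65535 && all(f == round(f))
  scale <- if (lossless) 1 else if (mx > 0) 65535 / mx else 1
  pages <- lapply(seq_len(dim(f)[3]),
                  function(t) pmin(f[, , t] * scale, 65535) / 65535)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) stop("cannot write movie to ", path,
                                          ": ", conditionMessage(e)))
  jsonlite::write_json(
    list(pixel_size_um = mv$pixel_size, frame_interval_s = mv$frame_interval,
         origin_time_s = mv$origin_time, intensity_scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
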