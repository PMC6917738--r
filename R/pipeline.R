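#' Run the full analysis pipeline on a movie
#'
#' Executes the requested stages and writes one CSV per stage plus a JSON of
#' scalar summaries. Outputs are deterministic given `config$seed`. A failing
#' stage aborts with the stage name and cause, and the partially written
#' output directory is cleaned of this run's files.
#'
#' @param mv A [movie()].
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("width", "architecture", "temporal", "treadmilling")`.
#' @return Invisibly, a list with the per-stage results and the `summary`
#'   list written to `summary.json`.
#' @export
run_pipeline <- function(mv, config = analysis_config(), out_dir = ".",
                         stages = c("width", "architecture", "temporal",
                                    "treadmilling")) {
  stopifnot(inherits(mv, "filnet_movie"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  results <- list()
  summary <- list(seed = config$seed)
  set.seed(config$seed)

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      file.remove(written[file.exists(written)])
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }

  if ("width" %in% stages) run_stage("width", function() {
    ws <- width_series(mv, config)
    emit(as.data.frame(ws), "width.csv")
    results$width <<- ws
    summary$width_ss_um <<- attr(ws, "width_ss_um")
  })
  if ("architecture" %in% stages) run_stage("architecture", function() {
    as <- architecture_series(mv, config)
    emit(as.data.frame(as), "architecture.csv")
    results$architecture <<- as
    summary$k_ss_um_inv <<- attr(as, "k_ss_um_inv")
    summary$rho_ss_um <<- attr(as, "rho_ss_um")
  })
  if ("temporal" %in% stages) run_stage("temporal", function() {
    ac <- temporal_autocorrelation(normalize_intensity(mv),
                                   block = config$autocorr_block,
                                   max_lag = config$autocorr_max_lag)
    ct <- correlation_time(ac)
    emit(as.data.frame(ac), "autocorr.csv")
    results$temporal <<- list(curve = ac, fit = ct)
    summary$tau_s <<- ct$tau_s
    summary$tau_censored <<- ct$censored
  })
  if ("treadmilling" %in% stages) run_stage("treadmilling", function() {
    dm <- differential_movie(mv, config$diff_sigma_xy, config$diff_sigma_t)
    spots <- detect_spots(dm, diameter = config$spot_diameter,
                          quality_percentile = config$quality_percentile)
    tracks <- link_trajectories(spots, config$link_max, config$gap_max,
                                config$min_track_len)
    vel <- track_velocities(tracks, mv$frame_interval, config$min_track_len)
    dc <- directional_autocorrelation(tracks, mv$frame_interval,
                                      min_step_um = config$dircorr_min_step_um)
    emit(as.data.frame(spots), "spots.csv")
    emit(as.data.frame(tracks), "tracks.csv")
    emit(as.data.frame(vel$per_track), "velocities.csv")
    emit(as.data.frame(dc), "dircorr.csv")
    results$treadmilling <<- list(spots = spots, tracks = tracks,
                                  velocities = vel, dircorr = dc)
    for (ch in vel$by_channel$channel) {
      row <- vel$by_channel[vel$by_channel$channel == ch, ]
      summary[[paste0("nu_", ifelse(ch == "growth", "plus", "minus"),
                      "_nm_s")]] <<- row$mean_nm_s
    }
  })

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(results, list(summary = summary)))
}
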