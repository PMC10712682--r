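#' Write / read a frame log as delimited text
#'
#' Format: CSV with header `t,r0c0,r0c1,...` (active units only), one row
#' per frame. The sampling rate is recovered from the timestamps on read.
#'
#' @param log A `frame_log`.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_frame_log` returns a `frame_log`.
#' @export
write_frame_log <- function(log, path) {
  df <- data.frame(t = log$t, log$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_log
#' @export
read_frame_log <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "t" || ncol(df) < 2) stop("not a frame log: ", path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  fs <- 1 / stats::median(diff(df$t))
  frame_log(df$t, counts, round(fs, 6))
}

#' Write / read a vertical GRF trace
#'
#' @param grf Data.frame with `t` and `Fz`.
#' @param path CSV path.
#' @return `path` invisibly; the reader returns the data.frame.
#' @export
write_grf <- function(grf, path) {
  utils::write.csv(grf[, c("t", "Fz")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grf
#' @export
read_grf <- function(path) utils::read.csv(path)

#' Write / read per-cycle event tables
#'
#' Used for both ground-truth events and detection output (the latter also
#' carries phase durations and a status column).
#'
#' @param events Data.frame of per-cycle events.
#' @param path CSV path.
#' @return `path` invisibly; the reader returns the data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) utils::read.csv(path)

#' Write a synthetic trial bundle to a directory
#'
#' Writes `frames.csv`, `grf.csv`, `truth.csv` and `config.json` (the
#' configuration snapshot, including the seed) into `dir`.
#'
#' @param trial A `synth_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frame_log(trial$frames, file.path(dir, "frames.csv"))
  write_grf(trial$grf, file.path(dir, "grf.csv"))
  write_events(trial$truth, file.path(dir, "truth.csv"))
  cfg <- trial$config
  cfg_list <- unclass(cfg)
  cfg_list$schema <- "insoleGait/trial-config/1"
  cfg_list$baseline_s <- trial$baseline_s
  jsonlite::write_json(cfg_list, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic trial bundle from a directory
#'
#' @param dir Directory written by [write_trial()].
#' @param layout Layout to attach (defaults to the packaged insole layout).
#' @return A `synth_trial`-like list with `frames`, `grf`, `truth`,
#'   `baseline_s` and `config`.
#' @export
read_trial <- function(dir, layout = default_insole_layout()) {
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"))
  structure(list(
    frames = read_frame_log(file.path(dir, "frames.csv")),
    grf = read_grf(file.path(dir, "grf.csv")),
    truth = read_events(file.path(dir, "truth.csv")),
    baseline_s = cfgj$baseline_s %||% 0,
    layout = layout,
    config = cfgj
  ), class = "synth_trial")
}
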