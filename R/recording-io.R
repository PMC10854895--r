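#' Multichannel LFP recording container
#'
#' In-memory container for a continuous multichannel recording: a
#' channels x samples signal matrix (microvolts), the sampling rate, channel
#' labels laid out as a 4x4 grid, and a sorted event table mirroring the
#' behavioural timestamps.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate, samples/second.
#' @param channel_ids character vector of channel labels (default
#'   `ch01..ch16` on a 4x4 grid).
#' @param events data.frame with columns `time_s`, `label` and optionally
#'   `trial` (0-based global trial index).
#' @return An `lfp_recording` object.
#' @export
lfp_recording <- function(signal, fs, channel_ids = NULL, events = NULL) {
  signal <- as.matrix(signal)
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(nrow(signal)))
  if (length(channel_ids) != nrow(signal))
    stop("channel_ids length must match the channel count", call. = FALSE)
  if (is.null(events))
    events <- data.frame(time_s = numeric(0), label = character(0),
                         trial = integer(0))
  if (is.unsorted(events$time_s))
    events <- events[order(events$time_s), , drop = FALSE]
  rownames(signal) <- channel_ids
  structure(list(signal = signal, fs = fs, channel_ids = channel_ids,
                 events = events),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, nrow(x$events)))
  invisible(x)
}

#' Write / read a recording on disk
#'
#' The on-disk layout is a directory holding `signal.bin` (IEEE-754
#' little-endian doubles, channel-major), `meta.json` (`fs`, `n_channels`,
#' `n_samples`, `channel_ids`) and `events.csv`. The round trip is
#' bit-exact.
#'
#' @param rec an [lfp_recording()].
#' @param path directory to create/overwrite.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "lfp_recording")) stop("not an lfp_recording", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path, call. = FALSE)
  meta <- list(format = "twostepSR-lfp-v1", fs = rec$fs,
               n_channels = nrow(rec$signal), n_samples = ncol(rec$signal),
               channel_ids = rec$channel_ids)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(path, "signal.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$signal), con, size = 8L, endian = "little")
  ev <- rec$events
  ev$time_s <- sprintf("%.17g", ev$time_s)  # exact double round trip
  write.csv(ev, file.path(path, "events.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a recording directory (missing meta.json): ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs))
    stop("malformed recording: meta.json lacks fs", call. = FALSE)
  meta$fs <- as.numeric(meta$fs)  # type-stable regardless of JSON integerness
  n_ch <- meta$n_channels
  n_s <- meta$n_samples
  con <- file(file.path(path, "signal.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n_ch * n_s, size = 8L, endian = "little")
  if (length(x) != n_ch * n_s)
    stop("malformed recording: signal.bin truncated", call. = FALSE)
  ev <- read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  ev$time_s <- as.numeric(ev$time_s)
  lfp_recording(matrix(x, nrow = n_ch), meta$fs,
                channel_ids = meta$channel_ids, events = ev)
}
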