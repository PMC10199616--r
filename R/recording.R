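#' Multichannel recording container
#'
#' A `recording` holds a channels-by-time sample matrix in physical units
#' together with its sampling rate, ordered channel labels, optional
#' per-channel grid geometry (for MEA probes) and a unit string.
#'
#' @param samples numeric matrix, channels in rows, time in columns. A plain
#'   vector is treated as a single channel.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param channel_ids character vector of channel labels, one per row of
#'   `samples`. Defaults to `"ch1" ... "chN"`.
#' @param geometry optional data frame with columns `channel_id`, `row`,
#'   `col` giving grid coordinates (one row per channel, no duplicate
#'   coordinates), or `NULL`.
#' @param units unit string for the sample values, e.g. `"pA"` or `"uV"`.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(samples, rate_hz, channel_ids = NULL, geometry = NULL,
                      units = "uV") {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x time)")
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number")
  }
  n_ch <- nrow(samples)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(n_ch))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != n_ch) {
    stop("`channel_ids` must have one entry per channel")
  }
  if (anyDuplicated(channel_ids)) stop("duplicate channel ids")
  if (!is.null(geometry)) {
    geometry <- as.data.frame(geometry)
    need <- c("channel_id", "row", "col")
    if (!all(need %in% names(geometry))) {
      stop("`geometry` needs columns channel_id, row, col")
    }
    geometry$channel_id <- as.character(geometry$channel_id)
    if (!setequal(geometry$channel_id, channel_ids) ||
        nrow(geometry) != n_ch) {
      stop("`geometry` must describe exactly the recording's channels")
    }
    if (anyDuplicated(geometry[, c("row", "col")])) {
      stop("duplicate grid coordinates in `geometry`")
    }
    geometry <- geometry[match(channel_ids, geometry$channel_id), , drop = FALSE]
    rownames(geometry) <- NULL
  }
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         channel_ids = channel_ids, geometry = geometry,
         units = as.character(units)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.3f s), units %s\n",
              nrow(x$samples), ncol(x$samples), x$rate_hz,
              ncol(x$samples) / x$rate_hz, x$units))
  if (!is.null(x$geometry)) cat("  with grid geometry\n")
  invisible(x)
}

#' Number of channels / duration helpers
#' @param rec a [recording()].
#' @return `n_channels()` the channel count; `duration_s()` the duration in
#'   seconds.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname n_channels
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$rate_hz

#' Extract one channel as a single-channel recording
#' @param rec a [recording()].
#' @param channel_id label of the channel to keep.
#' @return a single-channel `recording`.
#' @export
get_channel <- function(rec, channel_id) {
  i <- match(channel_id, rec$channel_ids)
  if (is.na(i)) stop("unknown channel id: ", channel_id)
  recording(rec$samples[i, , drop = FALSE], rec$rate_hz,
            channel_ids = channel_id, geometry = NULL, units = rec$units)
}
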