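#' Read a flat-binary multichannel recording
#'
#' Reads the package's on-disk recording container: little-endian int16
#' samples interleaved by time point (`ch1[t1], ch2[t1], ..., ch1[t2], ...`),
#' with a plain-text `key=value` sidecar meta file carrying the channel
#' count, sampling rate, volts-per-bit scale, channel labels and optional
#' grid geometry. The dialect is modelled on common acquisition-software
#' flat-binary formats but is intentionally a small, self-describing subset.
#'
#' Required meta keys: `nChans`, `sampleRateHz`, `dtype` (must be `int16`),
#' `voltsPerBit` (physical units per integer count), `channelIds`
#' (comma-separated). Optional: `units`, `geometryRows`, `geometryCols`
#' (comma-separated, one per channel).
#'
#' @param path_bin path to the binary payload.
#' @param path_meta path to the sidecar meta file.
#' @return a [recording()] scaled to physical units.
#' @seealso [write_flat_binary()]
#' @export
read_flat_binary <- function(path_bin, path_meta) {
  if (!file.exists(path_meta)) stop("meta file not found: ", path_meta)
  if (!file.exists(path_bin)) stop("binary file not found: ", path_bin)
  meta <- read_meta_file(path_meta)
  need <- c("nChans", "sampleRateHz", "dtype", "voltsPerBit", "channelIds")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("meta file missing required key(s): ", paste(missing, collapse = ", "))
  }
  if (meta$dtype != "int16") stop("unsupported dtype: ", meta$dtype)
  n_ch <- as.integer(meta$nChans)
  rate <- as.numeric(meta$sampleRateHz)
  scale <- as.numeric(meta$voltsPerBit)
  ids <- strsplit(meta$channelIds, ",", fixed = TRUE)[[1]]
  if (is.na(n_ch) || n_ch < 1L) stop("meta nChans invalid")
  if (is.na(rate) || rate <= 0) stop("meta sampleRateHz invalid")
  if (length(ids) != n_ch) {
    stop("meta contradictory: channelIds count != nChans")
  }
  sz <- file.info(path_bin)$size
  if (sz %% 2L != 0L) stop("corrupt binary: odd byte count")
  n_vals <- sz / 2L
  if (n_vals %% n_ch != 0L) {
    stop("corrupt binary: value count ", n_vals,
         " not divisible by nChans ", n_ch)
  }
  n_t <- n_vals / n_ch
  raw <- readBin(path_bin, what = "integer", n = n_vals, size = 2L,
                 signed = TRUE, endian = "little")
  samples <- matrix(as.numeric(raw), nrow = n_ch) * scale
  geometry <- NULL
  if (!is.null(meta$geometryRows) && !is.null(meta$geometryCols)) {
    gr <- as.integer(strsplit(meta$geometryRows, ",", fixed = TRUE)[[1]])
    gc <- as.integer(strsplit(meta$geometryCols, ",", fixed = TRUE)[[1]])
    if (length(gr) != n_ch || length(gc) != n_ch) {
      stop("meta contradictory: geometry length != nChans")
    }
    geometry <- data.frame(channel_id = ids, row = gr, col = gc)
  }
  recording(samples, rate, channel_ids = ids, geometry = geometry,
            units = meta$units %||% "uV")
}

#' Write a recording as flat binary + meta
#'
#' Quantizes to int16 with a scale chosen so the largest absolute sample
#' maps near full range (or a user-given scale), and writes the sidecar
#' meta needed by [read_flat_binary()]. Round-trip error is bounded by
#' `scale / 2` per sample.
#'
#' @param rec a [recording()].
#' @param path_bin,path_meta output paths.
#' @param scale physical units per integer count; default chooses
#'   `max(abs(samples)) / 32000` (1 for an all-zero recording).
#' @return the scale used, invisibly.
#' @export
write_flat_binary <- function(rec, path_bin, path_meta, scale = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$samples) < 1L) stop("recording has no channels")
  if (!all(is.finite(rec$samples))) stop("non-finite samples cannot be written")
  if (is.null(scale)) {
    m <- max(abs(rec$samples))
    scale <- if (m == 0) 1 else m / 32000
  }
  q <- round(rec$samples / scale)
  if (max(abs(q)) > 32767) stop("scale too small for int16 range")
  writeBin(as.integer(q), path_bin, size = 2L, endian = "little")
  lines <- c(
    paste0("nChans=", nrow(rec$samples)),
    paste0("sampleRateHz=", format(rec$rate_hz, digits = 15)),
    "dtype=int16",
    paste0("voltsPerBit=", format(scale, digits = 15)),
    paste0("channelIds=", paste(rec$channel_ids, collapse = ",")),
    paste0("units=", rec$units)
  )
  if (!is.null(rec$geometry)) {
    lines <- c(lines,
      paste0("geometryRows=", paste(rec$geometry$row, collapse = ",")),
      paste0("geometryCols=", paste(rec$geometry$col, collapse = ",")))
  }
  writeLines(lines, path_meta)
  invisible(scale)
}

read_meta_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed meta line: ", lines[which(eq < 0)[1]])
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substring(lines, eq + 1L))
  if (anyDuplicated(keys)) stop("duplicate meta key: ", keys[duplicated(keys)][1])
  stats::setNames(as.list(vals), keys)
}

#' Read a behavioral-state epoch table
#'
#' CSV with header `start_s,end_s,state`; times in seconds, half-open
#' `[start, end)` intervals; states from `{idle, running}`. Rows are sorted
#' and validated: positive length, no overlap, known states.
#'
#' @param path CSV path.
#' @return data frame with columns `start_s`, `end_s`, `state`.
#' @export
read_epoch_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(tbl))) {
    stop("epoch table needs columns start_s,end_s,state")
  }
  validate_epochs(tbl[need])
}

validate_epochs <- function(tbl) {
  tbl$start_s <- as.numeric(tbl$start_s)
  tbl$end_s <- as.numeric(tbl$end_s)
  tbl$state <- as.character(tbl$state)
  bad <- setdiff(unique(tbl$state), c("idle", "running"))
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  if (any(tbl$end_s <= tbl$start_s)) stop("epoch with end_s <= start_s")
  tbl <- tbl[order(tbl$start_s), , drop = FALSE]
  if (nrow(tbl) > 1L &&
      any(tbl$start_s[-1L] < tbl$end_s[-nrow(tbl)])) {
    stop("overlapping epochs")
  }
  rownames(tbl) <- NULL
  tbl
}

#' Read a channel-group map
#'
#' CSV with header `group,channel_id`, mapping group labels (e.g.
#' `CA1_pyr`, `DG`) to channel ids. Groups may overlap. When `rec` is
#' given, every referenced channel must exist in it.
#'
#' @param path CSV path.
#' @param rec optional [recording()] against which channel ids are checked.
#' @return named list of character vectors of channel ids.
#' @export
read_channel_groups <- function(path, rec = NULL) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "channel_id") %in% names(tbl))) {
    stop("channel group table needs columns group,channel_id")
  }
  tbl$channel_id <- as.character(tbl$channel_id)
  if (!is.null(rec)) {
    unknown <- setdiff(tbl$channel_id, rec$channel_ids)
    if (length(unknown)) {
      stop("channel id(s) not in recording: ", paste(unknown, collapse = ", "))
    }
  }
  split(tbl$channel_id, tbl$group)
}

#' Write a result table as CSV
#'
#' Plain comma-separated UTF-8 with a mandatory header and no row names;
#' the writer used by all pipeline outputs so that repeated runs are
#' byte-identical.
#'
#' @param rows data frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a plain-text configuration file
#'
#' Minimal TOML-style syntax: `[section]` headers, `key = value` lines,
#' `#` comments. Values are parsed as numbers, `true`/`false`, bare or
#' quoted strings, or flat arrays `[v1, v2, ...]`. Every tunable detection
#' parameter in the pipeline can be supplied through such a file.
#'
#' @param path config file path.
#' @return nested named list: `config$section$key`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substring(ln, eq + 1L))
    out[[section]][[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (grepl("^\\[.*\\]$", val)) {
    parts <- trimws(strsplit(sub("^\\[(.*)\\]$", "\\1", val), ",")[[1]])
    return(unlist(lapply(parts, parse_config_value)))
  }
  if (grepl('^".*"$', val)) return(substr(val, 2L, nchar(val) - 1L))
  if (val %in% c("true", "false")) return(val == "true")
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}
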