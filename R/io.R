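#' Write a recording as interleaved int16 binary plus JSON sidecar
#'
#' Samples are interleaved across channels (frame-major), quantized to
#' signed 16-bit at a volts-per-LSB chosen to span the signal range, with
#' the sampling metadata in `<path>.json`.
#'
#' @param recording an [MEARecording-class].
#' @param path output path for the binary block (sidecar at
#'   `paste0(path, ".json")`).
#' @param voltsPerLSB quantization step; defaults to spanning the observed
#'   range with 10\% headroom.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path, voltsPerLSB = NULL) {
  sig <- recording@signal
  if (is.null(voltsPerLSB)) {
    peak <- max(abs(sig), 1e-12)
    voltsPerLSB <- 1.1 * peak / 32767
  }
  q <- round(t(sig) / voltsPerLSB)  # interleaved: channels fastest
  q <- pmax(pmin(q, 32767), -32768)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  meta <- list(sampling_rate_hz = recording@samplingRate,
               n_channels = ncol(sig),
               volts_per_lsb = voltsPerLSB,
               channel_ids = recording@channelIds,
               duration_s = nrow(sig) / recording@samplingRate)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an interleaved int16 recording written by [writeRecording()]
#'
#' @param path path of the binary block; the JSON sidecar must sit at
#'   `paste0(path, ".json")`.
#' @return an [MEARecording-class] in volts.
#' @export
readRecording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("sampling_rate_hz", "n_channels", "volts_per_lsb")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sidecar ", sidecar, " lacks field(s): ", paste(miss, collapse = ", "))
  nBytes <- file.info(path)$size
  n <- nBytes / 2L
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
  nCh <- meta$n_channels
  sig <- t(matrix(raw, nrow = nCh)) * meta$volts_per_lsb
  ids <- meta$channel_ids %||% sprintf("ch%02d", seq_len(nCh))
  colnames(sig) <- ids
  new("MEARecording", signal = sig, samplingRate = meta$sampling_rate_hz,
      channelIds = as.character(ids), metadata = list(source = path))
}

#' Spike-time table import/export
#'
#' The tidy long format used across the pipeline: one row per spike with
#' `device`, `session`, `channel`, `time_s` columns.
#'
#' @param trains a [SpikeTrains-class] (or list) to export, or a CSV path
#'   to import.
#' @param path output CSV path.
#' @param meta list with `device`, `session` used on export.
#' @return `writeSpikeCsv`: the path, invisibly.  `readSpikeCsv`: a named
#'   list of [SpikeTrains-class] objects, one per device x session.
#' @export
writeSpikeCsv <- function(trains, path, meta = list()) {
  tl <- if (is(trains, "SpikeTrains")) trains@trains else trains
  ids <- if (is(trains, "SpikeTrains")) trains@channelIds else
    sprintf("ch%02d", seq_along(tl))
  rows <- do.call(rbind, lapply(seq_along(tl), function(ch) {
    if (!length(tl[[ch]])) return(NULL)
    data.frame(device = meta$device %||% "device-01",
               session = meta$session %||% 0,
               channel = ids[ch], time_s = tl[[ch]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(device = character(), session = numeric(),
                       channel = character(), time_s = numeric())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpikeCsv
#' @param interval recording interval (start, end) in seconds for the
#'   imported trains; `NULL` takes (0, max time rounded up).
#' @param nChannels total channel count (so silent channels are retained);
#'   `NULL` keeps only the channels present in the file.
#' @export
readSpikeCsv <- function(trains, interval = NULL, nChannels = NULL) {
  path <- trains
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device", "session", "channel", "time_s")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("spike CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(interval))
    interval <- c(0, ceiling(max(tab$time_s, 0)))
  out <- list()
  for (key in unique(paste(tab$device, tab$session, sep = "@"))) {
    sub <- tab[paste(tab$device, tab$session, sep = "@") == key, ]
    ids <- if (is.null(nChannels)) sort(unique(sub$channel)) else
      sort(union(sprintf("ch%02d", seq_len(nChannels)), unique(sub$channel)))
    tl <- lapply(ids, function(ch) sort(sub$time_s[sub$channel == ch]))
    out[[key]] <- new("SpikeTrains", trains = tl, interval = interval,
                      channelIds = ids,
                      metadata = list(device = sub$device[1L],
                                      session = sub$session[1L]))
  }
  out
}

#' Export ground truth and burst tables
#'
#' @param study an `"MEAStudy"`.
#' @param dir output directory.
#' @return invisibly, the paths written: `ground_truth.csv` (device,
#'   session, channel, unit_class, time_s) and `ground_truth_bursts.csv`
#'   (device, session, channel, t_start_s, t_end_s).
#' @export
writeGroundTruthCsv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spikes <- list(); bursts <- list()
  for (r in seq_len(nrow(study$sessions))) {
    truth <- study$truths[[r]]
    dev <- study$sessions$device[r]; ses <- study$sessions$session[r]
    for (ch in seq_along(truth@trains)) {
      tr <- truth@trains[[ch]]
      if (length(tr)) {
        spikes[[length(spikes) + 1L]] <- data.frame(
          device = dev, session = ses, channel = sprintf("ch%02d", ch),
          unit_class = truth@unitClass[ch], time_s = tr,
          stringsAsFactors = FALSE)
      }
      iv <- truth@burstIntervals[[ch]]
      if (nrow(iv)) {
        bursts[[length(bursts) + 1L]] <- data.frame(
          device = dev, session = ses, channel = sprintf("ch%02d", ch),
          t_start_s = iv[, 1L], t_end_s = iv[, 2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  p1 <- file.path(dir, "ground_truth.csv")
  p2 <- file.path(dir, "ground_truth_bursts.csv")
  utils::write.csv(do.call(rbind, spikes), p1, row.names = FALSE)
  utils::write.csv(do.call(rbind, bursts), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json: ", path)
  }
}

# small stable polynomial hash for config provenance stamps
.configHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
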