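# On-disk formats: 16-bit PCM WAV (minimal RIFF implementation), call
# annotation CSV, LFP float32 flat binary + JSON sidecar, spike and sync
# CSV.  All times are seconds from recording start.

#' Write a (multi-channel) waveform as 16-bit PCM WAV
#'
#' @param channels List of numeric vectors (equal length) or a single
#'   vector; values are clipped to [-1, 1].
#' @param path Output path.
#' @param sample_rate_hz Sampling rate.
#' @return `path`, invisibly.
#' @export
write_wav <- function(channels, path, sample_rate_hz) {
  if (is.numeric(channels)) channels <- list(channels)
  n <- unique(vapply(channels, length, 0L))
  stopifnot(length(n) == 1)
  nch <- length(channels)
  x <- do.call(rbind, channels)          # channels x samples
  x <- pmax(pmin(x, 1), -1)
  pcm <- as.integer(round(x * 32767))    # interleaved column-major
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * nch * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L * nch), con, size = 4,
           endian = "little")
  writeBin(as.integer(2L * nch), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV path.
#' @return List with `channels` (list of numeric vectors in [-1, 1]) and
#'   `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; nch <- NULL; fs <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      nch <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      if (fmt != 1L || bits != 16L) stop("only 16-bit PCM supported")
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little")
      m <- matrix(pcm / 32767, nrow = nch)
      return(list(channels = lapply(seq_len(nch), function(i) m[i, ]),
                  sample_rate_hz = fs))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}

#' Write call annotations as CSV
#'
#' Columns: `onset_s, offset_s, call_type, syllable_onsets, is_target`;
#' syllable onsets are ';'-joined seconds.
#'
#' @param events A `call_events` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  df <- data.frame(
    onset_s = sprintf("%.6f", events$onset_s),
    offset_s = sprintf("%.6f", events$offset_s),
    call_type = events$call_type,
    syllable_onsets = vapply(events$syllable_onsets_s,
                             function(s) paste(sprintf("%.6f", s),
                                               collapse = ";"), ""),
    is_target = events$is_target)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read call annotations written by [write_annotations()]
#' @param path CSV path.
#' @return A `call_events` table.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(call_events())
  syl <- lapply(strsplit(as.character(df$syllable_onsets), ";", fixed = TRUE),
                as.numeric)
  call_events(df$onset_s, df$offset_s, df$call_type, syl,
              is_target = as.logical(df$is_target))
}

#' Write an LFP channel set as float32 flat binary + JSON sidecar
#'
#' The binary holds channel-major float32 samples; the sidecar records
#' `sample_rate_hz`, `n_channels`, `n_samples`, and `site_xy_mm`.
#'
#' @param lfp An `lfp_channels` object.
#' @param path Binary output path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(lfp, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(t(lfp$samples)), con, size = 4, endian = "little")
  close(con)
  meta <- list(sample_rate_hz = lfp$sample_rate_hz,
               n_channels = nrow(lfp$samples),
               n_samples = ncol(lfp$samples),
               site_xy_mm = unname(apply(lfp$site_xy_mm, 1, as.numeric,
                                         simplify = FALSE)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an LFP channel set written by [write_lfp()]
#' @param path Binary path (sidecar expected at `paste0(path, ".json")`).
#' @return An `lfp_channels` object.
#' @export
read_lfp <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", meta$n_channels * meta$n_samples, size = 4,
               endian = "little")
  close(con)
  site <- meta$site_xy_mm
  site <- if (is.list(site)) do.call(rbind, lapply(site, unlist))
          else as.matrix(site)
  structure(list(samples = t(matrix(x, ncol = meta$n_channels)),
                 sample_rate_hz = meta$sample_rate_hz,
                 site_xy_mm = site,
                 duration_s = meta$n_samples / meta$sample_rate_hz),
            class = "lfp_channels")
}

#' Write spike trains as CSV (`unit_id, spike_time_s`)
#' @param spikes A `spike_trains` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(
    unit_id = rep(seq_along(spikes$times),
                  vapply(spikes$times, length, 0L)),
    spike_time_s = sprintf("%.6f", unlist(spikes$times)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains written by [write_spikes()]
#' @param path CSV path.
#' @param n_units Total unit count (captures silent trailing units).
#' @param duration_s Recording span.
#' @return A `spike_trains` object.
#' @export
read_spikes <- function(path, n_units = NULL, duration_s = NA) {
  df <- utils::read.csv(path)
  n_units <- n_units %||% max(df$unit_id, 1)
  times <- lapply(seq_len(n_units), function(u)
    sort(df$spike_time_s[df$unit_id == u]))
  structure(list(times = times, unit_channel = rep(1L, n_units),
                 duration_s = duration_s),
            class = "spike_trains")
}

#' Write a pair of sync trains as CSV (`clock, pulse_time_s`)
#' @param sync List with `audio` and `neural` `sync_pulses`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  df <- data.frame(
    clock = rep(c("audio", "neural"),
                c(length(sync$audio$times), length(sync$neural$times))),
    pulse_time_s = sprintf("%.7f", c(sync$audio$times, sync$neural$times)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sync trains written by [write_sync()]
#' @param path CSV path.
#' @param period_s Nominal pulse period.
#' @return List with `audio` and `neural` `sync_pulses`.
#' @export
read_sync <- function(path, period_s = 2) {
  df <- utils::read.csv(path)
  mk <- function(cl) structure(
    list(times = sort(df$pulse_time_s[df$clock == cl]), period_s = period_s),
    class = "sync_pulses")
  list(audio = mk("audio"), neural = mk("neural"))
}
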