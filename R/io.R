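# Readers and writers for the pipeline's on-disk artifacts: PCM16 WAV,
# multi-page TIFF, CSV/TSV tables, JSON. One convention everywhere:
# times in seconds as doubles, intervals half-open [start, end), sample
# indices 0-based; CSV is comma-separated, '.' decimal, UTF-8, header row.

#' Write an audio signal as 16-bit PCM WAV
#'
#' @param a An [audio_signal]; samples are clipped to [-1, 1] and scaled
#'   to 16-bit integers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(a, path) {
  x <- pmin(pmax(a$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # PCM
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(as.integer(a$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(a$rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")              # block align
  writeBin(16L, con, size = 2L, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path File path.
#' @return An [audio_signal] with samples in [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, integer(), size = 4L, endian = "little"))
  wave <- readChar(con, 4L)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2L, size = 2L, endian = "little")
      rate <- readBin(con, integer(), size = 4L, endian = "little")
      invisible(readBin(con, integer(), size = 4L, endian = "little"))
      invisible(readBin(con, integer(), size = 2L, endian = "little"))
      bits <- readBin(con, integer(), size = 2L, endian = "little")
      channels <- fmt[2L]
      if (sz > 16L) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz %/% 2L, size = 2L,
                         endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  if (!identical(bits, 16L) || !identical(channels, 1L)) {
    stop("only 16-bit mono PCM supported")
  }
  audio_signal(samples / 32767, rate)
}

#' Write an EMG recording as CSV
#'
#' One column per channel; the first line is a comment header carrying
#' the sampling rate (`# rate=<Hz>`).
#'
#' @param rec An [emg_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate=%g", rec$rate), con)
  df <- as.data.frame(rec$channels)
  names(df) <- sprintf("ch%d", rec$channel_meta$id)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an EMG recording written by [write_emg_csv()]
#' @param path File path.
#' @return An [emg_recording].
#' @export
read_emg_csv <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- as.numeric(sub("^#\\s*rate=", "", first))
  if (!is.finite(rate)) stop("missing '# rate=' header in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  emg_recording(as.matrix(df), rate)
}

#' Write a sampled curve as two-column CSV (time_s, value)
#' @param values Numeric samples.
#' @param rate Sampling rate, Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(values, rate, path) {
  df <- data.frame(time_s = (seq_along(values) - 1) / rate, value = values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column curve CSV into values + rate
#' @param path File path.
#' @return List with `values` and `rate` (inferred from the time grid).
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  rate <- if (nrow(df) > 1L) 1 / stats::median(diff(df$time_s)) else 1
  list(values = df$value, rate = rate)
}

#' Write zone labels as BED-like TSV (start_s, end_s, class)
#' @param z A [zone_labels] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zones_tsv <- function(z, path) {
  utils::write.table(z$zones, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read zone labels from TSV
#' @param path File path.
#' @param rate Rate for the reconstructed square wave, Hz.
#' @return A [zone_labels] object.
#' @export
read_zones_tsv <- function(path, rate = 600) {
  zdf <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  n <- round(max(zdf$end) * rate)
  t <- (seq_len(n) - 1) / rate
  sw <- integer(n)
  for (k in which(zdf$class == "nasal")) {
    sw[t >= zdf$start[k] & t < zdf$end[k]] <- 1L
  }
  zone_labels(zdf, sw, rate)
}

#' Write an image sequence as multi-page TIFF
#' @param seq An [image_sequence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mri_tiff <- function(seq, path) {
  pages <- lapply(seq_len(dim(seq$frames)[1L]),
                  function(f) seq$frames[f, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into an image sequence
#' @param path File path.
#' @param fps Frame rate to attach, frames/s.
#' @return An [image_sequence].
#' @export
read_mri_tiff <- function(path, fps = 14) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  arr <- array(0, dim = c(length(pages), h, w))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]]
  image_sequence(arr, fps)
}

#' Write a scenario to a directory
#'
#' Writes `emg.csv`, `audio_mri.wav`, `audio_emg.wav`, `truth.json`
#' (nasal intervals, warp knots, config echo) and, when present,
#' `mri.tif` and `velum.csv`.
#'
#' @param scn A `scenario` from [make_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_emg_csv(scn$emg, file.path(dir, "emg.csv"))
  write_wav(scn$audio_mri, file.path(dir, "audio_mri.wav"))
  write_wav(scn$audio_emg, file.path(dir, "audio_emg.wav"))
  write_curve_csv(scn$true_velum$values, scn$true_velum$rate,
                  file.path(dir, "velum.csv"))
  if (!is.null(scn$mri)) write_mri_tiff(scn$mri, file.path(dir, "mri.tif"))
  cfg <- scn$config
  truth <- list(
    nasal_intervals = apply(scn$true_nasal_intervals, 1L,
                            function(r) list(start = r[1L], end = r[2L])),
    warp_knots = if (is.null(cfg$warp_knots)) NULL else
      apply(cfg$warp_knots, 1L, function(r) list(t_mri = r[1L],
                                                 t_emg = r[2L])),
    config = cfg[c("n_utterances", "emg_rate", "mri_fps", "audio_rate_mri",
                   "audio_rate_emg", "n_channels", "burst_lead",
                   "burst_duration", "burst_snr", "closing_bursts",
                   "noise_sd", "utterance_spacing", "open_duration",
                   "seed")])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an utterance directory into the package's types
#'
#' Best-effort adapter for a directory of recordings: looks for an EMG
#' table (`emg.csv`), a velum curve (`velum.csv` or any
#' `*velum*.csv`), and the paired audio tracks (`audio_mri.wav`,
#' `audio_emg.wav`). Directories written by [write_scenario()]
#' round-trip losslessly; unrecognized layouts produce an error listing
#' the files found.
#'
#' @param path Directory path.
#' @return List with `emg` ([emg_recording]), `velum` ([velum_curve] or
#'   `NULL`), `audio_mri`, `audio_emg` ([audio_signal]s or `NULL`),
#'   `mri` ([image_sequence] or `NULL`), `truth` (parsed truth.json or
#'   `NULL`).
#' @export
read_deposited_corpus <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  files <- list.files(path)
  emg_f <- grep("emg.*\\.csv$", files, value = TRUE, ignore.case = TRUE)
  if (!length(emg_f)) {
    stop("unrecognized layout in ", path, "; files found: ",
         paste(files, collapse = ", "))
  }
  emg <- read_emg_csv(file.path(path, emg_f[1L]))
  if (ncol(emg$channels) != 5L) {
    warning(sprintf("expected 5 EMG channels, found %d; proceeding",
                    ncol(emg$channels)))
  }
  vel_f <- grep("velum.*\\.csv$", files, value = TRUE, ignore.case = TRUE)
  velum <- if (length(vel_f)) {
    cv <- read_curve_csv(file.path(path, vel_f[1L]))
    velum_curve(pmin(pmax(cv$values, 0), 1), cv$rate)
  } else NULL
  wav_mri <- grep("mri.*\\.wav$", files, value = TRUE, ignore.case = TRUE)
  wav_emg <- grep("emg.*\\.wav$", files, value = TRUE, ignore.case = TRUE)
  tif_f <- grep("\\.tif{1,2}$", files, value = TRUE, ignore.case = TRUE)
  truth_f <- grep("truth\\.json$", files, value = TRUE)
  list(
    emg = emg,
    velum = velum,
    audio_mri = if (length(wav_mri)) read_wav(file.path(path, wav_mri[1L]))
      else NULL,
    audio_emg = if (length(wav_emg)) read_wav(file.path(path, wav_emg[1L]))
      else NULL,
    mri = if (length(tif_f)) read_mri_tiff(file.path(path, tif_f[1L]))
      else NULL,
    truth = if (length(truth_f))
      jsonlite::read_json(file.path(path, truth_f[1L])) else NULL)
}
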