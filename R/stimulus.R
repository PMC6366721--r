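# Song stimuli: WAV input, preprocessing (high-pass + RMS normalization),
# syllable segmentation, spectrograms, and a synthetic song generator.

#' Construct a stimulus object
#'
#' @param waveform numeric vector of PCM samples (full-scale roughly
#'   \[-1, 1\])
#' @param sample_rate sampling rate (Hz)
#' @param syllables segmentation data.frame with columns `onset`, `offset`
#'   (s) and `label`; see [validate_segments()]
#' @param label identifier for the stimulus
#' @return object of class `stimulus`
#' @export
stimulus <- function(waveform, sample_rate = 44100, syllables = NULL,
                     label = "stim") {
  duration <- length(waveform) / sample_rate
  if (!is.null(syllables)) validate_segments(syllables, duration)
  structure(list(waveform = as.numeric(waveform), sample_rate = sample_rate,
                 duration = duration, syllables = syllables, label = label),
            class = "stimulus")
}

#' Validate a syllable segmentation
#'
#' Intervals must satisfy onset < offset, be sorted by onset,
#' non-overlapping, and lie within \[0, duration\].
#'
#' @param segments data.frame with columns `onset`, `offset`, `label`
#' @param duration stimulus duration (s); `Inf` skips the bounds check
#' @return the segmentation, invisibly; errors on violation
#' @export
validate_segments <- function(segments, duration = Inf) {
  need <- c("onset", "offset", "label")
  if (!all(need %in% names(segments)))
    stop("segmentation must have columns onset, offset, label")
  if (nrow(segments) == 0) return(invisible(segments))
  if (any(segments$onset >= segments$offset))
    stop("segmentation invalid: onset must precede offset")
  if (is.unsorted(segments$onset))
    stop("segmentation invalid: intervals must be sorted by onset")
  if (nrow(segments) > 1 &&
      any(segments$onset[-1] < segments$offset[-nrow(segments)]))
    stop("segmentation invalid: intervals overlap")
  if (any(segments$onset < 0) || any(segments$offset > duration))
    stop("segmentation invalid: intervals outside stimulus duration")
  invisible(segments)
}

#' Read and write syllable interval files
#'
#' Plain-text CSV with columns `onset_s`, `offset_s`, `label`, for
#' tool-agnostic round-tripping of segmentations.
#'
#' @param path file path
#' @return `read_segments`: data.frame with columns `onset`, `offset`,
#'   `label`
#' @export
read_segments <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s", "label") %in% names(df)))
    stop("interval file must have columns onset_s, offset_s, label")
  out <- data.frame(onset = df$onset_s, offset = df$offset_s,
                    label = as.character(df$label),
                    stringsAsFactors = FALSE)
  validate_segments(out)
  out
}

#' @rdname read_segments
#' @param segments segmentation data.frame
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  write.csv(data.frame(onset_s = segments$onset, offset_s = segments$offset,
                       label = segments$label),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' High-pass filter a waveform
#'
#' 4th-order Butterworth high-pass at `cutoff` Hz (single pass), removing
#' low-frequency and DC content before spectrographic analysis.
#'
#' @param waveform numeric samples
#' @param sample_rate sampling rate (Hz), > 1000
#' @param cutoff high-pass corner frequency (Hz)
#' @param order filter order
#' @return filtered waveform
#' @export
preprocess_waveform <- function(waveform, sample_rate, cutoff = 500,
                                order = 4) {
  if (sample_rate <= 1000) stop("sample_rate must exceed 1000 Hz")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "high")
  as.numeric(signal::filter(bf, waveform))
}

#' Scale a waveform to a target RMS amplitude
#'
#' @param waveform numeric samples
#' @param target target RMS (full-scale relative); default 0.1
#' @return rescaled waveform (unchanged if silent)
#' @export
normalize_rms <- function(waveform, target = 0.1) {
  r <- sqrt(mean(waveform^2))
  if (r < 1e-12) return(waveform)
  waveform * (target / r)
}

#' Load a song stimulus from disk
#'
#' Reads a mono PCM WAV file and its syllable interval file, high-pass
#' filters the waveform at 500 Hz (4th-order Butterworth) and normalizes
#' it to a common RMS amplitude so that all stimuli drive the cascade at
#' the same overall level.
#'
#' @param path WAV file (mono PCM)
#' @param segmentation_path CSV interval file (see [read_segments()])
#' @param rms_target common RMS amplitude
#' @param label stimulus identifier; default the file name
#' @return a `stimulus` object
#' @export
load_stimulus <- function(path, segmentation_path = NULL, rms_target = 0.1,
                          label = basename(path)) {
  w <- read_wav(path)
  x <- preprocess_waveform(w$samples, w$sample_rate)
  x <- normalize_rms(x, rms_target)
  seg <- if (!is.null(segmentation_path)) read_segments(segmentation_path)
  stimulus(x, w$sample_rate, syllables = seg, label = label)
}

#' Compute the stimulus spectrogram
#'
#' Short-time Fourier transform with a 256-point Hanning window; window
#' starts are placed on an exact `frame_step` grid (left-aligned, signal
#' zero-padded at the end), so a stimulus of duration `d` yields
#' `floor(d / frame_step)` frames. FFT bin magnitudes are averaged within
#' 50 equal-width bands on \[0, 8 kHz\] (bands narrower than the bin
#' spacing are filled by linear interpolation of the magnitude spectrum at
#' the band center). Amplitudes are reported in dB above a floor
#' `floor_db` below the spectrogram peak (log mode, default) or as raw
#' magnitudes (linear mode).
#'
#' @param stim a `stimulus` object
#' @param n_channels number of frequency channels
#' @param fmax upper frequency edge (Hz)
#' @param frame_step frame spacing (s)
#' @param window_size STFT window length (samples)
#' @param scale `"log"` or `"linear"`
#' @param floor_db dynamic range below peak mapped to 0 (log mode)
#' @return object of class `spectrogram`: list with `matrix`
#'   (n_frames x n_channels), `frame_step`, `channel_centers`,
#'   `scale_mode`, `syllables`, `label`
#' @export
compute_spectrogram <- function(stim, n_channels = 50, fmax = 8000,
                                frame_step = 1e-3, window_size = 256,
                                scale = c("log", "linear"),
                                floor_db = 70) {
  scale <- match.arg(scale)
  fs <- stim$sample_rate
  if (fs < 16000) stop("sample_rate must be at least 16 kHz")
  x <- stim$waveform
  if (length(x) < window_size) stop("stimulus shorter than one STFT window")
  n_frames <- floor(stim$duration / frame_step)
  starts <- round((seq_len(n_frames) - 1) * frame_step * fs) + 1
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, window_size - 1) /
                           (window_size - 1))
  xp <- c(x, numeric(window_size))   # zero-pad the tail
  seg <- vapply(starts, function(s) xp[s:(s + window_size - 1)] * win,
                numeric(window_size))
  mag <- Mod(stats::mvfft(seg))[seq_len(window_size / 2 + 1), , drop = FALSE]
  bin_freq <- (seq_len(window_size / 2 + 1) - 1) * fs / window_size

  width <- fmax / n_channels
  centers <- (seq_len(n_channels) - 0.5) * width
  band <- findInterval(bin_freq, seq(0, fmax, by = width),
                       rightmost.closed = FALSE)
  S <- matrix(0, nrow = n_frames, ncol = n_channels)
  for (ch in seq_len(n_channels)) {
    idx <- which(band == ch)
    if (length(idx) > 0) {
      S[, ch] <- colMeans(mag[idx, , drop = FALSE])
    } else {
      # band narrower than bin spacing: interpolate at the band center
      j <- findInterval(centers[ch], bin_freq)
      f <- (centers[ch] - bin_freq[j]) / (bin_freq[j + 1] - bin_freq[j])
      S[, ch] <- (1 - f) * mag[j, ] + f * mag[j + 1, ]
    }
  }

  if (scale == "log") {
    peak <- max(S)
    if (peak <= 0) {
      S[] <- 0
    } else {
      S <- 20 * log10(pmax(S, peak * 10^(-floor_db / 20)) / peak) + floor_db
    }
  }
  structure(list(matrix = S, frame_step = frame_step,
                 channel_centers = centers, scale_mode = scale,
                 floor_db = floor_db, syllables = stim$syllables,
                 label = stim$label),
            class = "spectrogram")
}

#' Generate a synthetic song-like stimulus
#'
#' Produces a waveform with the rhythmic, broadband structure of zebra
#' finch song: a sequence of syllables (harmonic stacks with fundamentals
#' of 500-2000 Hz and up to 8 harmonics, or band-limited noise bursts),
#' each 50-200 ms long, deeply amplitude-modulated at 10-50 Hz (song
#' syllables carry strong internal envelope modulation), at per-type
#' sound levels spanning about 12 dB, separated by
#' 10-60 ms silent gaps, and preceded by 50 ms of low-level background
#' noise that pads the RF convolution. A configurable fraction of
#' syllables are repeats of an earlier syllable and share its class
#' label, mirroring motif repetition in real song. Exact boundaries are
#' returned as the segmentation.
#'
#' @param seed integer seed; output is fully reproducible
#' @param n_syllables number of syllables (at least 2)
#' @param duration total duration (s), at least 0.5
#' @param sample_rate sampling rate (Hz)
#' @param repeat_fraction fraction of syllables that repeat an earlier
#'   syllable type
#' @param rms_target RMS amplitude of the returned waveform
#' @param label stimulus identifier
#' @return a `stimulus` object with segmentation attached
#' @export
generate_synthetic_song <- function(seed, n_syllables = 5, duration = 1,
                                    sample_rate = 44100,
                                    repeat_fraction = 1 / 3,
                                    rms_target = 0.1,
                                    label = sprintf("synth%04d", seed)) {
  if (n_syllables < 2) stop("n_syllables must be at least 2")
  if (duration < 0.5) stop("duration must be at least 0.5 s")
  fs <- sample_rate
  lead <- 0.050
  with_local_seed(seed, {
    n_unique <- max(1, ceiling(n_syllables * (1 - repeat_fraction)))
    # sequence of syllable types; repeats reuse an earlier type
    types <- integer(n_syllables)
    types[seq_len(min(n_unique, n_syllables))] <- seq_len(min(n_unique,
                                                              n_syllables))
    if (n_syllables > n_unique)
      types[(n_unique + 1):n_syllables] <-
        sample(n_unique, n_syllables - n_unique, replace = TRUE)
    types <- sample(types)   # shuffle order

    # lay out the song in integer samples so boundaries are exact
    n_total <- round(duration * fs)
    n_lead <- round(lead * fs)
    min_syl <- round(0.050 * fs)
    min_gap <- round(0.010 * fs)
    durs_u <- round(runif(n_unique, 0.050, 0.200) * fs)
    shortfall <- function(d) n_total - n_lead - sum(d[types]) -
      (n_syllables - 1) * min_gap
    if (shortfall(durs_u) < 0) {
      # shrink syllables toward the 50 ms minimum before giving up
      scl <- (n_total - n_lead - (n_syllables - 1) * min_gap) /
        sum(durs_u[types])
      durs_u <- pmax(floor(durs_u * scl), min_syl)
      # rounding can leave a few samples of deficit; take them from the
      # longest syllable type
      deficit <- -shortfall(durs_u)
      if (deficit > 0) {
        k <- which.max(durs_u)
        take <- ceiling(deficit / sum(types == k))
        durs_u[k] <- durs_u[k] - take
      }
      if (shortfall(durs_u) < 0 || any(durs_u < min_syl))
        stop("cannot pack ", n_syllables, " syllables into ", duration,
             " s")
    }
    gaps <- round(runif(n_syllables - 1, 0.010, 0.060) * fs)
    slack <- shortfall(durs_u)
    if (sum(gaps - min_gap) > slack)
      gaps <- min_gap + floor((gaps - min_gap) * slack /
                                max(sum(gaps - min_gap), 1))

    # per-type spectral recipes; levels vary across syllable types as in
    # real song (roughly a 12 dB range)
    recipes <- lapply(seq_len(n_unique), function(i) {
      f0 <- runif(1, 500, 2000)
      n_harm <- min(8, max(3, floor(7800 / f0)))  # stack reaches toward 8 kHz
      list(kind = if (runif(1) < 0.7) "harmonic" else "noise",
           level = runif(1, 0.25, 1),
           f0 = f0,
           n_harm = n_harm,
           harm_phase = runif(8, 0, 2 * pi),
           # slowly decaying stack plus a broadband noise bed keeps the
           # syllable energy spread across the whole band, as in song
           harm_amp = (1:8)^-0.5,
           noise_floor = runif(1, 0.1, 0.3),
           band = sort(c(runif(1, 500, 3000), runif(1, 4000, 7500))),
           am = runif(2, 10, 50),
           am_mix = runif(1, 0.2, 0.8),
           am_depth = runif(1, 0.5, 1),
           am_phase = runif(2, 0, 2 * pi))
    })

    synth_syll <- function(rc, dur) {
      n <- round(dur * fs)
      t <- (seq_len(n) - 1) / fs
      if (rc$kind == "harmonic") {
        k <- seq_len(rc$n_harm)
        y <- rowSums(vapply(k, function(j)
          rc$harm_amp[j] * sin(2 * pi * rc$f0 * j * t + rc$harm_phase[j]),
          numeric(n)))
        bed <- rnorm(n)
        bf <- signal::butter(2, c(500, 7500) / (fs / 2), type = "pass")
        bed <- as.numeric(signal::filter(bf, bed))
        y <- y / max(abs(y), 1e-12) +
          rc$noise_floor * bed / max(abs(bed), 1e-12)
      } else {
        y <- rnorm(n)
        bf <- signal::butter(2, rc$band / (fs / 2), type = "pass")
        y <- as.numeric(signal::filter(bf, y))
      }
      # irregular envelope: two-component modulation of variable depth
      e0 <- (1 - rc$am_mix) * sin(2 * pi * rc$am[1] * t + rc$am_phase[1]) +
        rc$am_mix * sin(2 * pi * rc$am[2] * t + rc$am_phase[2])
      e0 <- e0 / max(abs(e0), 1e-12)
      env <- (1 - rc$am_depth) + rc$am_depth * (0.5 + 0.5 * e0)^2
      edge <- pmin(1, pmin(t, dur - t) / 0.005)   # 5 ms on/off ramps
      y * env * edge
    }

    wave <- rnorm(n_lead) * 0.02   # low-level microphone noise
    onsets <- numeric(n_syllables)
    offsets <- numeric(n_syllables)
    for (i in seq_len(n_syllables)) {
      d <- durs_u[types[i]]
      y <- synth_syll(recipes[[types[i]]], d / fs)
      y <- y / max(abs(y), 1e-12) * recipes[[types[i]]]$level
      onsets[i] <- length(wave) / fs
      wave <- c(wave, y)
      offsets[i] <- length(wave) / fs
      if (i < n_syllables) wave <- c(wave, numeric(gaps[i]))
    }
    if (length(wave) < n_total)
      wave <- c(wave, numeric(n_total - length(wave)))
    wave <- wave[seq_len(n_total)]
    wave <- normalize_rms(wave, rms_target)
    seg <- data.frame(onset = onsets, offset = offsets,
                      label = sprintf("s%02d", types),
                      stringsAsFactors = FALSE)
    stimulus(wave, fs, syllables = seg, label = label)
  })
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus> '%s': %.3f s at %d Hz, %d syllables\n",
              x$label, x$duration, x$sample_rate,
              if (is.null(x$syllables)) 0L else nrow(x$syllables)))
  invisible(x)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> '%s': %d frames x %d channels (%s scale)\n",
              x$label, nrow(x$matrix), ncol(x$matrix), x$scale_mode))
  invisible(x)
}

# ---- minimal mono PCM WAV I/O ------------------------------------------
# 16-bit integer or 32-bit float RIFF/WAVE, the formats produced by
# standard recording chains; kept deliberately small.

#' Read a mono PCM WAV file
#'
#' Supports 16-bit integer and 32-bit float mono PCM.
#'
#' @param path file path
#' @return list with `samples` (numeric, full scale \[-1, 1\]) and
#'   `sample_rate`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      if (fmt$channels != 1) stop("only mono WAV files are supported")
      if (fmt$audio_format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$audio_format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "numeric", sz / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)")
      }
      return(list(samples = samples, sample_rate = fmt$sample_rate))
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
  }
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector, full scale \[-1, 1\] (clipped beyond)
#' @param sample_rate sampling rate (Hz)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(pmax(pmin(round(samples * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
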