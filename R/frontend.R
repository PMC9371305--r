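#' Audio front-end
#'
#' Waveform -> utterances -> fixed-length log-mel spectrograms. The
#' published front-end parameters are reproduced exactly: 16 kHz mono
#' input, utterances zero-padded or truncated to 7 s (112000 samples),
#' STFT with a 2048-sample Hamming window and 512-sample hop (centered,
#' reflection padding), magnitude spectrum into a 128-band Slaney-style
#' mel filterbank (fmin 0, fmax 8000 Hz), natural-log compressed with an
#' epsilon floor. A 7-s input yields a 128 x 219 matrix.
#'
#' @name audio-frontend
NULL

.TARGET_RATE <- 16000L
.TARGET_SAMPLES <- 112000L

#' Construct a waveform
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param rate sampling rate in Hz; anything other than 16000 is
#'   polyphase-resampled to 16000 at construction.
#' @return list with `samples` and `rate` (class `waveform`).
#' @export
waveform <- function(samples, rate = 16000) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (rate != .TARGET_RATE) {
    samples <- signal::resample(samples, .TARGET_RATE, rate)
    rate <- .TARGET_RATE
  }
  structure(list(samples = samples, rate = as.integer(rate)), class = "waveform")
}

.as_samples <- function(w) if (inherits(w, "waveform")) w$samples else as.numeric(w)

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for PCM 16- and 24-bit files; stereo input
#' is downmixed by channel averaging, and sampling rates other than
#' 16 kHz are resampled at load time.
#'
#' @param path WAV file path.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (rawToChar(readBin(con, "raw", 4L)) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (tag == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt/data chunk in ", path)
  if (fmt$audio_format != 1L) stop("only PCM WAV is supported")
  if (fmt$bits == 16L) {
    x <- readBin(data, "integer", length(data) %/% 2L, 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    n <- length(data) %/% 3L
    b <- matrix(as.integer(data[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else stop("unsupported bit depth: ", fmt$bits)
  if (fmt$channels > 1L) {
    nch <- fmt$channels
    nfr <- length(x) %/% nch
    x <- rowMeans(matrix(x[seq_len(nfr * nch)], ncol = nch, byrow = TRUE))
  }
  waveform(x, fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param w a [waveform()] or numeric vector.
#' @param path output path.
#' @param rate sampling rate (taken from `w` if it is a waveform).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, rate = 16000) {
  x <- .as_samples(w)
  if (inherits(w, "waveform")) rate <- w$rate
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeBin(charToRaw("RIFF"), con)
  writeBin(as.integer(36L + nbytes), con, 4L, endian = "little")
  writeBin(charToRaw("WAVEfmt "), con)
  writeBin(as.integer(c(16L, 1L + 65536L, rate)), con, 4L, endian = "little")
  writeBin(as.integer(c(rate * 2L, 2L + 16L * 65536L)), con, 4L, endian = "little")
  writeBin(charToRaw("data"), con)
  writeBin(as.integer(nbytes), con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Energy-based utterance segmentation
#'
#' Splits a waveform into speech segments by short-time energy: frames
#' whose energy (dB) exceeds both the utterance's median frame energy
#' plus `energy_threshold_db` and an absolute floor are marked active;
#' maximal active runs are merged across gaps shorter than `min_gap_s`
#' and runs shorter than `min_segment_s` are dropped. Segments are
#' disjoint, ordered and within the waveform bounds. A documented
#' energy-based stand-in for library silence-removal segmenters.
#'
#' @param w a [waveform()].
#' @param energy_threshold_db threshold relative to the median frame
#'   energy (dB; negative keeps frames quieter than the median).
#' @param min_segment_s minimum segment duration (s).
#' @param min_gap_s gaps shorter than this are bridged (s).
#' @param frame_length,hop_length analysis frame parameters (samples).
#' @param floor_db absolute activity floor (dBFS).
#' @return list of [waveform()] segments (possibly empty), with a
#'   `bounds` attribute giving `(start, end)` sample indices.
#' @export
segment_speech <- function(w, energy_threshold_db = -20, min_segment_s = 0.3,
                           min_gap_s = 0.2, frame_length = 2048L,
                           hop_length = 512L, floor_db = -60) {
  x <- .as_samples(w)
  if (length(x) == 0L) stop("empty waveform")
  n <- length(x)
  starts <- seq(1L, max(1L, n - frame_length + 1L), by = hop_length)
  e <- vapply(starts, function(s) {
    seg <- x[s:min(s + frame_length - 1L, n)]
    10 * log10(mean(seg^2) + 1e-12)
  }, numeric(1))
  active <- e > pmax(stats::median(e) + energy_threshold_db, floor_db)
  if (!any(active)) return(structure(list(), bounds = matrix(0, 0, 2)))
  r <- rle(active)
  ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
  runs <- cbind(begs[r$values], ends[r$values])
  # merge across short gaps
  min_gap_frames <- ceiling(min_gap_s * .TARGET_RATE / hop_length)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs) - 1L) + 1L) {
    if (runs[i, 1] - merged[nrow(merged), 2] - 1L < min_gap_frames)
      merged[nrow(merged), 2] <- runs[i, 2]
    else merged <- rbind(merged, runs[i, ])
  }
  # frames -> samples, drop short segments
  bounds <- t(apply(merged, 1, function(rg) {
    c(starts[rg[1]], min(starts[rg[2]] + frame_length - 1L, n))
  }))
  keep <- (bounds[, 2] - bounds[, 1] + 1L) >= min_segment_s * .TARGET_RATE
  bounds <- bounds[keep, , drop = FALSE]
  segs <- lapply(seq_len(nrow(bounds)), function(i)
    waveform(x[bounds[i, 1]:bounds[i, 2]]))
  structure(segs, bounds = bounds)
}

#' Fix an utterance to exactly 7 seconds
#'
#' Shorter inputs are post-padded with zeros to 112000 samples (7 s at
#' 16 kHz); longer inputs keep their first 112000 samples.
#'
#' @param w a [waveform()] or numeric vector at 16 kHz.
#' @return a [waveform()] of exactly 112000 samples.
#' @export
fix_duration <- function(w) {
  x <- .as_samples(w)
  if (length(x) == 0L) stop("empty waveform")
  if (length(x) >= .TARGET_SAMPLES) x <- x[seq_len(.TARGET_SAMPLES)]
  else x <- c(x, rep(0, .TARGET_SAMPLES - length(x)))
  structure(list(samples = x, rate = .TARGET_RATE), class = "waveform")
}

.hz_to_mel_slaney <- function(f) {
  ifelse(f < 1000, 3 * f / 200, 15 + 27 * log(f / 1000) / log(6.4))
}
.mel_to_hz_slaney <- function(m) {
  ifelse(m < 15, 200 * m / 3, 1000 * exp(log(6.4) * (m - 15) / 27))
}

#' Slaney-style mel filterbank
#'
#' Triangular filters on a mel-warped axis (linear below 1 kHz,
#' logarithmic above), area-normalized (each triangle scaled by
#' `2 / (f_hi - f_lo)`).
#'
#' @param n_mels number of bands.
#' @param n_fft FFT size (filters span `n_fft/2 + 1` bins).
#' @param rate sampling rate (Hz).
#' @param fmin,fmax frequency range (Hz).
#' @return `n_mels x (n_fft/2 + 1)` weight matrix with attribute
#'   `"center_freqs"`.
#' @export
mel_filterbank <- function(n_mels = 128L, n_fft = 2048L, rate = 16000,
                           fmin = 0, fmax = 8000) {
  mels <- seq(.hz_to_mel_slaney(fmin), .hz_to_mel_slaney(fmax),
              length.out = n_mels + 2L)
  fpts <- .mel_to_hz_slaney(mels)
  freqs <- (0:(n_fft %/% 2L)) * rate / n_fft
  fb <- matrix(0, n_mels, length(freqs))
  for (i in seq_len(n_mels)) {
    lo <- fpts[i]; ce <- fpts[i + 1L]; hi <- fpts[i + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  structure(fb, center_freqs = fpts[2:(n_mels + 1L)])
}

#' Log-mel spectrogram
#'
#' Centered STFT (reflection padding of `n_fft/2` samples each side,
#' Hamming window) of a 16 kHz waveform, magnitude spectrum, mel
#' filterbank, natural log with an epsilon floor. The frame count is
#' `1 + floor(N / hop)`; a 7-s input gives 128 x 219.
#'
#' @param w a [waveform()] or numeric vector at 16 kHz.
#' @param n_fft window length (samples).
#' @param hop_length hop (samples).
#' @param n_mels mel bands.
#' @param fmin,fmax filterbank range (Hz).
#' @param log_floor floor applied before the log.
#' @param normalize if `TRUE`, z-score the result (off by default).
#' @return `n_mels x T` matrix of log mel energies.
#' @export
mel_spectrogram <- function(w, n_fft = 2048L, hop_length = 512L, n_mels = 128L,
                            fmin = 0, fmax = 8000, log_floor = 1e-10,
                            normalize = FALSE) {
  if (inherits(w, "waveform") && w$rate != .TARGET_RATE)
    stop("input must be sampled at 16 kHz")
  x <- .as_samples(w)
  n <- length(x)
  if (n < 2L) stop("waveform too short")
  half <- n_fft %/% 2L
  # reflection padding (librosa-style, edge not repeated)
  left <- x[pmin(half + 1L, n):2L]
  right <- x[(n - 1L):max(1L, n - half)]
  xp <- c(left[max(1L, length(left) - half + 1L):length(left)], x,
          right[seq_len(min(half, length(right)))])
  nframes <- 1L + n %/% hop_length
  win <- signal::hamming(n_fft)
  frames <- vapply(seq_len(nframes), function(t) {
    s <- (t - 1L) * hop_length + 1L
    xp[s:(s + n_fft - 1L)] * win
  }, numeric(n_fft))
  S <- Mod(stats::mvfft(frames))[seq_len(half + 1L), , drop = FALSE]
  fb <- mel_filterbank(n_mels, n_fft, .TARGET_RATE, fmin, fmax)
  out <- log(pmax(fb %*% S, log_floor))
  if (normalize) out <- (out - mean(out)) / stats::sd(out)
  out
}

#' Preprocess one waveform into a speaker's utterance spectrograms
#'
#' Segments the waveform, fixes every segment to 7 s, and computes the
#' log-mel spectrogram of each.
#'
#' @param w a [waveform()].
#' @param ... passed to [segment_speech()].
#' @return list of 128 x 219 matrices (possibly empty).
#' @export
preprocess_waveform <- function(w, ...) {
  segs <- segment_speech(w, ...)
  lapply(segs, function(s) mel_spectrogram(fix_duration(s)))
}
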