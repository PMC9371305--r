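#' Synthetic corpus generator
#'
#' Generates a clinical-interview-shaped corpus with controllable MIL
#' structure: per-speaker variable-length utterance collections, a
#' single binary speaker label, configurable class balance, and — the
#' MIL ingredient — only a Bernoulli(`rho`) fraction of a positive
#' speaker's utterances carrying the class signature. Two paths exist:
#' a waveform generator (harmonic complexes in pink noise, interleaved
#' with silences, exercising the audio front-end end to end) and a fast
#' spectrogram generator (smooth random log-mel-like fields with the
#' signature as a localized mean shift) for layer and training tests.
#' Everything is determined by the seed, and the generator emits its own
#' bookkeeping of which utterances carry the signature.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' @param n_train,n_dev,n_test speakers per split as `c(normal,
#'   depressed)`; class imbalance is set through these counts.
#' @param utterances_per_speaker inclusive range of utterance counts.
#' @param rho prevalence of signature-bearing utterances within positive
#'   speakers, in (0, 1].
#' @param snr_db signal-to-noise ratio of the signature against the
#'   background (dB).
#' @param signature_bands mel bands receiving the mean shift
#'   (spectrogram path).
#' @param signature_shift_db signature magnitude shift (dB).
#' @param signature_peak_hz narrowband signature component (waveform
#'   path).
#' @param slowdown temporal-modulation slowdown factor of signature
#'   utterances (waveform path).
#' @param utter_duration_s utterance duration range (s), spanning both
#'   the pad and truncate paths of the 7-s duration fix.
#' @param gap_s silence gap range between utterances (s).
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_train = c(20, 20), n_dev = c(5, 5), n_test = c(5, 5),
                       utterances_per_speaker = c(10, 16),
                       rho = 0.5, snr_db = 10,
                       signature_bands = 40:60, signature_shift_db = 6,
                       signature_peak_hz = 2200, slowdown = 1.5,
                       utter_duration_s = c(2, 12), gap_s = c(0.3, 1.0),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(rho > 0, rho <= 1, all(c(n_train, n_dev, n_test) >= 0),
            sum(n_train) > 0, utterances_per_speaker[1] >= 1)
  structure(list(n_train = n_train, n_dev = n_dev, n_test = n_test,
                 utterances_per_speaker = utterances_per_speaker,
                 rho = rho, snr_db = snr_db,
                 signature_bands = signature_bands,
                 signature_shift_db = signature_shift_db,
                 signature_peak_hz = signature_peak_hz,
                 slowdown = slowdown,
                 utter_duration_s = utter_duration_s, gap_s = gap_s,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_roster <- function(cfg) {
  splits <- c(rep("train", sum(cfg$n_train)), rep("dev", sum(cfg$n_dev)),
              rep("test", sum(cfg$n_test)))
  labels <- c(rep(0L, cfg$n_train[1]), rep(1L, cfg$n_train[2]),
              rep(0L, cfg$n_dev[1]), rep(1L, cfg$n_dev[2]),
              rep(0L, cfg$n_test[1]), rep(1L, cfg$n_test[2]))
  data.frame(speaker_id = sprintf("S%03d", seq_along(splits)),
             split = splits, label = labels, stringsAsFactors = FALSE)
}

.sample_range <- function(rng) {
  vals <- rng[1]:rng[2]
  vals[sample.int(length(vals), 1L)]
}

.smooth_field <- function(nr, nc, radius = 2L) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- rep(1, 2L * radius + 1L) / (2L * radius + 1L)
  smooth_cols <- function(m, r) {             # edge-padded moving average
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)      # column-wise
    matrix(f[(r + 1L):(r + n), ], n, ncol(m))
  }
  z <- smooth_cols(z, radius)
  z <- t(smooth_cols(t(z), radius))
  z / stats::sd(z)
}

#' Simulate a spectrogram corpus (fast path)
#'
#' Draws log-mel-like 128 x 219 matrices from a smooth random field and
#' adds the class signature — a localized mean shift over
#' `signature_bands` — to the Bernoulli(`rho`) subset of positive
#' speakers' utterances. The signature shift is
#' `log(10) * signature_shift_db / 20` in natural-log magnitude units;
#' the background field standard deviation is the shift scaled down by
#' `snr_db`. Ground truth (which utterances carry the signature) is
#' attached as attribute `"ground_truth"`.
#'
#' @param cfg a [sim_config()].
#' @param n_freq,n_time spectrogram dimensions.
#' @return list of [speaker_record()]s with attribute `"ground_truth"`
#'   (data.frame: speaker_id, utterance, signature).
#' @export
simulate_spectrogram_corpus <- function(cfg, n_freq = 128L, n_time = 219L) {
  roster <- .sim_roster(cfg)
  set.seed(cfg$seed)
  shift <- log(10) * cfg$signature_shift_db / 20
  noise_sd <- shift * 10^(-cfg$snr_db / 20)
  base_level <- -2
  gt <- list(); corpus <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    nu <- .sample_range(cfg$utterances_per_speaker)
    speaker_offset <- stats::rnorm(1, 0, 0.3) * noise_sd
    sig <- if (roster$label[i] == 1L) stats::runif(nu) < cfg$rho else rep(FALSE, nu)
    utts <- lapply(seq_len(nu), function(u) {
      m <- base_level + speaker_offset + noise_sd * .smooth_field(n_freq, n_time)
      if (sig[u]) m[cfg$signature_bands, ] <- m[cfg$signature_bands, ] + shift
      pmax(m, log(1e-10))
    })
    corpus[[i]] <- speaker_record(roster$speaker_id[i], roster$split[i],
                                  roster$label[i], utts)
    gt[[i]] <- data.frame(speaker_id = roster$speaker_id[i],
                          utterance = seq_len(nu), signature = sig)
  }
  structure(corpus, ground_truth = do.call(rbind, gt))
}

.pink_noise <- function(n) {
  # 1/f spectral shaping of white noise
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  shaped <- W / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

.sim_utterance <- function(dur_s, f0, signature, cfg) {
  n <- round(dur_s * 16000)
  t <- seq_len(n) / 16000
  mod_rate <- 3.5 / (if (signature) cfg$slowdown else 1)
  env <- 0.6 + 0.4 * sin(2 * pi * mod_rate * t + stats::runif(1, 0, 2 * pi))
  sig <- rowSums(vapply(1:8, function(h)
    sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi)) / h, numeric(n)))
  x <- env * sig
  if (signature)
    x <- x + 0.5 * sin(2 * pi * cfg$signature_peak_hz * t)
  noise <- .pink_noise(n)
  x <- x / stats::sd(x)
  snr_lin <- 10^(cfg$snr_db / 20)
  y <- x + noise / snr_lin
  0.4 * y / max(abs(y))
}

#' Simulate a waveform corpus
#'
#' Per speaker, a sequence of utterances (harmonic complexes with a
#' random fundamental, amplitude-modulated, plus pink noise at the
#' configured SNR) interleaved with silences; positive speakers carry
#' the signature — an added narrowband component and a temporal
#' modulation slowdown — in a Bernoulli(`rho`) subset of utterances.
#' Each record holds both the full waveform (`$wave`, for segmentation)
#' and the individual utterance waveforms.
#'
#' @param cfg a [sim_config()].
#' @return list of [speaker_record()]s whose `utterances` are
#'   [waveform()]s; each record also has `$wave` (the concatenated
#'   signal with gaps) and `$bounds`; ground truth attached as with
#'   [simulate_spectrogram_corpus()].
#' @export
simulate_corpus <- function(cfg) {
  roster <- .sim_roster(cfg)
  set.seed(cfg$seed)
  gt <- list(); corpus <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    nu <- .sample_range(cfg$utterances_per_speaker)
    f0 <- stats::runif(1, 85, 255)
    sig <- if (roster$label[i] == 1L) stats::runif(nu) < cfg$rho else rep(FALSE, nu)
    utts <- vector("list", nu); pieces <- list(); bounds <- matrix(0L, nu, 2)
    pos <- 0L
    for (u in seq_len(nu)) {
      dur <- stats::runif(1, cfg$utter_duration_s[1], cfg$utter_duration_s[2])
      x <- .sim_utterance(dur, f0, sig[u], cfg)
      gap <- rep(0, round(stats::runif(1, cfg$gap_s[1], cfg$gap_s[2]) * 16000))
      pieces[[length(pieces) + 1L]] <- gap
      bounds[u, ] <- c(pos + length(gap) + 1L, pos + length(gap) + length(x))
      pieces[[length(pieces) + 1L]] <- x
      pos <- bounds[u, 2]
      utts[[u]] <- waveform(x)
    }
    rec <- speaker_record(roster$speaker_id[i], roster$split[i],
                          roster$label[i], utts)
    rec$wave <- waveform(unlist(pieces))
    rec$bounds <- bounds
    corpus[[i]] <- rec
    gt[[i]] <- data.frame(speaker_id = roster$speaker_id[i],
                          utterance = seq_len(nu), signature = sig)
  }
  structure(corpus, ground_truth = do.call(rbind, gt))
}

#' Convert a waveform corpus to spectrograms
#'
#' Applies [fix_duration()] and [mel_spectrogram()] to every utterance
#' of every speaker (using the generator's own utterance boundaries, not
#' re-segmentation).
#'
#' @param corpus output of [simulate_corpus()].
#' @return list of [speaker_record()]s with spectrogram utterances;
#'   ground truth carried over.
#' @export
corpus_to_spectrograms <- function(corpus) {
  out <- lapply(corpus, function(s) {
    speaker_record(s$speaker_id, s$split, s$label,
                   lapply(s$utterances, function(u) mel_spectrogram(fix_duration(u))))
  })
  structure(out, ground_truth = attr(corpus, "ground_truth"))
}
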