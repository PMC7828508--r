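#' Raw audio segment
#'
#' @param samples Numeric vector of audio samples.
#' @param rate_hz Audio sampling rate in Hz (e.g. 44100).
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("audio must be non-empty")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  structure(list(samples = samples, rate_hz = rate_hz,
                 duration_s = length(samples) / rate_hz),
            class = "audio_segment")
}

# Analytic signal x + i*H(x) via the frequency-domain construction:
# double positive frequencies, zero negative ones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Anti-aliased resampling from `from_hz` to `to_hz`. Uses the rational
# polyphase resampler from `signal`; large denominators (e.g. audio-rate
# 44100 -> 64) are reduced first by staged decimation.
resample_signal <- function(x, from_hz, to_hz) {
  if (abs(from_hz - to_hz) < 1e-9) return(x)
  if (to_hz > from_hz) stop("upsampling not supported")
  if (abs(from_hz - round(from_hz)) > 1e-9 || abs(to_hz - round(to_hz)) > 1e-9)
    stop("sampling rates must be integers")
  from <- round(from_hz); to <- round(to_hz)
  while (TRUE) {
    g <- gcd_int(from, to)
    if (from / g <= 500L) break
    d <- largest_decimation_factor(from, to)
    if (is.na(d)) break
    x <- signal::decimate(x, d)
    from <- from %/% d
  }
  g <- gcd_int(from, to)
  signal::resample(x, to %/% g, from %/% g)
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- a %% b; a <- b; b <- t }
  a
}

largest_decimation_factor <- function(from, to) {
  for (d in 10L:2L)
    if (from %% d == 0L && from %/% d >= 2L * to) return(d)
  NA_integer_
}

#' Extract the speech envelope of an audio segment
#'
#' Computes the power of the analytic signal (squared magnitude of the
#' Hilbert-transformed waveform), resamples it to the envelope rate with
#' anti-aliasing, and z-scores it over the whole segment.
#'
#' @param audio An [audio_segment()].
#' @param target_rate_hz Envelope rate in Hz (default 64).
#' @param power If `TRUE` (default) the squared magnitude of the analytic
#'   signal is used; if `FALSE`, the magnitude.
#' @param side,trial_id Metadata forwarded to the result.
#' @return An [envelope_signal()] at `target_rate_hz`, z-scored.
#' @export
extract_envelope <- function(audio, target_rate_hz = 64, power = TRUE,
                             side = NA_character_, trial_id = NA_character_) {
  if (!inherits(audio, "audio_segment")) stop("audio must be an audio_segment")
  if (target_rate_hz >= audio$rate_hz)
    stop("target rate must be below the audio rate")
  env <- Mod(analytic_signal(audio$samples))
  if (power) env <- env^2
  env <- resample_signal(env, audio$rate_hz, target_rate_hz)
  envelope_signal(z_score(env), rate_hz = target_rate_hz,
                  side = side, trial_id = trial_id)
}

#' Common average re-reference excluding EOG channels
#'
#' Subtracts, at every sample, the mean over the non-EOG channels from every
#' channel (EOG channels are re-referenced too but never contribute to the
#' reference).
#'
#' @param eeg An [eeg_segment()].
#' @return The re-referenced [eeg_segment()].
#' @export
car_rereference <- function(eeg) {
  keep <- !eeg$eog_mask
  if (!any(keep)) stop("all channels flagged EOG; no reference available")
  ref <- colMeans(eeg$data[keep, , drop = FALSE])
  eeg$data <- sweep(eeg$data, 2L, ref)
  eeg
}

# band-pass 2-8 Hz as a cascade of Butterworth high- and low-pass sections,
# applied forward-backward (zero phase)
bandpass_zero_phase <- function(x, lo_hz, hi_hz, fs) {
  hp <- signal::butter(3, lo_hz / (fs / 2), type = "high")
  lp <- signal::butter(4, hi_hz / (fs / 2), type = "low")
  x <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, x)
}

#' Offline EEG preprocessing chain
#'
#' The after-acquisition chain: 0.5 Hz high-pass, notch filters at the mains
#' frequency and its first harmonic, common average re-reference excluding
#' EOG channels, 2-8 Hz band-pass (all zero-phase), resampling to 64 Hz, and
#' per-channel z-scoring over the segment.
#'
#' @param eeg Raw-rate [eeg_segment()] (e.g. 1000 Hz).
#' @param band_lo_hz,band_hi_hz Band-pass edges in Hz (2 and 8).
#' @param notch_hz Frequencies to notch out, default `c(60, 120)`; use
#'   `NULL` to skip.
#' @param hp_hz High-pass cutoff in Hz (0.5).
#' @param target_rate_hz Output rate in Hz (64).
#' @return A 64 Hz [eeg_segment()], each channel z-scored.
#' @export
preprocess_eeg_offline <- function(eeg, band_lo_hz = 2, band_hi_hz = 8,
                                   notch_hz = c(60, 120), hp_hz = 0.5,
                                   target_rate_hz = 64) {
  stopifnot(inherits(eeg, "eeg_segment"))
  fs <- eeg$rate_hz
  hp <- signal::butter(2, hp_hz / (fs / 2), type = "high")
  x <- t(apply(eeg$data, 1L, function(ch) signal::filtfilt(hp, ch)))
  for (f0 in notch_hz) {
    if (f0 >= fs / 2) next
    bs <- signal::butter(2, c(f0 - 1, f0 + 1) / (fs / 2), type = "stop")
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(bs, ch)))
  }
  eeg$data <- x
  eeg <- car_rereference(eeg)
  x <- t(apply(eeg$data, 1L, function(ch)
    bandpass_zero_phase(ch, band_lo_hz, band_hi_hz, fs)))
  y <- t(apply(x, 1L, function(ch) resample_signal(ch, fs, target_rate_hz)))
  y <- t(apply(y, 1L, z_score))
  eeg_segment(y, rate_hz = target_rate_hz, channel_labels = eeg$channel_labels,
              eog_mask = eeg$eog_mask, trial_id = eeg$trial_id)
}

#' Minimal in-situ preprocessing of a streamed EEG buffer
#'
#' The causal chain run during an online session on the buffer accumulated so
#' far within a trial: common average re-reference excluding EOG channels, a
#' causal linear-phase FIR band-pass (windowed-sinc, Hamming) of the given
#' order, compensation of the FIR group delay (`fir_order/2` samples) by
#' discarding the leading transient so that output sample t aligns with input
#' sample t, resampling to 64 Hz, and per-channel z-scoring over the
#' processed span.
#'
#' @param buffer Raw-rate [eeg_segment()] holding all samples received so far
#'   in the current trial.
#' @param fir_order FIR filter order (default 1650; the filter has
#'   `fir_order + 1` taps).
#' @param band Band-pass edges in Hz, default `c(2, 8)`.
#' @param target_rate_hz Output rate in Hz (64).
#' @return A 64 Hz [eeg_segment()] covering the first
#'   `n_raw - fir_order/2` raw samples of the buffer (attribute
#'   `aligned_raw_samples`), each channel z-scored.
#' @export
preprocess_eeg_online_block <- function(buffer, fir_order = 1650,
                                        band = c(2, 8), target_rate_hz = 64) {
  stopifnot(inherits(buffer, "eeg_segment"))
  fs <- buffer$rate_hz
  n <- n_samples(buffer)
  delay <- fir_order %/% 2L
  if (n <= fir_order)
    stop("insufficient data: buffer must exceed the FIR order")
  eeg <- car_rereference(buffer)
  h <- as.numeric(signal::fir1(fir_order, band / (fs / 2), type = "pass"))
  idx <- (delay + 1L):n
  x <- t(apply(eeg$data, 1L, function(ch) {
    y <- signal::fftfilt(h, ch)
    y[idx]
  }))
  y <- t(apply(x, 1L, function(ch) resample_signal(ch, fs, target_rate_hz)))
  y <- t(apply(y, 1L, z_score))
  out <- eeg_segment(y, rate_hz = target_rate_hz,
                     channel_labels = buffer$channel_labels,
                     eog_mask = buffer$eog_mask, trial_id = buffer$trial_id)
  attr(out, "aligned_raw_samples") <- n - delay
  out
}
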