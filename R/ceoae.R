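#' Zero-phase band-pass filter for CEOAE waveforms
#'
#' Second-order Butterworth band-pass (250-6000 Hz by default) applied in
#' both forward and reverse time direction ([signal::filtfilt()]), so the
#' filtered waveform has zero phase delay.
#'
#' @param wave Pressure waveform (Pa).
#' @param fs Sample rate in Hz (default 30000).
#' @param band Passband edges in Hz.
#' @return Filtered waveform, same length.
#' @export
ceoae_bandpass <- function(wave, fs = 30000, band = c(250, 6000)) {
  stopifnot(all(is.finite(wave)))
  if (length(wave) <= 18)
    stop("waveform too short for the filter warm-up")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, wave))
}

#' Window a CEOAE response to the 6-16 ms analysis interval
#'
#' Zero outside 6-16 ms after the click; quarter-sine rise over 6-8 ms,
#' unity over 8-14 ms, quarter-cosine fall over 14-16 ms.
#'
#' @param wave Pressure waveform (Pa) starting at the click (t = 0).
#' @param fs Sample rate in Hz.
#' @param window_ms Start and end of the analysis window in ms.
#' @param ramp_ms Edge ramp duration in ms.
#' @return Windowed waveform, same length as the input.
#' @export
ceoae_window <- function(wave, fs = 30000, window_ms = c(6, 16),
                         ramp_ms = 2) {
  t_ms <- (seq_along(wave) - 1) / fs * 1000
  if (max(t_ms) < window_ms[2])
    stop("waveform must cover the full analysis window (",
         window_ms[2], " ms)")
  w <- numeric(length(wave))
  rise <- t_ms >= window_ms[1] & t_ms < window_ms[1] + ramp_ms
  flat <- t_ms >= window_ms[1] + ramp_ms & t_ms <= window_ms[2] - ramp_ms
  fall <- t_ms > window_ms[2] - ramp_ms & t_ms <= window_ms[2]
  w[rise] <- sin(pi / 2 * (t_ms[rise] - window_ms[1]) / ramp_ms)
  w[flat] <- 1
  w[fall] <- cos(pi / 2 * (t_ms[fall] - (window_ms[2] - ramp_ms)) / ramp_ms)
  wave * w
}

#' Artifact rejection of raw CEOAE trials
#'
#' A trial is rejected when the absolute response pressure exceeds the
#' threshold (5 mPa by default) anywhere inside the 6-16 ms scoring window.
#'
#' @param trials Matrix of raw trial buffers, one column per trial (Pa).
#' @param fs Sample rate in Hz.
#' @param threshold_pa Rejection threshold in Pa.
#' @param window_ms Scoring window in ms after the click.
#' @return List with `retained` (matrix of surviving columns),
#'   `n_rejected`, and `rejected` (indices).
#' @export
reject_trials <- function(trials, fs = 30000, threshold_pa = 0.005,
                          window_ms = c(6, 16)) {
  trials <- as.matrix(trials)
  t_ms <- (seq_len(nrow(trials)) - 1) / fs * 1000
  in_win <- t_ms >= window_ms[1] & t_ms <= window_ms[2]
  peak <- apply(abs(trials[in_win, , drop = FALSE]), 2, max)
  bad <- which(peak > threshold_pa)
  list(retained = trials[, setdiff(seq_len(ncol(trials)), bad), drop = FALSE],
       n_rejected = length(bad), rejected = bad)
}

#' Co-spectrum CEOAE amplitude from two replicates
#'
#' The square root of the integral, over the analysis band, of the
#' co-spectrum (real part of the cross-spectrum) between the two windowed
#' replicates, floored at zero before the root. For identical replicates this
#' equals the band-limited RMS amplitude of the waveform; for uncorrelated
#' replicates the co-spectrum integral averages to zero, so uncorrelated
#' noise does not inflate the amplitude estimate.
#'
#' @param a,b Windowed replicate waveforms (Pa), equal length.
#' @param fs Sample rate in Hz.
#' @param band Integration band in Hz.
#' @return Amplitude in Pa (>= 0).
#' @export
cospectrum_amplitude <- function(a, b, fs = 30000, band = c(250, 6000)) {
  if (length(a) != length(b)) stop("replicates must have equal length")
  n <- length(a)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  freq <- (seq_len(n) - 1) / n * fs
  # one-sided band selection; doubling accounts for the conjugate bins
  sel <- freq >= band[1] & freq <= band[2] & freq <= fs / 2
  co <- Re(fa * Conj(fb)) / n^2
  total <- 2 * sum(co[sel])
  sqrt(max(total, 0))
}

#' Replicate reproducibility
#'
#' Pearson correlation between the two windowed replicates. A CEOAE is
#' conventionally accepted as valid only when this exceeds 0.7.
#'
#' @param a,b Windowed replicate waveforms, equal length, non-zero variance.
#' @return Correlation in \[-1, 1\].
#' @export
ceoae_reproducibility <- function(a, b) {
  if (length(a) != length(b)) stop("replicates must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance replicate")
  stats::cor(a, b)
}

#' Full CEOAE analysis chain for one recording
#'
#' Applies the Methods-order pipeline: zero-phase band-pass filter, 6-16 ms
#' window with 2-ms rounded edges, then the co-spectrum amplitude and
#' replicate reproducibility. The recording is flagged valid when
#' reproducibility exceeds `min_reproducibility`.
#'
#' @param recording A `ceoae_recording` (see [generate_ceoae_recording()]) or
#'   any list with elements `replicate_a`, `replicate_b` and `fs`.
#' @param band Filter/integration band in Hz.
#' @param min_reproducibility Validity criterion (default 0.7).
#' @return List with `amplitude_pa`, `reproducibility` and `valid`.
#' @export
analyze_ceoae <- function(recording, band = c(250, 6000),
                          min_reproducibility = 0.7) {
  fs <- recording$fs
  a <- ceoae_window(ceoae_bandpass(recording$replicate_a, fs, band), fs)
  b <- ceoae_window(ceoae_bandpass(recording$replicate_b, fs, band), fs)
  rep_ab <- ceoae_reproducibility(a, b)
  list(amplitude_pa = cospectrum_amplitude(a, b, fs, band),
       reproducibility = rep_ab,
       valid = rep_ab > min_reproducibility)
}

#' Normalized CEOAE suppression index
#'
#' The elicitor-induced change in CEOAE amplitude (linear units) as a
#' percentage of the without-elicitor amplitude:
#' `100 * (amp_without - amp_with) / amp_without`. Negative values indicate
#' elicitor-induced enhancement. Scale-invariant: rescaling both amplitudes
#' by the same positive constant leaves the index unchanged.
#'
#' @param amp_without Without-elicitor amplitude (> 0).
#' @param amp_with With-elicitor amplitude.
#' @return Suppression in percent.
#' @export
suppression_index <- function(amp_without, amp_with) {
  if (any(!is.finite(amp_without)) || any(amp_without <= 0))
    stop("without-elicitor amplitude must be positive")
  100 * (amp_without - amp_with) / amp_without
}

#' Read / write CEOAE waveforms as two-column delimited text
#'
#' Columns `time_s` and `pressure_pa`; the sample rate is recovered from the
#' time column.
#'
#' @param path File path.
#' @return `read_ceoae_wave()` returns a list with `wave` and `fs`.
#' @export
read_ceoae_wave <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("time_s", "pressure_pa") %in% names(df)))
  fs <- 1 / stats::median(diff(df$time_s))
  list(wave = df$pressure_pa, fs = round(fs))
}

#' @rdname read_ceoae_wave
#' @param wave Pressure waveform (Pa).
#' @param fs Sample rate in Hz.
#' @export
write_ceoae_wave <- function(wave, fs, path) {
  df <- data.frame(time_s = (seq_along(wave) - 1) / fs, pressure_pa = wave)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
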