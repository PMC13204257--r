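# Analytic Morse wavelet CWT, computed as a frequency-domain filter bank.
# The generalized Morse wavelet has spectrum Psi(w) = U(w) c w^beta
# exp(-w^gamma); with symmetry parameter gamma = 3 and time-bandwidth
# product P^2 = 60 (so beta = 20) it matches the standard analytic wavelet
# used for nonstationary biomedical vibration signals. Wavelets are peak
# (L-infinity) normalized; every downstream biomarker is a ratio or
# normalized moment, so the amplitude convention is non-critical (asserted
# by a property test).

#' Morse wavelet and filter-bank parameters
#'
#' @param gamma Symmetry parameter (3 gives the most symmetric,
#'   Airy-family wavelet).
#' @param time_bandwidth Time-bandwidth product P^2; `beta` is derived as
#'   `time_bandwidth / gamma`.
#' @param voices_per_octave Number of center frequencies per octave.
#' @param f_min_hz,f_max_hz Analysis band limits in Hz.
#' @return List of class `morse_params` (with derived `beta`).
#' @export
morse_params <- function(gamma = 3, time_bandwidth = 60,
                         voices_per_octave = 12,
                         f_min_hz = 5, f_max_hz = 60) {
  if (gamma <= 0) stop("gamma must be positive")
  beta <- time_bandwidth / gamma
  if (beta <= 0) stop("time_bandwidth must be positive")
  if (f_min_hz <= 0 || f_min_hz >= f_max_hz)
    stop("analysis band must satisfy 0 < f_min < f_max")
  structure(list(gamma = gamma, time_bandwidth = time_bandwidth,
                 beta = beta, voices_per_octave = voices_per_octave,
                 f_min_hz = f_min_hz, f_max_hz = f_max_hz),
            class = "morse_params")
}

#' Morse wavelet frequency response
#'
#' Evaluates the peak-normalized analytic Morse spectrum
#' `Psi(w) = c w^beta exp(-w^gamma)` for `w >= 0` (zero for `w < 0`),
#' normalized so the maximum value 1 is attained at the peak frequency
#' `w_peak = (beta/gamma)^(1/gamma)`.
#'
#' @param omega Nonnegative angular frequencies (radians/sample or any
#'   consistent unit).
#' @param params A [morse_params()].
#' @return Numeric vector of responses in \[0, 1\].
#' @export
morse_freq_response <- function(omega, params = morse_params()) {
  g <- params$gamma
  b <- params$beta
  w_peak <- (b / g)^(1 / g)
  out <- numeric(length(omega))
  pos <- omega > 0
  # log-domain evaluation avoids overflow of w^beta for large beta
  out[pos] <- exp(b * (log(omega[pos]) - log(w_peak)) -
                    (omega[pos]^g - w_peak^g))
  out
}

#' Peak angular frequency of the Morse wavelet
#' @param params A [morse_params()].
#' @return `(beta/gamma)^(1/gamma)`.
#' @export
morse_peak_omega <- function(params = morse_params()) {
  (params$beta / params$gamma)^(1 / params$gamma)
}

#' Build the Morse CWT filter bank
#'
#' Constructs logarithmically spaced center frequencies spanning
#' `[f_min_hz, f_max_hz]` at `voices_per_octave` voices per octave
#' (anchored at `f_max_hz`, `ceil(V log2(f_max/f_min)) + 1` rows) and the
#' corresponding analytic wavelet spectra sampled on the FFT grid of the
#' internally padded segment length (`2 * n_samples`, symmetric reflection
#' padding in [cwt_morse()]).
#'
#' @param fs Sampling rate in Hz.
#' @param n_samples Segment length in samples.
#' @param params A [morse_params()].
#' @return List of class `morse_filterbank`: `filters` (n_freqs x 2n
#'   matrix of real spectra), `freqs_hz` (ascending), `fs`, `n_samples`,
#'   `params`.
#' @export
morse_filterbank <- function(fs, n_samples, params = morse_params()) {
  if (n_samples < 64) stop("segment too short for a filter bank (need >= 64 samples)")
  if (params$f_max_hz >= fs / 2)
    stop("analysis band must lie below Nyquist (", fs / 2, " Hz)")
  v <- params$voices_per_octave
  n_oct <- log2(params$f_max_hz / params$f_min_hz)
  n_freq <- floor(v * n_oct) + 1   # rows at fmax * 2^(-j/v) down to fmin
  freqs <- params$f_max_hz * 2^(-(rev(seq_len(n_freq)) - 1) / v)  # ascending
  m <- 2L * as.integer(n_samples)
  k <- 0:(m - 1)
  omega <- 2 * pi * k / m
  omega[k > m / 2] <- 0          # negative-frequency half: response forced 0
  w_peak <- morse_peak_omega(params)
  filters <- matrix(0, nrow = n_freq, ncol = m)
  for (i in seq_len(n_freq)) {
    s <- w_peak / (2 * pi * freqs[i] / fs)   # scale placing peak at freqs[i]
    row <- morse_freq_response(s * omega, params)
    row[k > m / 2] <- 0
    filters[i, ] <- row
  }
  structure(list(filters = filters, tfilters = t(filters),
                 freqs_hz = freqs, fs = fs,
                 n_samples = as.integer(n_samples), params = params),
            class = "morse_filterbank")
}

#' Continuous wavelet transform of one segment
#'
#' Computes complex CWT coefficients by multiplying the segment's spectrum
#' with each wavelet row and inverse-transforming. The segment is extended
#' to double length by symmetric reflection on both sides and the central
#' half retained, suppressing circular wrap-around at the boundaries.
#'
#' @param segment Numeric vector whose length matches the bank's
#'   `n_samples`.
#' @param bank A [morse_filterbank()].
#' @return Complex matrix `n_freqs x n_samples`.
#' @export
cwt_morse <- function(segment, bank) {
  n <- bank$n_samples
  if (length(segment) != n)
    stop("segment length ", length(segment),
         " does not match filter bank length ", n)
  hl <- floor(n / 2)
  hr <- n - hl
  y <- c(rev(segment[seq_len(hl)]), segment,
         rev(segment[(n - hr + 1):n]))
  m <- 2L * n
  spec <- stats::fft(y)
  prod <- bank$tfilters * spec            # m x n_freqs; spec recycles down
  coef <- stats::mvfft(prod, inverse = TRUE) / m
  t(coef[(hl + 1):(hl + n), , drop = FALSE])
}

#' Magnitude scalogram restricted to the analysis band
#'
#' Takes the elementwise modulus of the CWT coefficients and keeps the
#' frequency rows inside the configured analysis band.
#'
#' @param coeffs Complex coefficient matrix from [cwt_morse()].
#' @param bank The [morse_filterbank()] that produced the coefficients.
#' @return List of class `scalogram`: `magnitude` (n_freqs x n_times,
#'   ascending frequency), `freqs_hz`, `times_s`, `fs`.
#' @export
magnitude_scalogram <- function(coeffs, bank) {
  keep <- bank$freqs_hz >= bank$params$f_min_hz &
    bank$freqs_hz <= bank$params$f_max_hz
  mag <- Mod(coeffs[keep, , drop = FALSE])
  structure(list(magnitude = mag, freqs_hz = bank$freqs_hz[keep],
                 times_s = (seq_len(ncol(mag)) - 1) / bank$fs,
                 fs = bank$fs),
            class = "scalogram")
}

#' Scalogram of one segment (convenience wrapper)
#'
#' @param segment Numeric vector.
#' @param bank A [morse_filterbank()] matching the segment length.
#' @return A `scalogram`.
#' @export
segment_scalogram <- function(segment, bank) {
  magnitude_scalogram(cwt_morse(segment, bank), bank)
}
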