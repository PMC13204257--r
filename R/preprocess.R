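# Preprocessing chain: wrap-around integer conversion -> decimation ->
# Butterworth band-pass (zero-phase) -> z-score -> Savitzky-Golay + centered
# moving average -> head discard -> fixed 4 s / 2 s hop segmentation.

#' Preprocessing parameters
#'
#' @param decim_factor Integer decimation factor (10 maps 24 kHz to 2.4 kHz).
#' @param bp_order Total Butterworth band-pass order (4 = 2 poles per edge).
#' @param bp_lo_hz,bp_hi_hz Band-pass -3 dB cutoffs in Hz.
#' @param savgol_window_s Savitzky-Golay window in seconds (rounded to an
#'   odd number of samples).
#' @param savgol_polyorder Savitzky-Golay polynomial order.
#' @param movavg_window_s Centered moving-average span in seconds.
#' @param discard_head_s Seconds discarded from the start of each recording.
#' @param win_s Segment length in seconds.
#' @param hop_s Segment hop in seconds.
#' @return List of class `preprocess_params`.
#' @export
preprocess_params <- function(decim_factor = 10, bp_order = 4,
                              bp_lo_hz = 0.5, bp_hi_hz = 75,
                              savgol_window_s = 0.021, savgol_polyorder = 3,
                              movavg_window_s = 0.005,
                              discard_head_s = 2, win_s = 4, hop_s = 2) {
  p <- list(decim_factor = as.integer(decim_factor), bp_order = bp_order,
            bp_lo_hz = bp_lo_hz, bp_hi_hz = bp_hi_hz,
            savgol_window_s = savgol_window_s,
            savgol_polyorder = savgol_polyorder,
            movavg_window_s = movavg_window_s,
            discard_head_s = discard_head_s, win_s = win_s, hop_s = hop_s)
  if (p$decim_factor < 1) stop("decim_factor must be >= 1")
  if (p$bp_lo_hz <= 0 || p$bp_lo_hz >= p$bp_hi_hz)
    stop("band-pass cutoffs must satisfy 0 < lo < hi")
  if (p$hop_s > p$win_s) stop("hop_s must be <= win_s")
  if (p$bp_order %% 2 != 0) stop("bp_order must be even (poles split between edges)")
  structure(p, class = "preprocess_params")
}

#' Convert fixed-width integer counts to reals with wrap-around handling
#'
#' Reinterprets raw ADC counts as two's-complement values of the stated bit
#' width, then unwraps overflow events: any jump between adjacent samples
#' larger than half the representable range is treated as a counter
#' wrap-around and corrected by the full range.
#'
#' @param raw Integer-valued vector of raw counts.
#' @param bit_width One of 16, 24, 32.
#' @return Numeric vector of unwrapped values.
#' @export
wraparound_to_float <- function(raw, bit_width = 24) {
  if (!bit_width %in% c(16, 24, 32))
    stop("unsupported bit_width: ", bit_width, " (expected 16, 24 or 32)")
  full <- 2^bit_width
  half <- 2^(bit_width - 1)
  v <- as.numeric(raw) %% full
  v[v >= half] <- v[v >= half] - full   # two's-complement reinterpretation
  if (length(v) < 2) return(v)
  d <- diff(v)
  corr <- numeric(length(d))
  corr[d > half] <- -full
  corr[d < -half] <- full
  v + c(0, cumsum(corr))
}

#' Decimate a signal with anti-alias filtering
#'
#' Applies a maximally flat (Butterworth) anti-alias low-pass at 0.8 of the
#' target Nyquist, forward-backward for zero phase and a ripple-free
#' passband, then keeps every `factor`-th sample.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param factor Integer decimation factor.
#' @return List with `samples` and the new `fs = fs / factor`.
#' @export
decimate_signal <- function(x, fs, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("decimation factor must be >= 1")
  if (length(x) < factor) stop("signal shorter than one decimation step")
  if (factor == 1) return(list(samples = x, fs = fs))
  aa <- signal::butter(4, 0.8 / factor, type = "low")
  y <- signal::filtfilt(aa, x)
  list(samples = y[seq(1, length(y), by = factor)], fs = fs / factor)
}

butter_bandpass <- function(fs, params) {
  ny <- fs / 2
  if (params$bp_hi_hz >= ny)
    stop("band-pass upper cutoff ", params$bp_hi_hz,
         " Hz is not below Nyquist (", ny, " Hz)")
  signal::butter(params$bp_order / 2,
                 c(params$bp_lo_hz, params$bp_hi_hz) / ny, type = "pass")
}

#' Butterworth band-pass filter (zero phase)
#'
#' Designs the band-pass at the stated total order with -3 dB points at the
#' configured cutoffs and applies it forward-backward (zero phase) so pulse
#' morphology is preserved.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param params A [preprocess_params()].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, params = preprocess_params()) {
  flt <- butter_bandpass(fs, params)
  as.numeric(signal::filtfilt(flt, x))
}

#' Z-score normalization
#'
#' @param x Numeric signal with nonzero variance.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant (zero-variance) signal")
  (x - mean(x)) / s
}

#' Savitzky-Golay plus centered moving-average smoothing
#'
#' Applies a Savitzky-Golay filter (window rounded to an odd number of
#' samples) followed by a centered moving average; both passes use edge
#' replication so the output length equals the input length and no phase
#' shift is introduced.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param params A [preprocess_params()].
#' @return Smoothed signal, same length as `x`.
#' @export
smooth_signal <- function(x, fs, params = preprocess_params()) {
  sg_n <- max(params$savgol_polyorder + 2, round(params$savgol_window_s * fs))
  if (sg_n %% 2 == 0) sg_n <- sg_n + 1
  if (sg_n <= params$savgol_polyorder)
    stop("Savitzky-Golay window (", sg_n,
         " samples) must exceed the polynomial order")
  if (sg_n >= length(x)) stop("smoothing window longer than signal")
  half <- (sg_n - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- signal::sgolayfilt(xp, p = params$savgol_polyorder, n = sg_n)
  y <- y[(half + 1):(half + length(x))]

  ma_n <- max(1, round(params$movavg_window_s * fs))
  if (ma_n %% 2 == 0) ma_n <- ma_n + 1
  if (ma_n > 1) {
    half <- (ma_n - 1) / 2
    yp <- c(rep(y[1], half), y, rep(y[length(y)], half))
    y <- as.numeric(stats::filter(yp, rep(1 / ma_n, ma_n), sides = 2))
    y <- y[(half + 1):(half + length(x))]
  }
  y
}

#' Split a signal into fixed-length overlapping segments
#'
#' Discards the first `discard_head_s` seconds (initialization transient),
#' then cuts `win_s`-second windows advancing by `hop_s`; only complete
#' windows are retained.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param params A [preprocess_params()].
#' @return Matrix with one row per segment (`n_segments x win_samples`),
#'   with attribute `segment_times` (start offsets in seconds, relative to
#'   the original recording). Zero rows if no complete window fits.
#' @export
segment_signal <- function(x, fs, params = preprocess_params()) {
  head_n <- round(params$discard_head_s * fs)
  win_n <- round(params$win_s * fs)
  hop_n <- round(params$hop_s * fs)
  body <- if (head_n < length(x)) x[(head_n + 1):length(x)] else numeric(0)
  n_seg <- if (length(body) >= win_n) {
    floor((length(body) - win_n) / hop_n) + 1
  } else 0L
  if (n_seg == 0) {
    warning("recording too short for a complete segment")
    m <- matrix(numeric(0), nrow = 0, ncol = win_n)
    attr(m, "segment_times") <- numeric(0)
    return(m)
  }
  starts <- (seq_len(n_seg) - 1) * hop_n
  m <- t(vapply(starts, function(s) body[(s + 1):(s + win_n)],
                numeric(win_n)))
  attr(m, "segment_times") <- params$discard_head_s + starts / fs
  m
}

#' Preprocess one recording into an analysis segment set
#'
#' Runs the full chain: wrap-around conversion (integer input only),
#' decimation, Butterworth band-pass, z-score, Savitzky-Golay + moving
#' average smoothing, head discard and segmentation. The segment set carries
#' the (patient, side) group key: both recording positions of a side pool
#' into the same group.
#'
#' @param recording A `carotid_recording` (or any list with `samples`, `fs`,
#'   `patient_id`, `side`, `position`, `label`).
#' @param params A [preprocess_params()]. Set `decim_factor` so that
#'   `fs / decim_factor` equals the 2.4 kHz analysis rate; the default 10
#'   matches 24 kHz input. Use [auto_decim_params()] to adapt to fast-mode
#'   cohorts.
#' @param bit_width Bit width for wrap-around conversion when `samples` is
#'   integer-typed; float input bypasses conversion.
#' @return A `segment_set`: list with `segments` (matrix), `fs`,
#'   `group_key`, `patient_id`, `side`, `position`, `label`, `severity`,
#'   `segment_times`.
#' @export
preprocess_recording <- function(recording, params = preprocess_params(),
                                 bit_width = 24) {
  x <- recording$samples
  if (is.integer(x)) x <- wraparound_to_float(x, bit_width)
  dec <- decimate_signal(x, recording$fs, params$decim_factor)
  y <- bandpass_filter(dec$samples, dec$fs, params)
  y <- zscore(y)
  y <- smooth_signal(y, dec$fs, params)
  segs <- segment_signal(y, dec$fs, params)
  structure(list(segments = segs, fs = dec$fs,
                 group_key = paste(recording$patient_id, recording$side,
                                   sep = "_"),
                 patient_id = recording$patient_id, side = recording$side,
                 position = recording$position,
                 label = recording$label,
                 severity = recording$severity,
                 segment_times = attr(segs, "segment_times")),
            class = "segment_set")
}

#' Preprocessing parameters adapted to the recording rate
#'
#' Picks the decimation factor mapping `fs` onto the 2.4 kHz analysis rate
#' (factor 1 for fast-mode cohorts already generated at 2.4 kHz).
#'
#' @param fs Raw sampling rate in Hz.
#' @param ... Passed to [preprocess_params()].
#' @return A `preprocess_params` object.
#' @export
auto_decim_params <- function(fs, ...) {
  preprocess_params(decim_factor = max(1L, as.integer(round(fs / 2400))), ...)
}
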