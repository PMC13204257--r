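test_that("wrap-around conversion reinterprets and unwraps counter overflow", {
  # constant and zero sequences pass through unchanged
  expect_equal(wraparound_to_float(rep(5L, 10), 16), rep(5, 10))
  expect_equal(wraparound_to_float(rep(0L, 8), 24), rep(0, 8))
  # two-sample overflow: top of range to bottom unwraps to a +1 step
  for (w in c(16, 24, 32)) {
    top <- 2^(w - 1) - 1
    bottom <- -2^(w - 1)
    out <- wraparound_to_float(c(top, bottom), w)
    expect_equal(diff(out), 1)
  }
  # a ramp crossing the wrap point repeatedly stays a ramp
  w <- 16
  true_ramp <- seq(30000, 40000, by = 250)
  wrapped <- ((true_ramp + 2^15) %% 2^16) - 2^15
  expect_equal(wraparound_to_float(wrapped, w), true_ramp)
  expect_error(wraparound_to_float(1:4, 12), "bit_width")
})

test_that("decimation maps 24 kHz to 2.4 kHz and preserves in-band tones", {
  fs <- 24000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5 * t)
  out <- decimate_signal(x, fs, 10)
  expect_equal(out$fs, 2400)
  expect_equal(length(out$samples), length(x) / 10)
  # FFT-peak amplitude oracle: 5 Hz tone preserved within 1%
  spec <- Mod(stats::fft(out$samples)) / length(out$samples) * 2
  f <- (seq_along(out$samples) - 1) * out$fs / length(out$samples)
  peak_bin <- which.max(spec[f <= out$fs / 2])
  expect_equal(f[peak_bin], 5, tolerance = 1e-6)
  expect_equal(spec[peak_bin], 1, tolerance = 0.01)
  # identity factor
  out1 <- decimate_signal(x, fs, 1)
  expect_identical(out1$samples, x)
  expect_identical(out1$fs, fs)
})

test_that("Butterworth band-pass hits -3 dB at the design cutoffs", {
  fs <- 2400
  p <- preprocess_params()
  flt <- carotidscreen:::butter_bandpass(fs, p)
  # single-pass magnitude response at the cutoffs
  resp <- function(f_hz) {
    w <- 2 * pi * f_hz / fs
    z <- exp(1i * w)
    num <- sum(flt$b * z^-(seq_along(flt$b) - 1))
    den <- sum(flt$a * z^-(seq_along(flt$a) - 1))
    20 * log10(Mod(num / den))
  }
  expect_equal(resp(0.5), -3.0103, tolerance = 0.1)  # -3 dB = 20log10(1/sqrt(2))
  expect_equal(resp(75), -3.0103, tolerance = 0.1)
})

test_that("band-pass rejects DC, preserves mid-band tones, and is zero-phase", {
  fs <- 2400
  # DC rejection (interior chosen past the 0.5 Hz high-pass transients)
  y <- bandpass_filter(rep(1, 20 * fs), fs)
  interior <- y[(9 * fs):(11 * fs)]
  expect_lt(max(abs(interior)), 1e-3)
  # 30 Hz mid-band tone: the single-pass design loses ~1.3% at 30 Hz to
  # the 75 Hz edge, squared by the zero-phase (forward-backward) pass
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 30 * t)
  y <- bandpass_filter(x, fs)
  spec <- Mod(stats::fft(y)) / length(y) * 2
  f <- (seq_along(y) - 1) * fs / length(y)
  expect_equal(spec[which.min(abs(f - 30))], 1, tolerance = 0.03)
  cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # cutoffs at or above Nyquist rejected
  expect_error(bandpass_filter(x, 100, preprocess_params()), "Nyquist")
})

test_that("z-score normalizes and is affine-invariant", {
  set.seed(42)
  x <- rnorm(1000, mean = 3, sd = 7)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  expect_equal(zscore(2.5 * x - 11), z, tolerance = 1e-9)
  expect_error(zscore(rep(1, 10)), "constant")
})

test_that("smoothing reproduces low-degree polynomials and reduces noise", {
  fs <- 2400
  p <- preprocess_params(movavg_window_s = 0)  # Savitzky-Golay pass alone
  t <- seq_len(fs) / fs
  x <- 2 + 3 * t - 5 * t^2 + t^3               # degree <= polyorder (3)
  y <- smooth_signal(x, fs, p)
  interior <- 100:(fs - 100)
  expect_equal(y[interior], x[interior], tolerance = 1e-8)
  # constant preserved by the full chain
  p2 <- preprocess_params()
  expect_equal(smooth_signal(rep(2, fs), fs, p2), rep(2, fs),
               tolerance = 1e-10)
  # variance strictly reduced on white noise, across seeds
  for (s in 1:10) {
    set.seed(s)
    w <- rnorm(fs)
    expect_lt(stats::var(smooth_signal(w, fs, p2)), stats::var(w))
  }
})

test_that("segmentation counts complete windows after the head discard", {
  fs <- 100
  p <- preprocess_params()
  segs <- segment_signal(rnorm(60 * fs), fs, p)
  expect_equal(nrow(segs), 28)                    # floor((58-4)/2)+1
  expect_equal(ncol(segs), 4 * fs)
  expect_equal(nrow(segment_signal(rnorm(6 * fs), fs, p)), 1)
  expect_warning(s0 <- segment_signal(rnorm(5.9 * fs), fs, p), "too short")
  expect_equal(nrow(s0), 0)
})

test_that("segment count matches a brute-force window enumerator", {
  brute_count <- function(n_body, win_n, hop_n) {
    count <- 0
    start <- 0
    while (start + win_n <= n_body) {
      count <- count + 1
      start <- start + hop_n
    }
    count
  }
  fs <- 50
  set.seed(7)
  for (i in 1:25) {
    T_s <- runif(1, 5, 40)
    win <- sample(2:6, 1)
    hop <- sample(1:win, 1)
    p <- preprocess_params(win_s = win, hop_s = hop)
    x <- rnorm(round(T_s * fs))
    n_body <- length(x) - round(p$discard_head_s * fs)
    expected <- brute_count(n_body, win * fs, hop * fs)
    got <- if (expected == 0) {
      suppressWarnings(nrow(segment_signal(x, fs, p)))
    } else nrow(segment_signal(x, fs, p))
    expect_equal(got, expected)
  }
})

test_that("full chain yields 2.4 kHz 4 s segments with pooled group keys", {
  cfg <- cohort_config(n_patients = 1, duration_s = 60, fs_raw = 24000,
                       seed = 5)
  ch <- generate_cohort(cfg)
  ss1 <- preprocess_recording(ch$recordings[[1]], preprocess_params())
  expect_equal(ss1$fs, 2400)
  expect_equal(nrow(ss1$segments), 28)
  expect_equal(ncol(ss1$segments), 9600)          # 4 s x 2400 Hz
  # both positions of a side share the group key
  ss2 <- preprocess_recording(ch$recordings[[2]], preprocess_params())
  expect_identical(ss1$group_key, ss2$group_key)
  expect_identical(ss1$group_key, paste0(ch$recordings[[1]]$patient_id, "_",
                                         ch$recordings[[1]]$side))
})

test_that("preprocessing is invariant to positive amplitude scaling", {
  cfg <- cohort_config(n_patients = 1, duration_s = 10, fs_raw = 2400,
                       seed = 9)
  rec <- generate_cohort(cfg)$recordings[[1]]
  p <- auto_decim_params(2400)
  a <- preprocess_recording(rec, p)
  rec$samples <- 7.3 * rec$samples
  b <- preprocess_recording(rec, p)
  expect_equal(a$segments, b$segments, tolerance = 1e-9)
})
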