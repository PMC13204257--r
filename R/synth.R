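#' @keywords internal
"_PACKAGE"

# ---- seeded substreams -------------------------------------------------

# Deterministic 31-bit polynomial hash of strings; used to derive
# per-recording RNG substreams so cohort generation is independent of
# insertion order.
stable_hash <- function(...) {
  s <- paste(vapply(list(...), as.character, ""), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

derive_seed <- function(master_seed, ...) {
  h <- stable_hash(...)
  as.integer((as.numeric(master_seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# ---- configuration -----------------------------------------------------

#' Configuration for the synthetic carotid cohort generator
#'
#' Builds and validates the parameter set controlling a simulated bilateral
#' cohort of neck-surface vibration recordings. Each carotid side is
#' pathological with probability `prevalence_side`; pathological sides carry
#' a severity drawn from `severity_range` (analogue of percent stenosis,
#' label positive at severity >= 0.5, mirroring the clinical >=50% cut),
#' lower-stenosis sides a severity below the cut. Every recording is a
#' cardiac-cycle-locked train of damped low-frequency systolic pulses plus,
#' in proportion to severity, bursts of band-limited turbulence noise in
#' `turbulence_band`, on top of sensor noise and slow baseline drift.
#'
#' @param n_patients Number of patients (each contributes 2 sides x
#'   `positions_per_side` recordings).
#' @param prevalence_side Probability that a carotid side is pathological.
#' @param severity_range Severity interval for pathological sides, within
#'   \[0.5, 1\] by default.
#' @param nonpath_severity_max Upper severity bound for lower-stenosis sides.
#' @param heart_rate_bpm Length-2 vector (mean, SD) of per-patient heart
#'   rate in beats per minute.
#' @param duration_s Recording duration in seconds.
#' @param fs_raw Sampling rate in Hz. 24000 exercises the full decimation
#'   front end; 2400 is the fast mode (flagged in the cohort manifest).
#' @param pulse_center_freq_hz Length-2 range (Hz) from which each patient's
#'   systolic pulse oscillation frequency is drawn.
#' @param turbulence_band Length-2 (lo, hi) Hz band of the pathology burst.
#' @param turbulence_gain Burst amplitude multiplier per unit severity.
#' @param noise_sd Sensor white-noise standard deviation.
#' @param drift_amp Amplitude of the sub-0.5 Hz baseline drift component.
#' @param positions_per_side Recording positions per side (upper/lower neck).
#' @param position_gain_jitter Relative gain perturbation applied to
#'   positions beyond the first.
#' @param beat_jitter Relative SD of beat-to-beat interval variability.
#' @param seed Master RNG seed; per-recording substreams are derived by
#'   stable hashing of (patient, side, position).
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_patients = 2, duration_s = 8, fs_raw = 2400)
#' @export
cohort_config <- function(n_patients = 60,
                          prevalence_side = 0.3,
                          severity_range = c(0.5, 1),
                          nonpath_severity_max = 0.35,
                          heart_rate_bpm = c(70, 8),
                          duration_s = 60,
                          fs_raw = 24000,
                          pulse_center_freq_hz = c(6, 10.5),
                          turbulence_band = c(20, 40),
                          turbulence_gain = 1.2,
                          noise_sd = 0.3,
                          drift_amp = 0.3,
                          positions_per_side = 2,
                          position_gain_jitter = 0.1,
                          beat_jitter = 0.03,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              prevalence_side = prevalence_side,
              severity_range = severity_range,
              nonpath_severity_max = nonpath_severity_max,
              heart_rate_bpm = heart_rate_bpm,
              duration_s = duration_s, fs_raw = fs_raw,
              pulse_center_freq_hz = pulse_center_freq_hz,
              turbulence_band = turbulence_band,
              turbulence_gain = turbulence_gain,
              noise_sd = noise_sd, drift_amp = drift_amp,
              positions_per_side = as.integer(positions_per_side),
              position_gain_jitter = position_gain_jitter,
              beat_jitter = beat_jitter,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid cohort_config field '", field, "': ", msg, call. = FALSE)
  }
  if (!is.finite(cfg$n_patients) || cfg$n_patients < 1)
    fail("n_patients", "must be a positive integer")
  if (cfg$prevalence_side < 0 || cfg$prevalence_side > 1)
    fail("prevalence_side", "must lie in [0, 1]")
  sr <- cfg$severity_range
  if (length(sr) != 2 || sr[1] > sr[2] || sr[1] < 0 || sr[2] > 1)
    fail("severity_range", "must be an interval within [0, 1]")
  if (sr[1] < 0.5)
    fail("severity_range", "pathological severities must be >= 0.5 (label cut)")
  if (cfg$nonpath_severity_max < 0 || cfg$nonpath_severity_max >= 0.5)
    fail("nonpath_severity_max", "must lie in [0, 0.5)")
  if (cfg$duration_s <= 0) fail("duration_s", "must be positive")
  if (cfg$fs_raw <= 0) fail("fs_raw", "must be positive")
  tb <- cfg$turbulence_band
  if (length(tb) != 2 || tb[1] <= 0 || tb[1] >= tb[2] || tb[2] >= cfg$fs_raw / 2)
    fail("turbulence_band", "must satisfy 0 < lo < hi < fs_raw/2")
  pf <- cfg$pulse_center_freq_hz
  if (length(pf) != 2 || pf[1] <= 0 || pf[1] > pf[2] || pf[2] >= cfg$fs_raw / 2)
    fail("pulse_center_freq_hz", "must satisfy 0 < lo <= hi < fs_raw/2")
  if (cfg$positions_per_side < 1)
    fail("positions_per_side", "must be >= 1")
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (cfg$turbulence_gain < 0) fail("turbulence_gain", "must be >= 0")
  invisible(cfg)
}

# ---- per-patient physiology -------------------------------------------

draw_physiology <- function(patient_id, cfg) {
  with_seed(derive_seed(cfg$seed, "phys", patient_id), {
    hr <- max(40, stats::rnorm(1, cfg$heart_rate_bpm[1], cfg$heart_rate_bpm[2]))
    fp <- stats::runif(1, cfg$pulse_center_freq_hz[1], cfg$pulse_center_freq_hz[2])
    # pulse waveform morphology varies between patients: harmonic content
    # (energy up to ~3 x pulse frequency), decay time, and a benign
    # patient-specific systolic flow-murmur level in the low-20s Hz range
    h2 <- stats::runif(1, 0, 0.8)
    h3 <- stats::runif(1, 0, 0.5)
    tau <- stats::runif(1, 0.06, 0.16)
    # level kept in a narrow range: the benign variability that matters is
    # where the murmur sits in frequency, not how loud it is
    murmur <- stats::runif(1, 0.4, 0.9)
    mur_lo <- stats::runif(1, 8, 16)
    mur_hi <- min(30, mur_lo + stats::runif(1, 8, 14))
    list(heart_rate_bpm = hr, pulse_freq_hz = fp, harmonic2 = h2,
         harmonic3 = h3, pulse_tau = tau, murmur_amp = murmur,
         murmur_band = c(mur_lo, mur_hi))
  })
}

draw_truth <- function(patient_id, side, cfg) {
  with_seed(derive_seed(cfg$seed, "truth", patient_id, side), {
    path <- stats::runif(1) < cfg$prevalence_side
    sev <- if (path) {
      stats::runif(1, cfg$severity_range[1], cfg$severity_range[2])
    } else {
      stats::runif(1, 0, cfg$nonpath_severity_max)
    }
    # per-side turbulence sub-band within the configured band: onset varies
    # (stenosis-like elevation starting near 20 Hz through dissection-like
    # bands starting ~25 Hz), always extending into the upper part of the
    # band as the reported phenotypes do
    tb <- cfg$turbulence_band
    span <- tb[2] - tb[1]
    lo <- stats::runif(1, tb[1] + 0.3 * span, tb[1] + 0.5 * span)
    hi <- stats::runif(1, tb[2] - 0.3 * span, tb[2])
    list(patient_id = patient_id, side = side, severity = sev,
         label = as.integer(sev >= 0.5), burst_band = c(lo, hi))
  })
}

# ---- signal synthesis --------------------------------------------------

# Band-limited Gaussian noise via spectral masking: white noise is
# transformed, bins outside [lo, hi] Hz are zeroed with raised-cosine edge
# tapers (1 Hz wide), and the result inverse-transformed. Numerically
# stable at any sampling rate, unlike a very-narrow-band IIR design at
# 24 kHz.
bandlimited_noise <- function(n, fs, lo, hi, taper_hz = 1) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  mask <- rep(0, n)
  core <- freq >= lo & freq <= hi
  mask[core] <- 1
  rising <- freq > lo - taper_hz & freq < lo
  mask[rising] <- 0.5 * (1 + cos(pi * (lo - freq[rising]) / taper_hz))
  falling <- freq > hi & freq < hi + taper_hz
  mask[falling] <- 0.5 * (1 + cos(pi * (freq[falling] - hi) / taper_hz))
  x <- Re(stats::fft(spec * mask, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Synthesize one carotid vibration recording
#'
#' Generates a single-channel acceleration trace for one (patient, side,
#' position): a train of exponentially damped systolic pulse oscillations at
#' the patient's pulse frequency, plus severity-scaled bursts of
#' band-limited turbulence noise windowed over each systolic interval, plus
#' white sensor noise and slow baseline drift. Random components are drawn
#' in a fixed order from the recording's derived substream, so recordings
#' that share (patient, side, position) differ between severities only
#' through the turbulence amplitude.
#'
#' @param truth List with `patient_id`, `side`, `severity`, `label` (see
#'   [generate_cohort()]).
#' @param phys Per-patient physiology list (`heart_rate_bpm`,
#'   `pulse_freq_hz`), shared across that patient's recordings.
#' @param position Recording position (1 = upper neck, 2 = lower).
#' @param config A [cohort_config()].
#' @return A `carotid_recording`: list with `samples`, `fs`, `patient_id`,
#'   `side`, `position`, `severity`, `label`.
#' @export
generate_recording <- function(truth, phys, position, config) {
  cfg <- config
  stopifnot(truth$severity >= 0, truth$severity <= 1)
  fs <- cfg$fs_raw
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  seed <- derive_seed(cfg$seed, "rec", truth$patient_id, truth$side, position)
  with_seed(seed, {
    period <- 60 / phys$heart_rate_bpm
    n_beats <- ceiling(cfg$duration_s / period) + 2
    gaps <- period * (1 + cfg$beat_jitter * stats::rnorm(n_beats))
    beat_t <- stats::runif(1, 0, period) + cumsum(c(0, gaps[-n_beats]))
    beat_t <- beat_t[beat_t < cfg$duration_s]
    beat_amp <- 1 + 0.1 * stats::rnorm(length(beat_t))

    x <- numeric(n)
    tau <- if (is.null(phys$pulse_tau)) 0.10 else phys$pulse_tau
    pulse_len <- round(0.5 * fs)      # pulse support, 0.5 s
    for (k in seq_along(beat_t)) {
      i0 <- floor(beat_t[k] * fs) + 1
      idx <- i0:min(i0 + pulse_len - 1, n)
      tt <- t[idx] - beat_t[k]
      h2 <- if (is.null(phys$harmonic2)) 0 else phys$harmonic2
      h3 <- if (is.null(phys$harmonic3)) 0 else phys$harmonic3
      x[idx] <- x[idx] + beat_amp[k] * exp(-tt / tau) *
        (sin(2 * pi * phys$pulse_freq_hz * tt) +
           h2 * sin(4 * pi * phys$pulse_freq_hz * tt) +
           h3 * sin(6 * pi * phys$pulse_freq_hz * tt))
    }

    # turbulence burst: always drawn (fixed RNG order), scaled by severity;
    # each side carries its own phenotype sub-band within the config band
    bb <- if (is.null(truth$burst_band)) cfg$turbulence_band else
      truth$burst_band
    turb <- bandlimited_noise(n, fs, bb[1], bb[2])
    win <- numeric(n)
    b_start <- 0.08                   # burst onset after pulse, s
    b_len <- 0.25                     # burst duration, s
    wlen <- round(b_len * fs)
    for (k in seq_along(beat_t)) {
      i0 <- floor((beat_t[k] + b_start) * fs) + 1
      idx <- i0:min(i0 + wlen - 1, n)
      if (idx[1] > n) next
      win[idx] <- win[idx] +
        0.5 * (1 - cos(2 * pi * (seq_along(idx) - 1) / wlen))
    }
    # per-recording sensor-coupling variability of the burst amplitude
    coupling <- exp(0.25 * stats::rnorm(1))
    x <- x + truth$severity * cfg$turbulence_gain * coupling * turb * win

    # benign systolic flow murmur (patient-specific level, 12-28 Hz):
    # label-independent mid-frequency content below the upper half-band
    mur_amp <- if (is.null(phys$murmur_amp)) 0 else phys$murmur_amp
    if (mur_amp > 0) {
      mb <- if (is.null(phys$murmur_band)) c(10, 28) else phys$murmur_band
      mur <- bandlimited_noise(n, fs, mb[1], mb[2])
      x <- x + mur_amp * mur * win
    }

    x <- x + cfg$noise_sd * stats::rnorm(n)
    f_drift <- stats::runif(1, 0.05, 0.3)
    x <- x + cfg$drift_amp * sin(2 * pi * f_drift * t + stats::runif(1, 0, 2 * pi))

    if (position > 1) {
      gain <- 1 + cfg$position_gain_jitter * stats::rnorm(1)
      x <- x * abs(gain)
    }
    structure(list(samples = x, fs = fs,
                   patient_id = truth$patient_id, side = truth$side,
                   position = as.integer(position),
                   severity = truth$severity, label = truth$label),
              class = "carotid_recording")
  })
}

#' Generate a synthetic bilateral cohort
#'
#' Draws per-patient physiology and per-side ground truth, then synthesizes
#' one recording per (patient, side, position). Deterministic given
#' `config$seed`; physiological parameters are shared across a patient's
#' recordings and ground truth across a side's positions.
#'
#' @param config A [cohort_config()].
#' @return List with `recordings` (list of `carotid_recording`) and `truth`
#'   (data.frame: patient_id, side, severity, label — one row per side).
#' @examples
#' ch <- generate_cohort(cohort_config(n_patients = 2, duration_s = 8,
#'                                     fs_raw = 2400))
#' length(ch$recordings)  # 2 patients x 2 sides x 2 positions = 8
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  truth_rows <- list()
  recordings <- list()
  for (pid in ids) {
    phys <- draw_physiology(pid, config)
    for (side in c("L", "R")) {
      tr <- draw_truth(pid, side, config)
      truth_rows[[paste(pid, side)]] <-
        data.frame(patient_id = pid, side = side, severity = tr$severity,
                   label = tr$label, stringsAsFactors = FALSE)
      for (pos in seq_len(config$positions_per_side)) {
        recordings[[length(recordings) + 1]] <-
          generate_recording(tr, phys, pos, config)
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(recordings = recordings, truth = truth)
}

# ---- cohort I/O --------------------------------------------------------

#' Write a cohort to disk
#'
#' Serializes each recording as a mono IEEE-float WAV plus a metadata CSV
#' (patient_id, side, position, severity, label, filename) and a JSON
#' manifest echoing the generator configuration (including the sampling
#' rate, which flags fast-mode cohorts) and the file list.
#'
#' @param recordings List of `carotid_recording`.
#' @param truth Ground-truth data.frame from [generate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @param config Optional [cohort_config()] echoed into the manifest.
#' @return Path to the manifest JSON, invisibly.
#' @export
write_cohort <- function(recordings, truth, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  meta <- do.call(rbind, lapply(recordings, function(r) {
    fn <- sprintf("%s_%s_pos%d.wav", r$patient_id, r$side, r$position)
    write_wav(r$samples, r$fs, file.path(out_dir, fn))
    data.frame(patient_id = r$patient_id, side = r$side,
               position = r$position, severity = r$severity,
               label = r$label, fs = r$fs, filename = fn,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  manifest <- list(
    config = if (is.null(config)) NULL else unclass(config),
    fast_mode = if (is.null(config)) NA else config$fs_raw < 24000,
    n_recordings = nrow(meta),
    files = meta$filename
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory containing `metadata.csv` and WAV files.
#' @return List with `recordings` and `truth`, as from [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "metadata.csv")
  if (!file.exists(mpath)) stop("no metadata.csv in cohort directory: ", dir)
  meta <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(meta)), function(i) {
    wav <- read_wav(file.path(dir, meta$filename[i]))
    structure(list(samples = wav$samples, fs = wav$fs,
                   patient_id = meta$patient_id[i], side = meta$side[i],
                   position = as.integer(meta$position[i]),
                   severity = meta$severity[i],
                   label = as.integer(meta$label[i])),
              class = "carotid_recording")
  })
  tpath <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tpath)) {
    utils::read.csv(tpath, stringsAsFactors = FALSE)
  } else {
    unique(meta[, c("patient_id", "side", "severity", "label")])
  }
  list(recordings = recordings, truth = truth)
}
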