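# Shared fixtures and independent oracles. Expensive cohort-derived feature
# tables are memoized so several test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

# Small fast-mode cohort feature table (generated at the 2.4 kHz analysis
# rate; decimation is exercised separately by the preprocessing tests).
cached_cohort_features <- function(n_patients = 16, duration_s = 10,
                                   seed = 101L) {
  key <- paste("ft", n_patients, duration_s, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cfg <- cohort_config(n_patients = n_patients, duration_s = duration_s,
                         fs_raw = 2400, seed = seed)
    ch <- generate_cohort(cfg)
    segsets <- lapply(ch$recordings, preprocess_recording,
                      params = auto_decim_params(2400))
    .fixture_cache[[key]] <- feature_table(segsets)
  }
  .fixture_cache[[key]]
}

# Scalogram object with arbitrary frequency grid and magnitude matrix, for
# closed-form feature oracles.
toy_scalogram <- function(freqs, magnitude) {
  structure(list(magnitude = magnitude, freqs_hz = freqs,
                 times_s = seq_len(ncol(magnitude)) - 1, fs = 1),
            class = "scalogram")
}

# Point mass: all energy in the row nearest f_target.
point_mass_scalogram <- function(f_target, freqs = seq(5, 60, by = 2.5),
                                 n_times = 8, value = 2) {
  m <- matrix(0, length(freqs), n_times)
  m[which.min(abs(freqs - f_target)), ] <- value
  toy_scalogram(freqs, m)
}

# Group-structured random feature frame (no signal pipeline): n_groups
# patient-sides, n_seg segments each, p features; feature 1 carries the
# class effect, plus a per-group random effect to make segments within a
# side correlated.
make_feature_frame <- function(n_groups = 40, n_seg = 6, p = 4,
                               effect = 2, group_sd = 0.5, seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, length.out = n_groups)
  rows <- lapply(seq_len(n_groups), function(g) {
    re <- rnorm(p, sd = group_sd)
    x <- matrix(rnorm(n_seg * p), n_seg, p) +
      matrix(re, n_seg, p, byrow = TRUE)
    x[, 1] <- x[, 1] + effect * labels[g]
    df <- as.data.frame(x)
    colnames(df) <- paste0("f", seq_len(p))
    cbind(data.frame(patient_id = sprintf("G%02d", g), side = "L",
                     position = 1, segment_index = seq_len(n_seg),
                     group_key = sprintf("G%02d_L", g),
                     severity = 0.5 * labels[g] + 0.2,
                     label = labels[g]),
          df)
  })
  do.call(rbind, rows)
}

# FFT-based band-energy fraction oracle: share of spectral power in
# [lo, hi] Hz relative to the power in [ref_lo, ref_hi] Hz.
fft_band_fraction <- function(x, fs, lo, hi, ref_lo = 5, ref_hi = 60) {
  n <- length(x)
  pw <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  pw <- pw[keep]
  f <- f[keep]
  sum(pw[f >= lo & f <= hi]) / sum(pw[f >= ref_lo & f <= ref_hi])
}

# Brute-force pairwise AUROC oracle (ties count one half).
brute_auroc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Brute-force BH step-up oracle.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  cummin_rev <- Inf
  for (i in m:1) {
    cummin_rev <- min(cummin_rev, p[ord[i]] * m / i)
    adj[ord[i]] <- min(1, cummin_rev)
  }
  adj
}

# Brute-force threshold scan used against select_threshold.
brute_threshold <- function(probs, labels, sens_min = 0.9) {
  u <- sort(unique(probs))
  cand <- c(u[1] - 1e-6, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1e-6)
  stats_at <- function(tt) {
    c(sens = sum(probs >= tt & labels == 1) / sum(labels == 1),
      spec = sum(probs < tt & labels == 0) / sum(labels == 0))
  }
  st <- t(vapply(cand, stats_at, c(sens = 0, spec = 0)))
  feas <- which(st[, "sens"] >= sens_min)
  best <- max(st[feas, "spec"])
  list(tau = min(cand[feas][st[feas, "spec"] == best]), spec = best)
}
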