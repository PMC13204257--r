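# Interpretable scalogram biomarkers. Energies integrate |W|^2 over grid
# cells; frequency-axis statistics (centroid, spread, roll-off) use the
# actual row frequencies in Hz, never row indices, since the grid is
# log-spaced. All features are ratios or normalized moments, hence
# invariant to positive scaling of the input signal and to the wavelet
# amplitude convention.

#' Feature extraction configuration
#'
#' @param band Analysis band (f_lo, f_hi) in Hz.
#' @param upper_fractions Fractional upper-band sizes q for the
#'   high-frequency energy ratios.
#' @param rolloff_quantiles Cumulative-energy quantiles for roll-off.
#' @param entropy_normalized Normalize spectral-image entropy by
#'   `log(n_cells)` so it lies in \[0, 1\].
#' @param sobel_log If `TRUE`, Sobel gradients are taken on
#'   `log1p`-compressed magnitude instead of raw magnitude (both scaled to
#'   \[0, 1\] first).
#' @return List of class `feature_config`; `core_set` names the six final
#'   biomarkers in reporting order.
#' @export
feature_config <- function(band = c(5, 60),
                           upper_fractions = c(0.3, 0.4, 0.5),
                           rolloff_quantiles = c(0.85, 0.95),
                           entropy_normalized = TRUE,
                           sobel_log = FALSE) {
  stopifnot(all(upper_fractions > 0 & upper_fractions < 1),
            all(rolloff_quantiles > 0 & rolloff_quantiles < 1))
  structure(list(band = band, upper_fractions = upper_fractions,
                 rolloff_quantiles = rolloff_quantiles,
                 entropy_normalized = entropy_normalized,
                 sobel_log = sobel_log,
                 core_set = c("hf_fraction_top50", "gini_sparsity",
                              "spectral_centroid_hz", "sobel_edge_energy",
                              "image_entropy", "spectral_spread_hz")),
            class = "feature_config")
}

#' Lower edge of a fractional upper band
#'
#' For an analysis band (f_lo, f_hi) and fraction q, the upper-q band is
#' `[f_hi - q (f_hi - f_lo), f_hi]`; e.g. the upper 50% of 5-60 Hz is
#' 32.5-60 Hz.
#'
#' @param f_lo,f_hi Band edges in Hz.
#' @param q Fraction in (0, 1).
#' @return Cut frequency in Hz.
#' @export
fractional_band_cut <- function(f_lo, f_hi, q) {
  if (!is.finite(q) || q <= 0 || q >= 1)
    stop("fraction q must lie strictly inside (0, 1)")
  if (f_lo >= f_hi) stop("band must satisfy f_lo < f_hi")
  f_hi - q * (f_hi - f_lo)
}

scal_energy <- function(scal) scal$magnitude^2

#' Band energy of a scalogram
#'
#' Sum of squared magnitudes over rows with `f_a <= f <= f_b`, all times.
#'
#' @param scal A `scalogram`.
#' @param f_a,f_b Band limits in Hz.
#' @return Nonnegative energy (0 with a warning if no rows fall in band).
#' @export
band_energy <- function(scal, f_a, f_b) {
  rows <- scal$freqs_hz >= f_a & scal$freqs_hz <= f_b
  if (!any(rows)) {
    warning("no frequency rows in [", f_a, ", ", f_b, "] Hz")
    return(0)
  }
  sum(scal_energy(scal)[rows, , drop = FALSE])
}

#' High-frequency energy ratio
#'
#' Energy above the fractional cut `f_cut(q)` normalized by total band
#' energy or by the complementary lower fraction.
#'
#' @param scal A `scalogram`.
#' @param q Upper-band fraction in (0, 1).
#' @param denominator `"total"` or `"lower"`.
#' @param band Analysis band used for the cut (defaults to the scalogram's
#'   frequency range endpoints from [feature_config()]).
#' @return Ratio in \[0, 1\] for `"total"`; nonnegative (possibly `Inf`)
#'   for `"lower"`.
#' @export
hf_ratio <- function(scal, q, denominator = c("total", "lower"),
                     band = c(5, 60)) {
  denominator <- match.arg(denominator)
  f_cut <- fractional_band_cut(band[1], band[2], q)
  e <- scal_energy(scal)
  upper <- scal$freqs_hz >= f_cut
  e_up <- sum(e[upper, , drop = FALSE])
  if (denominator == "total") {
    e_tot <- sum(e)
    if (e_tot <= 0) stop("zero total energy")
    e_up / e_tot
  } else {
    e_lo <- sum(e[!upper, , drop = FALSE])
    if (e_lo <= 0) {
      warning("zero lower-band energy; ratio undefined (+Inf)")
      return(Inf)
    }
    e_up / e_lo
  }
}

freq_marginal <- function(scal) {
  p <- rowSums(scal_energy(scal))
  tot <- sum(p)
  if (tot <= 0) stop("zero total energy")
  p / tot
}

#' Spectral centroid along the frequency axis
#' @param scal A `scalogram`.
#' @return Energy-weighted mean frequency in Hz.
#' @export
spectral_centroid <- function(scal) {
  sum(scal$freqs_hz * freq_marginal(scal))
}

#' Spectral spread along the frequency axis
#' @param scal A `scalogram`.
#' @return Energy-weighted frequency standard deviation in Hz.
#' @export
spectral_spread <- function(scal) {
  p <- freq_marginal(scal)
  c0 <- sum(scal$freqs_hz * p)
  sqrt(sum((scal$freqs_hz - c0)^2 * p))
}

#' Spectral roll-off frequency
#'
#' Lowest grid frequency at which the cumulative frequency-marginal energy
#' (accumulated upward from the bottom of the band) reaches `p` of the
#' total.
#'
#' @param scal A `scalogram`.
#' @param p Cumulative-energy quantile in (0, 1).
#' @return Frequency in Hz.
#' @export
spectral_rolloff <- function(scal, p) {
  stopifnot(p > 0, p < 1)
  marg <- freq_marginal(scal)
  cum <- cumsum(marg)
  scal$freqs_hz[which(cum >= p - 1e-12)[1]]
}

region_rows <- function(scal, region, q = 0.5, band = c(5, 60)) {
  f_cut <- fractional_band_cut(band[1], band[2], q)
  switch(region,
         full = rep(TRUE, length(scal$freqs_hz)),
         upper = scal$freqs_hz >= f_cut,
         lower = scal$freqs_hz < f_cut,
         stop("unknown region: ", region))
}

#' Spectral-image entropy
#'
#' Shannon entropy of the energy distribution over scalogram cells in a
#' region (full band, or upper/lower fractional band), optionally
#' normalized by `log(n_cells)` to \[0, 1\].
#'
#' @param scal A `scalogram`.
#' @param region `"full"`, `"upper"` or `"lower"`.
#' @param q Fraction defining the upper/lower split (default 0.5).
#' @param normalized Normalize to \[0, 1\].
#' @param band Analysis band for the split.
#' @return Entropy (nats, or unitless if normalized); `NA` if the region
#'   has zero energy.
#' @export
image_entropy <- function(scal, region = "full", q = 0.5, normalized = TRUE,
                          band = c(5, 60)) {
  rows <- region_rows(scal, region, q, band)
  s <- scal_energy(scal)[rows, , drop = FALSE]
  tot <- sum(s)
  if (tot <= 0) {
    warning("zero energy in region '", region, "'; entropy undefined")
    return(NA_real_)
  }
  p <- as.numeric(s) / tot
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (normalized) h / log(length(s)) else h
}

# Standard 3x3 Sobel pair ([[-1,0,1],[-2,0,2],[-1,0,1]] and transpose),
# evaluated in separable form ([1,2,1] smoothing x [-1,0,1] difference)
# with edge replication.
sobel_gradient_magnitude <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  up <- img[c(1, seq_len(nr - 1)), , drop = FALSE]      # row i-1, replicated
  dn <- img[c(seq_len(nr - 1) + 1, nr), , drop = FALSE] # row i+1
  sm_v <- up + 2 * img + dn                             # [1,2,1] over rows
  df_v <- dn - up                                       # [-1,0,1] over rows
  le <- function(m) m[, c(1, seq_len(nc - 1)), drop = FALSE]
  ri <- function(m) m[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  gx <- ri(sm_v) - le(sm_v)             # horizontal difference of smoothed
  gy <- le(df_v) + 2 * df_v + ri(df_v)  # horizontal smoothing of difference
  sqrt(gx^2 + gy^2)
}

#' Sobel edge energy of the scalogram image
#'
#' Scales the magnitude image to \[0, 1\] by its own maximum, convolves
#' with the standard 3x3 Sobel pair (edge replication), and averages the
#' gradient magnitude over the requested region.
#'
#' @param scal A `scalogram`.
#' @param region `"full"`, `"upper"` or `"lower"`.
#' @param q Fraction defining the upper/lower split.
#' @param log_compress Apply `log1p` compression before scaling.
#' @param band Analysis band for the split.
#' @return Mean gradient magnitude (normalized units); 0 for a constant
#'   image.
#' @export
sobel_edge_energy <- function(scal, region = "full", q = 0.5,
                              log_compress = FALSE, band = c(5, 60)) {
  img <- scal$magnitude
  if (log_compress) img <- log1p(img)
  rng <- max(img)
  if (rng <= 0 || diff(range(img)) == 0) return(0)
  img <- img / rng
  if (nrow(img) < 3 || ncol(img) < 3)
    stop("scalogram too small for Sobel gradients (need >= 3x3)")
  g <- sobel_gradient_magnitude(img)
  rows <- region_rows(scal, region, q, band)
  mean(g[rows, , drop = FALSE])
}

#' Gini sparsity index
#'
#' Standard Gini sparsity of the nonnegative magnitude values: 0 for a
#' perfectly uniform image, approaching 1 - 1/N for a single spike.
#' With values sorted ascending `x_(1..N)`,
#' `G = 2 sum(k x_(k)) / (N sum(x)) - (N + 1)/N`.
#'
#' @param scal A `scalogram`, or a nonnegative numeric vector.
#' @return Gini index in \[0, 1).
#' @export
gini_sparsity <- function(scal) {
  x <- if (inherits(scal, "scalogram")) as.numeric(scal$magnitude) else
    as.numeric(scal)
  if (any(x < 0)) stop("Gini sparsity requires nonnegative values")
  tot <- sum(x)
  if (tot <= 0) stop("Gini sparsity undefined for all-zero input")
  x <- sort.int(x, method = "radix")
  n <- length(x)
  2 * sum(seq_len(n) * x) / (n * tot) - (n + 1) / n
}

#' Extract the biomarker vector of one scalogram
#'
#' Computes the six core biomarkers — upper-50% high-frequency energy
#' fraction, Gini sparsity, spectral centroid (Hz), Sobel edge energy,
#' normalized spectral-image entropy, spectral spread (Hz) — and the
#' extended screening set (fractional high-frequency ratios to total and to
#' the complementary lower band at q = 0.3/0.4/0.5, 85%/95% roll-offs,
#' upper/lower entropy and Sobel ratios, upper-half-band proportion).
#'
#' @param scal A `scalogram`.
#' @param config A [feature_config()].
#' @return Named list of feature values, core set first.
#' @export
extract_features <- function(scal, config = feature_config()) {
  band <- config$band
  f <- scal$freqs_hz
  s <- scal_energy(scal)          # |W|^2, computed once and shared
  marg <- rowSums(s)
  e_tot <- sum(marg)
  if (e_tot <= 0) stop("zero total energy")
  p_f <- marg / e_tot

  region_energy <- function(rows) sum(marg[rows])
  # H_region = -sum(s L)/tot + log(tot), with L = log(s) computed once
  sl <- s * log(s)
  sl[s == 0] <- 0
  sl_row <- rowSums(sl)
  n_t <- ncol(s)
  entropy_of <- function(rows) {
    tot <- sum(marg[rows])
    if (tot <= 0) return(NA_real_)
    h <- -sum(sl_row[rows]) / tot + log(tot)
    if (config$entropy_normalized) h / log(sum(rows) * n_t) else h
  }

  # Sobel gradient computed once on the normalized image, averaged per region
  img <- scal$magnitude
  if (config$sobel_log) img <- log1p(img)
  grad <- if (max(img) > 0 && diff(range(img)) > 0) {
    sobel_gradient_magnitude(img / max(img))
  } else NULL
  sobel_of <- function(rows) {
    if (is.null(grad)) return(0)
    mean(grad[rows, , drop = FALSE])
  }

  cut50 <- fractional_band_cut(band[1], band[2], 0.5)
  up50 <- f >= cut50

  out <- list()
  out$hf_fraction_top50 <- region_energy(up50) / e_tot
  out$gini_sparsity <- gini_sparsity(scal)
  out$spectral_centroid_hz <- sum(f * p_f)
  out$sobel_edge_energy <- sobel_of(rep(TRUE, length(f)))
  out$image_entropy <- entropy_of(rep(TRUE, length(f)))
  out$spectral_spread_hz <- sqrt(sum((f - out$spectral_centroid_hz)^2 * p_f))

  for (q in config$upper_fractions) {
    tag <- sprintf("%02d", round(100 * q))
    up <- f >= fractional_band_cut(band[1], band[2], q)
    e_up <- region_energy(up)
    out[[paste0("hf_q", tag, "_total")]] <- e_up / e_tot
    e_lo <- e_tot - e_up
    out[[paste0("hf_q", tag, "_lower")]] <- if (e_lo > 0) e_up / e_lo else
      NA_real_
  }
  cum <- cumsum(p_f)
  for (p in config$rolloff_quantiles) {
    out[[sprintf("rolloff_%02d_hz", round(100 * p))]] <-
      f[which(cum >= p - 1e-12)[1]]
  }
  h_up <- entropy_of(up50)
  h_lo <- entropy_of(!up50)
  out$entropy_ul_ratio <- if (is.na(h_lo) || is.na(h_up) || h_lo == 0)
    NA_real_ else h_up / h_lo
  s_up <- sobel_of(up50)
  s_lo <- sobel_of(!up50)
  out$sobel_ul_ratio <- if (s_lo == 0) NA_real_ else s_up / s_lo
  # proportion of energy above the band midpoint; on the 5-60 Hz band this
  # midpoint coincides with the q = 0.5 fractional cut (32.5 Hz)
  out$hf_upper_half <- region_energy(f >= mean(band)) / e_tot
  out
}

#' Feature table for a list of segment sets
#'
#' Runs the scalogram and biomarker extraction over every segment of every
#' recording and assembles the per-segment feature table with identity,
#' group-key and label columns (core six features first).
#'
#' @param segsets List of `segment_set` objects (one per recording), all at
#'   the same sampling rate and segment length.
#' @param morse A [morse_params()].
#' @param config A [feature_config()].
#' @return data.frame with columns patient_id, side, position,
#'   segment_index, group_key, severity, label, then the features.
#' @export
feature_table <- function(segsets, morse = morse_params(),
                          config = feature_config()) {
  segsets <- Filter(function(s) nrow(s$segments) > 0, segsets)
  if (length(segsets) == 0) stop("no segments available")
  n_samp <- ncol(segsets[[1]]$segments)
  fs <- segsets[[1]]$fs
  bank <- morse_filterbank(fs, n_samp, morse)
  rows <- list()
  for (ss in segsets) {
    if (ncol(ss$segments) != n_samp || ss$fs != fs)
      stop("segment sets differ in length or rate")
    for (i in seq_len(nrow(ss$segments))) {
      scal <- segment_scalogram(ss$segments[i, ], bank)
      fv <- extract_features(scal, config)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = ss$patient_id, side = ss$side, position = ss$position,
        segment_index = i, group_key = ss$group_key,
        severity = ss$severity, label = ss$label,
        as.data.frame(fv), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the feature columns in a feature table
#' @param features A feature table from [feature_table()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(colnames(features),
          c("patient_id", "side", "position", "segment_index", "group_key",
            "severity", "label"))
}
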