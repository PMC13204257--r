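test_that("fractional band cut follows the upper-fraction rule", {
  expect_equal(fractional_band_cut(5, 60, 0.5), 32.5)   # upper 50% = 32.5-60
  expect_equal(fractional_band_cut(5, 60, 0.3), 43.5)   # 60 - 0.3 * 55
  expect_equal(fractional_band_cut(5, 60, 1 - 1e-9), 5, tolerance = 1e-6)
  expect_error(fractional_band_cut(5, 60, 0), "q")
  expect_error(fractional_band_cut(5, 60, 1), "q")
})

test_that("band energy is complete, additive, and zero on empty input", {
  sc <- toy_scalogram(seq(5, 60, by = 5), matrix(runif(12 * 6), 12, 6))
  e_tot <- sum(sc$magnitude^2)
  expect_equal(band_energy(sc, 5, 60), e_tot)
  expect_equal(band_energy(sc, 5, 30) + band_energy(sc, 30.001, 60), e_tot)
  sc0 <- toy_scalogram(seq(5, 60, by = 5), matrix(0, 12, 6))
  expect_equal(band_energy(sc0, 5, 60), 0)
  expect_warning(band_energy(sc, 61, 70), "no frequency rows")
})

test_that("high-frequency ratios match counting oracles on known grids", {
  freqs <- seq(5, 60, by = 5)
  lowmass <- point_mass_scalogram(10, freqs)
  expect_equal(hf_ratio(lowmass, 0.5, "total"), 0)
  highmass <- point_mass_scalogram(50, freqs)
  expect_equal(hf_ratio(highmass, 0.5, "total"), 1)
  # uniform energy on a 44-row CWT grid: ratio = fraction of rows >= 32.5
  bank <- morse_filterbank(2400, 256)
  sc <- toy_scalogram(bank$freqs_hz,
                      matrix(1, length(bank$freqs_hz), 16))
  expect_equal(hf_ratio(sc, 0.5, "total"),
               sum(bank$freqs_hz >= 32.5) / length(bank$freqs_hz))
  # lower-denominator variant and its +Inf sentinel
  expect_equal(hf_ratio(lowmass, 0.5, "lower"), 0)
  expect_warning(r <- hf_ratio(highmass, 0.5, "lower"), "undefined")
  expect_identical(r, Inf)
})

test_that("centroid, spread, and roll-off match closed forms", {
  freqs <- seq(5, 60, by = 5)
  pm <- point_mass_scalogram(30, freqs)
  expect_equal(spectral_centroid(pm), 30)
  expect_equal(spectral_spread(pm), 0)
  expect_equal(spectral_rolloff(pm, 0.85), 30)
  expect_equal(spectral_rolloff(pm, 0.95), 30)
  # equal masses at 20 and 40 Hz
  two <- toy_scalogram(freqs, {
    m <- matrix(0, 12, 4); m[freqs == 20, ] <- 1; m[freqs == 40, ] <- 1; m
  })
  expect_equal(spectral_centroid(two), 30)
  expect_equal(spectral_spread(two), 10)
  # 80%/20% two-point mass: 0.85 roll-off jumps to the upper row
  skew <- toy_scalogram(freqs, {
    m <- matrix(0, 12, 1)
    m[freqs == 10, ] <- sqrt(0.8); m[freqs == 50, ] <- sqrt(0.2); m
  })
  expect_equal(spectral_rolloff(skew, 0.85), 50)
  expect_equal(spectral_rolloff(skew, 0.75), 10)
  # monotone cumulative: 0.85 <= 0.95 roll-off on random scalograms
  set.seed(11)
  for (i in 1:20) {
    sc <- toy_scalogram(freqs, matrix(runif(12 * 8), 12, 8))
    expect_lte(spectral_rolloff(sc, 0.85), spectral_rolloff(sc, 0.95))
  }
  # uniform marginal: centroid equals the brute-force row mean
  unif <- toy_scalogram(freqs, matrix(1, 12, 5))
  expect_equal(spectral_centroid(unif), mean(freqs))
})

test_that("spectral-image entropy matches closed-form values", {
  freqs <- c(10, 40)
  unif <- toy_scalogram(freqs, matrix(1, 2, 8))
  expect_equal(image_entropy(unif, "full", normalized = TRUE), 1)
  single <- toy_scalogram(freqs, {
    m <- matrix(0, 2, 8); m[1, 1] <- 3; m
  })
  expect_equal(image_entropy(single, "full", normalized = FALSE), 0)
  # two cells with energies 0.25 / 0.75
  two <- toy_scalogram(freqs, matrix(c(sqrt(0.25), sqrt(0.75)), 2, 1))
  expect_equal(image_entropy(two, "full", normalized = FALSE),
               -(0.25 * log(0.25) + 0.75 * log(0.75)))
})

test_that("Sobel edge energy matches a hand convolution of the step image", {
  freqs <- seq(5, 60, length.out = 9)
  flat <- toy_scalogram(freqs, matrix(1, 9, 9))
  expect_equal(sobel_edge_energy(flat), 0)
  # vertical step 0 -> 1 between columns 5 and 6 of a [0,1] image:
  # interior |G| = 4 at the step-adjacent columns (kernel row sum), 0 away
  img <- matrix(0, 9, 10)
  img[, 6:10] <- 1
  g <- carotidscreen:::sobel_gradient_magnitude(img)
  expect_true(all(g[2:8, 5] == 4))
  expect_true(all(g[2:8, 6] == 4))
  expect_true(all(g[2:8, c(2:4, 7:9)] == 0))
  # scale invariance by construction
  sc1 <- toy_scalogram(freqs, matrix(runif(81), 9, 9))
  sc2 <- sc1; sc2$magnitude <- 17 * sc2$magnitude
  expect_equal(sobel_edge_energy(sc2), sobel_edge_energy(sc1),
               tolerance = 1e-12)
})

test_that("Gini sparsity matches its closed-form extremes", {
  freqs <- c(10, 20, 30)
  expect_equal(gini_sparsity(toy_scalogram(freqs, matrix(2, 3, 4))), 0)
  n <- 12
  spike <- matrix(0, 3, 4); spike[2, 2] <- 5
  expect_equal(gini_sparsity(toy_scalogram(freqs, spike)), (n - 1) / n)
  set.seed(3)
  x <- runif(50)
  expect_equal(gini_sparsity(3.7 * x), gini_sparsity(x), tolerance = 1e-12)
  expect_error(gini_sparsity(rep(0, 5)), "all-zero")
})

test_that("core feature vector is invariant to signal amplitude scaling", {
  bank <- morse_filterbank(2400, 2400)
  set.seed(17)
  x <- rnorm(2400)
  f1 <- extract_features(segment_scalogram(x, bank))
  f2 <- extract_features(segment_scalogram(7 * x, bank))
  core <- feature_config()$core_set
  expect_equal(unlist(f1[core]), unlist(f2[core]), tolerance = 1e-9)
  # and to the wavelet amplitude convention: rescaling the scalogram
  sc <- segment_scalogram(x, bank)
  sc2 <- sc; sc2$magnitude <- 0.123 * sc$magnitude
  expect_equal(unlist(extract_features(sc)[core]),
               unlist(extract_features(sc2)[core]), tolerance = 1e-9)
})

test_that("feature ranges and orderings hold on random scalograms", {
  set.seed(23)
  bank <- morse_filterbank(2400, 256)
  for (i in 1:10) {
    sc <- toy_scalogram(bank$freqs_hz,
                        matrix(stats::rexp(44 * 16), 44, 16))
    fv <- extract_features(sc)
    ratios <- unlist(fv[c("hf_fraction_top50", "hf_q30_total",
                          "hf_q40_total", "hf_q50_total", "hf_upper_half")])
    expect_true(all(ratios >= 0 & ratios <= 1))
    expect_gte(fv$spectral_centroid_hz, 5)
    expect_lte(fv$spectral_centroid_hz, 60)
    expect_lte(fv$rolloff_85_hz, fv$rolloff_95_hz)
    expect_gte(fv$image_entropy, 0)
    expect_lte(fv$image_entropy, 1)
    expect_gte(fv$gini_sparsity, 0)
    expect_lt(fv$gini_sparsity, 1)
    expect_gte(fv$spectral_spread_hz, 0)
    # identical value from the q = 0.5 cut and the band midpoint
    expect_equal(fv$hf_fraction_top50, fv$hf_upper_half)
  }
})

test_that("moving energy mass upward never decreases the hf ratio", {
  # brute-force mass-moving oracle on a small grid
  freqs <- seq(5, 60, by = 5)
  set.seed(5)
  for (i in 1:15) {
    m <- matrix(runif(12 * 3), 12, 3)
    sc <- toy_scalogram(freqs, m)
    r0 <- hf_ratio(sc, 0.5, "total")
    below <- which(freqs < 32.5)
    above <- which(freqs >= 32.5)
    src <- sample(below, 1)
    dst <- sample(above, 1)
    col <- sample(3, 1)
    # move half the squared mass from a low row to a high row
    delta2 <- m[src, col]^2 / 2
    m2 <- m
    m2[src, col] <- sqrt(m[src, col]^2 - delta2)
    m2[dst, col] <- sqrt(m[dst, col]^2 + delta2)
    r1 <- hf_ratio(toy_scalogram(freqs, m2), 0.5, "total")
    expect_gte(r1, r0 - 1e-12)
  }
})
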