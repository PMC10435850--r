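test_that("frame grid arithmetic follows the hop/window invariant", {
  sec <- trim_auscultation(noise_recording(dur = 1.2, rate = 44100), 0)
  g <- make_grid(sec, hop_s = 0.012, window_s = 0.024)
  expect_equal(g$hop, 529L)
  expect_equal(g$window, 1058L)
  expect_equal(g$n_frames, (52920L - 1058L) %/% 529L + 1L)  # = 99
  expect_equal(g$n_frames, 99L)

  # window = hop = section duration -> exactly one frame
  one <- make_grid(trim_auscultation(noise_recording(dur = 0.1, rate = 8000), 0),
                   hop_s = 0.1, window_s = 0.1)
  expect_equal(one$n_frames, 1L)

  short <- trim_auscultation(noise_recording(dur = 0.010, rate = 44100), 0)
  expect_error(make_grid(short, hop_s = 0.012, window_s = 0.024), "shorter")
  expect_error(make_grid(sec, hop_s = 0.024, window_s = 0.012), "window_s")
})

test_that("the default layout has exactly 148 uniquely named features", {
  lay <- default_feature_layout()
  expect_equal(lay$n_features, 148L)
  expect_equal(length(lay$names), 148L)
  expect_equal(anyDuplicated(lay$names), 0L)
})

test_that("silence maps to a fixed, finite feature vector", {
  lay <- default_feature_layout()
  sec <- trim_auscultation(audio_recording(numeric(44100), 44100), 0)
  g <- make_grid(sec)
  raw <- extract_raw_features(sec, g, lay)
  expect_true(all(is.finite(raw)))
  expect_true(all(raw[, grep("^mel_logE", colnames(raw))] == lay$floor_db))
  expect_true(all(raw[, grep("^bandvar", colnames(raw))] == 0))
  expect_true(all(raw[, "zcr"] == 0))
  expect_true(all(raw[, "spec_centroid"] == 0))
  expect_true(all(raw[, "log_rms"] == lay$floor_db))
  # every frame of silence is the same vector
  expect_true(all(apply(raw, 2, function(col) all(col == col[1]))))
})

test_that("a pure 650-Hz tone maximizes the band that holds 650 Hz", {
  rate <- 44100
  t <- (0:(round(0.5 * rate) - 1)) / rate
  sec <- trim_auscultation(audio_recording(0.5 * sin(2 * pi * 650 * t), rate), 0)
  lay <- default_feature_layout()
  g <- make_grid(sec)
  raw <- extract_raw_features(sec, g, lay)
  mel <- raw[, grep("^mel_logE", colnames(raw))]
  observed_band <- apply(mel, 1, which.max)

  # independent FFT-based band-energy oracle: band energies of one frame
  # computed from scratch with the filter geometry
  win <- g$window
  n_fft <- 2L^as.integer(ceiling(log2(win)))
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  frame <- sec$samples[1:win] * hann
  spec <- Mod(fft(c(frame, numeric(n_fft - win)))[1:(n_fft / 2 + 1)])^2
  freqs <- (0:(n_fft / 2)) * rate / n_fft
  m <- function(f) 2595 * log10(1 + f / 700)
  m_inv <- function(x) 700 * (10^(x / 2595) - 1)
  edges <- m_inv(seq(m(50), m(0.999 * rate / 2), length.out = 42))
  tri <- sapply(seq_len(40), function(b) {
    w <- pmax(0, pmin((freqs - edges[b]) / (edges[b + 1] - edges[b]),
                      (edges[b + 2] - freqs) / (edges[b + 2] - edges[b + 1])))
    sum(w * spec)
  })
  expect_equal(unique(observed_band), which.max(tri))
  # and that band's triangle actually spans 650 Hz
  expect_lt(edges[which.max(tri)], 650)
  expect_gt(edges[which.max(tri) + 2], 650)
})

test_that("feature extraction is deterministic and shift-covariant", {
  rec <- noise_recording(dur = 0.6, rate = 44100, seed = 7)
  sec <- trim_auscultation(rec, 0)
  g <- make_grid(sec)
  lay <- default_feature_layout()
  a <- extract_raw_features(sec, g, lay)
  b <- extract_raw_features(sec, g, lay)
  expect_identical(a, b)

  # chunk size only regroups BLAS calls; values agree to rounding
  c2 <- extract_raw_features(sec, g, lay, chunk = 7L)
  expect_equal(a, c2, tolerance = 1e-12)

  # dropping exactly one hop from the front shifts rows by one
  shifted <- audio_recording(rec$samples[(g$hop + 1):rec$n_samples], rec$rate)
  g2 <- make_grid(trim_auscultation(shifted, 0))
  s <- extract_raw_features(trim_auscultation(shifted, 0), g2, lay)
  expect_equal(s[1:(g2$n_frames), ], a[2:(g2$n_frames + 1), ],
               tolerance = 1e-12)
})

test_that("min-max normalization maps onto [-1, 1] with clipping", {
  raw <- matrix(c(0, 10, 3), ncol = 1, dimnames = list(NULL, "f1"))
  nm <- fit_normalizer(raw)
  mid <- apply_normalizer(matrix(5, 1, 1, dimnames = list(NULL, "f1")), nm)
  expect_equal(unname(mid[1, 1]), 0)
  over <- apply_normalizer(matrix(12, 1, 1, dimnames = list(NULL, "f1")), nm)
  expect_equal(unname(over[1, 1]), 1)

  # constant feature -> always 0
  cst <- matrix(rep(4, 5), ncol = 1, dimnames = list(NULL, "f1"))
  expect_true(all(apply_normalizer(cst, fit_normalizer(cst)) == 0))

  # identity-range map leaves in-range data unchanged
  idm <- structure(list(min = c(f1 = -1), max = c(f1 = 1), names = "f1"),
                   class = "feature_normalizer")
  x <- matrix(seq(-1, 1, 0.5), ncol = 1, dimnames = list(NULL, "f1"))
  expect_equal(unname(apply_normalizer(x, idm)), unname(x))

  # any input lands in [-1, 1]
  set.seed(8)
  big <- matrix(rnorm(200, sd = 50), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  nm2 <- fit_normalizer(big[1:50, ])
  z <- apply_normalizer(big[51:100, ], nm2)
  expect_true(all(z >= -1 & z <= 1))

  # layout mismatch
  bad <- matrix(0, 1, 1, dimnames = list(NULL, "other"))
  expect_error(apply_normalizer(bad, nm), "layout mismatch")
  expect_error(fit_normalizer(matrix(numeric(0), 0, 1)), "empty")
})

test_that("normalized features of real audio respect the layout contract", {
  sim <- synth_recording(swallow_scenario(duration_s = 1.5,
                                          swallow_window = c(0.4, 1.0),
                                          seed = 21))
  sec <- trim_auscultation(sim$recording, 0.2)
  g <- make_grid(sec)
  raw <- extract_raw_features(sec, g)
  nm <- fit_normalizer(raw)
  x <- apply_normalizer(raw, nm)
  expect_equal(dim(x), c(g$n_frames, 148L))
  expect_true(all(x >= -1 & x <= 1))
  expect_true(all(is.finite(x)))
})
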