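#' Build a frame grid over an auscultation section
#'
#' Frames are placed at 12-ms intervals by default, with a 24-ms
#' Hann-tapered analysis window (a window longer than the hop is needed
#' for stable cepstra). Hop and window are converted to whole samples by
#' rounding; frame `k` (0-based) covers samples `[k*hop, k*hop + window)`.
#'
#' @param section an `auscultation_section` (or an [audio_recording()],
#'   taken whole).
#' @param hop_s frame interval in seconds (default 0.012).
#' @param window_s analysis window in seconds (default 0.024).
#' @return An object of class `frame_grid` with fields `hop`, `window`
#'   (samples), `hop_s`, `window_s`, `n_frames`, `rate`.
#' @export
make_grid <- function(section, hop_s = 0.012, window_s = 0.024) {
  section <- as_section(section)
  rate <- section$rate
  hop <- as.integer(round(hop_s * rate))
  window <- as.integer(round(window_s * rate))
  if (hop < 1L || window < 1L) stop("hop and window must each round to >= 1 sample")
  if (window < hop) stop("window_s must be >= hop_s")
  n <- length(section$samples)
  if (n < window)
    stop(sprintf("section of %d samples shorter than one %d-sample window", n, window))
  n_frames <- (n - window) %/% hop + 1L
  structure(
    list(hop = hop, window = window, hop_s = hop_s, window_s = window_s,
         n_frames = as.integer(n_frames), rate = rate),
    class = "frame_grid"
  )
}

#' @export
print.frame_grid <- function(x, ...) {
  cat(sprintf("<frame_grid> %d frames, hop %d / window %d samples @ %g Hz\n",
              x$n_frames, x$hop, x$window, x$rate))
  invisible(x)
}

#' Default 148-dimension feature layout
#'
#' The per-frame feature vector combines every technique used for
#' fine-crackle discrimination — frequency-band analysis, local variance,
#' cepstrum analysis and liftering — in a fixed, serialized order:
#'
#' * 40 log-energies on a mel-spaced triangular filter bank
#'   (`f_min`–`f_max` Hz, capped at Nyquist), floored at `floor_db`;
#' * 24 liftered cepstral coefficients c1–c24 (DCT-II of the log-mel
#'   spectrum, low-time lifter keeping quefrencies up to `lifter_cutoff`);
#' * 24 within-window delta-cepstra (second half-window minus first);
#' * 40 per-band local variance features (variance of the log band energy
#'   across 4 sub-blocks of the window);
#' * 20 scalar descriptors: zero-crossing rate, spectral centroid and
#'   bandwidth, rolloff at 5 quantiles, within-window flux, flatness,
#'   crest factor, frame log-RMS, envelope skewness and kurtosis, and 6
#'   high-to-low band energy log-ratios (splits at 250–8000 Hz).
#'
#' @param n_mel number of mel bands (default 40).
#' @param n_cepstra number of cepstral coefficients (default 24).
#' @param f_min,f_max filter bank range in Hz (defaults 50 and 20000; the
#'   effective upper edge is capped just below Nyquist at extraction time).
#' @param lifter_cutoff highest retained quefrency index (default 24).
#' @param floor_db floor for log-energies, dB re full scale (default -80).
#' @return An object of class `feature_layout` with `names` (length 148)
#'   and the configuration fields.
#' @export
default_feature_layout <- function(n_mel = 40L, n_cepstra = 24L,
                                   f_min = 50, f_max = 20000,
                                   lifter_cutoff = 24L, floor_db = -80) {
  splits <- c(250, 500, 1000, 2000, 4000, 8000)
  names <- c(
    sprintf("mel_logE_%02d", seq_len(n_mel)),
    sprintf("ceps_%02d", seq_len(n_cepstra)),
    sprintf("dceps_%02d", seq_len(n_cepstra)),
    sprintf("bandvar_%02d", seq_len(n_mel)),
    "zcr", "spec_centroid", "spec_bandwidth",
    sprintf("rolloff_q%02d", c(25, 50, 75, 90, 95)),
    "spec_flux", "spec_flatness", "crest_factor", "log_rms",
    "env_skewness", "env_kurtosis",
    sprintf("hl_ratio_%d", splits)
  )
  if (anyDuplicated(names)) stop("internal: duplicate feature names")
  structure(
    list(names = names, n_features = length(names),
         n_mel = as.integer(n_mel), n_cepstra = as.integer(n_cepstra),
         f_min = f_min, f_max = f_max,
         lifter_cutoff = as.integer(lifter_cutoff),
         floor_db = floor_db, band_splits = splits),
    class = "feature_layout"
  )
}

#' @export
print.feature_layout <- function(x, ...) {
  cat(sprintf("<feature_layout> %d features (%d mel bands, %d cepstra)\n",
              x$n_features, x$n_mel, x$n_cepstra))
  invisible(x)
}

# mel scale helpers
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filter bank as a (n_mel x n_bins) matrix for an FFT of
# length n_fft at the given rate. Upper edge capped below Nyquist.
mel_filterbank <- function(n_mel, f_min, f_max, n_fft, rate) {
  f_max <- min(f_max, 0.999 * rate / 2)
  edges <- mel_to_hz(seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mel + 2L))
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (0:(n_bins - 1L)) * rate / n_fft
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  attr(fb, "freqs") <- freqs
  attr(fb, "edges") <- edges
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in), rows k = 1..n_out (c0 skipped).
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out)
  m <- 0:(n_in - 1L)
  sqrt(2 / n_in) * cos(outer(k, m + 0.5) * pi / n_in)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

# Power spectra of windowed frame columns, zero-padded to n_fft.
# x: (len x m) matrix -> (n_fft/2+1 x m) power spectrum matrix.
power_spectra <- function(x, n_fft) {
  m <- ncol(x)
  pad <- matrix(0, n_fft - nrow(x), m)
  z <- stats::mvfft(rbind(x, pad))
  Mod(z[seq_len(n_fft %/% 2L + 1L), , drop = FALSE])^2
}

col_moments <- function(e) {
  # standardized skewness / excess-free kurtosis of each column; 0 when flat
  mu <- colMeans(e)
  d <- sweep(e, 2, mu)
  v <- colMeans(d^2)
  s <- sqrt(v)
  ok <- s > 1e-12
  sk <- ku <- numeric(ncol(e))
  sk[ok] <- colMeans(d^3)[ok] / s[ok]^3
  ku[ok] <- colMeans(d^4)[ok] / v[ok]^2 - 3
  list(skew = sk, kurt = ku)
}

#' Extract raw (unnormalized) per-frame features
#'
#' Computes the 148 features of `layout` for every frame of `grid` over
#' `section`. Deterministic: identical input and configuration give a
#' bitwise-identical matrix. Silence maps to a fixed finite vector
#' (log-energies at the floor, variances and descriptors at 0).
#'
#' @param section an `auscultation_section` (or [audio_recording()]).
#' @param grid a [make_grid()] result built on `section`.
#' @param layout a [default_feature_layout()].
#' @param chunk frames processed per block (memory bound; default 2048).
#' @return numeric matrix, `grid$n_frames` rows x 148 named columns, with
#'   the grid attached as attribute `"grid"`.
#' @export
extract_raw_features <- function(section, grid, layout = default_feature_layout(),
                                 chunk = 2048L) {
  section <- as_section(section)
  if (any(!is.finite(section$samples))) stop("non-finite sample values")
  stopifnot(inherits(grid, "frame_grid"), inherits(layout, "feature_layout"))
  rate <- grid$rate
  win <- grid$window
  hop <- grid$hop
  nf <- grid$n_frames

  n_fft <- next_pow2(win)
  half <- win %/% 2L
  n_fft_h <- next_pow2(half)
  blk <- win %/% 4L
  n_fft_b <- next_pow2(blk)

  fb  <- mel_filterbank(layout$n_mel, layout$f_min, layout$f_max, n_fft, rate)
  fbh <- mel_filterbank(layout$n_mel, layout$f_min, layout$f_max, n_fft_h, rate)
  fbb <- mel_filterbank(layout$n_mel, layout$f_min, layout$f_max, n_fft_b, rate)
  dct  <- dct_matrix(layout$n_cepstra, layout$n_mel)
  wfull <- hann_window(win)
  whalf <- hann_window(half)
  wblk  <- hann_window(blk)
  lifter <- as.numeric(seq_len(layout$n_cepstra) <= layout$lifter_cutoff)
  floor_lin <- 10^(layout$floor_db / 10)
  freqs <- attr(fb, "freqs")
  eps <- 1e-12

  out <- matrix(NA_real_, nf, layout$n_features,
                dimnames = list(NULL, layout$names))

  for (start in seq(1L, nf, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nf)
    m <- length(idx)
    pos <- outer(seq_len(win), (idx - 1L) * hop, `+`)
    fr <- matrix(section$samples[pos], nrow = win)

    # full-window spectrum -> mel log-energies, cepstra
    P <- power_spectra(fr * wfull, n_fft)
    melE <- fb %*% P
    logE <- 10 * log10(pmax(melE, floor_lin))
    ceps <- (dct %*% (logE / 10)) * lifter   # natural log-like scale (dB/10)

    # half-window spectra -> delta-cepstra, flux
    h1 <- fr[seq_len(half), , drop = FALSE] * whalf
    h2 <- fr[(win - half + 1L):win, , drop = FALSE] * whalf
    P1 <- power_spectra(h1, n_fft_h); P2 <- power_spectra(h2, n_fft_h)
    l1 <- 10 * log10(pmax(fbh %*% P1, floor_lin))
    l2 <- 10 * log10(pmax(fbh %*% P2, floor_lin))
    dceps <- (dct %*% ((l2 - l1) / 10)) * lifter
    s1 <- colSums(P1); s2 <- colSums(P2)
    p1n <- sweep(P1, 2, pmax(s1, eps), "/")
    p2n <- sweep(P2, 2, pmax(s2, eps), "/")
    flux <- sqrt(colSums((p2n - p1n)^2))
    flux[s1 < eps & s2 < eps] <- 0

    # 4 sub-blocks -> local variance of log band energy
    bl <- vapply(0:3, function(b) {
      sub <- fr[(b * blk + 1L):((b + 1L) * blk), , drop = FALSE] * wblk
      10 * log10(pmax(fbb %*% power_spectra(sub, n_fft_b), floor_lin))
    }, matrix(0, layout$n_mel, m))            # n_mel x m x 4
    bmu <- (bl[, , 1] + bl[, , 2] + bl[, , 3] + bl[, , 4]) / 4
    bvar <- ((bl[, , 1] - bmu)^2 + (bl[, , 2] - bmu)^2 +
             (bl[, , 3] - bmu)^2 + (bl[, , 4] - bmu)^2) / 4
    if (m == 1L) { bmu <- matrix(bmu); bvar <- matrix(bvar) }

    # scalar descriptors
    zcr <- colSums(abs(diff(sign(fr) + (fr == 0))) > 0) / (win - 1L)
    tot <- colSums(P)
    live <- tot > eps
    centroid <- bandwidth <- numeric(m)
    centroid[live] <- colSums(freqs * P[, live, drop = FALSE]) / tot[live]
    bandwidth[live] <- sqrt(colSums((outer(freqs, centroid[live], `-`)^2) *
                                      P[, live, drop = FALSE]) / tot[live])
    cum <- apply(P, 2, cumsum)
    roll <- vapply(c(.25, .50, .75, .90, .95), function(q) {
      r <- numeric(m)
      r[live] <- freqs[colSums(cum[, live, drop = FALSE] <
                                 rep(q * tot[live], each = nrow(cum))) + 1L]
      r
    }, numeric(m))
    if (m == 1L) roll <- matrix(roll, nrow = 1L)
    gm <- exp(colMeans(log(P + eps)))
    flat <- numeric(m); flat[live] <- gm[live] / colMeans(P + eps)[live]
    wfr <- fr * wfull
    rms <- sqrt(colMeans(wfr^2))
    crest <- numeric(m)
    crest[rms > eps] <- apply(abs(wfr[, rms > eps, drop = FALSE]), 2, max) /
      rms[rms > eps]
    log_rms <- 10 * log10(pmax(colMeans(fr^2), floor_lin))
    mo <- col_moments(abs(fr))
    ratios <- vapply(layout$band_splits, function(f0) {
      hi <- colSums(P[freqs >= f0, , drop = FALSE])
      lo <- colSums(P[freqs < f0, , drop = FALSE])
      log10((hi + eps) / (lo + eps))
    }, numeric(m))
    if (m == 1L) ratios <- matrix(ratios, nrow = 1L)

    out[idx, ] <- cbind(t(logE), t(ceps), t(dceps), t(bvar),
                        zcr, centroid, bandwidth, roll,
                        flux, flat, crest, log_rms,
                        mo$skew, mo$kurt, ratios)
  }
  if (any(!is.finite(out))) stop("internal: non-finite feature values")
  attr(out, "grid") <- grid
  out
}

#' Fit a per-feature min-max normalizer
#'
#' Maps each feature affinely from its training range onto \[-1, 1\];
#' application clips out-of-range values at the bounds. A constant feature
#' maps identically to 0. Min-max (rather than z-scoring) is used because
#' it guarantees the stated range.
#'
#' @param raw raw feature matrix (or a list of matrices pooled by rows).
#' @return An object of class `feature_normalizer` with per-feature `min`
#'   and `max`.
#' @export
fit_normalizer <- function(raw) {
  if (is.list(raw) && !is.matrix(raw)) raw <- do.call(rbind, raw)
  if (is.null(raw) || nrow(raw) == 0L) stop("empty training set")
  structure(
    list(min = apply(raw, 2, min), max = apply(raw, 2, max),
         names = colnames(raw)),
    class = "feature_normalizer"
  )
}

#' Apply a fitted normalizer
#'
#' @param raw raw feature matrix with the same layout the normalizer was
#'   fitted on.
#' @param normalizer a [fit_normalizer()] result.
#' @return matrix of the same shape, every value in \[-1, 1\]; the `"grid"`
#'   attribute of `raw`, if present, is carried over.
#' @export
apply_normalizer <- function(raw, normalizer) {
  stopifnot(inherits(normalizer, "feature_normalizer"))
  if (ncol(raw) != length(normalizer$min) ||
      !identical(colnames(raw), normalizer$names))
    stop("feature layout mismatch between matrix and normalizer")
  rng <- normalizer$max - normalizer$min
  ok <- rng > 0
  x <- raw
  x[, ok] <- sweep(sweep(raw[, ok, drop = FALSE], 2, normalizer$min[ok]),
                   2, rng[ok], "/") * 2 - 1
  x[, !ok] <- 0
  x <- pmin(pmax(x, -1), 1)
  attr(x, "grid") <- attr(raw, "grid")
  x
}
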