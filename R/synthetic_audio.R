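# Seeded synthetic data: crackle-burst recordings with ground-truth frame
# labels, teacher sets for training, and patient cohorts with a planted
# linear covariate structure. All randomness flows through run_seeded(),
# which restores the caller's RNG state.

run_seeded <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fine-crackle burst specification
#'
#' A fine crackle is modeled as an exponentially damped sinusoid,
#' `a * exp(-t / tau) * sin(2 pi f t)` — the standard parsimonious
#' surrogate for a short transient crackle. Defaults: 650 Hz center
#' frequency, 4-ms damping constant, 10-ms burst.
#'
#' @param center_freq carrier frequency, Hz.
#' @param damping_tau exponential decay constant, seconds.
#' @param burst_dur burst duration, seconds (must be >= `damping_tau`).
#' @param amplitude peak amplitude, relative (0, 1].
#' @return An object of class `crackle_spec`.
#' @export
crackle_spec <- function(center_freq = 650, damping_tau = 0.004,
                         burst_dur = 0.01, amplitude = 0.8) {
  stopifnot(center_freq > 0, damping_tau > 0, burst_dur >= damping_tau,
            amplitude >= 0, amplitude <= 1)   # amplitude 0 = silent burst
  structure(list(center_freq = center_freq, damping_tau = damping_tau,
                 burst_dur = burst_dur, amplitude = amplitude),
            class = "crackle_spec")
}

#' Synthesize one crackle burst
#'
#' @param spec a [crackle_spec()].
#' @param rate sampling rate, Hz; must exceed twice the center frequency.
#' @return numeric waveform of length `round(burst_dur * rate)`.
#' @export
synth_crackle <- function(spec = crackle_spec(), rate = 44100) {
  stopifnot(inherits(spec, "crackle_spec"))
  if (rate <= 2 * spec$center_freq)
    stop("sampling rate too low for a ", spec$center_freq, "-Hz burst (aliasing)")
  n <- round(spec$burst_dur * rate)
  t <- (seq_len(n) - 1) / rate
  spec$amplitude * exp(-t / spec$damping_tau) * sin(2 * pi * spec$center_freq * t)
}

#' Water-swallow recording scenario
#'
#' Describes one simulated swallow trial: background noise for
#' `duration_s` seconds with crackle bursts arriving as a homogeneous
#' Poisson process of rate `burst_rate` inside `swallow_window`. The
#' window must lie within `[0.2, duration_s - 0.2]` so the bursts survive
#' edge trimming. Defaults emulate a 3-mL water swallow: a 4-s recording
#' with a 1-s swallow at 30 bursts/s, white background noise, 10 dB SNR.
#'
#' @param duration_s trial duration, seconds.
#' @param n_trials number of trials per participant (default 3).
#' @param burst_rate bursts per second inside the swallow window.
#' @param swallow_window `c(start_s, end_s)` of the swallow; `NULL`
#'   places it at the central 25% of the trial (`c(1.5, 2.5)` for the
#'   4-s default).
#' @param noise_rms background noise RMS amplitude (> 0).
#' @param snr_db target burst-to-noise power ratio, dB, measured over the
#'   burst support.
#' @param noise_type `"white"` or `"pink"` (1/f).
#' @param rate sampling rate, Hz.
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @return An object of class `swallow_scenario`.
#' @export
swallow_scenario <- function(duration_s = 4, n_trials = 3, burst_rate = 30,
                             swallow_window = NULL, noise_rms = 0.05,
                             snr_db = 10, noise_type = c("white", "pink"),
                             rate = 44100, seed = 1L) {
  noise_type <- match.arg(noise_type)
  if (is.null(swallow_window))
    swallow_window <- c(0.375, 0.625) * duration_s
  stopifnot(duration_s > 0.4, n_trials >= 1, burst_rate >= 0, noise_rms >= 0,
            length(swallow_window) == 2L)
  if (swallow_window[1] < 0.2 || swallow_window[2] > duration_s - 0.2 ||
      swallow_window[1] >= swallow_window[2])
    stop("swallow_window must lie within [0.2, duration_s - 0.2]")
  structure(list(duration_s = duration_s, n_trials = as.integer(n_trials),
                 burst_rate = burst_rate, swallow_window = swallow_window,
                 noise_rms = noise_rms, snr_db = snr_db,
                 noise_type = noise_type, rate = rate, seed = as.integer(seed)),
            class = "swallow_scenario")
}

synth_noise <- function(n, rms, type) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  if (type == "pink") {
    z <- stats::fft(x)
    f <- c(1, seq_len(n - 1))                 # avoid DC blow-up
    f <- pmin(f, n - f + 1)
    z <- z / sqrt(f)
    x <- Re(stats::fft(z, inverse = TRUE)) / n
    x <- x / stats::sd(x)
  }
  x * rms
}

#' Synthesize a labeled swallow recording
#'
#' Generates background noise plus crackle bursts at Poisson times inside
#' the swallow window, scales the bursts so the realized burst-support
#' SNR equals `scenario$snr_db` exactly, and returns the per-frame
#' ground-truth label track on the frame grid of the trimmed
#' auscultation section (a frame is labeled 1 iff it overlaps a burst).
#'
#' @param scenario a [swallow_scenario()]; its `seed` drives all
#'   randomness.
#' @param spec a [crackle_spec()].
#' @param edge_s edge exclusion applied before framing (default 0.2 s).
#' @param hop_s,window_s frame grid parameters.
#' @return list with `recording` ([audio_recording()]), `labels` (0/1 per
#'   frame of the trimmed grid), `grid`, `burst_times` (seconds),
#'   `signal` and `noise` components, and `realized_snr_db`.
#' @export
synth_recording <- function(scenario, spec = crackle_spec(), edge_s = 0.2,
                            hop_s = 0.012, window_s = 0.024) {
  stopifnot(inherits(scenario, "swallow_scenario"))
  rate <- scenario$rate
  n <- round(scenario$duration_s * rate)
  run_seeded(scenario$seed, {
    noise <- synth_noise(n, scenario$noise_rms, scenario$noise_type)
    win <- scenario$swallow_window
    latest <- win[2] - spec$burst_dur
    n_b <- if (scenario$burst_rate > 0 && latest > win[1])
      stats::rpois(1, scenario$burst_rate * (win[2] - win[1])) else 0L
    burst_times <- if (n_b > 0) sort(stats::runif(n_b, win[1], latest)) else numeric(0)

    burst <- synth_crackle(spec, rate)
    signal <- numeric(n)
    for (t0 in burst_times) {
      i0 <- round(t0 * rate) + 1L
      ii <- i0:(i0 + length(burst) - 1L)
      signal[ii] <- signal[ii] + burst
    }

    realized <- NA_real_
    if (n_b > 0) {
      if (scenario$noise_rms == 0)
        stop("cannot realize a finite SNR with zero noise_rms")
      support <- signal != 0
      p_sig <- mean(signal[support]^2)
      p_noise <- mean(noise^2)
      g <- sqrt(p_noise * 10^(scenario$snr_db / 10) / p_sig)
      signal <- signal * g
      realized <- 10 * log10(mean(signal[support]^2) / p_noise)
    }

    x <- noise + signal
    peak <- max(abs(x), 1)
    if (peak > 1) { x <- x / peak; noise <- noise / peak; signal <- signal / peak }

    rec <- audio_recording(x, rate)
    section <- trim_auscultation(rec, edge_s)
    grid <- make_grid(section, hop_s = hop_s, window_s = window_s)
    labels <- label_frames(grid, burst_times, spec$burst_dur,
                           offset_s = section$start_s)
    list(recording = rec, labels = labels, grid = grid,
         burst_times = burst_times, signal = signal, noise = noise,
         realized_snr_db = realized)
  })
}

# 1 for each frame whose [start, start+window) interval (in absolute
# seconds, frames laid on the section starting at offset_s) overlaps any
# burst interval [t, t + burst_dur).
label_frames <- function(grid, burst_times, burst_dur, offset_s = 0) {
  starts <- offset_s + (seq_len(grid$n_frames) - 1L) * grid$hop / grid$rate
  ends <- starts + grid$window / grid$rate
  lab <- integer(grid$n_frames)
  for (t0 in burst_times)
    lab[starts < t0 + burst_dur & ends > t0] <- 1L
  lab
}

#' Synthesize a labeled teacher set
#'
#' Builds `n_clips` short clips: positive clips contain crackle bursts in
#' noise, negative clips noise only. Frame labels are exact by
#' construction. The default size of 50 clips mirrors the size of the
#' teacher data used to train the deployed discriminator.
#'
#' @param n_clips number of clips (default 50).
#' @param pos_fraction fraction of positive clips, strictly in (0, 1).
#' @param spec a [crackle_spec()].
#' @param seed integer seed.
#' @param rate sampling rate, Hz.
#' @param clip_dur clip duration, seconds.
#' @param burst_rate bursts/s within a positive clip (at least one burst
#'   is always placed).
#' @param noise_rms,snr_db background level and burst SNR.
#' @param hop_s,window_s frame grid parameters for the label tracks.
#' @return An object of class `teacher_set`: `clips` (each with
#'   `recording`, `labels`, `label`), and `layout = NULL` (callers pick
#'   the layout at training time).
#' @export
synth_teacher_set <- function(n_clips = 50L, pos_fraction = 0.5,
                              spec = crackle_spec(), seed = 1L, rate = 44100,
                              clip_dur = 0.8, burst_rate = 8,
                              noise_rms = 0.05, snr_db = 10,
                              hop_s = 0.012, window_s = 0.024) {
  stopifnot(n_clips >= 2L)
  if (pos_fraction <= 0 || pos_fraction >= 1)
    stop("pos_fraction must be strictly between 0 and 1")
  n_pos <- round(n_clips * pos_fraction)
  if (n_pos == 0L || n_pos == n_clips)
    stop("teacher set must contain both classes")
  is_pos <- rep(c(1L, 0L), c(n_pos, n_clips - n_pos))

  clips <- lapply(seq_len(n_clips), function(i) {
    run_seeded(seed + i, {
      n <- round(clip_dur * rate)
      noise <- synth_noise(n, noise_rms, "white")
      burst_times <- numeric(0)
      signal <- numeric(n)
      if (is_pos[i] == 1L) {
        margin <- 0.05
        latest <- clip_dur - margin - spec$burst_dur
        n_b <- max(1L, stats::rpois(1, burst_rate * (latest - margin)))
        burst_times <- sort(stats::runif(n_b, margin, latest))
        burst <- synth_crackle(spec, rate)
        for (t0 in burst_times) {
          i0 <- round(t0 * rate) + 1L
          ii <- i0:(i0 + length(burst) - 1L)
          signal[ii] <- signal[ii] + burst
        }
        support <- signal != 0
        g <- sqrt(mean(noise^2) * 10^(snr_db / 10) / mean(signal[support]^2))
        signal <- signal * g
      }
      x <- noise + signal
      peak <- max(abs(x), 1)
      if (peak > 1) x <- x / peak
      rec <- audio_recording(x, rate)
      grid <- make_grid(rec, hop_s = hop_s, window_s = window_s)
      list(recording = rec,
           labels = label_frames(grid, burst_times, spec$burst_dur),
           label = is_pos[i])
    })
  })
  structure(list(clips = clips, layout = NULL, seed = as.integer(seed)),
            class = "teacher_set")
}

#' @export
print.teacher_set <- function(x, ...) {
  pos <- sum(vapply(x$clips, `[[`, integer(1), "label"))
  cat(sprintf("<teacher_set> %d clips (%d positive, %d negative)\n",
              length(x$clips), pos, length(x$clips) - pos))
  invisible(x)
}

#' Synthetic patient cohort specification
#'
#' Covariate distributions emulate the clinical profile of an ALS cohort
#' (age, functional scores, respiratory and swallowing measures); the
#' swallowing sound index is generated as a linear model
#' `index = beta0 + sum(beta_j * covariate_j) + eps`, `eps ~ N(0, sigma)`,
#' clipped to \[0, 1\]. Bounded scores are drawn as rounded truncated
#' normals within their scale limits.
#'
#' @param n_patients cohort size (>= 3).
#' @param beta named numeric vector of true coefficients on covariates
#'   (default: 0.006 per ALSFRS-R total point, the magnitude scale of the
#'   reported age-adjusted association).
#' @param beta0 intercept (default chosen so the mean index is ~0.21).
#' @param sigma residual SD of the index.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 24L,
                        beta = c(alsfrs_r_total = 0.006),
                        beta0 = -0.025, sigma = 0.04, seed = 1L) {
  stopifnot(n_patients >= 3L, sigma >= 0)
  structure(list(n_patients = as.integer(n_patients), beta = beta,
                 beta0 = beta0, sigma = sigma, seed = as.integer(seed)),
            class = "cohort_spec")
}

# rounded, range-clipped normal draw
rnorm_score <- function(n, mean, sd, lo, hi, digits = 0) {
  pmin(hi, pmax(lo, round(stats::rnorm(n, mean, sd), digits)))
}

#' Generate a synthetic patient cohort
#'
#' One row per patient with the covariates of a clinical background
#' table (age, sex, BMI, disease duration, ALSFRS-R total and bulbar
#' sub-score, onset type, albumin, %VC, tongue pressure, MASA total and
#' pharyngeal scores) and a swallowing sound `index` generated from the
#' planted linear model of `spec`. The true coefficients are attached as
#' attributes `true_beta`, `true_beta0`, `sigma` for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` of class `c("swallow_cohort", "data.frame")`.
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  run_seeded(spec$seed, {
    d <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      age = rnorm_score(n, 64.0, 11.8, 18, 95, 1),
      sex = ifelse(stats::runif(n) < 0.542, "female", "male"),
      bmi = rnorm_score(n, 21.9, 3.3, 14, 40, 1),
      duration_months = pmin(114, pmax(4, round(stats::rlnorm(n, log(17.5), 0.8)))),
      alsfrs_r_total = rnorm_score(n, 39, 7, 0, 48),
      alsfrs_r_bulbar = rnorm_score(n, 10.5, 2.2, 0, 12),
      onset_type = ifelse(stats::runif(n) < 0.208, "bulbar", "limb"),
      albumin = rnorm_score(n, 4.1, 0.4, 2, 6, 1),
      pct_vc = rnorm_score(n, 80.5, 20.4, 10, 140, 1),
      tongue_pressure = rnorm_score(n, 27.6, 16.2, 0.5, 80, 1),
      masa_total = rnorm_score(n, 192, 10, 100, 200),
      masa_pharyngeal = rnorm_score(n, 67, 3, 40, 70),
      stringsAsFactors = FALSE
    )
    for (v in names(spec$beta))
      if (!v %in% names(d)) stop("unknown covariate in beta: ", v)
    zero_var <- vapply(names(spec$beta),
                       function(v) stats::var(as.numeric(d[[v]])) == 0, logical(1))
    if (any(zero_var))
      warning("degenerate covariate distribution (zero variance): ",
              paste(names(spec$beta)[zero_var], collapse = ", "))
    lin <- spec$beta0
    for (v in names(spec$beta)) lin <- lin + spec$beta[[v]] * as.numeric(d[[v]])
    d$index <- pmin(1, pmax(0, lin + stats::rnorm(n, 0, spec$sigma)))
    attr(d, "true_beta") <- spec$beta
    attr(d, "true_beta0") <- spec$beta0
    attr(d, "sigma") <- spec$sigma
    class(d) <- c("swallow_cohort", "data.frame")
    d
  })
}
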