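# Shared fixtures, built in code at test time.

# seeded noise recording
noise_recording <- function(dur = 1, rate = 44100, seed = 1, rms = 0.1) {
  set.seed(seed)
  audio_recording(rms * rnorm(round(dur * rate)), rate)
}

# hand-built frame_decisions with a given 0/1 track (hop_s sets the
# frames-per-second binning)
fake_decisions <- function(present, hop_s = 0.01, threshold = 0) {
  grid <- structure(
    list(hop = 1L, window = 1L, hop_s = hop_s, window_s = 2 * hop_s,
         n_frames = length(present), rate = 1 / hop_s),
    class = "frame_grid")
  structure(
    list(y = ifelse(present > 0, threshold + 1, threshold - 1),
         present = as.integer(present), threshold = threshold, grid = grid),
    class = "frame_decisions")
}

trial_of <- function(fraction, n = 100) {
  fake_decisions(rep(c(1L, 0L), c(round(fraction * n), n - round(fraction * n))))
}

# teacher set that is linearly separable at the frame level: positive
# clips are sustained tones (clip-level label 1), negative clips are
# near-silence; frame energy alone separates the classes.
tone_silence_teacher <- function(n_clips = 10, rate = 44100, dur = 0.25) {
  n <- round(dur * rate)
  t <- (seq_len(n) - 1) / rate
  clips <- lapply(seq_len(n_clips), function(i) {
    if (i %% 2L == 1L) {
      amp <- 0.3 + 0.02 * i
      rec <- audio_recording(amp * sin(2 * pi * (600 + 10 * i) * t), rate)
      list(recording = rec, label = 1L)
    } else {
      set.seed(1000 + i)
      rec <- audio_recording(1e-4 * rnorm(n), rate)
      list(recording = rec, label = 0L)
    }
  })
  structure(list(clips = clips, layout = NULL), class = "teacher_set")
}

# small random normalized feature matrix with layout names
random_feature_matrix <- function(n, seed = 1, layout = default_feature_layout()) {
  set.seed(seed)
  x <- matrix(runif(n * layout$n_features, -1, 1), nrow = n,
              dimnames = list(NULL, layout$names))
  x
}

# crackle_model built by hand from coefficients
manual_model <- function(a, threshold = 0, layout = default_feature_layout()) {
  normalizer <- structure(
    list(min = setNames(rep(-1, layout$n_features), layout$names),
         max = setNames(rep(1, layout$n_features), layout$names),
         names = layout$names),
    class = "feature_normalizer")
  structure(
    list(a = a, threshold = threshold, normalizer = normalizer,
         layout = layout, hop_s = 0.012, window_s = 0.024,
         training_meta = list(), stumps = list()),
    class = "crackle_model")
}
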