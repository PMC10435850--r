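# End-to-end: recording(s) -> trimmed section -> frames -> features ->
# frame decisions -> per-trial index -> swallowing sound index.

#' Frame decisions for one recording
#'
#' Trims the auscultation edges, frames the section on the model's grid,
#' extracts and normalizes features and scores them.
#'
#' @param rec an [audio_recording()] or `auscultation_section`.
#' @param model a `crackle_model`.
#' @param edge_s edge exclusion in seconds (default 0.2; ignored when a
#'   section is passed).
#' @return a `frame_decisions` object.
#' @export
classify_recording <- function(rec, model, edge_s = 0.2) {
  section <- if (inherits(rec, "auscultation_section")) rec
             else trim_auscultation(rec, edge_s)
  grid <- make_grid(section, hop_s = model$hop_s, window_s = model$window_s)
  raw <- extract_raw_features(section, grid, model$layout)
  score_frames(raw, model)
}

#' Swallowing sound index over repeated trials
#'
#' Applies [classify_recording()] and [compute_trial_index()] to each
#' trial recording and aggregates with [aggregate_trials()].
#'
#' @param recordings list of [audio_recording()] objects (one per trial).
#' @param model a `crackle_model`.
#' @param edge_s edge exclusion per trial, seconds.
#' @param scale reported scale for the aggregate.
#' @return a `swallowing_sound_index`.
#' @export
swallow_index_from_recordings <- function(recordings, model, edge_s = 0.2,
                                          scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  if (length(recordings) == 0L) stop("no trial recordings")
  trials <- lapply(seq_along(recordings), function(i) {
    dec <- classify_recording(recordings[[i]], model, edge_s)
    compute_trial_index(dec, trial_id = i)
  })
  aggregate_trials(trials, scale = scale)
}

#' Swallowing sound index from WAV files
#'
#' @param paths character vector of trial WAV paths.
#' @inheritParams swallow_index_from_recordings
#' @return a `swallowing_sound_index`.
#' @export
swallow_index_from_wavs <- function(paths, model, edge_s = 0.2,
                                    scale = c("fraction", "percent")) {
  recs <- lapply(paths, read_wav)
  swallow_index_from_recordings(recs, model, edge_s, scale)
}
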