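# FCQV and the swallowing sound index.
#
# The per-trial index is the fraction of auscultation-section frames in
# which the target (fine-crackle / bolus inflow) sound was detected:
#   INDEX = target frames / total frames (x 100 on the percent scale).
# The per-second FCQV series is the same fraction restricted to each
# second; the swallowing sound index of a participant is the maximum of
# the per-trial indices over the repeated water-swallow trials. Both the
# fraction and the percent scale are always carried, with fraction as the
# reported default (matching the magnitude of published indices).

# seconds bin of each frame, from the frame start time on the grid
frame_seconds <- function(decisions) {
  grid <- decisions$grid
  if (is.null(grid)) stop("frame_decisions carry no grid")
  floor((seq_along(decisions$y) - 1L) * grid$hop_s)
}

#' Per-second fine-crackle quantitative values (FCQV)
#'
#' For each second of the decision track, the fraction of frames in which
#' the target sound was present (x 100 on the percent scale). Frames are
#' binned by their start time; a trailing partial second is computed over
#' its actual frame count rather than discarded, so short 3-mL swallow
#' recordings lose no data.
#'
#' @param decisions a `frame_decisions` object from [score_frames()] (or
#'   any list with `present` and `grid`).
#' @param scale `"fraction"` (default) or `"percent"`.
#' @return An object of class `fcqv_series`: `values` (one per second),
#'   `seconds` (count), `n_frames`/`n_target` per second, and `scale`.
#' @export
compute_fcqv <- function(decisions, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  if (length(decisions$present) == 0L) stop("empty decision track")
  sec <- frame_seconds(decisions)
  lv <- factor(sec, levels = sort(unique(sec)))
  n_tot <- as.integer(table(lv))
  n_pos <- as.integer(tapply(decisions$present, lv, sum))
  frac <- n_pos / n_tot
  structure(
    list(values = if (scale == "percent") 100 * frac else frac,
         seconds = length(frac), second = as.numeric(levels(lv)),
         n_frames = n_tot, n_target = n_pos, scale = scale),
    class = "fcqv_series"
  )
}

#' @export
print.fcqv_series <- function(x, ...) {
  cat(sprintf("<fcqv_series> %d seconds (%s scale): %s\n", x$seconds, x$scale,
              paste(signif(x$values, 3), collapse = " ")))
  invisible(x)
}

#' Per-trial swallowing sound index
#'
#' Exact frame counts over the whole auscultation section:
#' `index_fraction = n_target / n_total`, `index_percent = 100 x` that.
#'
#' @param decisions a `frame_decisions` object.
#' @param trial_id optional identifier carried into the result.
#' @return An object of class `trial_index` with `n_target_frames`,
#'   `n_total_frames`, `index_fraction`, `index_percent`.
#' @export
compute_trial_index <- function(decisions, trial_id = NA) {
  n_total <- length(decisions$present)
  if (n_total == 0L) stop("zero total frames")
  n_target <- sum(decisions$present > 0)
  structure(
    list(trial_id = trial_id,
         n_target_frames = as.integer(n_target),
         n_total_frames = as.integer(n_total),
         index_fraction = n_target / n_total,
         index_percent = 100 * n_target / n_total),
    class = "trial_index"
  )
}

#' @export
print.trial_index <- function(x, ...) {
  cat(sprintf("<trial_index> %d/%d frames -> %.4f (%.2f%%)\n",
              x$n_target_frames, x$n_total_frames,
              x$index_fraction, x$index_percent))
  invisible(x)
}

#' Aggregate repeated trials into the swallowing sound index
#'
#' The participant-level swallowing sound index is the maximum of the
#' per-trial indices (typically over three 3-mL water swallows).
#'
#' @param trials list of `trial_index` objects.
#' @param scale reported scale, `"fraction"` (default) or `"percent"`.
#' @return An object of class `swallowing_sound_index`: `value` (max on
#'   the chosen scale), `value_fraction`, `value_percent`, `which_max`,
#'   and the per-trial `trials`.
#' @export
aggregate_trials <- function(trials, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  if (length(trials) == 0L) stop("empty trial list")
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_index")))
  fr <- vapply(trials, `[[`, numeric(1), "index_fraction")
  structure(
    list(value = if (scale == "percent") 100 * max(fr) else max(fr),
         value_fraction = max(fr), value_percent = 100 * max(fr),
         which_max = which.max(fr), scale = scale, trials = trials),
    class = "swallowing_sound_index"
  )
}

#' @export
print.swallowing_sound_index <- function(x, ...) {
  cat(sprintf("<swallowing_sound_index> %.4f (%.2f%%), max of %d trial(s)\n",
              x$value_fraction, x$value_percent, length(x$trials)))
  invisible(x)
}

#' FCQV-threshold swallow discriminator
#'
#' Flags each second in which the FCQV exceeds the threshold; the overall
#' decision is whether any second exceeds it (target sound present).
#'
#' @param fcqv an `fcqv_series`.
#' @param fcqv_threshold threshold on the same scale as the series.
#' @param scale scale the threshold is expressed on; must match the
#'   series.
#' @return list with per-second logical `flags` and overall boolean
#'   `present`.
#' @export
detect_swallow <- function(fcqv, fcqv_threshold,
                           scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fcqv, "fcqv_series"))
  if (!identical(scale, fcqv$scale))
    stop("threshold scale (", scale, ") does not match series scale (",
         fcqv$scale, ")")
  flags <- fcqv$values > fcqv_threshold
  list(flags = flags, present = any(flags))
}
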