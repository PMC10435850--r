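# Frame-level fine-crackle discriminator.
#
# Training follows boosting with depth-1 stumps on single normalized
# features; the deployed model is strictly linear, y = sum(a_i * x_i)
# compared against a learned threshold. The linear coefficients are the
# least-squares projection of the boosted additive margin onto the linear
# form over the training frames, so both printed facts of the method —
# AdaBoost training and a linear deployed score — hold simultaneously.

# Best stump over all features for weights w; labels y in {-1,+1}.
# Returns feature index j, threshold theta, polarity p in {-1,+1} and the
# weighted error. Prediction rule: p * sign(x_j - theta), with sign(0) -> -1.
best_stump <- function(X, y, w, orders) {
  n <- nrow(X)
  best <- list(err = Inf, j = NA_integer_, theta = NA_real_, polarity = 1)
  # err(theta, p=+1) = P_w(y=+1, x<=theta) + P_w(y=-1, x>theta)
  wp_tot <- sum(w[y > 0])
  for (j in seq_len(ncol(X))) {
    o <- orders[[j]]
    xv <- X[o, j]
    dif <- diff(xv) > 0
    if (!any(dif)) next                       # constant feature
    cs <- cumsum((w[o]) * (y[o] > 0))         # weight of positives at or below
    csn <- cumsum((w[o]) * (y[o] < 0))
    wn_tot <- sum(w) - wp_tot
    k <- which(dif)                           # split after sorted position k
    err_pos <- cs[k] + (wn_tot - csn[k])      # predict +1 above theta
    err_neg <- wp_tot - cs[k] + csn[k]        # predict +1 at/below theta
    e_min_pos <- min(err_pos); e_min_neg <- min(err_neg)
    if (e_min_pos <= e_min_neg && e_min_pos < best$err) {
      kk <- k[which.min(err_pos)]
      best <- list(err = e_min_pos, j = j,
                   theta = (xv[kk] + xv[kk + 1L]) / 2, polarity = 1)
    } else if (e_min_neg < e_min_pos && e_min_neg < best$err) {
      kk <- k[which.min(err_neg)]
      best <- list(err = e_min_neg, j = j,
                   theta = (xv[kk] + xv[kk + 1L]) / 2, polarity = -1)
    }
  }
  best
}

stump_predict <- function(x, theta, polarity) {
  polarity * ifelse(x > theta, 1, -1)
}

# Boost stumps over a normalized feature matrix and project the margin
# onto the linear form. X: n x p in [-1,1]; lab01: 0/1 frame labels.
# Returns a (length p), the stump list and the boosted margin.
boost_linear <- function(X, lab01, rounds) {
  y <- ifelse(lab01 > 0, 1, -1)
  n <- nrow(X)
  w <- ifelse(y > 0, 1 / (2 * sum(y > 0)), 1 / (2 * sum(y < 0)))
  orders <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))

  Fmargin <- numeric(n)
  stumps <- list()
  for (t in seq_len(rounds)) {
    st <- best_stump(X, y, w, orders)
    if (!is.finite(st$err) || st$err >= 0.5) break
    err <- max(st$err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    h <- stump_predict(X[, st$j], st$theta, st$polarity)
    Fmargin <- Fmargin + alpha * h
    stumps[[length(stumps) + 1L]] <-
      list(feature = st$j, theta = st$theta, polarity = st$polarity,
           alpha = alpha, err = st$err)
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
    if (st$err < 1e-9) break                  # perfect stump; margin fixed
  }
  if (length(stumps) == 0L) stop("boosting found no informative feature split")

  # least-squares projection of the boosted margin onto y = sum(a_i x_i),
  # restricted to the features the stumps actually vote on (all others
  # get coefficient 0); an intercept is carried during the fit and
  # absorbed by the threshold
  used <- sort(unique(vapply(stumps, `[[`, integer(1), "feature")))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, used, drop = FALSE]),
                       Fmargin)
  a <- numeric(ncol(X))
  cf <- fit$coefficients[-1L]
  cf[is.na(cf)] <- 0
  a[used] <- cf
  list(a = a, stumps = stumps, Fmargin = Fmargin)
}

#' Train the fine-crackle frame discriminator
#'
#' Boosts decision stumps on single normalized features over the pooled
#' frames of a labeled teacher set, then projects the boosted margin onto
#' the linear form `y = sum(a_i * x_i)` by least squares. The decision
#' threshold on `y` is chosen by [choose_threshold()] (maximum balanced
#' accuracy on the training frames). Initial boosting weights are balanced
#' per class, because crackle frames are rare in recordings.
#'
#' @param teacher a teacher set as produced by [synth_teacher_set()]: a
#'   list with `clips` (each clip a list with an [audio_recording()]
#'   `recording` and per-frame 0/1 `labels`, or a clip-level `label` that
#'   is broadcast to all frames) and optionally `layout`.
#' @param rounds boosting rounds (default 100).
#' @param seed integer seed recorded with the model; training itself is
#'   deterministic (tie-breaks go to the lowest feature index).
#' @param layout feature layout (default [default_feature_layout()]).
#' @param hop_s,window_s frame grid parameters.
#' @param edge_s edge exclusion applied to each clip before framing
#'   (default 0: teacher clips are taken whole; set 0.2 when the label
#'   tracks were produced on trimmed sections).
#' @return An object of class `crackle_model`: coefficients `a` (148),
#'   `threshold`, `normalizer`, `layout`, and `training_meta` (rounds
#'   used, seed, training error of the boosted and of the linear model,
#'   degenerate-threshold flag).
#' @export
train_crackle_model <- function(teacher, rounds = 100L, seed = 1L,
                                layout = NULL,
                                hop_s = 0.012, window_s = 0.024,
                                edge_s = 0) {
  if (is.null(layout)) layout <- teacher$layout
  if (is.null(layout)) layout <- default_feature_layout()
  if (length(teacher$clips) == 0L) stop("empty teacher set")

  feats <- lapply(teacher$clips, function(clip) {
    section <- if (edge_s > 0) trim_auscultation(clip$recording, edge_s)
               else clip$recording
    grid <- make_grid(section, hop_s = hop_s, window_s = window_s)
    raw <- extract_raw_features(section, grid, layout)
    lab <- if (!is.null(clip$labels)) clip$labels else rep(clip$label, grid$n_frames)
    if (length(lab) != grid$n_frames)
      stop("label track length does not match the clip's frame grid")
    list(raw = raw, lab = as.integer(lab))
  })
  raw <- do.call(rbind, lapply(feats, `[[`, "raw"))
  lab01 <- unlist(lapply(feats, `[[`, "lab"))
  if (length(unique(lab01)) < 2L)
    stop("teacher set must contain both positive and negative frames")

  normalizer <- fit_normalizer(raw)
  X <- apply_normalizer(raw, normalizer)
  bl <- boost_linear(X, lab01, rounds)
  a <- bl$a
  scores <- drop(X %*% a)
  thr <- choose_threshold(scores, lab01)

  boosted_err <- mean((bl$Fmargin > 0) != (lab01 > 0))
  linear_err <- mean((scores > thr$threshold) != (lab01 > 0))
  n <- nrow(X)
  stumps <- bl$stumps
  structure(
    list(a = a, threshold = thr$threshold,
         normalizer = normalizer, layout = layout,
         hop_s = hop_s, window_s = window_s,
         training_meta = list(
           rounds_requested = as.integer(rounds),
           rounds_used = length(stumps), seed = as.integer(seed),
           boosted_training_error = boosted_err,
           linear_training_error = linear_err,
           degenerate_threshold = thr$degenerate,
           n_frames = n, n_positive = sum(lab01 > 0)),
         stumps = stumps),
    class = "crackle_model"
  )
}

#' @export
print.crackle_model <- function(x, ...) {
  cat(sprintf(paste0("<crackle_model> %d coefficients, threshold %.4g; ",
                     "%d boosting rounds, training error %.3f (linear form)\n"),
              length(x$a), x$threshold, x$training_meta$rounds_used,
              x$training_meta$linear_training_error))
  invisible(x)
}

#' Choose the decision threshold on frame scores
#'
#' Scans the midpoints between adjacent distinct sorted scores (plus
#' sentinels below the minimum and above the maximum) and returns the
#' threshold maximizing balanced accuracy of the rule `score > threshold
#' => positive`. When several candidates tie, the middle one of the tied
#' range is taken, so the threshold sits at the midpoint between the two
#' adjacent candidate scores; this also makes the choice equivariant
#' under a constant shift of all scores.
#'
#' @param scores numeric frame scores.
#' @param labels 0/1 frame labels.
#' @return list with `threshold`, `balanced_accuracy`, `degenerate`
#'   (TRUE when all scores are equal, in which case the threshold is that
#'   common value).
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  if (length(unique(labels)) < 2L) stop("both classes required")
  su <- sort(unique(scores))
  if (length(su) == 1L)
    return(list(threshold = su, balanced_accuracy = 0.5, degenerate = TRUE))
  span <- su[length(su)] - su[1]
  cand <- c(su[1] - span / 2, (su[-length(su)] + su[-1]) / 2,
            su[length(su)] + span / 2)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  ba <- vapply(cand, function(th) {
    sens <- sum(scores > th & labels == 1L) / np
    spec <- sum(scores <= th & labels == 0L) / nn
    (sens + spec) / 2
  }, numeric(1))
  best <- which(ba >= max(ba) - 1e-12)
  pick <- best[ceiling(length(best) / 2)]
  list(threshold = cand[pick], balanced_accuracy = max(ba), degenerate = FALSE)
}

#' Score frames with a trained model
#'
#' Normalizes raw features with the model's stored normalizer (skipped if
#' the matrix is already normalized), computes the exact dot product
#' `y[k] = sum(a_i * x[k, i])` and thresholds it.
#'
#' @param features raw or normalized feature matrix with the model's
#'   layout (column names must match).
#' @param model a `crackle_model`.
#' @param normalized set `TRUE` if `features` is already in \[-1, 1\].
#' @return An object of class `frame_decisions`: `y` (scores), `present`
#'   (0/1), `threshold`, and the `grid` attribute of the input if present.
#' @export
score_frames <- function(features, model, normalized = FALSE) {
  stopifnot(inherits(model, "crackle_model"))
  if (!identical(colnames(features), model$layout$names))
    stop("feature layout mismatch between matrix and model")
  x <- if (normalized) features else apply_normalizer(features, model$normalizer)
  y <- drop(x %*% model$a)
  structure(
    list(y = y, present = as.integer(y > model$threshold),
         threshold = model$threshold, grid = attr(features, "grid")),
    class = "frame_decisions"
  )
}

#' @export
print.frame_decisions <- function(x, ...) {
  cat(sprintf("<frame_decisions> %d frames, %d positive (threshold %.4g)\n",
              length(x$y), sum(x$present), x$threshold))
  invisible(x)
}

#' Save / load a crackle model as JSON
#'
#' The model file is a single JSON document holding the layout, the
#' normalizer, the 148 coefficients, the threshold and the training
#' metadata, written with 17 significant digits so that scores reproduce
#' bitwise after a round trip.
#'
#' @param model a `crackle_model`.
#' @param path file path for the JSON document.
#' @return `save_crackle_model` returns `path` invisibly;
#'   `load_crackle_model` returns the `crackle_model`.
#' @export
save_crackle_model <- function(model, path) {
  stopifnot(inherits(model, "crackle_model"))
  doc <- list(
    layout = model$layout[c("names", "n_mel", "n_cepstra", "f_min", "f_max",
                            "lifter_cutoff", "floor_db", "band_splits")],
    normalizer = list(min = unname(model$normalizer$min),
                      max = unname(model$normalizer$max),
                      names = model$normalizer$names),
    a = model$a, threshold = model$threshold,
    hop_s = model$hop_s, window_s = model$window_s,
    training_meta = model$training_meta,
    stumps = model$stumps
  )
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname save_crackle_model
#' @param path file path for the JSON document.
#' @export
load_crackle_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  layout <- structure(c(doc$layout,
                        list(n_features = length(doc$layout$names))),
                      class = "feature_layout")
  layout$names <- unlist(layout$names)
  layout$band_splits <- unlist(layout$band_splits)
  normalizer <- structure(
    list(min = stats::setNames(unlist(doc$normalizer$min), unlist(doc$normalizer$names)),
         max = stats::setNames(unlist(doc$normalizer$max), unlist(doc$normalizer$names)),
         names = unlist(doc$normalizer$names)),
    class = "feature_normalizer")
  structure(
    list(a = unlist(doc$a), threshold = doc$threshold,
         normalizer = normalizer, layout = layout,
         hop_s = doc$hop_s, window_s = doc$window_s,
         training_meta = doc$training_meta,
         stumps = doc$stumps),
    class = "crackle_model"
  )
}
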