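test_that("boosting isolates a single perfectly separating feature", {
  X <- random_feature_matrix(300, seed = 11)
  lab <- as.integer(X[, 7] > 0.3)
  bl <- swallowsound:::boost_linear(X, lab, rounds = 60)

  expect_equal(which.max(abs(bl$a)), 7L)

  # brute-force training error of the deployed linear rule
  scores <- drop(X %*% bl$a)
  thr <- choose_threshold(scores, lab)
  brute_err <- sum((scores > thr$threshold) != (lab > 0)) / length(lab)
  expect_equal(brute_err, 0)
})

test_that("inverting labels inverts every decision", {
  X <- random_feature_matrix(200, seed = 12)
  lab <- as.integer(X[, 7] > 0)
  b1 <- swallowsound:::boost_linear(X, lab, rounds = 40)
  b2 <- swallowsound:::boost_linear(X, 1L - lab, rounds = 40)
  expect_equal(b2$a, -b1$a, tolerance = 1e-8)

  t1 <- choose_threshold(drop(X %*% b1$a), lab)
  t2 <- choose_threshold(drop(X %*% b2$a), 1L - lab)
  d1 <- drop(X %*% b1$a) > t1$threshold
  d2 <- drop(X %*% b2$a) > t2$threshold
  expect_identical(d2, !d1)
})

test_that("degenerate teacher sets are rejected", {
  ts <- tone_silence_teacher(n_clips = 4)
  for (i in seq_along(ts$clips)) ts$clips[[i]]$label <- 1L
  expect_error(train_crackle_model(ts, rounds = 5), "both positive and negative")
  expect_error(train_crackle_model(list(clips = list())), "empty")
})

test_that("training reaches zero error on a linearly separable teacher set", {
  ts <- tone_silence_teacher(n_clips = 10)
  m <- train_crackle_model(ts, rounds = 50, seed = 2)
  expect_equal(m$training_meta$linear_training_error, 0)
  expect_length(m$a, 148L)
  expect_true(all(is.finite(m$a)))
})

test_that("frame scores are the exact dot product with the Holder bound", {
  lay <- default_feature_layout()

  zero <- manual_model(rep(0, 148), threshold = 0.5, layout = lay)
  x <- random_feature_matrix(20, seed = 13)
  d0 <- score_frames(x, zero, normalized = TRUE)
  expect_equal(d0$y, rep(0, 20))
  expect_equal(d0$present, rep(0L, 20))

  a <- c(0.5, rep(0, 147))
  m <- manual_model(a, threshold = 0, layout = lay)
  one <- matrix(c(1, rep(0, 147)), 1, dimnames = list(NULL, lay$names))
  expect_equal(score_frames(one, m, normalized = TRUE)$y, 0.5)

  set.seed(14)
  a2 <- rnorm(148)
  m2 <- manual_model(a2, layout = lay)
  d2 <- score_frames(random_feature_matrix(50, seed = 15), m2, normalized = TRUE)
  expect_true(max(abs(d2$y)) <= sum(abs(a2)) + 1e-12)

  bad <- x[, c(2:148, 1)]
  expect_error(score_frames(bad, m2, normalized = TRUE), "layout mismatch")
})

test_that("threshold choice is balanced, shift-equivariant and flags degeneracy", {
  s <- c(rep(1, 10), rep(-1, 10))
  lab <- rep(c(1L, 0L), each = 10)
  th <- choose_threshold(s, lab)
  expect_equal(th$threshold, 0)
  expect_equal(th$balanced_accuracy, 1)
  expect_false(th$degenerate)

  deg <- choose_threshold(rep(2.5, 20), lab)
  expect_true(deg$degenerate)
  expect_equal(deg$threshold, 2.5)
  expect_equal(deg$balanced_accuracy, 0.5)

  set.seed(16)
  s2 <- rnorm(60)
  lab2 <- as.integer(s2 + rnorm(60, sd = 0.5) > 0)
  base <- choose_threshold(s2, lab2)
  shifted <- choose_threshold(s2 + 3.25, lab2)
  expect_equal(shifted$threshold, base$threshold + 3.25)
  expect_equal(shifted$balanced_accuracy, base$balanced_accuracy)

  expect_error(choose_threshold(s, rep(1L, 20)), "both classes")
})

test_that("model JSON serialization round-trips scores bitwise", {
  ts <- synth_teacher_set(n_clips = 8, seed = 31, clip_dur = 0.4)
  m <- train_crackle_model(ts, rounds = 20, seed = 31)
  f <- withr::local_tempfile(fileext = ".json")
  save_crackle_model(m, f)
  m2 <- load_crackle_model(f)
  expect_identical(m2$a, m$a)
  expect_identical(m2$threshold, m$threshold)
  expect_identical(unname(m2$normalizer$min), unname(m$normalizer$min))

  sim <- synth_recording(swallow_scenario(duration_s = 1.5,
                                          swallow_window = c(0.4, 1.1),
                                          seed = 32))
  sec <- trim_auscultation(sim$recording, 0.2)
  raw <- extract_raw_features(sec, make_grid(sec), m$layout)
  expect_identical(score_frames(raw, m)$y, score_frames(raw, m2)$y)
})

test_that("teacher clip order does not change held-out decisions", {
  ts <- synth_teacher_set(n_clips = 10, seed = 41, clip_dur = 0.4)
  perm <- ts
  set.seed(42)
  perm$clips <- perm$clips[sample(length(perm$clips))]
  m1 <- train_crackle_model(ts, rounds = 25, seed = 41)
  m2 <- train_crackle_model(perm, rounds = 25, seed = 41)

  sim <- synth_recording(swallow_scenario(duration_s = 1.5,
                                          swallow_window = c(0.4, 1.1),
                                          seed = 43))
  d1 <- classify_recording(sim$recording, m1)
  d2 <- classify_recording(sim$recording, m2)
  expect_equal(d1$present, d2$present)
})
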