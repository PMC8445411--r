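# Tap-log IO, double-tap cleaning, ITI extraction, accuracy scoring and
# learning/practice bookkeeping.

test_that("tap logs round-trip through the CSV and JSON dialects", {
  set.seed(11)
  recs <- c(records_with_flags(c(TRUE, TRUE), pid = "P01"),
            records_with_flags(c(FALSE, TRUE), pid = "P02",
                               condition = "LearnFromDemonstration"))
  for (dialect in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_tap_log(recs, path, dialect = dialect)
    back <- read_tap_log(path, dialect = dialect)
    expect_length(back, 4)
    expect_identical(vapply(back, `[[`, "", "participant_id"),
                     c("P01", "P01", "P02", "P02"))
    for (i in seq_along(recs)) {
      expect_equal(back[[i]]$taps$events$drum_id, recs[[i]]$taps$events$drum_id)
      expect_equal(back[[i]]$taps$events$onset, recs[[i]]$taps$events$onset,
                   tolerance = 1e-6)
      expect_equal(back[[i]]$taps$events$offset, recs[[i]]$taps$events$offset,
                   tolerance = 1e-6)
    }
  }
})

test_that("reading scores accuracy when a melody is supplied", {
  recs <- records_with_flags(c(FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tap_log(recs, path)
  back <- read_tap_log(path, melody = default_melody())
  expect_false(back[[1]]$correct)
  expect_true(back[[2]]$correct)
})

test_that("degenerate and malformed tap logs are reported", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_warning(out <- read_tap_log(empty), "empty")
  expect_identical(out, list())

  header_only <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("participant_id", "condition", "trial_index", "tap_index",
                     "drum_id", "onset_ms", "offset_ms", "velocity"),
                   collapse = ","), header_only)
  expect_warning(out <- read_tap_log(header_only), "no rows")
  expect_identical(out, list())

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,condition,trial_index,tap_index,drum_id,onset_ms,offset_ms,velocity",
               "P1,LearnFromPerformance,1,1,2,100,50,60"), bad)
  err <- tryCatch(read_tap_log(bad), error = identity)
  expect_s3_class(err, "taptrans_validation_error")
  expect_match(conditionMessage(err), "row 1")

  bad_drum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,condition,trial_index,tap_index,drum_id,onset_ms,offset_ms,velocity",
               "P1,LearnFromPerformance,1,1,7,100,150,60"), bad_drum)
  expect_error(read_tap_log(bad_drum), "drum_id",
               class = "taptrans_validation_error")

  expect_error(read_tap_log(withr::local_tempfile(), dialect = "csv"),
               class = "taptrans_io_error")
})

test_that("MIDI dialect is explicitly unsupported", {
  path <- withr::local_tempfile(fileext = ".mid")
  file.create(path)
  expect_error(read_tap_log(path, dialect = "midi"),
               class = "taptrans_unsupported_dialect")
})

test_that("double taps on the same drum merge by deleting the inner bounce", {
  ev <- data.frame(drum_id = c(2, 2), onset = c(0, 160),
                   offset = c(150, 260), velocity = c(60, 80))
  merged <- clean_double_taps(tap_sequence("t", ev), min_gap = 50)
  expect_equal(nrow(merged$events), 1)
  expect_equal(merged$events$onset, 0)
  expect_equal(merged$events$offset, 260)
  expect_equal(merged$events$velocity, 80)

  # different drums never merge, however close
  ev2 <- data.frame(drum_id = c(2, 3), onset = c(0, 160),
                    offset = c(150, 260), velocity = c(60, 80))
  expect_equal(nrow(clean_double_taps(tap_sequence("t", ev2), 50)$events), 2)

  # wide gaps never merge
  ev3 <- data.frame(drum_id = c(2, 2), onset = c(0, 400),
                    offset = c(150, 500), velocity = c(60, 80))
  expect_equal(nrow(clean_double_taps(tap_sequence("t", ev3), 50)$events), 2)

  expect_error(clean_double_taps(tap_sequence("t", ev), min_gap = -1),
               class = "taptrans_validation_error")
})

test_that("a run of bounces collapses to one tap and cleaning is idempotent", {
  ev <- data.frame(drum_id = rep(3, 3),
                   onset = c(0, 110, 220), offset = c(100, 210, 320),
                   velocity = c(50, 70, 60))
  once <- clean_double_taps(tap_sequence("t", ev), min_gap = 50)
  expect_equal(nrow(once$events), 1)
  expect_equal(once$events$onset, 0)
  expect_equal(once$events$offset, 320)
  expect_equal(once$events$velocity, 70)
  twice <- clean_double_taps(once, min_gap = 50)
  expect_identical(twice$events, once$events)

  set.seed(42)
  for (rep_i in 1:20) {
    itis <- random_itis()
    seq <- taps_from_itis(itis)
    once <- clean_double_taps(seq, 50)
    expect_identical(clean_double_taps(once, 50)$events, once$events)
  }
})

test_that("ITI extraction follows the offset-to-onset definition", {
  onsets <- seq(0, by = 500, length.out = 12)
  ev <- data.frame(drum_id = default_melody()$pitches, onset = onsets,
                   offset = onsets + 100, velocity = 64)
  expect_equal(extract_itis(tap_sequence("t", ev)), rep(400, 11))

  # overlap: next onset before previous offset gives a negative ITI
  ev2 <- ev
  ev2$onset[5] <- ev2$offset[4] - 30
  expect_warning(itis <- extract_itis(tap_sequence("t", ev2)), "negative")
  expect_equal(itis[4], -30)
  clamped <- suppressWarnings(extract_itis(tap_sequence("t", ev2),
                                           clamp_negative = TRUE))
  expect_equal(clamped[4], 0)

  expect_error(extract_itis(tap_sequence("t", ev[1:11, ])),
               class = "taptrans_length_error")
})

test_that("ITI extraction inverts tap materialisation exactly", {
  set.seed(7)
  for (dur in c(50, 100, 250)) {
    itis <- random_itis()
    expect_equal(extract_itis(itis_to_taps(itis, tap_duration = dur)), itis)
  }
  expect_error(itis_to_taps(c(rep(100, 10), -5)),
               class = "taptrans_validation_error")
})

test_that("accuracy depends only on drum order and detects the reversed mapping", {
  mel <- default_melody()
  good <- taps_from_itis(build_representation())
  acc <- score_sequence_accuracy(good, mel)
  expect_true(acc$correct)
  expect_true(is.na(acc$first_mismatch_index))
  expect_false(acc$reversed_mapping)

  # timing changes are irrelevant
  slow <- taps_from_itis(build_representation() * 3)
  expect_true(score_sequence_accuracy(slow, mel)$correct)

  rev_mel <- melody(5L - mel$pitches, mel$chunk_structure)
  reversed <- itis_to_taps(build_representation(), rev_mel)
  acc_rev <- score_sequence_accuracy(reversed, mel)
  expect_false(acc_rev$correct)
  expect_true(acc_rev$reversed_mapping)

  sub_pitches <- mel$pitches
  sub_pitches[5] <- setdiff(1:4, sub_pitches[5])[1]
  sub <- itis_to_taps(build_representation(),
                      melody(sub_pitches, mel$chunk_structure))
  acc_sub <- score_sequence_accuracy(sub, mel)
  expect_false(acc_sub$correct)
  expect_equal(acc_sub$first_mismatch_index, 5L)
  expect_false(acc_sub$reversed_mapping)

  short <- tap_sequence("t", good$events[1:11, ])
  expect_false(score_sequence_accuracy(short, mel)$correct)
})

test_that("phase partition takes the terminal ten correct trials as practice", {
  # errors on trials 1-2 then ten correct: 2 learning repetitions, 2 errors
  recs <- records_with_flags(c(FALSE, FALSE, rep(TRUE, 10)))
  parts <- partition_phases(recs)
  expect_length(parts$learning, 2)
  expect_length(parts$practice, 10)
  expect_true(all(vapply(parts$practice, `[[`, TRUE, "correct")))
  lr <- learning_rate_summary(parts)
  expect_equal(lr$n_learning_trials, 2)
  expect_equal(lr$n_errors, 2)

  # errors on trials 1 and 10, trials 2-9 correct, then ten correct:
  # 10 learning repetitions but only 2 errors
  recs_b <- records_with_flags(c(FALSE, rep(TRUE, 8), FALSE, rep(TRUE, 10)))
  lr_b <- learning_rate_summary(partition_phases(recs_b))
  expect_equal(lr_b$n_learning_trials, 10)
  expect_equal(lr_b$n_errors, 2)

  # error-free participant
  lr_c <- learning_rate_summary(partition_phases(records_with_flags(rep(TRUE, 10))))
  expect_equal(lr_c$n_learning_trials, 0)
  expect_equal(lr_c$n_errors, 0)

  # correct trials before a late error count as learning, not practice
  recs_d <- records_with_flags(c(rep(TRUE, 3), FALSE, rep(TRUE, 10)))
  parts_d <- partition_phases(recs_d)
  expect_length(parts_d$learning, 4)
  expect_identical(unique(vapply(parts_d$learning, `[[`, "", "phase")),
                   "learning")

  expect_error(partition_phases(records_with_flags(c(rep(TRUE, 9), FALSE))),
               class = "taptrans_incomplete_participant")
  expect_error(partition_phases(records_with_flags(rep(TRUE, 5))),
               class = "taptrans_incomplete_participant")
})

test_that("partition is a disjoint cover preserving trial order", {
  set.seed(99)
  for (i in 1:10) {
    n_learning <- sample(0:8, 1)
    flags <- c(if (n_learning > 0) c(stats::runif(n_learning - 1) > 0.4, FALSE),
               rep(TRUE, 10))
    parts <- partition_phases(records_with_flags(flags))
    all_idx <- vapply(c(parts$learning, parts$practice), `[[`, 1L,
                      "trial_index")
    expect_identical(sort(all_idx), seq_along(flags))
    expect_length(parts$practice, 10)
  }
})

test_that("melody definitions validate and round-trip as JSON", {
  expect_error(melody(c(1, 2, 5)), class = "taptrans_validation_error")
  expect_error(melody(rep(1, 12), chunk_structure = c(3, 3)),
               class = "taptrans_validation_error")
  mel <- default_melody()
  expect_length(mel$pitches, 12)
  expect_equal(sum(mel$chunk_structure), 12)
  expect_equal(chunk_boundaries(mel), c(3, 6, 8, 10))
  path <- withr::local_tempfile(fileext = ".json")
  write_melody(mel, path)
  expect_equal(read_melody(path), mel)
})
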