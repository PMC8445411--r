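# Tap-log IO, artefact cleaning, ITI extraction, accuracy scoring and
# learning/practice phase bookkeeping.

#' Construct a tap sequence
#'
#' A tap sequence holds the raw drum events of one production: per tap the
#' drum identity (1-4, mapping to the pitches C, E, G, A), onset and offset in
#' milliseconds from trial start, and strike velocity in arbitrary force
#' units. Events are stored sorted by onset.
#'
#' @param trial_id identifier for the trial.
#' @param events data frame with columns `drum_id`, `onset`, `offset`,
#'   `velocity`.
#' @return An object of class `tap_sequence`.
#' @export
tap_sequence <- function(trial_id, events) {
  events <- as.data.frame(events)
  required <- c("drum_id", "onset", "offset", "velocity")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop_taptrans(sprintf("tap events lack column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "taptrans_validation_error")
  }
  events <- events[required]
  if (nrow(events) > 0) {
    if (any(events$drum_id %% 1 != 0) || any(events$drum_id < 1) ||
        any(events$drum_id > 4)) {
      stop_taptrans("drum_id must be an integer in 1..4",
                    "taptrans_validation_error")
    }
    if (any(events$onset < 0)) {
      stop_taptrans("onsets must be non-negative", "taptrans_validation_error")
    }
    bad <- which(events$offset <= events$onset)
    if (length(bad) > 0) {
      stop_taptrans(sprintf("offset must exceed onset (violated at event %d)",
                            bad[1]),
                    "taptrans_validation_error")
    }
    events <- events[order(events$onset), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(trial_id = trial_id, events = events), class = "tap_sequence")
}

#' @export
print.tap_sequence <- function(x, ...) {
  cat(sprintf("<tap_sequence> trial %s: %d events\n",
              format(x$trial_id), nrow(x$events)))
  invisible(x)
}

#' Define a melody
#'
#' The to-be-learned melody is a fixed order of 12 drum hits over four drums
#' tuned to C, E, G and A, with a chunking structure (default 3-3-2-2-2) that
#' induces the rhythmic grouping: chunk boundaries are where long inter-tap
#' intervals occur.
#'
#' @param pitches integer vector of 12 drum ids in 1..4.
#' @param chunk_structure integer vector of chunk sizes summing to
#'   `length(pitches)`.
#' @return An object of class `melody`.
#' @export
melody <- function(pitches, chunk_structure = c(3, 3, 2, 2, 2)) {
  pitches <- as.integer(pitches)
  if (any(pitches < 1) || any(pitches > 4)) {
    stop_taptrans("melody pitches must be drum ids in 1..4",
                  "taptrans_validation_error")
  }
  chunk_structure <- as.integer(chunk_structure)
  if (any(chunk_structure < 1) || sum(chunk_structure) != length(pitches)) {
    stop_taptrans("chunk_structure must be positive sizes summing to the melody length",
                  "taptrans_validation_error")
  }
  structure(list(pitches = pitches, chunk_structure = chunk_structure),
            class = "melody")
}

#' Default 12-note study melody
#'
#' A synthetic stand-in for the study melody (the exact pitch order of the
#' original stimulus is not part of this package): 12 hits over the four
#' drums, 3-3-2-2-2 chunking, no immediately repeated drum. Accuracy scoring
#' depends only on the drum order, so any fixed order with these properties
#' plays the same role.
#'
#' @return A `melody` object.
#' @export
default_melody <- function() {
  melody(c(1, 2, 3, 2, 3, 4, 3, 1, 2, 3, 4, 2))
}

#' Chunk-boundary interval indices of a melody
#'
#' Interval index i separates notes i and i + 1; the boundary indices are the
#' cumulative chunk sizes short of the final note (for 3-3-2-2-2: 3, 6, 8, 10).
#'
#' @param mel a `melody`.
#' @return Integer vector of boundary interval indices.
#' @export
chunk_boundaries <- function(mel) {
  cs <- cumsum(mel$chunk_structure)
  cs[cs < length(mel$pitches)]
}

#' Read or write a melody definition (JSON)
#'
#' @param path file path.
#' @return `read_melody()` returns a `melody`; `write_melody()` returns the
#'   path invisibly.
#' @export
read_melody <- function(path) {
  obj <- jsonlite::fromJSON(path)
  melody(obj$pitches, obj$chunk_structure)
}

#' @rdname read_melody
#' @param mel a `melody` object.
#' @export
write_melody <- function(mel, path) {
  jsonlite::write_json(list(pitches = mel$pitches,
                            chunk_structure = mel$chunk_structure),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' Construct a production record
#'
#' One trial of one participant: the raw taps plus bookkeeping (condition,
#' 1-based trial index, learning/practice phase, melodic correctness) and,
#' for correct trials once extracted, the 11-interval ITI sequence.
#'
#' @param participant_id identifier.
#' @param condition `"LearnFromPerformance"` or `"LearnFromDemonstration"`.
#' @param trial_index 1-based trial number within participant.
#' @param taps a `tap_sequence`, or `NULL` when only ITIs are carried.
#' @param correct logical or `NA` (unscored).
#' @param phase `"learning"`, `"practice"` or `NA` (unpartitioned).
#' @param itis numeric length-11 ITI vector or `NULL`.
#' @return An object of class `production_record`.
#' @export
production_record <- function(participant_id, condition, trial_index,
                              taps = NULL, correct = NA, phase = NA_character_,
                              itis = NULL) {
  condition <- as.character(condition_factor(condition))
  if (!is.null(itis)) itis <- assert_itis(itis, "itis")
  if (!is.null(taps) && !inherits(taps, "tap_sequence")) {
    stop_taptrans("`taps` must be a tap_sequence", "taptrans_validation_error")
  }
  structure(
    list(participant_id = as.character(participant_id),
         condition = condition,
         trial_index = as.integer(trial_index),
         phase = phase, correct = correct, taps = taps, itis = itis),
    class = "production_record"
  )
}

#' @export
print.production_record <- function(x, ...) {
  cat(sprintf("<production_record> %s trial %d [%s] correct=%s\n",
              x$participant_id, x$trial_index,
              if (is.na(x$phase)) "unpartitioned" else x$phase,
              format(x$correct)))
  invisible(x)
}

TAPLOG_COLUMNS <- c("participant_id", "condition", "trial_index", "tap_index",
                    "drum_id", "onset_ms", "offset_ms", "velocity")

#' Read a tap log
#'
#' Reads raw productions from the tap-log CSV dialect (one row per tap with
#' columns `participant_id, condition, trial_index, tap_index, drum_id,
#' onset_ms, offset_ms, velocity`) or the JSON dialect (an array of trial
#' objects). Taps are returned untouched (no double-tap cleaning); records are
#' sorted by participant then trial index. If a melody is supplied each trial
#' is scored for melodic accuracy on read.
#'
#' Standard MIDI file import is not supported by this build; requesting
#' `dialect = "midi"` raises an error.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"json"`.
#' @param melody optional `melody` used to score correctness.
#' @return A list of `production_record` objects.
#' @export
read_tap_log <- function(path, dialect = c("csv", "json", "midi"),
                         melody = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_taptrans(sprintf("tap log not found: %s", path), "taptrans_io_error")
  }
  if (dialect == "midi") {
    stop_taptrans("standard MIDI import is not supported; use the csv or json dialect",
                  "taptrans_unsupported_dialect")
  }
  if (dialect == "csv") {
    if (file.size(path) == 0) {
      warning("empty tap log: ", path)
      return(list())
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(TAPLOG_COLUMNS, names(df))
    if (length(missing_cols) > 0) {
      stop_taptrans(sprintf("tap-log CSV lacks column(s): %s",
                            paste(missing_cols, collapse = ", ")),
                    "taptrans_parse_error")
    }
    if (nrow(df) == 0) {
      warning("tap log has a header but no rows: ", path)
      return(list())
    }
    num_cols <- c("trial_index", "tap_index", "drum_id", "onset_ms",
                  "offset_ms", "velocity")
    for (cc in num_cols) {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      bad <- which(is.na(v) & !is.na(df[[cc]]) | is.na(df[[cc]]))
      if (length(bad) > 0) {
        stop_taptrans(sprintf("malformed value in column %s at data row %d of %s",
                              cc, bad[1], path),
                      "taptrans_parse_error")
      }
      df[[cc]] <- v
    }
    bad_drum <- which(!(df$drum_id %in% 1:4))
    if (length(bad_drum) > 0) {
      stop_taptrans(sprintf("unknown drum_id %s at data row %d of %s",
                            format(df$drum_id[bad_drum[1]]), bad_drum[1], path),
                    "taptrans_validation_error")
    }
    bad_off <- which(df$offset_ms <= df$onset_ms)
    if (length(bad_off) > 0) {
      stop_taptrans(sprintf("offset <= onset at data row %d of %s",
                            bad_off[1], path),
                    "taptrans_validation_error")
    }
    keys <- unique(df[c("participant_id", "condition", "trial_index")])
    keys <- keys[order(keys$participant_id, keys$trial_index), , drop = FALSE]
    records <- lapply(seq_len(nrow(keys)), function(i) {
      k <- keys[i, ]
      sub <- df[df$participant_id == k$participant_id &
                  df$trial_index == k$trial_index, , drop = FALSE]
      sub <- sub[order(sub$tap_index), , drop = FALSE]
      taps <- tap_sequence(
        trial_id = sprintf("%s_%03d", k$participant_id, k$trial_index),
        events = data.frame(drum_id = sub$drum_id, onset = sub$onset_ms,
                            offset = sub$offset_ms, velocity = sub$velocity)
      )
      production_record(k$participant_id, k$condition, k$trial_index,
                        taps = taps)
    })
  } else {
    trials <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(trials) == 0) {
      warning("empty tap log: ", path)
      return(list())
    }
    records <- lapply(trials, function(tr) {
      ev <- do.call(rbind, lapply(tr$taps, function(e) {
        data.frame(drum_id = e$drum_id, onset = e$onset, offset = e$offset,
                   velocity = e$velocity)
      }))
      production_record(tr$participant_id, tr$condition, tr$trial_index,
                        taps = tap_sequence(
                          sprintf("%s_%03d", tr$participant_id, tr$trial_index),
                          ev))
    })
    ord <- order(vapply(records, `[[`, "", "participant_id"),
                 vapply(records, `[[`, 1L, "trial_index"))
    records <- records[ord]
  }
  if (!is.null(melody)) {
    records <- lapply(records, function(r) {
      r$correct <- score_sequence_accuracy(r$taps, melody)$correct
      r
    })
  }
  records
}

#' Write a tap log
#'
#' Serialises production records to the tap-log CSV dialect or the JSON trial
#' dialect; `read_tap_log()` on the result round-trips the raw taps.
#'
#' @param records list of `production_record`s (with taps).
#' @param path output path.
#' @param dialect `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_tap_log <- function(records, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    rows <- lapply(records, function(r) {
      ev <- r$taps$events
      if (is.null(ev) || nrow(ev) == 0) return(NULL)
      data.frame(participant_id = r$participant_id, condition = r$condition,
                 trial_index = r$trial_index, tap_index = seq_len(nrow(ev)),
                 drum_id = ev$drum_id,
                 onset_ms = sprintf("%.6f", ev$onset),
                 offset_ms = sprintf("%.6f", ev$offset),
                 velocity = sprintf("%.6f", ev$velocity))
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- as.data.frame(stats::setNames(
      replicate(length(TAPLOG_COLUMNS), character(0), simplify = FALSE),
      TAPLOG_COLUMNS))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- lapply(records, function(r) {
      ev <- r$taps$events
      list(participant_id = r$participant_id, condition = r$condition,
           trial_index = r$trial_index,
           taps = lapply(seq_len(nrow(ev)), function(i) {
             list(drum_id = ev$drum_id[i], onset = ev$onset[i],
                  offset = ev$offset[i], velocity = ev$velocity[i])
           }))
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Merge double taps (drumstick bounces)
#'
#' When the drumstick bounces, one intended strike registers as two taps on
#' the same drum in very quick succession. Whenever two consecutive events on
#' the same drum are separated by less than `min_gap` ms (second onset minus
#' first offset), they are merged by deleting the intervening offset and
#' onset: the merged tap keeps the first onset, the second offset, and the
#' maximum velocity. The rule is applied left-to-right until a fixpoint, so
#' a run of bounces collapses into a single tap. Cleaning is idempotent.
#'
#' @param seq a `tap_sequence`.
#' @param min_gap merge threshold in milliseconds (default 50, below the
#'   physiological limit for intentional repeated strikes).
#' @return A cleaned `tap_sequence`.
#' @export
clean_double_taps <- function(seq, min_gap = 50) {
  assert_scalar_number(min_gap, "min_gap", lower = 0)
  ev <- seq$events
  i <- 1L
  while (i < nrow(ev)) {
    if (ev$drum_id[i + 1L] == ev$drum_id[i] &&
        (ev$onset[i + 1L] - ev$offset[i]) < min_gap) {
      ev$offset[i] <- ev$offset[i + 1L]
      ev$velocity[i] <- max(ev$velocity[i], ev$velocity[i + 1L])
      ev <- ev[-(i + 1L), , drop = FALSE]
      # stay on i: the next event may bounce into the merged tap too
    } else {
      i <- i + 1L
    }
  }
  rownames(ev) <- NULL
  seq$events <- ev
  seq
}

#' Extract the inter-tap-interval sequence
#'
#' ITI i is the onset of note i + 1 minus the offset of note i (the silent
#' gap between strikes), giving 11 intervals for a 12-note production. The
#' sequence must already be cleaned and contain exactly 12 events. Overlapping
#' taps produce negative ITIs, which are retained with a warning by default;
#' `clamp_negative = TRUE` floors them at 0.
#'
#' @param seq a cleaned `tap_sequence` with 12 events.
#' @param clamp_negative clamp negative intervals to zero?
#' @return Numeric vector of 11 ITIs (ms).
#' @export
extract_itis <- function(seq, clamp_negative = FALSE) {
  ev <- seq$events
  if (nrow(ev) != N_NOTES) {
    stop_taptrans(
      sprintf("expected %d tap events, got %d (trial %s)", N_NOTES, nrow(ev),
              format(seq$trial_id)),
      "taptrans_length_error"
    )
  }
  itis <- ev$onset[2:N_NOTES] - ev$offset[1:N_ITIS]
  if (any(itis < 0)) {
    if (clamp_negative) {
      itis <- pmax(itis, 0)
    } else {
      warning(sprintf("negative ITI(s) from overlapping taps in trial %s retained",
                      format(seq$trial_id)))
    }
  }
  itis
}

#' Score melodic accuracy of a production
#'
#' A production is correct iff its drum order equals the melody exactly (same
#' length, same order); timing plays no role. The left-right reversed drum
#' mapping (1 <-> 4, 2 <-> 3) is detected separately: some learners initially
#' play back mirror-imaged positions. Reversed productions are reported, never
#' auto-corrected.
#'
#' @param seq a `tap_sequence`.
#' @param melody a `melody`.
#' @return A list with `correct`, `first_mismatch_index` (NA when correct) and
#'   `reversed_mapping`.
#' @export
score_sequence_accuracy <- function(seq, melody) {
  produced <- seq$events$drum_id
  target <- melody$pitches
  reversed <- identical(as.integer(produced), as.integer(5L - target))
  if (length(produced) == length(target) &&
      all(produced == target)) {
    return(list(correct = TRUE, first_mismatch_index = NA_integer_,
                reversed_mapping = reversed))
  }
  upto <- min(length(produced), length(target))
  mism <- which(produced[seq_len(upto)] != target[seq_len(upto)])
  first <- if (length(mism) > 0) mism[1] else upto + 1L
  list(correct = FALSE, first_mismatch_index = as.integer(first),
       reversed_mapping = reversed)
}

#' Partition trials into learning and practice phases
#'
#' The learning phase ends when the participant completes ten consecutive
#' correct trials; those final ten are the practice trials, and everything
#' before them (including correct trials later followed by an error) belongs
#' to the learning phase. Participants without a terminal run of ten correct
#' trials are incomplete and raise an error.
#'
#' @param records list of `production_record`s in trial order, correctness
#'   scored.
#' @param n_practice length of the terminal correct run (default 10).
#' @return A list with elements `learning` and `practice`, each a list of
#'   records with their `phase` field set.
#' @export
partition_phases <- function(records, n_practice = 10L) {
  correct <- vapply(records, function(r) isTRUE(r$correct), logical(1))
  scored <- vapply(records, function(r) !is.na(r$correct), logical(1))
  if (!all(scored)) {
    stop_taptrans("all records must have correctness scored before partitioning",
                  "taptrans_validation_error")
  }
  n <- length(records)
  if (n < n_practice || !all(correct[(n - n_practice + 1L):n])) {
    stop_taptrans(
      sprintf("incomplete participant: no terminal run of %d consecutive correct trials",
              n_practice),
      "taptrans_incomplete_participant"
    )
  }
  cut <- n - n_practice
  records <- lapply(seq_len(n), function(i) {
    records[[i]]$phase <- if (i <= cut) "learning" else "practice"
    records[[i]]
  })
  list(learning = records[seq_len(cut)],
       practice = records[(cut + 1L):n])
}

#' Learning-rate bookkeeping
#'
#' Counts the learning repetitions (all trials before the terminal ten
#' consecutive correct practice trials) and the total number of error trials.
#' A participant who errs only on trials 1-2 then plays ten correct trials
#' completed 2 learning repetitions with 2 errors; one who errs on trials 1
#' and 10 (with trials 2-9 correct) before the terminal run completed 10
#' learning repetitions but still only 2 errors.
#'
#' @param records list of `production_record`s (partitioned or not) for one
#'   participant, or the list returned by [partition_phases()].
#' @return A list with `n_learning_trials` and `n_errors`.
#' @export
learning_rate_summary <- function(records) {
  if (is.list(records) && !is.null(records$learning) &&
      !is.null(records$practice)) {
    parts <- records
  } else {
    parts <- partition_phases(records)
  }
  all_records <- c(parts$learning, parts$practice)
  list(
    n_learning_trials = length(parts$learning),
    n_errors = sum(vapply(all_records, function(r) !isTRUE(r$correct),
                          logical(1)))
  )
}
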