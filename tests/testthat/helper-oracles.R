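# Independent oracles and small fixture builders used across the suite.

# Semi-partial correlation via the explicit residual regression it is
# algebraically equal to: correlate d with the residuals of regressing the
# controlled variable on the baseline (intercept included).
spc_oracle <- function(d, m, a, control = "model") {
  if (control == "production") {
    tmp <- d; d <- m; m <- tmp
  }
  stats::cor(d, stats::residuals(stats::lm(m ~ a)))
}

# Pearson correlation from the raw covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# Welch two-sample t statistic and Welch-Satterthwaite df, by hand.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df)
}

# A positive, rhythm-like random ITI vector.
random_itis <- function(n = 11, base = 250, spread = 150) {
  abs(stats::rnorm(n, base, spread)) + 30
}

# Tap sequence realising given ITIs on the default melody.
taps_from_itis <- function(itis, tap_duration = 100, trial_id = "t",
                           mel = default_melody()) {
  itis_to_taps(itis, mel, tap_duration = tap_duration, trial_id = trial_id)
}

# One participant's records: correctness flags in trial order, all trials
# realised as productions of the flat representation (errors get one
# substituted drum so accuracy scoring fails them).
records_with_flags <- function(flags, pid = "P1",
                               condition = "LearnFromPerformance") {
  mel <- default_melody()
  rep_itis <- build_representation()
  wrong_pitches <- mel$pitches
  wrong_pitches[1] <- setdiff(1:4, wrong_pitches[1])[1]
  wrong <- melody(wrong_pitches, mel$chunk_structure)
  lapply(seq_along(flags), function(i) {
    m <- if (flags[i]) mel else wrong
    production_record(pid, condition, i,
                      taps = itis_to_taps(rep_itis, m,
                                          trial_id = sprintf("%s_%d", pid, i)),
                      correct = flags[i])
  })
}

# Small complete seed set built from deterministic vectors.
toy_seed_set <- function(learning_context = "Performance") {
  rep_itis <- build_representation()
  original <- rep_itis + c(3, -4, 8, 1, -6, 5, -2, 7, -3, 2, -1)
  learning <- modulate_context(rep_itis,
                               context_modulation(tempo_scale = 1.2,
                                                  exaggeration = 1.4))
  pool <- lapply(1:5, function(k) {
    rep_itis + sin(seq_len(11) + k) * 40 + k
  })
  seed_set(original, learning, learning_context, pool)
}
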