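# Generative simulator of transmission episodes: a stable internal
# representation of the rhythm, context modulations (performative
# exaggeration, pedagogical slowing), scalar production noise, participant
# idiosyncrasy, and learners with per-dimension copy/reconstruct weights.

#' Parameters of the model's internal rhythm representation
#'
#' The representation is a flat pulse of `base_tempo` ms per interval, with
#' chunk-boundary intervals lengthened by `boundary_multiplier` (the pauses
#' that mark the ends of rhythmic groups). Defaults (250 ms, x2.4) give the
#' canonical 250/600 pattern for the 3-3-2-2-2 melody.
#'
#' @param base_tempo short-interval duration in ms (> 0).
#' @param boundary_multiplier lengthening factor at chunk boundaries (>= 1).
#' @param melody a [melody()].
#' @return An object of class `representation_params`.
#' @export
representation_params <- function(base_tempo = 250, boundary_multiplier = 2.4,
                                  melody = default_melody()) {
  assert_scalar_number(base_tempo, "base_tempo", lower = 1e-9)
  assert_scalar_number(boundary_multiplier, "boundary_multiplier", lower = 1)
  structure(list(base_tempo = base_tempo,
                 boundary_multiplier = boundary_multiplier,
                 melody = melody),
            class = "representation_params")
}

#' Build the internal-representation ITI sequence
#'
#' @param params a [representation_params()].
#' @return Numeric ITI vector: `base_tempo` everywhere except the chunk
#'   boundary indices, which carry `base_tempo * boundary_multiplier`.
#' @export
build_representation <- function(params = representation_params()) {
  mel <- params$melody
  n <- length(mel$pitches) - 1L
  itis <- rep(params$base_tempo, n)
  b <- chunk_boundaries(mel)
  if (any(b > n)) {
    stop_taptrans("chunk structure inconsistent with melody length",
                  "taptrans_validation_error")
  }
  itis[b] <- params$base_tempo * params$boundary_multiplier
  itis
}

#' Context modulation parameters
#'
#' A production context modulates the representation along two orthogonal
#' timing dimensions: `tempo_scale` (s) rescales the mean interval (absolute
#' timing; s > 1 slows down) and `exaggeration` (g) expands the contrast
#' between long and short intervals around the mean (relative timing; g > 1
#' exaggerates). `style_sd` adds per-production multiplicative shape noise
#' (lognormal sd on the log scale) reflecting spontaneous stylistic
#' variation from production to production within the context; it is 0 for
#' the uninstructed Original context and largest for the Performance context,
#' reproducing the observed consistency ordering of the three contexts.
#'
#' @param tempo_scale s > 0.
#' @param exaggeration g > 0.
#' @param style_sd per-production shape noise sd (>= 0).
#' @return An object of class `context_modulation`.
#' @export
context_modulation <- function(tempo_scale = 1, exaggeration = 1,
                               style_sd = 0) {
  assert_scalar_number(tempo_scale, "tempo_scale", lower = 1e-9)
  assert_scalar_number(exaggeration, "exaggeration", lower = 1e-9)
  assert_scalar_number(style_sd, "style_sd", lower = 0)
  structure(list(tempo_scale = tempo_scale, exaggeration = exaggeration,
                 style_sd = style_sd),
            class = "context_modulation")
}

#' Apply a context modulation to a representation
#'
#' Mean-centred contrast transform: `out_i = s * (mean(rep) + g * (rep_i -
#' mean(rep)))`. The output mean is exactly `s * mean(rep)` (tempo is
#' controlled solely by s) and the long/short contrast is scaled by g, so the
#' absolute and relative dimensions are orthogonal by construction. Identity
#' at s = g = 1. Values are floored at `min_iti`; a fully floored result
#' triggers a degenerate-modulation warning.
#'
#' @param rep numeric ITI vector.
#' @param mod a [context_modulation()].
#' @param min_iti floor for intervals, ms.
#' @return Modulated numeric ITI vector.
#' @export
modulate_context <- function(rep, mod, min_iti = 20) {
  rep <- assert_itis(rep, "rep", n = length(rep))
  m <- mean(rep)
  out <- mod$tempo_scale * (m + mod$exaggeration * (rep - m))
  floored <- out < min_iti
  if (all(floored)) {
    warning("degenerate modulation: all intervals floored at min_iti")
  }
  out[floored] <- min_iti
  out
}

#' Production noise parameters
#'
#' Two trial-level terms follow the scalar (Weber-like) timing model:
#' `cv` is the per-interval coefficient of variation of unit-mean
#' multiplicative lognormal noise, and `tempo_jitter_sd` the sd of a global
#' log-tempo factor shared by all intervals of one production. Two
#' participant-level terms capture individual idiosyncrasy, constant across
#' a participant's trials and deliberately additive in milliseconds (a
#' learner's preferred tempo and habitual rhythmic quirks are properties of
#' the learner, not of the tempo of the seed they happen to watch):
#' `participant_tempo_sd` is the sd of an additive preferred-tempo offset
#' applied to every interval, and `participant_shape_sd` the sd of a fixed
#' additive zero-mean per-interval pattern (idiosyncratic rhythm, orthogonal
#' to tempo by construction). The participant terms put simulated novice
#' reproductions a few hundred ms (root-sum-square over the 11 intervals)
#' from the seed they learn from and give the mixed model's participant
#' random effects something real to estimate. Setting all four to 0
#' recovers determinism.
#'
#' @param cv per-interval coefficient of variation (>= 0).
#' @param tempo_jitter_sd sd of the per-production global log-tempo factor.
#' @param participant_tempo_sd sd (ms) of the participant tempo offset.
#' @param participant_shape_sd sd (ms) of the participant shape pattern.
#' @param min_iti floor for rendered intervals, ms.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(cv = 0.07, tempo_jitter_sd = 0.02,
                         participant_tempo_sd = 50,
                         participant_shape_sd = 45,
                         min_iti = 20) {
  assert_scalar_number(cv, "cv", lower = 0)
  assert_scalar_number(tempo_jitter_sd, "tempo_jitter_sd", lower = 0)
  assert_scalar_number(participant_tempo_sd, "participant_tempo_sd", lower = 0)
  assert_scalar_number(participant_shape_sd, "participant_shape_sd", lower = 0)
  structure(list(cv = cv, tempo_jitter_sd = tempo_jitter_sd,
                 participant_tempo_sd = participant_tempo_sd,
                 participant_shape_sd = participant_shape_sd,
                 min_iti = min_iti),
            class = "noise_params")
}

#' Draw participant-level idiosyncrasy effects
#'
#' One draw of the participant-level noise terms: an additive tempo offset
#' (ms; truncated at two standard deviations so an extreme preference cannot
#' push a whole production onto the minimum-interval floor) and a fixed
#' additive per-interval shape pattern, centred to zero mean so it moves the
#' rhythm but not the tempo. Draws from the current RNG state.
#'
#' @param noise a [noise_params()].
#' @param n_itis number of intervals.
#' @return A list with `tempo_offset` and `shape_pattern` (length `n_itis`).
#' @export
participant_effects <- function(noise, n_itis = N_ITIS) {
  off <- stats::rnorm(1, 0, noise$participant_tempo_sd)
  lim <- 2 * noise$participant_tempo_sd
  pat <- stats::rnorm(n_itis, 0, noise$participant_shape_sd)
  list(
    tempo_offset = max(min(off, lim), -lim),
    shape_pattern = pat - mean(pat)
  )
}

#' Render one noisy production of a target ITI sequence
#'
#' `out_i = (target_i + tempo_offset + pattern_i) * J * eps_i`, with
#' `J = exp(N(0, tempo_jitter_sd))` shared across intervals and
#' `eps_i = exp(N(-cv^2/2, cv))` independent per interval (unit-mean
#' multiplicative noise); the participant terms default to none. Output is
#' floored at `noise$min_iti`. Draws from the current RNG state, so results
#' are reproducible under `set.seed()`; zero noise returns the target
#' exactly.
#'
#' @param target numeric ITI vector.
#' @param noise a [noise_params()].
#' @param participant optional [participant_effects()] draw.
#' @return Numeric ITI vector.
#' @export
render_production <- function(target, noise = noise_params(),
                              participant = NULL) {
  n <- length(target)
  base <- target
  if (!is.null(participant)) {
    base <- base + participant$tempo_offset + participant$shape_pattern
  }
  J <- exp(stats::rnorm(1, 0, noise$tempo_jitter_sd))
  eps <- exp(stats::rnorm(n, -noise$cv^2 / 2, noise$cv))
  pmax(base * J * eps, noise$min_iti)
}

#' Learner strategy: per-dimension copy/reconstruct weights
#'
#' The learner's production target mixes the Learning seed (what they saw)
#' with the Original representation (what they infer) separately on the two
#' timing dimensions: `w_abs` weights the absolute dimension (tempo = mean
#' ITI) and `w_rel` the relative dimension (shape = ITIs divided by their
#' mean). w = 1 is a pure copy of the Learning seed on that dimension, w = 0
#' pure reconstruction of the Original representation. The default (w_abs =
#' 1, w_rel = 0) is the copy-the-tempo, reconstruct-the-rhythm profile.
#' `preferred_tempo_scale`, when not `NA`, switches the learner to a
#' seed-ignoring confound world: the target is the Original shape played at
#' `preferred_tempo_scale * mean(rep)` regardless of the seeds (used to
#' probe the slow-preferred-tempo confound).
#'
#' @param w_abs,w_rel weights in `[0, 1]`.
#' @param preferred_tempo_scale `NA` (default) or a positive tempo scale.
#' @return An object of class `learner_strategy`.
#' @export
learner_strategy <- function(w_abs = 1, w_rel = 0,
                             preferred_tempo_scale = NA_real_) {
  assert_scalar_number(w_abs, "w_abs", lower = 0, upper = 1)
  assert_scalar_number(w_rel, "w_rel", lower = 0, upper = 1)
  if (!is.na(preferred_tempo_scale)) {
    assert_scalar_number(preferred_tempo_scale, "preferred_tempo_scale",
                         lower = 1e-9)
  }
  structure(list(w_abs = w_abs, w_rel = w_rel,
                 preferred_tempo_scale = preferred_tempo_scale),
            class = "learner_strategy")
}

#' Compose the learner's production target
#'
#' Decomposes each sequence q into tempo (mean(q)) and shape (q / mean(q)),
#' mixes the two sources per dimension with the strategy weights, renormalises
#' the mixed shape to unit mean, and recombines: target = tempo * shape.
#' w = (1,1) returns the Learning seed exactly; w = (0,0) the Original
#' representation exactly; w = (1,0) the Original shape at the Learning
#' seed's tempo.
#'
#' @param original_rep numeric ITI vector (the inferred representation).
#' @param learning_seed numeric ITI vector (the observed seed).
#' @param strategy a [learner_strategy()].
#' @return Numeric ITI vector.
#' @export
simulate_learner_target <- function(original_rep, learning_seed,
                                    strategy = learner_strategy()) {
  if (mean(original_rep) <= 0 || mean(learning_seed) <= 0) {
    stop_taptrans("sequences must have positive mean", "taptrans_validation_error")
  }
  if (!is.na(strategy$preferred_tempo_scale)) {
    shape <- original_rep / mean(original_rep)
    return(shape * (strategy$preferred_tempo_scale * mean(original_rep)))
  }
  tempo <- strategy$w_abs * mean(learning_seed) +
    (1 - strategy$w_abs) * mean(original_rep)
  shape <- strategy$w_rel * (learning_seed / mean(learning_seed)) +
    (1 - strategy$w_rel) * (original_rep / mean(original_rep))
  shape <- shape / mean(shape)
  tempo * shape
}

#' Learning-phase generative parameters
#'
#' The number of error trials is drawn as a negative-binomial-like count
#' (`n_errors ~ NegBin(mu = mean_errors, size = dispersion)`; `dispersion =
#' Inf` gives Poisson), and each error is preceded by a Geometric number of
#' correct learning trials with mean `mean_correct_run`. The final learning
#' trial is always an error (otherwise it would belong to the terminal
#' correct run), so the phase-partition bookkeeping recovers the generated
#' counts exactly.
#'
#' @param mean_errors mean error count (>= 0).
#' @param dispersion negative-binomial size parameter (> 0, or `Inf`).
#' @param mean_correct_run mean correct trials preceding each error (>= 0).
#' @return An object of class `learning_phase_params`.
#' @export
learning_phase_params <- function(mean_errors = 4, dispersion = 2,
                                  mean_correct_run = 1.5) {
  assert_scalar_number(mean_errors, "mean_errors", lower = 0)
  if (!identical(dispersion, Inf)) {
    assert_scalar_number(dispersion, "dispersion", lower = 1e-9)
  }
  assert_scalar_number(mean_correct_run, "mean_correct_run", lower = 0)
  structure(list(mean_errors = mean_errors, dispersion = dispersion,
                 mean_correct_run = mean_correct_run),
            class = "learning_phase_params")
}

#' Simulate one participant's learning phase
#'
#' Draws the error count and arranges learning trials (see
#' [learning_phase_params()]). Draws from the current RNG state.
#'
#' @param params a [learning_phase_params()].
#' @return A list with `n_learning_trials`, `n_errors`, and `correct_flags`
#'   (logical vector over the learning trials; empty for error-free
#'   participants).
#' @export
simulate_learning_phase <- function(params = learning_phase_params()) {
  if (params$mean_errors == 0) {
    n_err <- 0L
  } else if (identical(params$dispersion, Inf)) {
    n_err <- stats::rpois(1, params$mean_errors)
  } else {
    n_err <- stats::rnbinom(1, size = params$dispersion,
                            mu = params$mean_errors)
  }
  if (n_err == 0) {
    return(list(n_learning_trials = 0L, n_errors = 0L,
                correct_flags = logical(0)))
  }
  p <- 1 / (1 + params$mean_correct_run)
  runs <- stats::rgeom(n_err, p)
  flags <- unlist(lapply(runs, function(k) c(rep(TRUE, k), FALSE)))
  list(n_learning_trials = length(flags), n_errors = as.integer(n_err),
       correct_flags = flags)
}

#' Full simulation configuration
#'
#' Bundles every generative parameter of a simulated transmission study:
#' sample sizes, the representation, the per-context modulations, noise,
#' learner strategy, learning-phase model, the covariate model for the three
#' melodic-perception (MBEA-O) subscales, and the master RNG seed. The
#' defaults are the study conditions: 16 participants per learning condition,
#' 10 practice trials, 10 model productions per context of which one is shown
#' (leaving a pool of 27 unshown productions), Performance modulation
#' s = 1.0 / g = 1.6, Demonstration s = 1.4 / g = 1.5.
#'
#' @param n_per_condition participants per learning condition.
#' @param n_practice_trials terminal consecutive-correct criterion.
#' @param n_pool_per_context model productions recorded per context.
#' @param representation a [representation_params()].
#' @param contexts named list of [context_modulation()]s for `Original`,
#'   `Performance` and `Demonstration`.
#' @param noise a [noise_params()].
#' @param strategy a [learner_strategy()].
#' @param learning_phase a [learning_phase_params()].
#' @param covariate_model list with `means` and `sds` (length 3: scale,
#'   metre, key subscales).
#' @param reconstruct_to what pure reconstruction (w = 0) converges on:
#'   `"original_seed"` (default; the Original video as the learner observed
#'   it, idiosyncrasies included - the only realisation of the model's
#'   representation available to a learner) or `"representation"` (the
#'   latent noiseless representation, an idealisation of perfect pragmatic
#'   inference).
#' @param rng_seed master seed; every stream is derived from it via
#'   [substream_seed()].
#' @param include_taps materialise tap events (set `FALSE` for fast
#'   ITI-only simulation in replicate studies).
#' @param tap_duration tap duration used when materialising taps, ms.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_condition = 16,
                       n_practice_trials = 10,
                       n_pool_per_context = 10,
                       representation = representation_params(),
                       contexts = list(
                         Original = context_modulation(1, 1, 0.08),
                         Performance = context_modulation(1.0, 1.6, 0.30),
                         Demonstration = context_modulation(1.4, 1.5, 0.15)
                       ),
                       noise = noise_params(),
                       strategy = learner_strategy(),
                       learning_phase = learning_phase_params(),
                       covariate_model = list(means = c(0, 0, 0),
                                              sds = c(1, 1, 1)),
                       reconstruct_to = c("original_seed", "representation"),
                       rng_seed = 1L,
                       include_taps = TRUE,
                       tap_duration = 100) {
  reconstruct_to <- match.arg(reconstruct_to)
  if (n_per_condition < 1) {
    stop_taptrans("n_per_condition must be >= 1", "taptrans_validation_error")
  }
  needed <- c("Original", "Performance", "Demonstration")
  if (!all(needed %in% names(contexts))) {
    stop_taptrans(sprintf("contexts must name %s", paste(needed, collapse = ", ")),
                  "taptrans_validation_error")
  }
  structure(
    list(n_per_condition = as.integer(n_per_condition),
         n_practice_trials = as.integer(n_practice_trials),
         n_pool_per_context = as.integer(n_pool_per_context),
         representation = representation, contexts = contexts, noise = noise,
         strategy = strategy, learning_phase = learning_phase,
         covariate_model = covariate_model, reconstruct_to = reconstruct_to,
         rng_seed = as.integer(rng_seed),
         include_taps = isTRUE(include_taps), tap_duration = tap_duration),
    class = "sim_config"
  )
}

condition_to_context <- c(LearnFromPerformance = "Performance",
                          LearnFromDemonstration = "Demonstration")

# Render the model's production pool for one context: per-production style
# jitter on the shape (normalised to unit mean, so style moves the rhythm
# pattern but never the tempo; tempo is governed solely by the context's
# tempo_scale plus trial jitter), then trial noise.
render_context_pool <- function(rep, mod, noise, n_pool) {
  target <- modulate_context(rep, mod, min_iti = noise$min_iti)
  prods <- lapply(seq_len(n_pool), function(j) {
    style <- exp(stats::rnorm(length(target), 0, mod$style_sd))
    style <- style * mean(target) / mean(target * style)
    render_production(target * style, noise)
  })
  list(productions = prods, target = target)
}

# The production shown to learners, emulating the curation of the study
# stimuli: a video displaying a clear but typical degree of expressive /
# contextual modulation. The deviation from the exact context target has a
# fixed, typical magnitude (the context's style plus motor noise, on the
# log scale) with a random pattern, and is tempo-preserving, so the shown
# seed carries the context's tempo exactly.
render_shown_seed <- function(rep, mod, noise) {
  target <- modulate_context(rep, mod, min_iti = noise$min_iti)
  s_eff <- sqrt(mod$style_sd^2 + noise$cv^2)
  if (s_eff == 0) return(target)
  z <- stats::rnorm(length(target))
  z <- (z - mean(z)) / stats::sd(z)
  f <- exp(s_eff * z)
  # preserve the production mean exactly: style moves the rhythm pattern,
  # never the tempo
  f <- f * mean(target) / mean(target * f)
  pmax(target * f, noise$min_iti)
}

# Substitute one drum in a melody's pitch order (an error production).
# Deterministic in the trial index, so materialising taps never consumes
# random numbers and the generated timings are identical with and without
# include_taps.
substitute_wrong_drum <- function(pitches, trial) {
  i <- ((trial - 1L) %% length(pitches)) + 1L
  pitches[i] <- setdiff(1:4, pitches[i])[1]
  pitches
}

#' Simulate a full transmission experiment
#'
#' End-to-end emulation of the study's structure, fully reproducible from
#' `config$rng_seed`: builds the Original representation; renders the model's
#' production pool in each context (with its modulation and tempo-preserving
#' style noise), one production per context being shown to learners and the
#' remaining productions forming the grand-average pool; then
#' simulates each learner (participant idiosyncrasy, learning phase with
#' error trials, and the terminal practice trials rendered around the
#' learner's copy/reconstruct target) and draws their perception-test
#' covariates.
#'
#' @param config a [sim_config()].
#' @return An object of class `transmission_sim`: a list with `seeds` (a
#'   [seed_set()] per condition), `records` (all `production_record`s),
#'   `covariates` (one row per participant), and `truth` (the generating
#'   config).
#' @export
simulate_experiment <- function(config = sim_config()) {
  rep_itis <- build_representation(config$representation)
  mel <- config$representation$melody
  noise <- config$noise

  set.seed(substream_seed(config$rng_seed, "seed_pool"))
  pools <- list()
  shown <- list()
  for (ctx in c("Original", "Performance", "Demonstration")) {
    shown[[ctx]] <- render_shown_seed(rep_itis, config$contexts[[ctx]], noise)
    rp <- render_context_pool(rep_itis, config$contexts[[ctx]], noise,
                              config$n_pool_per_context - 1L)
    pools[[ctx]] <- rp$productions
  }
  unshown_pool <- c(pools$Original, pools$Performance, pools$Demonstration)

  seeds <- list(
    LearnFromPerformance = seed_set(shown$Original, shown$Performance,
                                    "Performance", unshown_pool),
    LearnFromDemonstration = seed_set(shown$Original, shown$Demonstration,
                                      "Demonstration", unshown_pool)
  )

  n <- config$n_per_condition
  participants <- data.frame(
    participant_id = sprintf("P%03d", seq_len(2 * n)),
    condition = rep(CONDITIONS, each = n),
    stringsAsFactors = FALSE
  )

  records <- list()
  cov_rows <- list()
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    cond <- participants$condition[i]
    set.seed(substream_seed(config$rng_seed, paste0("participant_", pid)))
    pe <- participant_effects(noise)
    reconstruction_target <- if (config$reconstruct_to == "original_seed") {
      seeds[[cond]]$original
    } else {
      rep_itis
    }
    target <- simulate_learner_target(reconstruction_target,
                                      seeds[[cond]]$learning,
                                      config$strategy)
    lp <- simulate_learning_phase(config$learning_phase)
    cm <- config$covariate_model
    mbea <- stats::rnorm(3, cm$means, cm$sds)

    trial <- 0L
    prec <- list()
    for (ok in lp$correct_flags) {
      trial <- trial + 1L
      itis <- render_production(target, noise, pe)
      taps <- NULL
      if (config$include_taps) {
        pitches <- if (ok) mel$pitches else substitute_wrong_drum(mel$pitches,
                                                                  trial)
        taps <- itis_to_taps(itis, melody(pitches, mel$chunk_structure),
                             tap_duration = config$tap_duration,
                             trial_id = sprintf("%s_%03d", pid, trial))
      }
      prec[[trial]] <- production_record(
        pid, cond, trial, taps = taps, correct = ok, phase = "learning",
        itis = if (ok) itis else NULL
      )
    }
    for (j in seq_len(config$n_practice_trials)) {
      trial <- trial + 1L
      itis <- render_production(target, noise, pe)
      taps <- NULL
      if (config$include_taps) {
        taps <- itis_to_taps(itis, mel, tap_duration = config$tap_duration,
                             trial_id = sprintf("%s_%03d", pid, trial))
      }
      prec[[trial]] <- production_record(
        pid, cond, trial, taps = taps, correct = TRUE, phase = "practice",
        itis = itis
      )
    }
    records <- c(records, prec)
    cov_rows[[i]] <- data.frame(
      participant_id = pid, condition = cond,
      mbea_scale = mbea[1], mbea_metre = mbea[2], mbea_key = mbea[3],
      n_learning_trials = lp$n_learning_trials, n_errors = lp$n_errors,
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(seeds = seeds, records = records,
         covariates = do.call(rbind, cov_rows), truth = config),
    class = "transmission_sim"
  )
}

#' @export
print.transmission_sim <- function(x, ...) {
  cov <- x$covariates
  cat(sprintf("<transmission_sim> %d participants (%s), %d records\n",
              nrow(cov),
              paste(sprintf("%s: %d", names(table(cov$condition)),
                            as.integer(table(cov$condition))), collapse = ", "),
              length(x$records)))
  for (cond in names(x$seeds)) {
    s <- x$seeds[[cond]]
    cat(sprintf("  %s: RMSD(original, learning) = %.2f ms, pool n = %d\n",
                cond, euclidean_rmsd(s$original, s$learning), length(s$pool)))
  }
  invisible(x)
}

#' Materialise tap events from an ITI sequence
#'
#' Inverse of [extract_itis()] for fixed tap duration: builds 12 tap events
#' whose extracted ITI sequence equals the input exactly. The first onset is
#' 0; each subsequent onset is the previous offset plus the ITI.
#'
#' @param itis numeric ITI vector (positive).
#' @param melody a [melody()] supplying the drum order.
#' @param tap_duration tap (onset-to-offset) duration, ms.
#' @param trial_id trial identifier.
#' @param velocity constant velocity written to the events.
#' @return A `tap_sequence`.
#' @export
itis_to_taps <- function(itis, melody = default_melody(), tap_duration = 100,
                         trial_id = "sim", velocity = 64) {
  if (any(itis <= 0)) {
    stop_taptrans("ITIs must be positive to materialise taps",
                  "taptrans_validation_error")
  }
  n <- length(itis) + 1L
  if (length(melody$pitches) != n) {
    stop_taptrans("melody length must be one more than the ITI count",
                  "taptrans_validation_error")
  }
  onsets <- numeric(n)
  for (k in seq_len(n - 1L)) {
    onsets[k + 1L] <- onsets[k] + tap_duration + itis[k]
  }
  tap_sequence(trial_id, data.frame(
    drum_id = melody$pitches, onset = onsets,
    offset = onsets + tap_duration, velocity = velocity
  ))
}
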