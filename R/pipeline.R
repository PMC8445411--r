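# End-to-end pipeline: configuration, record preparation, report generation
# and canonical fixtures.

#' Pipeline run configuration
#'
#' Collects every analytic choice into one object so that sensitivity
#' analyses are single-field reruns: the run mode, input paths (analyse
#' mode), the simulation configuration (simulate modes), metric options
#' (RMSD convention, SPC control orientation, double-tap merge gap, negative
#' ITI clamp), inference options (alpha, df method), the output directory and
#' the RNG seed.
#'
#' @param mode `"simulate"`, `"analyse"` or `"simulate+analyse"`.
#' @param sim a [sim_config()] (simulate modes).
#' @param taplog_path,covariates_path,seed_paths analyse-mode inputs:
#'   tap-log CSV, covariates CSV, and a named list of seed CSV paths per
#'   condition (see [read_seed_pool()]).
#' @param melody_path optional melody JSON; defaults to [default_melody()].
#' @param rmsd_method,spc_control,min_gap,clamp_negative metric options.
#' @param alpha,df_method inference options.
#' @param out_dir output directory (created if needed); `NULL` suppresses
#'   file output.
#' @param rng_seed master seed (mandatory in simulate modes).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate+analyse", "simulate", "analyse"),
                       sim = sim_config(),
                       taplog_path = NULL, covariates_path = NULL,
                       seed_paths = NULL, melody_path = NULL,
                       rmsd_method = "sum", spc_control = "model",
                       min_gap = 50, clamp_negative = FALSE,
                       alpha = 0.05, df_method = "Satterthwaite",
                       out_dir = NULL, rng_seed = NULL) {
  mode <- match.arg(mode)
  if (mode != "analyse") {
    if (is.null(rng_seed)) rng_seed <- sim$rng_seed
    sim$rng_seed <- as.integer(rng_seed)
  }
  if (mode == "analyse") {
    for (p in c(taplog_path, covariates_path, unlist(seed_paths))) {
      if (is.null(p)) next
      if (!file.exists(p)) {
        stop_taptrans(sprintf("input file not found: %s", p),
                      "taptrans_io_error")
      }
    }
    if (is.null(taplog_path) || is.null(covariates_path) ||
        is.null(seed_paths)) {
      stop_taptrans("analyse mode needs taplog_path, covariates_path and seed_paths",
                    "taptrans_validation_error")
    }
  }
  structure(
    list(mode = mode, sim = sim, taplog_path = taplog_path,
         covariates_path = covariates_path, seed_paths = seed_paths,
         melody_path = melody_path, rmsd_method = rmsd_method,
         spc_control = spc_control, min_gap = min_gap,
         clamp_negative = clamp_negative, alpha = alpha,
         df_method = df_method, out_dir = out_dir,
         rng_seed = rng_seed),
    class = "run_config"
  )
}

#' Prepare raw production records for analysis
#'
#' Applies the data-preparation steps to raw records: double-tap cleaning,
#' accuracy scoring against the melody, phase partitioning per participant,
#' and ITI extraction for correct trials (error trials keep no ITIs).
#'
#' @param records list of `production_record`s with raw taps.
#' @param melody a [melody()].
#' @param min_gap double-tap merge threshold, ms.
#' @param clamp_negative passed to [extract_itis()].
#' @return List of prepared records (phases set, practice ITIs present),
#'   sorted by participant and trial.
#' @export
prepare_records <- function(records, melody = default_melody(), min_gap = 50,
                            clamp_negative = FALSE) {
  records <- lapply(records, function(r) {
    r$taps <- clean_double_taps(r$taps, min_gap = min_gap)
    acc <- score_sequence_accuracy(r$taps, melody)
    r$correct <- acc$correct
    if (acc$correct) {
      r$itis <- extract_itis(r$taps, clamp_negative = clamp_negative)
    }
    r
  })
  pids <- vapply(records, `[[`, "", "participant_id")
  out <- list()
  for (pid in unique(pids)) {
    sub <- records[pids == pid]
    ord <- order(vapply(sub, `[[`, 1L, "trial_index"))
    parts <- partition_phases(sub[ord])
    out <- c(out, parts$learning, parts$practice)
  }
  out
}

summarise_seeds <- function(seeds) {
  lapply(seeds, function(ss) {
    idio <- seed_idiosyncrasy(ss)
    list(learning_context = ss$learning_context,
         pool_size = length(ss$pool),
         rmsd_original_learning = euclidean_rmsd(ss$original, ss$learning),
         idiosyncrasy_original = unname(idio["original"]),
         idiosyncrasy_learning = unname(idio["learning"]))
  })
}

write_stage <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes the configured stages: simulation (writing tap-log, seed,
#' covariate and truth files), analysis (read/clean/extract, phase
#' partition, evidence table, mixed models, learning-rate and covariate
#' screens, tempo-confound control, direction verdicts), and report
#' generation. All intermediate tables are written as CSV under
#' `config$out_dir` plus a JSON report; the run is deterministic given the
#' same configuration and inputs. Stage progress is logged to stderr.
#'
#' @param config a [run_config()].
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_stage <- function(fmt, ...) message(sprintf(paste0("[taptrans] ", fmt), ...))

  sim <- NULL
  if (config$mode %in% c("simulate", "simulate+analyse")) {
    log_stage("simulate: seed %d", config$sim$rng_seed)
    sim <- simulate_experiment(config$sim)
    if (!is.null(out_dir)) {
      if (config$sim$include_taps) {
        write_tap_log(sim$records, file.path(out_dir, "taplog.csv"))
      }
      write_stage(sim$covariates, out_dir, "covariates.csv")
      for (cond in names(sim$seeds)) {
        write_seed_pool(sim$seeds[[cond]],
                        file.path(out_dir, paste0("seeds_", cond, ".csv")))
      }
      jsonlite::write_json(
        list(rng_seed = config$sim$rng_seed,
             n_per_condition = config$sim$n_per_condition,
             strategy = unclass(config$sim$strategy),
             noise = unclass(config$sim$noise),
             contexts = lapply(config$sim$contexts, unclass)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
    if (config$mode == "simulate") {
      report <- structure(list(mode = "simulate",
                               n_participants = nrow(sim$covariates),
                               n_records = length(sim$records),
                               seeds = summarise_seeds(sim$seeds),
                               config_echo = list(rng_seed = config$sim$rng_seed)),
                          class = "run_report")
      if (!is.null(out_dir)) {
        jsonlite::write_json(unclass(report),
                             file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      return(report)
    }
  }

  if (config$mode == "analyse") {
    log_stage("analyse: reading %s", config$taplog_path)
    mel <- if (is.null(config$melody_path)) default_melody() else
      read_melody(config$melody_path)
    raw <- read_tap_log(config$taplog_path, dialect = "csv")
    records <- prepare_records(raw, mel, min_gap = config$min_gap,
                               clamp_negative = config$clamp_negative)
    seeds <- list(
      LearnFromPerformance = read_seed_pool(config$seed_paths$LearnFromPerformance,
                                            "Performance"),
      LearnFromDemonstration = read_seed_pool(config$seed_paths$LearnFromDemonstration,
                                              "Demonstration")
    )
    cov_in <- utils::read.csv(config$covariates_path, stringsAsFactors = FALSE)
    # learning-rate counts are recomputed from the records themselves
    pids <- vapply(records, `[[`, "", "participant_id")
    counts <- do.call(rbind, lapply(unique(pids), function(pid) {
      lr <- learning_rate_summary(records[pids == pid])
      data.frame(participant_id = pid,
                 n_learning_trials = lr$n_learning_trials,
                 n_errors = lr$n_errors, stringsAsFactors = FALSE)
    }))
    covariates <- merge(cov_in[setdiff(names(cov_in),
                                       c("n_learning_trials", "n_errors"))],
                        counts, by = "participant_id", sort = FALSE)
  } else {
    records <- sim$records
    seeds <- sim$seeds
    covariates <- sim$covariates
  }

  log_stage("evidence table: %d records", length(records))
  evidence <- build_evidence_table(records, seeds, covariates,
                                   rmsd_method = config$rmsd_method,
                                   spc_control = config$spc_control)
  write_stage(evidence, out_dir, "evidence.csv")

  log_stage("inference")
  fits <- list(rmsd = fit_evidence_model(evidence, "rmsd",
                                         df_method = config$df_method),
               spc = fit_evidence_model(evidence, "spc",
                                        df_method = config$df_method))
  model_tab <- do.call(rbind, lapply(fits, function(f) {
    cbind(metric = f$metric, f$coefficients)
  }))
  rownames(model_tab) <- NULL
  write_stage(model_tab, out_dir, "models.csv")
  verdicts <- rbind(classify_direction(fits$rmsd, config$alpha),
                    classify_direction(fits$spc, config$alpha))
  write_stage(verdicts, out_dir, "verdicts.csv")

  learning_rates <- compare_learning_rates(covariates)
  screens <- covariate_screens(covariates)
  tempo_control <- raw_rmsd_tempo_control(evidence)
  write_stage(learning_rates, out_dir, "learning_rates.csv")
  write_stage(screens, out_dir, "covariate_screens.csv")
  write_stage(tempo_control, out_dir, "tempo_control.csv")

  evidence_summary <- stats::aggregate(value ~ condition + metric,
                                       data = evidence, FUN = mean)
  names(evidence_summary)[names(evidence_summary) == "value"] <- "mean_value"

  report <- structure(
    list(mode = config$mode,
         version = as.character(utils::packageVersion("taptrans")),
         n_participants = length(unique(evidence$participant_id)),
         n_records = length(records),
         n_evidence_rows = nrow(evidence),
         seeds = summarise_seeds(seeds),
         evidence_summary = evidence_summary,
         models = model_tab,
         verdicts = verdicts,
         learning_rates = learning_rates,
         covariate_screens = screens,
         tempo_control = tempo_control,
         config_echo = list(mode = config$mode, rng_seed = config$rng_seed,
                            rmsd_method = config$rmsd_method,
                            spc_control = config$spc_control,
                            min_gap = config$min_gap,
                            clamp_negative = config$clamp_negative,
                            alpha = config$alpha,
                            df_method = config$df_method)),
    class = "run_report"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> mode: %s; %d participants\n", x$mode,
              x$n_participants))
  for (cond in names(x$seeds)) {
    s <- x$seeds[[cond]]
    cat(sprintf("  %s (%s seed): RMSD to Original %.2f ms; idiosyncrasy r = %.3f (orig) / %.3f (learn)\n",
                cond, s$learning_context, s$rmsd_original_learning,
                s$idiosyncrasy_original, s$idiosyncrasy_learning))
  }
  if (!is.null(x$verdicts)) {
    cat("direction verdicts:\n")
    v <- x$verdicts
    for (i in seq_len(nrow(v))) {
      cat(sprintf("  %s / %s: %s (estimate %.4g, p = %.4g)\n", v$metric[i],
                  v$term[i], v$verdict[i], v$estimate[i], v$p[i]))
    }
  }
  invisible(x)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()]; `sim` sub-keys mirror [sim_config()] (scalar fields
#' only: sample sizes, noise, strategy, contexts as s/g/style_sd triples,
#' learning phase, rng_seed).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- list()
  if (!is.null(y$sim)) {
    s <- y$sim
    if (!is.null(s$contexts)) {
      sim_args$contexts <- lapply(s$contexts, function(cc) {
        context_modulation(cc$tempo_scale %||% 1, cc$exaggeration %||% 1,
                           cc$style_sd %||% 0)
      })
    }
    if (!is.null(s$noise)) sim_args$noise <- do.call(noise_params, s$noise)
    if (!is.null(s$strategy)) {
      sim_args$strategy <- do.call(learner_strategy, s$strategy)
    }
    if (!is.null(s$learning_phase)) {
      sim_args$learning_phase <- do.call(learning_phase_params,
                                         s$learning_phase)
    }
    for (k in c("n_per_condition", "n_practice_trials", "n_pool_per_context",
                "rng_seed", "include_taps", "tap_duration")) {
      if (!is.null(s[[k]])) sim_args[[k]] <- s[[k]]
    }
  }
  args <- y[setdiff(names(y), "sim")]
  args$sim <- do.call(sim_config, sim_args)
  do.call(run_config, args)
}

#' Write the canonical fixture set
#'
#' Writes small plain-text fixtures into a directory: the melody definition,
#' the noiseless 250/600 representation, tap logs for the two worked
#' learning-rate bookkeeping participants (errors on trials 1-2 with ten
#' correct after, giving counts (2, 2); errors on trials 1 and 10 with
#' trials 2-9 correct and ten correct after, giving counts (10, 2)), and a
#' tiny 4-participant simulated dataset in the tap-log dialect.
#'
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mel <- default_melody()
  rep_itis <- build_representation()

  write_melody(mel, file.path(dir, "melody.json"))
  utils::write.csv(data.frame(interval_index = seq_along(rep_itis),
                              iti_ms = rep_itis),
                   file.path(dir, "representation.csv"), row.names = FALSE)

  wrong <- melody(substitute_first_drum(mel$pitches), mel$chunk_structure)
  trial_taps <- function(pid, idx, ok) {
    m <- if (ok) mel else wrong
    r <- itis_to_taps(rep_itis, m, trial_id = sprintf("%s_%03d", pid, idx))
    production_record(pid, "LearnFromPerformance", idx, taps = r)
  }
  worked_a <- lapply(seq_len(12), function(i) {
    trial_taps("WORKED_A", i, ok = !(i %in% 1:2))
  })
  worked_b <- lapply(seq_len(20), function(i) {
    trial_taps("WORKED_B", i, ok = !(i %in% c(1, 10)))
  })
  write_tap_log(c(worked_a, worked_b),
                file.path(dir, "worked_examples.csv"))

  tiny <- run_config(mode = "simulate",
                     sim = sim_config(n_per_condition = 2, rng_seed = 977L),
                     out_dir = file.path(dir, "tiny_dataset"))
  run_pipeline(tiny)

  invisible(list.files(dir, recursive = TRUE, full.names = TRUE))
}

# deterministic single-drum substitution used by the fixtures
substitute_first_drum <- function(pitches) {
  pitches[1] <- setdiff(1:4, pitches[1])[1]
  pitches
}
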