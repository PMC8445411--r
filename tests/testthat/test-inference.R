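# Evidence table construction, mixed-model fitting, learning-rate and
# covariate statistics, direction classification.

sim_small <- function(seed = 99, ...) {
  simulate_experiment(sim_config(rng_seed = seed, include_taps = FALSE, ...))
}

test_that("the evidence table has one row per practice trial per metric", {
  sim <- sim_small()
  tab <- build_evidence_table(sim)
  expect_equal(nrow(tab), 32 * 10 * 2)
  expect_setequal(unique(tab$metric), c("rmsd", "spc"))
  counts <- table(tab$participant_id, tab$metric)
  expect_true(all(counts == 10))
  expect_true(all(tab$trial_index %in% 1:10))
  # evidence is the signed difference of the stored similarities
  rmsd_rows <- tab[tab$metric == "rmsd", ]
  expect_equal(rmsd_rows$value,
               rmsd_rows$similarity_original - rmsd_rows$similarity_learning)
  spc_rows <- tab[tab$metric == "spc", ]
  expect_equal(spc_rows$value,
               spc_rows$similarity_learning - spc_rows$similarity_original)
})

test_that("a zero-noise pure-copy world gives constant per-condition rmsd values", {
  cfg <- sim_config(
    n_per_condition = 2,
    noise = noise_params(cv = 0, tempo_jitter_sd = 0,
                         participant_tempo_sd = 0, participant_shape_sd = 0),
    contexts = list(Original = context_modulation(1, 1, 0),
                    Performance = context_modulation(1.0, 1.6, 0),
                    Demonstration = context_modulation(1.4, 1.5, 0)),
    strategy = learner_strategy(1, 1),
    learning_phase = learning_phase_params(mean_errors = 0),
    rng_seed = 3, include_taps = FALSE
  )
  sim <- simulate_experiment(cfg)
  practice <- Filter(function(r) identical(r$phase, "practice"), sim$records)
  for (r in practice) {
    ss <- sim$seeds[[r$condition]]
    expect_equal(rmsd_evidence(r$itis, ss),
                 euclidean_rmsd(ss$learning, ss$original), tolerance = 1e-9)
  }
})

test_that("the evidence table round-trips through CSV unchanged", {
  sim <- sim_small(7)
  tab <- build_evidence_table(sim)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$value, tab$value, tolerance = 1e-9)
  expect_identical(back$participant_id, tab$participant_id)
  expect_identical(back$metric, tab$metric)
})

test_that("missing covariates are an explicit error", {
  sim <- sim_small(8)
  cov_bad <- sim$covariates
  cov_bad$mbea_scale[3] <- NA
  expect_error(build_evidence_table(sim$records, sim$seeds, cov_bad),
               class = "taptrans_missing_data")
  cov_short <- sim$covariates[setdiff(names(sim$covariates), "mbea_key")]
  expect_error(build_evidence_table(sim$records, sim$seeds, cov_short),
               class = "taptrans_missing_data")
})

test_that("a constant response degenerates to an intercept-only fit", {
  sim <- sim_small(9)
  tab <- build_evidence_table(sim)
  tab$value[tab$metric == "rmsd"] <- 42
  fit <- fit_evidence_model(tab, "rmsd")
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"],
               42)
  expect_identical(fit$fallback, "degenerate")
})

test_that("with no participant-level variance the fit matches OLS", {
  # balanced design, iid noise: mixed-model fixed effects equal OLS
  set.seed(41)
  sim <- sim_small(10)
  tab <- build_evidence_table(sim)
  tab <- tab[tab$metric == "rmsd", ]
  is_demo <- as.integer(tab$condition == "LearnFromDemonstration")
  tab$value <- 100 + 50 * is_demo + 2 * tab$trial_index +
    5 * tab$mbea_scale + rnorm(nrow(tab), 0, 10)
  fit <- suppressWarnings(fit_evidence_model(tab, "rmsd"))

  dat <- tab
  dat$condition <- factor(dat$condition,
                          levels = c("LearnFromPerformance",
                                     "LearnFromDemonstration"))
  dat$log_learning <- log(dat$n_learning_trials + 1)
  for (v in c("trial_index", "log_learning", "mbea_scale", "mbea_metre",
              "mbea_key")) {
    dat[[v]] <- dat[[v]] - mean(dat[[v]])
  }
  ols <- stats::lm(value ~ condition + trial_index + log_learning +
                     mbea_scale + mbea_metre + mbea_key, dat)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("the fitted model recovers a known condition shift", {
  # inject a known shift on top of a null world and check coverage
  set.seed(43)
  hits <- 0
  for (rep_i in 1:5) {
    sim <- sim_small(100 + rep_i,
                     strategy = learner_strategy(0.5, 0.5),
                     contexts = list(Original = context_modulation(1, 1, 0.08),
                                     Performance = context_modulation(1, 1, 0.08),
                                     Demonstration = context_modulation(1, 1, 0.08)))
    tab <- build_evidence_table(sim)
    tab$value[tab$metric == "rmsd" &
                tab$condition == "LearnFromDemonstration"] <-
      tab$value[tab$metric == "rmsd" &
                  tab$condition == "LearnFromDemonstration"] + 200
    fit <- suppressWarnings(fit_evidence_model(tab, "rmsd"))
    co <- fit$coefficients
    row <- co[co$term == "conditionLearnFromDemonstration", ]
    ci <- row$estimate + c(-1, 1) * stats::qt(0.975, row$df) * row$se
    if (ci[1] <= 200 && 200 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("fit results carry Satterthwaite dfs and classified directions", {
  sim <- sim_small(11)
  tab <- build_evidence_table(sim)
  fit <- suppressWarnings(fit_evidence_model(tab, "rmsd"))
  expect_s3_class(fit, "evidence_lmm")
  co <- fit$coefficients
  expect_setequal(co$term,
                  c("(Intercept)", "conditionLearnFromDemonstration",
                    "trial_index", "log_learning", "mbea_scale", "mbea_metre",
                    "mbea_key"))
  expect_true(all(is.finite(co$df) & co$df > 0))
  expect_true(all(co$p >= 0 & co$p <= 1))
  # fractional (not integer) dfs are the signature of the Satterthwaite method
  expect_true(any(abs(co$df - round(co$df)) > 1e-6))

  verdicts <- classify_direction(fit)
  expect_equal(nrow(verdicts), 2)
  expect_setequal(verdicts$term, c("intercept", "condition"))
  expect_true(all(verdicts$verdict %in%
                    c("copying", "reconstruction", "indeterminate")))

  # the residual-df fallback is available and flagged
  fit_ols <- fit_evidence_model(tab, "rmsd", df_method = "residual")
  expect_identical(fit_ols$fallback, "ols")
  expect_equal(fit_ols$coefficients$df,
               rep(fit_ols$n_obs - 7, nrow(fit_ols$coefficients)))
})

test_that("direction classification applies the sign-and-alpha rule", {
  fake <- structure(list(coefficients = data.frame(
    term = c("(Intercept)", "conditionLearnFromDemonstration"),
    estimate = c(-0.58, 291.09), se = c(0.26, 73.06), df = c(24.42, 24.01),
    t = c(-2.19, 3.98), p = c(0.038, 0.0005), stringsAsFactors = FALSE),
    metric = "spc"), class = "evidence_lmm")
  v <- classify_direction(fake, alpha = 0.05)
  expect_identical(v$verdict[v$term == "intercept"], "reconstruction")
  expect_identical(v$verdict[v$term == "condition"], "copying")

  fake$coefficients$p <- c(0.5, 0.5)
  v2 <- classify_direction(fake, alpha = 0.05)
  expect_true(all(v2$verdict == "indeterminate"))
})

test_that("learning-rate comparison is a Welch t with pooled-sd Cohen's d", {
  cov <- data.frame(
    participant_id = sprintf("P%02d", 1:6),
    condition = rep(c("LearnFromDemonstration", "LearnFromPerformance"),
                    each = 3),
    n_learning_trials = c(1, 2, 3, 4, 5, 6),
    n_errors = c(1, 2, 4, 2, 3, 6),
    mbea_scale = rnorm(6), mbea_metre = rnorm(6), mbea_key = rnorm(6)
  )
  out <- compare_learning_rates(cov)
  h <- welch_oracle(c(1, 2, 3), c(4, 5, 6))
  row <- out[out$measure == "n_learning_trials", ]
  expect_equal(row$t, h$t, tolerance = 1e-10)
  expect_equal(row$df, h$df, tolerance = 1e-10)
  expect_equal(row$cohens_d, -3)

  # identical groups: t = 0, d = 0
  cov0 <- cov
  cov0$n_learning_trials <- rep(c(1, 2, 3), 2)
  cov0$n_errors <- rep(c(2, 4, 6), 2)
  out0 <- compare_learning_rates(cov0)
  expect_equal(out0$t[out0$measure == "n_learning_trials"], 0)
  expect_equal(out0$cohens_d[out0$measure == "n_learning_trials"], 0)

  # label swap flips the sign of t and d
  cov_sw <- cov
  cov_sw$condition <- rev(cov$condition)
  out_sw <- compare_learning_rates(cov_sw)
  expect_equal(out_sw$t[1], -out$t[1], tolerance = 1e-10)
  expect_equal(out_sw$cohens_d[1], -out$cohens_d[1], tolerance = 1e-10)

  expect_error(compare_learning_rates(cov[1:4, ]),
               class = "taptrans_validation_error")
})

test_that("the confidence interval excludes zero exactly when p < .05", {
  set.seed(44)
  for (i in 1:50) {
    cov <- data.frame(
      participant_id = sprintf("P%02d", 1:12),
      condition = rep(c("LearnFromPerformance", "LearnFromDemonstration"),
                      each = 6),
      n_learning_trials = rpois(12, 6) + rep(c(0, sample(0:4, 1)), each = 6),
      n_errors = rpois(12, 3),
      mbea_scale = rnorm(12), mbea_metre = rnorm(12), mbea_key = rnorm(12)
    )
    out <- compare_learning_rates(cov)
    for (j in seq_len(nrow(out))) {
      excludes <- out$ci_lower[j] > 0 || out$ci_upper[j] < 0
      expect_identical(excludes, out$p[j] < 0.05)
    }
  }
})

test_that("covariate screens match the textbook r-to-t conversion", {
  set.seed(45)
  cov <- data.frame(
    participant_id = sprintf("P%02d", 1:30),
    condition = rep(c("LearnFromPerformance", "LearnFromDemonstration"), 15),
    n_learning_trials = rpois(30, 8), n_errors = rpois(30, 3),
    mbea_scale = rnorm(30), mbea_metre = rnorm(30), mbea_key = rnorm(30)
  )
  out <- covariate_screens(cov)
  expect_equal(nrow(out), 6)
  for (j in seq_len(nrow(out))) {
    r <- stats::cor(cov[[out$subscale[j]]], cov[[out$measure[j]]])
    tval <- r * sqrt(28) / sqrt(1 - r^2)
    expect_equal(out$r[j], r, tolerance = 1e-12)
    expect_equal(out$t[j], tval, tolerance = 1e-12)
    expect_equal(out$df[j], 28)
    expect_equal(out$p[j], 2 * stats::pt(-abs(tval), 28), tolerance = 1e-12)
  }
  # a perfectly correlated pair
  cov$mbea_scale <- cov$n_errors
  out2 <- covariate_screens(cov)
  row <- out2[out2$subscale == "mbea_scale" & out2$measure == "n_errors", ]
  expect_equal(row$r, 1)
  expect_lt(row$p, 1e-12)
})

test_that("independent covariates reject at close to the nominal rate", {
  set.seed(46)
  ps <- replicate(400, {
    cov <- data.frame(
      participant_id = sprintf("P%02d", 1:30),
      condition = rep(c("LearnFromPerformance", "LearnFromDemonstration"), 15),
      n_learning_trials = rpois(30, 8), n_errors = rpois(30, 3),
      mbea_scale = rnorm(30), mbea_metre = rnorm(30), mbea_key = rnorm(30)
    )
    covariate_screens(cov)$p[1]
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.11)
})

test_that("the tempo-control comparison works on participant means", {
  sim <- sim_small(12)
  tab <- build_evidence_table(sim)
  out <- raw_rmsd_tempo_control(tab)
  per <- stats::aggregate(similarity_learning ~ participant_id + condition,
                          tab[tab$metric == "rmsd", ], mean)
  h <- welch_oracle(
    per$similarity_learning[per$condition == "LearnFromPerformance"],
    per$similarity_learning[per$condition == "LearnFromDemonstration"])
  expect_equal(out$t, h$t, tolerance = 1e-10)
  expect_equal(out$df, h$df, tolerance = 1e-10)
  expect_type(out$interpretation, "character")

  # identical conditions give t = 0
  tab0 <- tab[tab$metric == "rmsd", ]
  tab0$similarity_learning <- rep(c(500, 600), length.out = nrow(tab0))
  tab0$metric <- "rmsd"
  perf_ids <- unique(tab0$participant_id[tab0$condition == "LearnFromPerformance"])
  demo_ids <- unique(tab0$participant_id[tab0$condition == "LearnFromDemonstration"])
  tab0$similarity_learning <- 550 +
    as.integer(factor(tab0$participant_id)) %% 4
  mirror <- tab0
  expect_equal(raw_rmsd_tempo_control(rbind(
    tab0[tab0$condition == "LearnFromPerformance", ],
    within(tab0[tab0$condition == "LearnFromPerformance", ], {
      condition <- "LearnFromDemonstration"
      participant_id <- paste0(participant_id, "x")
    })))$t, 0, tolerance = 1e-10)
})
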