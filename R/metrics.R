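# Absolute-timing (Euclidean/RMSD) and relative-timing (semi-partial
# correlation) similarity metrics, and the signed evidence scores that
# operationalise copying versus reconstruction.

#' Euclidean (RMSD) distance between ITI sequences
#'
#' Proximity of two productions in absolute timing. Following the study's
#' Eq-1 convention this is the plain Euclidean distance,
#' \eqn{\sqrt{\sum_i (x_i - y_i)^2}}, despite the historical "RMSD" name;
#' `method = "mean"` exposes the root-mean-square variant
#' \eqn{\sqrt{\frac{1}{n}\sum_i (x_i - y_i)^2}} for sensitivity analyses.
#' The distance is symmetric, non-negative, invariant under a common additive
#' shift of both sequences, and scales linearly under a common multiplicative
#' scaling.
#'
#' @param x,y numeric ITI vectors of equal length (11 in this design).
#' @param method `"sum"` (Euclidean, default) or `"mean"` (root mean square).
#' @return Distance in milliseconds.
#' @export
euclidean_rmsd <- function(x, y, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_taptrans(sprintf("ITI sequences must be numeric and of equal length (%d vs %d)",
                          length(x), length(y)),
                  "taptrans_validation_error")
  }
  ss <- sum((x - y)^2)
  if (method == "mean") sqrt(ss / length(x)) else sqrt(ss)
}

#' Pearson correlation between two ITI sequences
#'
#' The pairwise consistency measure: plain Pearson correlation of the two
#' 11-vectors. Errors on zero variance (a flat sequence has no rhythm to
#' correlate).
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_xcorr <- function(x, y) {
  if (length(x) != length(y)) {
    stop_taptrans("sequences must have equal length", "taptrans_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_taptrans("correlation undefined: a sequence has zero variance",
                  "taptrans_undefined_correlation")
  }
  stats::cor(x, y)
}

#' Mean pairwise cross-correlation of a production pool
#'
#' Consistency of a set of productions: the mean of [pearson_xcorr()] over
#' all unordered pairs. This is the statistic summarised as the "mean
#' cross-correlation" of a model's productions within a context.
#'
#' @param pool list of numeric ITI vectors (>= 2).
#' @return Mean pairwise correlation.
#' @export
mean_pairwise_xcorr <- function(pool) {
  if (length(pool) < 2) {
    stop_taptrans("need at least 2 sequences", "taptrans_validation_error")
  }
  pairs <- utils::combn(length(pool), 2)
  mean(apply(pairs, 2, function(ij) pearson_xcorr(pool[[ij[1]]], pool[[ij[2]]])))
}

#' Grand-average ITI sequence of a pool
#'
#' Element-wise arithmetic mean of the pool of the model's unshown
#' productions; used as the baseline of melody-generic similarity that any
#' two productions of the same piece share.
#'
#' @param pool non-empty list of numeric ITI vectors.
#' @return Numeric ITI vector.
#' @export
grand_average_iti <- function(pool) {
  if (length(pool) == 0) {
    stop_taptrans("empty pool", "taptrans_validation_error")
  }
  rowMeans(do.call(cbind, pool))
}

#' Semi-partial correlation with a baseline control
#'
#' Correlation between the participant's production `d` and the model
#' sequence `m` after the grand-average baseline `a` is removed from `m` by
#' least squares: \eqn{r_{d(m \cdot a)} = (r_{dm} - r_{da} r_{ma}) /
#' \sqrt{1 - r_{ma}^2}}. Equivalently (and tested as such), the Pearson
#' correlation of `d` with the residuals of regressing `m` on `a` with an
#' intercept. Removing the baseline from the model sequence strips the
#' melody-generic structure carried by every seed, leaving the residual
#' similarity of the production to what is idiosyncratic about that seed.
#' `control = "production"` instead residualises `d`, for sensitivity
#' analyses. The result is a genuine correlation and lies in `[-1, 1]`
#' (floating error is clipped at tolerance 1e-12).
#'
#' @param d participant production (numeric ITI vector).
#' @param m model sequence of interest.
#' @param a baseline (grand-average) sequence.
#' @param control which variable the baseline is partialled out of:
#'   `"model"` (default) or `"production"`.
#' @return Semi-partial correlation coefficient.
#' @export
semipartial_similarity <- function(d, m, a, control = c("model", "production")) {
  control <- match.arg(control)
  if (length(d) != length(m) || length(d) != length(a)) {
    stop_taptrans("sequences must have equal length", "taptrans_validation_error")
  }
  if (control == "production") {
    tmp <- d; d <- m; m <- tmp
  }
  r_dm <- pearson_xcorr(d, m)
  r_da <- pearson_xcorr(d, a)
  r_ma <- pearson_xcorr(m, a)
  if (abs(r_ma) >= 1 - 1e-12) {
    stop_taptrans("degenerate control: the model sequence is collinear with the baseline",
                  "taptrans_degenerate_control")
  }
  r <- (r_dm - r_da * r_ma) / sqrt(1 - r_ma^2)
  if (abs(r) > 1) {
    if (abs(r) > 1 + 1e-12) {
      stop_taptrans("semi-partial correlation outside [-1, 1] beyond tolerance",
                    "taptrans_numeric_error")
    }
    r <- sign(r)
  }
  r
}

#' Construct a seed set
#'
#' The comparison material for one learning condition: the Original seed (the
#' model's uninstructed production of the melody), the Learning seed (the
#' Performance or Demonstration production shown to the learner), and the
#' grand-average pool of the model's unshown productions (27 in the study
#' design). The element-wise grand average of the pool is precomputed and
#' stored.
#'
#' @param original,learning numeric ITI vectors (length 11).
#' @param learning_context `"Performance"` or `"Demonstration"`.
#' @param pool list of numeric ITI vectors (the unshown productions; must not
#'   include the shown seeds).
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(original, learning,
                     learning_context = c("Performance", "Demonstration"),
                     pool) {
  learning_context <- match.arg(learning_context)
  original <- assert_itis(original, "original")
  learning <- assert_itis(learning, "learning")
  if (length(pool) == 0) {
    stop_taptrans("seed pool must be non-empty", "taptrans_validation_error")
  }
  pool <- lapply(pool, assert_itis, arg = "pool element")
  structure(
    list(original = original, learning = learning,
         learning_context = learning_context, pool = pool,
         grand_average = grand_average_iti(pool)),
    class = "seed_set"
  )
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> learning context: %s; pool of %d unshown productions\n",
              x$learning_context, length(x$pool)))
  cat(sprintf("  RMSD(original, learning) = %.2f ms\n",
              euclidean_rmsd(x$original, x$learning)))
  invisible(x)
}

#' Signed absolute-timing evidence score
#'
#' RMSD of the production to the Original seed minus RMSD to the Learning
#' seed. Positive values mean the production sits closer to the Learning
#' seed in absolute timing - evidence for copying; negative values mean it
#' sits closer to the Original - evidence for reconstruction. Antisymmetric
#' under exchange of the two seeds.
#'
#' @param prod numeric ITI vector of the learner's production.
#' @param seeds a `seed_set`.
#' @param method passed to [euclidean_rmsd()].
#' @return Signed evidence value in milliseconds.
#' @export
rmsd_evidence <- function(prod, seeds, method = c("sum", "mean")) {
  method <- match.arg(method)
  euclidean_rmsd(prod, seeds$original, method = method) -
    euclidean_rmsd(prod, seeds$learning, method = method)
}

#' Signed relative-timing evidence score
#'
#' Semi-partial correlation of the production with the Learning seed minus
#' that with the Original seed, both controlling for the grand average of the
#' unshown pool. Positive values mean greater residual structural similarity
#' to the Learning seed - evidence for copying; negative values favour
#' reconstruction. Antisymmetric under exchange of the two seeds; each SPC is
#' a correlation so the score lies in `[-2, 2]`.
#'
#' @param prod numeric ITI vector of the learner's production.
#' @param seeds a `seed_set`.
#' @param control passed to [semipartial_similarity()].
#' @return Signed evidence value (dimensionless).
#' @export
spc_evidence <- function(prod, seeds, control = c("model", "production")) {
  control <- match.arg(control)
  a <- seeds$grand_average
  semipartial_similarity(prod, seeds$learning, a, control = control) -
    semipartial_similarity(prod, seeds$original, a, control = control)
}

#' Seed idiosyncrasy check
#'
#' Simple Pearson correlation of each shown seed with the grand average of
#' the unshown pool. A shown seed much less correlated with the grand average
#' than the others is idiosyncratic, which can distort the strength of the
#' residual (semi-partial) similarities computed against it.
#'
#' @param seeds a `seed_set`.
#' @return Named numeric vector with elements `original` and `learning`.
#' @export
seed_idiosyncrasy <- function(seeds) {
  a <- seeds$grand_average
  c(original = pearson_xcorr(seeds$original, a),
    learning = pearson_xcorr(seeds$learning, a))
}

#' Read or write named seed ITI sequences (CSV)
#'
#' Plain CSV with a `role` column (`original`, `learning`, or `pool`), an
#' optional `context` column, and eleven columns `iti_1` .. `iti_11`. This is
#' the layout used for exported seed material.
#'
#' @param path file path.
#' @param learning_context learning context label for the reconstructed
#'   `seed_set`.
#' @return `read_seed_pool()` returns a `seed_set`.
#' @export
read_seed_pool <- function(path, learning_context = c("Performance", "Demonstration")) {
  learning_context <- match.arg(learning_context)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  iti_cols <- paste0("iti_", 1:11)
  if (!all(c("role", iti_cols) %in% names(df))) {
    stop_taptrans("seed CSV needs columns role, iti_1..iti_11",
                  "taptrans_parse_error")
  }
  take <- function(rows) lapply(seq_len(nrow(rows)), function(i) {
    as.numeric(rows[i, iti_cols])
  })
  orig <- take(df[df$role == "original", , drop = FALSE])
  learn <- take(df[df$role == "learning", , drop = FALSE])
  pool <- take(df[df$role == "pool", , drop = FALSE])
  if (length(orig) != 1 || length(learn) != 1) {
    stop_taptrans("seed CSV must contain exactly one original and one learning row",
                  "taptrans_validation_error")
  }
  seed_set(orig[[1]], learn[[1]], learning_context, pool)
}

#' @rdname read_seed_pool
#' @param seeds a `seed_set`.
#' @export
write_seed_pool <- function(seeds, path) {
  mat <- rbind(seeds$original, seeds$learning,
               do.call(rbind, seeds$pool))
  df <- data.frame(role = c("original", "learning",
                            rep("pool", length(seeds$pool))),
                   context = c("Original", seeds$learning_context,
                               rep("", length(seeds$pool))))
  itidf <- as.data.frame(mat)
  names(itidf) <- paste0("iti_", 1:11)
  utils::write.csv(cbind(df, itidf), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
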