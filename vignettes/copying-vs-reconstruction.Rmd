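---
title: "Distinguishing copying from reconstruction in rhythm transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing copying from reconstruction in rhythm transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When one person learns a behaviour by watching another, two very different
cognitive processes can produce superficially similar outcomes. Under
*copying*, the learner reproduces the surface form of what they observed,
and any deviation is random copying error. Under *reconstruction*, the
learner infers what the demonstrator's underlying representation must have
been — discounting features they recognise as incidental to the current
context — and converges back on that inferred representation rather than on
the observed surface form.

The two processes can be separated experimentally by driving a wedge
between the surface form and the representation: have the model produce the
behaviour under a context the learner does not share (performing for an
audience, or demonstrating pedagogically), so that the production carries
*embedded incidental modulations* — systematic deviations from the model's
uninstructed behaviour that cannot simply be omitted, because they are
woven into integral dimensions of the action. A copier will reproduce the
modulated surface form; a reconstructor will converge back on the
uninstructed behaviour.

`taptrans` implements this logic for a timed 12-note drummed melody. The
melody (four drums, pitches C–E–G–A) has a 3-3-2-2-2 chunking structure,
and its production has two integral timing dimensions:

* **absolute timing** — the overall tempo;
* **relative timing** — the rhythmic shape, i.e. the proportional
  relations among the 11 inter-tap intervals (ITIs).

Learners watch one uninstructed *Original* video and then learn, by
turn-taking, from one *Learning* video: either a *Performance* (exaggerated
long/short contrast at unchanged tempo) or a *Demonstration* (the same kind
of exaggeration plus a general slowing). After the learning phase ends with
ten consecutive correct trials (the *practice* trials), the question is
whether the practice timing tracks the Learning video (copying) or the
Original (reconstruction), separately per dimension.

## Data preparation

A production is a sequence of tap events (drum id, onset, offset,
velocity). Preparation mirrors the standard steps:

* **Double-tap merging** (`clean_double_taps()`): two consecutive events on
  the same drum closer than `min_gap` (second onset minus first offset) are
  a drumstick bounce; the intervening offset and onset are deleted,
  left-to-right to a fixpoint. The threshold defaults to 50 ms — below the
  physiological limit for intentional repeated strikes; it is a config
  option because no single value is canonical.
* **ITI extraction** (`extract_itis()`): ITI *i* is the onset of note
  *i + 1* minus the offset of note *i*, giving 11 intervals from 12 notes.
  Overlapping taps produce negative ITIs; these are retained with a warning
  by default (the definition permits them), with an optional clamp at 0.
* **Accuracy and phases** (`score_sequence_accuracy()`,
  `partition_phases()`): a trial is correct iff the drum order matches the
  melody exactly; the final ten consecutive correct trials are the practice
  phase and everything before — including correct trials later followed by
  an error — is the learning phase. The left-right reversed drum mapping
  (1↔4, 2↔3) is detected and reported but never auto-corrected.
* ITIs are computed only for correct trials; error trials rarely have 12
  usable taps and never enter the timing analyses.

## The two evidence scores

Both metrics compare each practice production `d` to the Original seed and
to the Learning seed, and both are signed so that **positive = copying,
negative = reconstruction**.

**Absolute timing.** Proximity is the Euclidean distance between ITI
vectors,

$$\mathrm{RMSD}(x, y) = \sqrt{\sum_{i=1}^{11} (x_i - y_i)^2},$$

the sqrt-of-*sum* convention (the quantity is conventionally called RMSD in
this literature although it is the plain Euclidean distance; a
root-mean-square variant is available as `method = "mean"`). The evidence
score is `RMSD(d, Original) − RMSD(d, Learning)`: positive when the
production sits closer to the Learning seed.

**Relative timing.** Structural similarity is the semi-partial correlation
of `d` with a seed `m`, controlling a grand-average baseline `a` — the
element-wise mean ITI vector of the model's 27 *unshown* productions
(across all three contexts). Any two productions of the same melody are
substantially correlated simply because they share the melody's generic
structure; `a` carries exactly that generic structure, so correlating `d`
with the residual of `m` after removing `a`,

$$r_{d(m \cdot a)} = \frac{r_{dm} - r_{da} r_{ma}}{\sqrt{1 - r_{ma}^2}},$$

isolates similarity to what is *idiosyncratic* about that particular seed.
The baseline is partialled out of the model sequence (the seed), because
the melody-generic structure to be removed is the part carried by every
seed; the orientation is exposed as an option (`control = "production"`)
since the semi-partial is asymmetric. The evidence score is
`SPC(d, Learning | a) − SPC(d, Original | a)`.

Both scores are antisymmetric under exchange of the two seeds, and both are
exactly zero when the two seeds coincide.

## Inference

Evidence scores (one per practice trial per metric) are analysed with a
linear mixed-effects model (`lmerTest`): fixed effects for learning
condition (treatment contrast with Learn-from-Performance as reference),
practice trial number (1–10), `log(learning trials + 1)`, and the three
MBEA-O melodic-perception subscales; random participant intercepts and
participant trial slopes; REML estimation with Satterthwaite degrees of
freedom. Design choices worth stating:

* **Centred covariates.** The continuous covariates are mean-centred, so
  the intercept is the adjusted mean evidence in the reference condition —
  the "reference-condition bias" that the direction verdict interprets —
  rather than an extrapolation to zero trials and zero test scores.
* **Log learning trials.** The exposure covariate enters as `log(n + 1)`
  so error-free participants (n = 0) are representable; the logarithm
  reflects the assumption that late exposures to the Learning video matter
  less than early ones.
* **Singular-fit ladder.** If the full random structure is singular the
  model falls back, with a warning and a flag in the result, to random
  intercepts only; nothing is silent. A zero-variance response
  short-circuits to the degenerate constant fit. With balanced data the
  fixed-effect estimates coincide with OLS when the random-effect variances
  vanish, which is tested against an explicit OLS oracle.
* **Verdicts.** `classify_direction()` labels the intercept and the
  condition effect `copying` (positive, p < α), `reconstruction`
  (negative, p < α) or `indeterminate`. No multiple-testing correction is
  applied across the two metrics, matching the analysis design this
  package follows; the report notes this.

Learning rates are compared by Welch t tests with pooled-sd Cohen's d.
`raw_rmsd_tempo_control()` implements the confound check for the absolute
dimension: apparent copying of the Demonstration's slow tempo could instead
be learners' generally slower preferred tempo; in that case raw distances
to the Learning seed should be significantly *larger* in the Performance
condition (whose seed is fast). A null result supports genuine copying.

## The generative model

`simulate_experiment()` generates complete synthetic studies so that every
stage of the pipeline — including the mixed model's sign and error
calibration — can be tested without human data. The generative world:

1. **Representation.** A flat 250 ms pulse with chunk-boundary intervals at
   250 × 2.4 = 600 ms (indices 3, 6, 8, 10 for 3-3-2-2-2).
2. **Context modulation.** `out = s(mean + g(rep − mean))`: the tempo scale
   `s` and the contrast exaggeration `g` act on orthogonal dimensions by
   construction. Defaults: Performance `s = 1.0, g = 1.6`; Demonstration
   `s = 1.4, g = 1.5`. With the default representation these put the
   Demonstration seed ≈ 840 ms and the Performance seed ≈ 500 ms
   (Euclidean) from the Original seed.
3. **Style variation.** Each of the model's productions carries a
   per-production lognormal shape modulation (`style_sd`; Original 0.08,
   Demonstration 0.15, Performance 0.30), normalised so the production
   *mean is preserved exactly* — expressive style moves the rhythm, never
   the tempo, keeping the two dimensions separable. These values reproduce
   the qualitative consistency ordering of the three contexts (mean
   pairwise cross-correlation of the pools: Original ≈ .95 >
   Demonstration ≈ .88 > Performance ≈ .8): a uniform contrast change alone
   cannot, since correlation is scale-invariant.
4. **Curated shown seeds.** The videos shown to learners are modelled as
   curated exemplars: the deviation of a shown seed from its exact context
   target has a *typical, fixed magnitude* (the context's style plus motor
   noise on the log scale) with a random pattern, again tempo-preserving.
   This mirrors how stimuli are actually selected (clear, representative
   exemplars of the contextual modulation) and keeps the seed geometry
   stable across simulated replicate studies. The remaining 9 productions
   per context form the 27-strong unshown pool.
5. **Learners.** A learner's production target mixes the Learning seed and
   the Original *as observed* with per-dimension weights: tempo
   `w_abs·tempo(Learning) + (1 − w_abs)·tempo(Original)`, shape likewise
   with `w_rel`. The default profile `w_abs = 1, w_rel = 0` copies the
   tempo and reconstructs the rhythm. Pure reconstruction converges on the
   *shown Original production* (idiosyncrasies included) rather than the
   latent representation, for two reasons: the latent representation is
   unobservable to a learner, who saw exactly one uninstructed production;
   and the semi-partial metric is, by design, sensitive to similarity with
   the shown seed's residual — convergence to the latent representation
   would be invisible to it (the grand average *is* essentially the latent
   shape). An idealised `reconstruct_to = "representation"` mode is
   available.
6. **Production noise.** Trial-level noise is multiplicative lognormal:
   per-interval cv 0.07 (unit mean) and a shared 2% log-tempo jitter —
   scalar (Weber-like) timing variability. Participant-level idiosyncrasy
   is additive in milliseconds: a preferred-tempo offset (sd 50 ms,
   truncated at ±2 sd) and a fixed zero-mean per-interval rhythm pattern
   (sd 45 ms). Additivity is deliberate: a learner's preferred tempo and
   habitual quirks belong to the learner and do not scale with the tempo
   of the seed they happen to watch, so a pure copier deviates equally
   from a slow Demonstration and a fast Performance — exactly the premise
   the tempo-confound control relies on. Together these place simulated
   novices several hundred ms (root-sum-square) from the seed they learn
   from, the scale observed for non-musicians reproducing an expert's
   timing, and they give the participant random effects real variance.
7. **Learning phase.** Error counts are negative-binomial (mean 4,
   dispersion 2); each error is preceded by a Geometric number (mean 1.5)
   of correct learning trials and the last learning trial is always an
   error, so the phase bookkeeping reconstructs the generated counts
   exactly. MBEA-O subscales are independent standard normals, uncorrelated
   with strategy (the study design treats them as exploratory covariates).
8. **Reproducibility.** One master seed governs everything through named
   substreams (`substream_seed()`), so any component can be regenerated in
   isolation and the whole dataset is bit-reproducible.

### Reference worlds used in validation

* **Study-profile world** (defaults): `w_abs = 1, w_rel = 0` with the
  contexts above. Expected signature: a significantly positive condition
  effect on RMSD evidence (copying the absolute dimension is only
  detectable when the Learning seed's tempo actually differs, i.e. in the
  Demonstration condition) and a significantly negative SPC intercept
  (reconstruction of the relative dimension in both conditions).
* **Null world**: all three contexts identical to Original with style
  variation off, and a symmetric blend learner `w = (0.5, 0.5)`. Under
  this world the two shown videos are exchangeable and the learner has no
  basis to favour either, so the true mean of both evidence scores is
  zero; an asymmetric strategy under exchangeable seeds would encode a
  genuine preference that the test *should* detect, and would not be a
  null. Style is off because the null isolates the core noise model.
* **Copying world** (for the tempo-confound control): `w = (1, 1)`.
* **Confound world**: learners ignore both seeds and play the Original
  shape at a fixed slow preferred tempo
  (`preferred_tempo_scale = 1.4`, matching the Demonstration's slowing),
  with correspondingly tight individual tempo scatter (sd 40 ms) — the
  confound hypothesis is a shared population-level preference.

## What the simulations do and do not show

The generator reproduces the features the analysis relies on: a stable
chunked representation, orthogonal tempo/shape modulations, seed
consistency ordering, realistic seed separations, learner strategies that
differ by timing dimension, and participant-clustered variability. Passing
sign-recovery and calibration tests therefore shows that the *pipeline*
measures what it claims to measure under the stated generative assumptions.

It does not show that human learners behave like the generator. Real data
additionally contain: serial dependence across trials (fatigue, drift),
melody-learning carryover into early practice trials, non-stationary
strategies, velocity/loudness structure (ignored throughout), and
stimulus idiosyncrasies richer than a uniform contrast transform plus
lognormal style.

One structural limitation deserves emphasis: in this design *all
participants of a condition share the same two shown videos*. Seed-level
sampling noise is therefore a cluster effect that participant-level mixed
models cannot estimate — the classic stimuli-as-fixed-effects problem.
In simulated replicate studies the realised seed pair shifts both
conditions' true evidence means coherently, which makes intercept tests
somewhat anticonservative under seed-resampling nulls even when the shown
seeds are modelled as curated (fixed-magnitude) exemplars, as done here:
the relative-timing intercept test rejects at roughly 11–13% rather than
5% across seed-resampled null replicates. The same clustering caps how
reliably a single 16 + 16 study can detect the slow-preferred-tempo
confound world (roughly 80% of replicates), and makes the raw-distance
control itself strongly stimulus-dependent when learners reconstruct the
rhythm (the Performance seed's idiosyncratic shape inflates raw distances
to it). Inference from any single study of this design is conditional on
its stimuli; generalising over stimuli would require replication with
fresh seed videos.

## Numerical choices

* Distances use the sqrt-of-sum convention; correlations the sample
  (n − 1) covariance convention (the ratio cancels, so the population
  convention gives identical values).
* Semi-partial values may exceed 1 in magnitude only through floating
  error and are clipped at tolerance 1e-12; a baseline collinear with the
  controlled seed (|r| ≥ 1 − 1e-12) raises a degenerate-control error.
* Modulated and rendered ITIs are floored at 20 ms (a physical lower bound
  for distinguishable strikes); an all-floored modulation warns.
* Trial indices are 1-based; times are milliseconds.
* Merged double taps keep the maximum velocity (velocity is unused
  downstream, so the choice is inert).

## Problem sizes used in the test suite

Unit and property tests run on 11-vectors and small synthetic datasets
(2–4 participants). The validation suite runs replicate simulated studies
at the full study design (16 + 16 participants × 10 practice trials):
100 replicates for sign recovery, 200 for null calibration, and 100 per
world for the tempo-confound discrimination, sizes chosen to give binomial
standard errors of a few percent on the reported rates while keeping a
full run of the suite in the minutes range on one core.
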