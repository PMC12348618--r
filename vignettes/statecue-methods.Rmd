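---
title: "Brain-state dynamics of appetite: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state dynamics of appetite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

`statecue` implements a dynamic analysis of appetite during naturalistic
food-cue video viewing. The measured quantities are (a) parcellated BOLD
time series (T TRs x P cortical parcels, TR = 1 s, 100 parcels grouped into
17 functional networks) from subjects passively watching food-cue videos,
(b) continuous 3-point appetite ratings from an independent rater group
watching the same videos (no key press = no desire, coded 0), and (c)
subject covariates: BMI, age, head motion, post-viewing food craving, and
six monthly BMI follow-ups.

The pipeline decomposes the BOLD series into recurring discrete brain
states with a hidden Markov model, aligns state occupancy with the group
appetite course through sliding windows, predicts windowed appetite from
occupancy with nested cross-validated ridge regression, summarizes each
subject by a *state expression* (the correlation between a state's
occupancy course and the appetite course), and relates expression to BMI
and craving (group tests, partial correlation, mediation) and to BMI
trajectories (average-linkage clustering of the monthly series).

Because no empirical recordings ship with the package, a first-class
synthetic-cohort generator produces all three inputs with planted ground
truth, and the test suite validates every stage against that truth or
against brute-force oracles.

## The state model

Brain activity is modelled as a K-state hidden Markov chain with Gaussian
emissions. Each subject/run series is standardized per parcel (zero mean,
unit variance within run, sample-SD convention), all runs are concatenated,
and PCA reduces the P parcels to the D components that explain 90% of
variance. The HMM has a K-simplex initial distribution, a row-stochastic
K x K transition matrix, and per-state full-covariance Gaussians in PC
space.

Estimation is Baum–Welch EM with k-means initialization and multiple
restarts (default 5), scaled forward–backward recursions implemented in
C++, and Viterbi decoding for hard state assignments. Subject runs are
independent chains: the recursion restarts at every concatenation boundary
with the initial distribution. Numerical safeguards: emission densities are
row-rescaled before exponentiation; covariances receive a 1e-6 ridge
(escalating on repeated Cholesky failure); EM stops when the relative
log-likelihood change falls below `tol` (default 1e-6) and the trace is
checked to be nondecreasing in tests. Variational-Bayes estimation is a
possible extension; EM reproduces the quantities this pipeline consumes
(state assignments, occupancies, activation patterns).

Hard (Viterbi) assignments drive fractional occupancy and state profiles;
posterior-weighted (soft) occupancy is available by option.

### Choosing K

`k_selection()` scores each candidate K by split-half stability: subjects
are split at random into halves, a model is fitted on each half in a shared
PCA space, both models decode the first half's data, and agreement is
measured three ways — zRand (pair-counting agreement z-scored against the
hypergeometric permutation null), NMI (mutual information normalized by the
mean entropy), and the activity concordance index (mean correlation of
optimally matched activation maps, assignment solved exactly). The chosen K
maximizes the mean of the three metrics after min-max scaling across the K
range (ties break toward smaller K); the rule is overridable.

Two behaviours of this procedure are worth knowing. First, zRand grows with
the number of clusters and its min-max-scaled value is noisy, so the
composite can prefer K above the generative truth. Second, when subjects
deviate from the shared stimulus-locked path in single isolated TRs (the
generator's deviation model), a model with one extra state can park those
deviant frames in a reproducible wide-covariance "collector" state that
both half-models discover independently; stability at K_true + 1 then
rivals or exceeds K_true. On reference cohorts (20 subjects, two 500-TR
runs, 6 planted states, 10% deviation rate) the composite peaks at the true
K in roughly 6 of 10 seeded replicates — informative, but not a guarantee.
Both effects are properties of stability-based selection on
stimulus-locked designs, not of the implementation.

## Ratings and alignment

Rater key presses are binned by TR (mean of presses within the bin, 0 for
silence — absence of pressing is treated as absence of desire and enters
the z-scoring), z-scored per rater over time, and averaged into the group
appetite course. The course is convolved with a canonical double-gamma
haemodynamic kernel (peak 6 s, undershoot 16 s, ratio 6, 32-s support, unit
absolute sum; all configurable — the kernel peaks near 5 s) using causal
zero-padded convolution, to respect the lag between neural events and the
BOLD signal.

Cross-rater reliability is the mean Spearman–Brown-corrected split-half
rank correlation over random half-splits (odd counts give the extra rater
to the larger half), with a surrogate null built by re-correlating one
half after shuffling its rank order, and an add-one right-tailed p so p is
never exactly zero. Note that this procedure compares a *mean over splits*
against *single-split* null draws; under true independence the mean has
much smaller variance than a single draw, so the test is conservative
(measured type I rate at alpha = 0.05 is ~0.00–0.02 rather than 0.05, and
it becomes more conservative as the rater count grows). For strongly
correlated raters — the regime the procedure is used in — this conservatism
is immaterial.

Sliding windows are 0-based half-open TR intervals of 5 TRs advancing by
2 TRs; trailing TRs without a full window are dropped so occupancy
denominators are constant. Runs of 391 and 287 TRs yield 194 and 142
windows. Per window the design holds each state's fractional occupancy and
the mean HRF-convolved group appetite — the target is stimulus-locked and
identical across subjects.

## Prediction

Windowed appetite is predicted from the K occupancy features by ridge
regression (closed form on centred data, unpenalized intercept) under
nested leave-one-subject-out cross-validation. Inside each outer fold: age,
sex and motion are regressed out of each feature by OLS fitted on the
training rows only (constant confounds, e.g. sex in a single-sex cohort,
are dropped); features are min-max scaled with training parameters (test
values may leave [0, 1]); the penalty is chosen from 20 log-spaced
candidates between 0.001 and 1000 by an inner 5-fold subject-level CV that
scores each candidate by accuracy (mean held-out Pearson r; a fold with
constant predictions scores 0) and stability (mean pairwise correlation of
the fold models' weight vectors), both min-max scaled, picking the
candidate closest to the ideal point (1, 1) (ties toward the smaller
penalty). Inner folds split subjects, not rows, to respect exchangeability.
The group-level penalty minimizes the mean inner-criterion distance across
outer folds; the group-level prediction is the dot product of the
group-mean preprocessed occupancy per window with the final model's
weights. Cross-stimulus generalization refits on all of one stimulus's data
at the group penalty and evaluates on the other.

Leave-one-subject-out validation with a shared stimulus has a subtle
optimism: any finite-sample association between the features' shared
(stimulus-locked) structure and window-level target noise is learned from
the training subjects and *transfers* to the held-out subject, because
both see the same windows. Under a shuffled-target null the mean held-out
r is therefore not zero but positive, decaying roughly like sqrt(K/W)
after shrinkage (measured: ~0.18 at 120 windows, ~0.10 at the reference
geometry of 496 windows). Cross-*stimulus* generalization does not inherit
this bias, which is one reason to weight it when interpreting results.

Feature importance uses a cluster bootstrap: subjects are resampled with
replacement (windows within a subject are dependent), preprocessing and the
ridge fit are repeated inside each resample, and Z = mean/SD of each
coefficient across resamples, with two-tailed normal p-values and BH-FDR
flags. One caveat is intrinsic to this design: because the target is
stimulus-locked and fixed across resamples, the finite-sample association
between a truly null feature and the target's window-level noise is *also*
fixed, so Z measures the across-subject stability of that spurious fit
rather than its sampling error. Null features therefore show |Z| < 2 in
only about half of replicate cohorts, while planted nonzero features are
detected essentially always. Interpreting |Z| as a stability ranking (as
the pipeline does when picking the expression state) is sound; interpreting
it as a calibrated test of zero association across stimuli is not.

## Association and trajectories

State expression is the Pearson correlation between a subject's windowed
occupancy of one state (runs concatenated; per-run values also obtainable)
and the group appetite target; constant occupancy yields a missing value.
Expression is invariant to affine rescaling of the target. Group contrasts
use pooled-variance t-tests (Welch optional); BMI associations use partial
correlation (OLS residuals on covariates, t-distributed p with
n - c - 2 df). Condition-wise occupancy validation uses one-way
repeated-measures ANOVA (subject as blocking factor; identical conditions
are reported as F = 0) with BH-corrected paired t-tests.

Mediation (BMI -> expression -> craving, age-adjusted; all variables one
value per subject, so the single-level case of the two-path model) reports
a, b, c, c-prime by OLS — the identity a*b + c' = c holds exactly — and a
BCa bootstrap interval for a*b: subjects resampled with replacement, bias
correction from the fraction of draws below the estimate, acceleration from
jackknife skewness. Full mediation is declared when the indirect interval
excludes zero and the direct path's percentile interval covers it. The
proportion mediated is reported as (c - c')/c. Under a fully independent
null the interval is conservative (coverage ~0.98 at n = 50), a known
property of bootstrap intervals for products of coefficients.

Six-point BMI trajectories are compared by Pearson correlation of the
within-subject-centred series (level removed, shape retained; a
first-difference mode is available), clustered with average linkage
(UPGMA) on distance 1 - r, and cut at two clusters; type 1 is the cluster
with the larger mean slope. Davies–Bouldin (lower better) and
Calinski–Harabasz (higher better) index curves are computed on the centred
vectors — the clustering's own feature space. Expression differences
between types use the same two-sample t-test.

## The synthetic cohort

The generator emulates the study design: a single stimulus-locked group
state path per run sampled from a sticky chain (self-transition 0.9,
uniform otherwise, uniform start); states defined by activation of 1–3
disjoint network blocks (amplitude 1, zero elsewhere, so planted maps have
zero pairwise cosine); observations = state mean + white Gaussian noise
per parcel (SD 0.5). An optional spatially correlated noise mode exists but
is off by default: shared low-rank noise lets stability-based model
selection split states along the common noise directions, which defeats
K-recovery experiments (and, conversely, is a realistic caveat for real
data, where a 90%-variance PCA compresses far more than the ~84 of 100
dimensions retained on white-noise cohorts).

Subjects copy the group path but deviate independently per TR to a
uniformly drawn state. The deviation probability is modulated by a planted
per-subject coupling gain, eps_i = 0.1 * (1 - 0.8 * tanh(gain_i)), so that
subjects with higher gain track the stimulus (and hence the appetite
course) more faithfully — this is what makes estimated state expression
recoverable and correlated with the stored latent. The latent gain, not the
estimated expression, carries the planted mediation (a = b = 0.5, c' = 0 by
default) so that recovery tests can separate estimation error from
generative truth. The gain-BMI correlation targets 0.32 by construction;
BMI is drawn half from a healthy-weight (20.4 +/- 1.2) and half from an
overweight/obese (26.9 +/- 1.6) distribution, mirroring the two-group
design.

The latent appetite course is the state-to-weight map of the group path,
smoothed by a 5-TR moving average and rescaled to [0, 3]; raters add
Gaussian noise (SD 0.3) and threshold at the 50th/70th/85th percentiles of
the noiseless course into ordinal presses 1–3 — the percentiles guarantee
all three levels occur; rating sparsity (the no-press fraction, 50% here)
is a modelling choice, as no empirical value is available. Trajectory
type 1 adds +0.15 BMI/month; type 2 is flat for four months then declines
0.1/month; monthly measurement noise is 0.05 kg/m^2 — in the correlation
feature space the type templates must stay >= 3x the noise scale, and the
type-2 template's centred norm is only 0.19, which pins the noise default.
P(type 1) follows a logistic in the gain with slope 0.9, planting a
between-type gain difference of d ~ 0.8. One RNG stream is derived
deterministically per subject/rater from the cohort seed, so subsets
reproduce independently of cohort size; a fixed seed reproduces the cohort
bitwise.

What the generator does not emulate: temporal autocorrelation of BOLD
noise, scanner drift and physiological confounds, voxel-level structure,
inter-subject latency differences, and rating response latency. Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the stated generative assumptions, not robustness to every
property of real data.

## Problem sizes used by the test suite

Validation experiments are scaled to run on one CPU: the reference
recovery cohort is 20 subjects x two 500-TR runs x 100 parcels with
K_true = 6; K-selection recovery uses 8 replicate cohorts with 3 split-half
repeats and 2 EM restarts per fit; prediction experiments use 336-window
designs (the study's two-video window count) with bootstrap B = 500;
reliability calibration uses 200 replicate cohorts at 500 iterations;
mediation calibration uses 350 null runs at B = 2000 and 20 recovery runs
at B = 1000 (study-scale protocols — 5000/10,000 iterations — remain the
function defaults). The acceptance script reports the quantities each run
computes together with the problem size used.

## Known limitations

- EM can converge to local optima; restarts mitigate but do not eliminate
  this, and split-half stability inherits the resulting variance.
- The composite K-selection rule can prefer K_true + 1 on cohorts with
  isolated single-TR deviations (collector states) and generally leans on
  zRand's growth with K.
- Bootstrap importance Z-scores are stability rankings, not calibrated
  null tests, under stimulus-locked targets (see above).
- The split-half reliability p-value is conservative under independence.
- Windowed targets assume all subjects watched identical, synchronized
  stimuli; the pipeline has no drift correction.
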