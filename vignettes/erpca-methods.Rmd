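---
title: "Condition-wise temporal PCA of Go/NoGo ERPs: models and methods"
author: "erpca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-wise temporal PCA of Go/NoGo ERPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

In the equiprobable auditory Go/NoGo task, participants hear a random
series of two tones (75 targets and 75 non-targets per 150-tone block at a
fixed 1100 ms stimulus-onset asynchrony) and press a button to the target
tone only. Stimulus-locked EEG averages (event-related potentials, ERPs)
contain a sequence of overlapping components — N1 subcomponents (N1-1,
Processing Negativity), P2/N2, P3a, P3b, slow waves (SW1, SW2) and a late
positivity (LP) — whose amplitudes index distinct processing stages.

`erpca` implements a complete, testable version of the condition-wise
temporal-PCA approach to quantifying these components in a two-arm
(placebo/caffeine) crossover design:

1. preprocess each session to artifact-free average ERPs,
2. decompose each drug x stimulus cell with its own temporal PCA
   (covariance matrix, Kaiser normalization, unrestricted Varimax),
3. select and label components, match them across the drug arms with
   Tucker's congruence coefficient,
4. test topography and drug effects with planned single-df
   repeated-measures contrasts, with directional (one-sided) p-values for
   predicted amplifications,
5. and, since no public data exist for this paradigm, generate fully
   synthetic sessions with planted ground truth so that every stage can be
   validated by parameter recovery.

Decomposing each condition separately — four PCAs instead of one — avoids
misallocating condition-specific variance across conditions, which is the
methodological point of the pipeline.

# Preprocessing model

Preprocessing follows the classical ERP chain, each step a small exported
function (`regress_eog()`, `lowpass_zero_phase()`, `extract_epochs()`,
`baseline_correct()`, `reject_artifacts()`, `select_valid_trials()`,
`average_and_downsample()`):

* **Ocular correction** removes the least-squares contribution of the four
  EOG channels from every scalp channel, one fit per recording session
  (blocks pooled). The coefficients are estimated on first-differenced
  data: the EEG background is strongly autocorrelated, and differencing
  whitens it, which sharpens the propagation estimates several-fold
  without changing the model (the contamination is linear in the EOG
  either way). The correction itself is applied to the raw data. An
  exactly zero EOG channel contributes nothing; a constant non-zero
  channel makes the fit singular and is rejected.
* **Low-pass filtering** is a 4th-order Butterworth (24 dB/octave design
  slope) applied forward-backward for zero phase lag, with odd-symmetric
  edge padding so constants pass unchanged. The quoted slope is the
  one-pass design slope; the forward-backward magnitude response is its
  square.
* **Epochs** span -100..750 ms around stimulus onset on a left-closed
  sample grid: at 512 Hz this is 436 samples (-99.6..750.0 ms), so that
  half-sampling the averages (every second sample, no anti-alias
  refilter — the data are already low-passed far below the new Nyquist)
  yields exactly 218 variables. With 26 participants, 2 blocks and 19
  channels the PCA input is then 988 cases x 218 variables (ratio 4.53).
* **Baseline** is the mean over all prestimulus samples, per epoch and
  channel.
* **Artifact rejection** flags epochs in which any *scalp* channel exceeds
  +/-75 uV at any sample; EOG channels are exempt.
* **Behavioral selection** excludes NoGo trials with a response
  (commissions), Go trials without one (omissions), and Go trials whose
  reaction time falls outside the individual mean +/- 1.5 SD. The RT mean
  and SD are computed per subject and session with both blocks pooled
  (the block split is not part of the rule); a degenerate SD of 0 excludes
  nothing. Fast-RT and delayed-RT *errors* in the behavioral battery are
  defined as RTs below and above those same bounds. Artifact and
  behavioral flags are independent columns, so the two rejections commute.

# The temporal PCA estimator

`erp_pca()` is the package's central fitting function and returns a
classed object with `print`, `summary`, `coef`, `fitted`, `residuals`,
`predict`, `plot` and `screeplot` methods.

Let \(X\) be the case matrix (cases = subject x block x channel, columns =
218 time points, uV). With column means \(m\) and \(X_c = X - 1m'\), the
estimator eigendecomposes the time-by-time covariance
\(S = X_c'X_c/(n-1) = V \Lambda V'\) and scales

\[ L = V\Lambda^{1/2} \quad (\text{uV-scaled loadings}), \qquad
   U = X_c V \Lambda^{-1/2} \quad (\text{standardized scores}), \]

so that \(X_c = U L'\) exactly when all factors are kept. Factors with
eigenvalues below \(10^{-10}\) of the largest are dropped (the epsilon
guard for rank-deficient or zero-variance input). All remaining factors —
"unrestricted" rotation — enter a Varimax rotation with Kaiser
normalization: loadings are row-normalized by their communalities,
rotated, and restored. The rotation maximizes the variance of squared
normalized loadings; the implementation tracks the criterion across
iterations (it is non-decreasing, and the best iterate is returned with a
warning if the iteration cap is hit) and runs from two deterministic
starts — the identity and one fixed rotation — because the SVD-based
ascent can stall on the symmetric saddle of an exactly balanced mixing.
`stats::varimax` is used in the test suite as an independent cross-check,
never as the implementation.

After rotation, factors are re-ordered by decreasing rotated variance
(sum of squared loadings over the covariance trace) and sign-flipped so
each factor's peak loading is positive; polarity is carried by the scores.
Peak latency is the time of the largest absolute loading.

**Selection** takes every factor at or above a 2% variance floor, in
decreasing order. For the caffeine decomposition, a component whose label
matches one selected in the placebo decomposition is additionally taken
if its variance exceeds 1%. Both floors are parameters; the defaults
mirror their conventional use as deliberately arbitrary limits that keep
the component count orderly.

**Labelling** assigns each candidate factor the schema label whose latency
window contains the factor's peak and whose planted topography is most
congruent with the factor's grand-mean amplitude map; labels are assigned
greedily, each at most once, ties broken by variance, leftovers labelled
"unknown". The default windows (N1-1 70-130, PN 130-260, P2/N2b 160-280,
P3a 250-400, P3b 280-450, SW1 350-600, SW2 450-750, LP 500-750 ms) are
configurable. Because factor scores are centered over cases, a factor's
grand-mean map always sums to zero across channels; template topographies
are therefore channel-mean-centered before the congruence is computed.

**Component amplitude** at a channel is the factor score of that
channel's case times the loading at the factor's peak latency, averaged
over blocks — the "peak amplitude" convention (the alternative, a signed
maximum over time, is not used). **Reconstitution** sums the selected
components back into per-site grand-mean waveforms and correlates them
with the raw grand means; with every factor selected the correlation is
1 by construction, and an empty selection returns the column-mean
waveform.

# Matching and planned contrasts

Components are matched across drug arms by label. For each pair the
package reports Tucker's congruence coefficient
\(r_c = \sum a_ib_i / \sqrt{\sum a_i^2 \sum b_i^2}\) of the temporal
loadings **and** of the grand-mean topographies, plus the topographic
Pearson correlation with df = 17 for 19 sites. The similarity class uses
the *smaller* of the two congruences — conservative, with both reported:
\(r_c \ge 0.95\) equality, \(0.85 \le r_c < 0.95\) similarity, otherwise
unmatched (the printed convention leaves a gap between 0.94 and 0.95;
values there fall in "similarity"). Unmatched pairs are excluded from the
drug statistics.

Amplitudes of matched components are analyzed on a 3 x 3 grid (frontal/
central/parietal x left/midline/right; F3..P4). For the temporally
focused PN the hemispheric pairs are replaced by the outer rows F7/8,
T7/8, P7/8. The planned single-df contrasts are F>P, C>F/P, L>R, M>L/R,
their four products (cell coefficients are the elementwise products of
the main-effect maps), and with drug: the Drug main effect and Drug x
each topographic term. Each contrast reduces to per-subject scores (the
coefficient-weighted cell sums, on caffeine-minus-placebo maps for drug
terms); the repeated-measures F is the squared one-sample t on those
scores, df = (1, n-1), with partial eta-squared \(F/(F+df_e)\). This
equivalence is enforced against a brute-force linear-model oracle in the
tests.

The two-step logic: step 1 establishes each component's *defining
topography* as the significant placebo-condition contrasts; step 2 tests
drug terms, halving the p-value (one-sided) only for observed increases
in the global effect or in interactions with the defining topography —
the predicted direction is the sign of the corresponding placebo
estimate (for the Drug main, the sign of the placebo grand mean, so an
increase in a negativity is a more negative difference). Unpredicted
decreases and non-defining terms keep two-sided p-values, and no
multiplicity correction is applied (all contrasts are planned and do not
exceed the effect's degrees of freedom). The applied rule is logged per
contrast.

The behavioral battery is six paired one-tailed t-tests (df = n-1) on Go
omission %, fast-RT %, delayed-RT %, NoGo commission %, mean Go RT and RT
variability, directional for the expected caffeine-related reduction.

# The synthetic session generator

`simulate_session()` builds continuous 23-channel recordings per block:

* **Planted components.** Each template is a Gaussian temporal bump
  (half-sine optional) times a spatial weight map (Gaussian foci on the
  schematic 10-20 layout, |w| <= 1) times condition, drug and subject
  factors. The default library follows the processing schema: shared
  N1-1 (-12 uV, 100 ms) and PN (-8 uV, 190 ms, temporal focus), NoGo-only
  P2/N2b (composite map: central positive/frontal negative), NoGo-dominant
  P3a (10 uV, 310 ms, Go multiplier 0.75), Go-only P3b (15 uV, 400 ms,
  left-parietal), NoGo-only SW1 and LP, and a frontal-negative/
  parietal-positive SW2 in both conditions. Amplitudes sit in the upper
  realistic range for adult auditory ERPs; with the default noise this
  puts ~80% of dataset variance into the leading components and
  reconstitution correlations in 0.97-1.00, consistent with a
  well-behaved recording. All drug multipliers default to 1: no planted
  effect.
* **Amplitude variability.** Amplitudes factor as
  \(f_s \cdot g_{s,j} \cdot h_{s,j,b}\): a shared subject factor
  (log-normal, sdlog 0.3), a per-subject *per-component* factor (sdlog
  0.6) constant across the crossover arms, and a per-block state factor
  (sdlog 0.25). The component-specific terms are essential, not
  cosmetic: with a single shared factor the planted components' case
  amplitudes are nearly collinear, and the Varimax criterion *provably
  prefers* a merged solution (we measured a higher criterion for the
  merged rotation than for the oracle-aligned one), which no rotation
  algorithm could undo. Semi-independent individual differences in
  component expression are also what real ERP data show.
* **Noise.** AR(1) in time (coefficient 0.9 at 512 Hz) with spatially
  correlated channel mixing (exponential correlation over the layout),
  marginal sd 17 uV per single trial. This makes the +/-75 uV rule reject
  roughly 2% of trials, so that together with the behavioral exclusions
  the accepted-trial counts land near the familiar ~70-of-75 regime, with
  more NoGo than Go trials retained.
* **Ocular model.** A Poisson blink source (0.1/s, 150 uV) and
  independent ocular activity (25 uV) plus sensor noise drive the four
  EOG channels; scalp contamination is constructed as beta %*% EOG with
  frontally weighted coefficients. Because the contamination is exactly
  linear in the *recorded* EOG and the EOG channels are not collinear,
  the planted propagation matrix is identifiable and regression recovers
  it within a few percent — a designed-in ground truth for the
  correction step.
* **Behavior.** Ex-Gaussian RTs (mu 255, sigma 35, tau 60 ms: mean
  315 ms, SD ~69 ms, delayed-RT errors outnumbering fast-RT errors as
  observed in this task), omission rate 2.1%, commission rate 1.4%.
* **Determinism.** Every stochastic element draws from a sub-stream
  derived from one master seed; identical configurations reproduce
  sessions bit-identically.

Ground truth (templates, all amplitude factors, EOG propagation,
noiseless per-condition epochs) is stored with every session, so recovery
tests never re-derive it.

What the generator does *not* emulate: biophysical head volume
conduction (maps are schematic foci, not dipole projections),
non-stationary or non-Gaussian EEG (alpha bursts, drowsiness), latency
jitter of components across trials and subjects, and any pharmacokinetic
time course. Passing recovery tests therefore shows the estimator is
correct under a realistic amplitude/noise model — not that real EEG meets
that model.

# Calibration, problem sizes and known limitations

* **Recovery suite.** Parameter recovery is assessed on the placebo Go
  decomposition (5 planted components) at the full design size (n = 24,
  150-tone blocks) over a fixed set of three seeds, reporting each
  component's mean temporal and topographic congruence across seeds.
  Single-seed temporal congruences range ~0.93-0.98; the mean per
  component clears 0.95 and topographies clear 0.90 at every seed. The
  residual, seed-dependent shortfall from 1 is not estimator error: it is
  the share of genuinely correlated amplitude variance that an orthogonal
  simple-structure rotation must allocate somewhere. Kaiser
  normalization is kept on throughout because the method specifies it,
  although unnormalized rotation recovers slightly better on some draws.
* **Statistical calibration** uses the generator's amplitude-level mode
  (`simulate_component_amplitudes()`): planted topography x subject
  factors x drug multiplier plus Gaussian measurement noise whose sd is
  derived from the single-trial noise and the expected accepted-trial
  count (`measurement_noise_sd()`), about 1.7 uV per site. This mode
  exists so the type-I calibration can run 2000 replicates and the power
  estimate 200 replicates in seconds; under the null the one-sided
  global rejection rate is exactly alpha by construction, and a planted
  30% P3b amplification at n = 24 is detected with power near 1.
* **End-to-end sensitivity.** A single full-pipeline study with the same
  planted 30% effect yields a noisier paired difference than the
  amplitude-level model predicts: the placebo and caffeine amplitudes
  come from two *separate* rotations, and the small, arm-specific
  admixtures of neighboring components (multiplied by the large
  between-subject component variability) add to the per-subject
  difference. This is the within-pair analogue of the variance
  misallocation that motivates condition-wise PCA, and it means a single
  simulated study detects the 30% effect less reliably than the
  amplitude-level calibration suggests. The end-to-end check in the test
  suite therefore verifies that the pipeline's estimated drug effect has
  the planted sign and magnitude, while the formal power criterion is
  evaluated at the amplitude level.
* **Problem sizes.** The default full study (24 subjects x 2 drugs x 2
  blocks x 150 tones at 512 Hz) simulates, preprocesses and decomposes in
  about two minutes; the test suite reuses one such run across its
  checks and keeps dedicated simulations small.
* **Numerical choices.** Covariance uses the n-1 denominator; centering
  is by case-matrix column means. Rotation convergence: relative
  tolerance 1e-7, 1000 iterations max. Degenerate inputs (zero-variance
  columns, rank-deficient cases) are handled by the eigenvalue guard.
  The contrast engine treats scores that vanish at machine precision as
  exact zeros so that flat maps yield F = 0 regardless of BLAS rounding.
  The heuristic loading-weighting variant of the rotation used by some
  ERP-PCA toolboxes is not reproduced exactly (its reference
  implementation is external); plain Kaiser-normalized Varimax on
  covariance loadings is the default, with `kaiser = FALSE` exposed.
* **Scope.** EDF+ ingestion is not provided; the long-format epoch table
  (CSV) is the canonical interchange, with `read_epoch_table()` /
  `write_epoch_table()` providing a lossless round trip with unit and
  schema guards. Oblique rotations, spatial/spatiotemporal PCA and
  parallel-analysis retention are out of scope by design.

# Reproducing a full analysis

```{r, eval = FALSE}
library(erpca)
cfg <- simulate_config(seed = 101) # 24 subjects, 2 x 150-tone blocks
res <- run_pipeline(cfg)           # simulate -> preprocess -> 4 PCAs ->
print(res)                         # match -> contrasts -> behavior
res$matches$go                     # congruence table, Fig. 4-style
res$contrasts[["go P3b"]]$drug     # drug contrasts with sidedness trace
write_results(res, "results/")     # CSV/JSON bundle, re-runnable
```
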