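---
title: "Methods: prefrontal fNIRS connectivity features and four-class classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prefrontal fNIRS connectivity features and four-class classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stroopfc)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
haemodynamics optically: near-infrared light at two wavelengths (here 750
and 850 nm) is injected into the scalp and the attenuation at detectors
2.5 cm away reflects changes in oxy- (HBO) and deoxy-haemoglobin (HBR)
concentration in the underlying tissue. `stroopfc` implements a complete
pipeline that turns such prefrontal recordings, acquired while subjects
perform a colour-word Stroop task, into a small set of physiologically
interpretable features and uses them to classify each subject into one of
four states: healthy control (HC), migraine without aura (MIG), obsessive
compulsive disorder (OCD), or schizophrenia (SCZ).

The task protocol the package assumes (and that its simulator emulates) is
a block design: a 30 s baseline, then 15 stimulus blocks — 5 each of
neutral (N), congruent (C), and incongruent (IC) Stroop stimuli in
randomized order. Each block holds 6 trials (2.5 s stimulus + 4 s blank =
6.5 s), so blocks span 39 s, and a 20 s rest follows every block:
30 + 15×39 + 15×20 = 915 s in total, 90 trials. Recordings cover 16
equidistant channels sampled at 1.77 Hz.

## Signal conditioning

**Channel screening.** Channels whose raw intensity coefficient of
variability, `CV = 100·sd/mean` (population standard deviation, full
recording), exceeds 7.5 % at either wavelength are dropped. The threshold,
the window, and the both-wavelengths rule are configurable
(`cv_threshold_pct`); the default is the strict interpretation (a channel
must pass at both wavelengths, using the whole recording).

**Optical density and the modified Beer–Lambert law.** Intensities are
referenced to the 30 s pre-task baseline:
`OD(t) = −log10(I(t)/Ī_base)`. Per channel and time point the 2×2 linear
system `OD(λ) = (ε_HBO(λ)·ΔHBO + ε_HBR(λ)·ΔHBR)·d·DPF` is solved for the
concentration changes, with source–detector distance `d = 2.5` cm and
differential pathlength factor `DPF = 6` at both wavelengths. The
extinction coefficients are stored explicitly in `DEFAULT_EXTINCTION`
(a standard published compilation evaluated at 750/850 nm, in
µM⁻¹·cm⁻¹) rather than taken from any library default, so results are
reproducible against the configuration alone; any invertible matrix is
internally consistent with the forward model.

**High-pass filtering.** HBO series are high-pass filtered at 0.009 Hz
with an 8th-order Butterworth filter, applied forward and backward (zero
phase — connectivity analysis must not be distorted in phase; the
zero-phase pass squares the magnitude response, `|H(f)|² =
1/(1+(fc/f)^16)`). Numerically, a single 8th-order transfer function at
`fc/fs ≈ 0.005` is ill-conditioned in double precision (its stop-band
floor sits near 1e−4), so the filter is realised as a cascade of four
second-order sections derived from the analytic Butterworth poles via the
bilinear transform with frequency prewarping. Each series is demeaned and
extended by odd reflection (about three filter time constants) before
filtering so edge transients stay out of the record. With this
implementation the measured stop-band at 0.002 Hz is below 1e−4 and the
pass-band at 0.1 Hz within 1 % of unity, matching the analytic response.

**Motion artifacts.** The original screening of motion-contaminated
trials was visual. The package provides an automated surrogate
(`amplitude_threshold`): a trial is flagged when any retained channel
deviates from its median by more than `artifact_scale_multiplier` (default
10) times its robust scale (MAD) inside a window from 5 s before trial
onset to 5 s after stimulus offset. `manual_flags` passes pre-existing
flags through. Because adjacent trials sit 6.5 s apart, these ±5 s windows
overlap: one spike can legitimately flag several trials. Artifact
exclusion (dropping whole blocks from connectivity and flagged trials from
behaviour) is off by default and controlled by one switch
(`exclude_artifact_blocks`).

## Partial-correlation connectivity

HBO signals mix neuronal and systemic (cardiac, respiratory, blood
pressure, vascular tone) haemodynamics; shared systemic components inflate
channel-pair correlations. The filtered HBO series of all retained
channels are therefore averaged into a single global regressor, and each
pair's Pearson correlation is replaced by the first-order partial
correlation given that regressor:

r_xy|z = (r_xy − r_xz·r_yz) / √((1−r_xz²)(1−r_yz²)).

Correlations are computed over task samples only: each block's samples
(half-open window `[floor(onset·fs), floor((onset+duration)·fs))`, a
convention fixed to avoid ±1-sample drift) are concatenated in block
order, and the global regressor is truncated and concatenated with exactly
the same index set. The result is a 16×16 symmetric matrix with unit
diagonal; rejected channels leave `NA` rows/columns in the container and
all downstream algebra operates on the retained submatrix.

One property worth knowing: partialling out the *mean* of N channels
induces an exact −1/(N−1) background correlation among otherwise
independent channels (≈ −0.067 at N = 16). This is a property of
global-signal regression itself, not an implementation artifact; the test
suite checks off-diagonals of independent-noise inputs against this value
rather than against zero.

## Network decomposition and features

The connectivity matrix is eigendecomposed and split into a
cognitive-mode (CM) and a default-mode (DM) component. "Component
weights" are interpreted as the eigenvalues of the symmetric FC matrix.
Three documented threshold strategies are provided, because the original
optimization procedure is published elsewhere and not reproducible from
the description alone:

* `mean_eigenvalue` (default): θ = the spectrum mean. For a correlation
  matrix the mean eigenvalue is exactly 1, so components carrying more
  than one channel's share of variance land above the threshold.
* `fixed_count_k`: exactly k components above θ.
* `elbow_max_gap`: θ at the midpoint of the largest spectral gap.

Components with eigenvalue above θ form the CM matrix (the task-dominant
side during a Stroop block design; a config switch `cm_is_above_threshold`
can invert the assignment, which the description leaves open), the rest
the DM matrix; by the spectral theorem the two sum exactly back to the
input, which the tests assert to 1e−10 for every strategy. Eigenvector
signs are fixed deterministically (largest-magnitude entry positive) so
decompositions are identical across runs and platforms; note the component
matrices λ·v·vᵀ are sign-invariant in any case. Whether θ should be chosen
per subject or globally is likewise open; the package computes it per
subject, which keeps subjects independent and is the only choice available
when subjects are processed incrementally.

Each component matrix becomes a weighted graph: diagonal zeroed, negative
entries mapped by absolute value (default; `clamp_zero` drops
anti-correlated edges instead — both policies exposed since the source
description is silent). The feature is Latora–Marchiori weighted global
efficiency,

E = 1/(N(N−1)) · Σ_{i≠j} 1/d_ij,

with `d_ij` the weighted shortest-path length under edge length = 1/weight
(the standard weighted convention; `one_minus_w` is available and requires
weights < 1). Zero-weight edges are absent and unreachable pairs
contribute 0. No ideal-graph normalisation is applied — the classifiers
only need consistent relative values. Shortest paths are computed by a
vectorised Floyd–Warshall; the suite checks 1000 random graphs against an
independent igraph shortest-path oracle to 1e−12. `GE_cm` and `GE_dm` are
the efficiencies of the two component graphs. Whether the original
analysis used weighted or binarised graphs is not stated; weighted is the
default here.

The behavioural feature is the cognitive quotient,
`CQ = (100·n_correct/n_trials) / mean(RT)` over all trials, in percent
per second — higher for subjects who answer both accurately and fast.
Per-condition reaction time and error rate summaries are reported
descriptively but never fed to the classifiers.

## Classifiers

Three supervised algorithms sit behind one `fit_classifier()` /
`predict()` surface, with per-training-fold z-scoring on by default (the
three features differ by orders of magnitude: GE ∈ [0, 1], CQ in tens):

* **Gaussian naive Bayes** — per-class, per-feature Gaussian likelihoods
  with a variance floor of 1e−9·(feature range)², ties broken towards the
  first class level.
* **LDA** — the classic pooled-covariance (Fisher/Bayes) discriminant,
  with ridge 1e−8·mean(diag Σ) so degenerate folds (singleton classes)
  fit with a warning instead of failing.
* **SVM** — soft-margin C-classification (C = 10) with the Pearson VII
  universal (PUK) kernel
  `K(x,y) = 1/(1 + (2·‖x−y‖·√(2^{1/ω}−1)/σ)²)^ω`, ω = σ = 1, trained by
  sequential minimal optimization on a precomputed Gram matrix
  (maximal-violating-pair working sets, KKT-gap stopping rule, dual
  tolerance 1e−8, deterministic tie-breaking). Multiclass is one-vs-one
  with pairwise voting; voting ties break by largest aggregate decision
  value, then class order. The exact PUK distance scaling differs between
  software traditions by a constant; the formula above is this package's
  definition. The dual solutions are cross-checked against an
  interior-point QP solver in the tests.

## Evaluation

`cross_validate()` runs 10 repetitions of stratified 10-fold
cross-validation. Folds balance class counts to within ±1 *and* fold
totals exactly (remainder subjects go to the least-loaded folds), are
deterministic given the seed, and run r uses `base_seed + r`, recorded in
the report. Per run, fold predictions are pooled into one confusion
matrix from which five metrics are computed: accuracy and one-vs-rest
precision, recall, specificity, and F1, aggregated as the support-weighted
mean over the four classes (macro averaging available via config; the
averaging rule for a 4-class scalar metric had to be fixed somewhere, and
support weighting keeps the algebraic identity accuracy = weighted
recall, which the tests assert). Metrics are reported as mean ± SD over
the 10 runs, and confusion counts pooled over all runs.

Condition comparisons are two-tailed t-tests on the 10 run-level metric
values: Welch two-sample tests between algorithms (pooled-variance
optional), paired tests between feature sets of the same algorithm.
Degenerate inputs use the convention t = 0, p = 1 for equal constant
samples and p = 0 otherwise. Because run-level values from one data set
share that data set, such t-tests are only calibrated for comparisons
*within* the same data: `comparison_null_pvalues()` therefore checks
calibration by cross-validating the same label-permuted data twice with
independent fold seeds — the two conditions then differ only by fold
randomness and the p-values must be uniform. Comparing runs from two
*different* permutations or cohorts would mix between-data-set variance
into a within-run test and concentrate p near zero; that is a property of
run-level CV t-tests generally, worth keeping in mind when reading such
comparisons anywhere.

No nested hyperparameter search is performed: C, ω, σ are fixed study
constants, and a grid search on the full evaluation set would leak.

## The synthetic cohort generator

No public recording repository exists for this protocol, so the package
ships a generator whose defaults *are* the study conditions: cohort sizes
13/20/26/21 (HC/MIG/OCD/SCZ), the full 915 s timeline, and a signal model
mirroring the assumptions behind the analysis:

HBO_i(t) = a_i·f_cm(t) + b_i·f_dm(t) + task(t) + systemic(t) + ε_i(t)

* `f_cm`, `f_dm` — latent AR(1) factors (φ = 0.9, unit variance).
  Channels 1–8 load on the cognitive-mode factor, 9–16 on the
  default-mode factor, with alternating signs so the factors cancel from
  the channel mean: otherwise global-signal regression would remove the
  very structure being designed in. Class effects enter through the
  loading scale: cm coupling 0.90/0.82/0.55/0.35 for HC/MIG/OCD/SCZ, dm
  coupling 0.60 for every class (so GE_cm carries the class signal and
  GE_dm stays uninformative), with a 6 % log-normal between-subject
  jitter. HC and MIG are deliberately the closest pair — interictal
  migraineurs resemble controls — so classification errors should
  concentrate there.
* `task` — condition boxcars convolved with a canonical double-gamma HRF
  (peak ≈ 6 s, undershoot ≈ 16 s), amplitude 0.2 µM scaled per class
  (1.0/0.9/0.7/0.5) with alternating channel signs. The original analysis
  is connectivity-based and uses no explicit HRF; it exists here purely
  to give the task blocks realistic structure.
* `systemic` — Mayer-wave (0.3 µM, 0.1 Hz) and respiratory (0.2 µM,
  0.3 Hz) sinusoids with random phases plus a slow drift (0.5 µM, below
  the filter cutoff), shared across channels with ±20 % gain spread.
* `ε` — white noise, SD 0.5 µM. HBR = −0.3·HBO + noise, consistent with
  analysing HBO only while keeping the Beer–Lambert chain exercised.

Behaviour is drawn per class and condition: correctness Bernoulli
(e.g. HC 0.97/0.96/0.90 for N/C/IC vs SCZ 0.78/0.75/0.62), reaction times
log-normal (HC ≈ 0.85–1.15 s vs SCZ ≈ 2.1–2.8 s medians, within-subject
sdlog 0.15) truncated at the 6.5 s response window, with between-subject
jitter on both. These produce CQ distributions whose class means are
separated by at least about three within-class SDs, with HC–MIG the
narrowest gap by design. Optionally the generator runs the haemoglobin series through the
*forward* Beer–Lambert model to emit raw dual-wavelength intensities, and
can plant channels with excess intensity variability (CV ≈ 10 %, caught
by the 7.5 % screen) and motion spikes (25 µM, ≈ 20× the robust scale)
inside chosen trials; planted defects are recorded in attributes so tests
can assert that screening finds exactly them.

Every subject derives all of its random draws from one seed, split
deterministically by purpose (timeline, signals, behaviour, planted
defects), so adding a new noise source never perturbs existing draws and
`(config, seed)` determines every output bit. A `class_effects = "null"`
switch gives all classes one shared parameter set for calibration
studies.

**What the generator does not emulate:** photon transport and optics
(intensities come from the inverse of the same Beer–Lambert model the
pipeline inverts, so that conversion is exercised, not validated against
physics); realistic motion artifact waveforms (spikes only);
non-stationary vigilance or learning effects across the session;
spatially structured noise between neighbouring channels. Passing tests
on synthetic cohorts therefore demonstrate that the pipeline recovers the
structure this model plants — not that the features separate real
patient groups.

## Problem sizes and numerical conventions

The test suite runs the full chain on cohorts of 80 subjects (the default
class mix) for the null-calibration and effect-recovery checks, 100
label-permutation replicates at reduced CV scale (10 runs × 5 folds,
naive Bayes) for t-test calibration, 1000 random graphs (≤ 10 nodes) and
1000 random triples for the efficiency and partial-correlation oracles,
and 12–16-subject cohorts elsewhere; these sizes keep the designed
effects detectable while the whole suite stays quick. Chance level for
the null cohort is taken as the majority-class rate (26/80 = 32.5 %) with
a 99 % binomial band. Other conventions: symmetry tolerance 1e−8 before
eigendecomposition; correlations clamped to [−1, 1] after floating-point
arithmetic; partial correlations with |r| = 1 against the regressor raise
an error naming the channels; empty blocks or cohorts are errors, never
silently empty results.

## Known limitations

* The CM/DM threshold optimization of the original companion work is not
  reproduced; the three strategies above are documented replacements.
* SNIRF ingestion is not implemented; recordings enter via the native
  text bundle (`write_recording()`/`read_recording()`) with SNIRF
  reserved as a format name.
* HBR-based features are intentionally out of scope (the analysis uses
  HBO only); HBR is carried through the data model for completeness.
* The t-test comparisons inherit the usual caveats of run-level CV
  statistics described above.
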