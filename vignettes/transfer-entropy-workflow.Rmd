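---
title: "Estimating directed information flow with teflow: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating directed information flow with teflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(teflow)
```

`teflow` detects directed interactions between pairs of analog,
trial-based signals with transfer entropy (TE). This vignette is the
package's methodological account: the estimator and its assumptions,
what every tunable parameter does and why its default is what it is,
what the built-in simulators emulate (and do not), the numerical and
design choices made where the method leaves them open, and the known
limitations.

## 1. The model and its assumptions

Treating the two observed series X and Y as (approximately) Markov
processes, Y's transition probabilities should not depend on X's past
if there is no directed interaction X→Y. TE measures the departure
from that condition as a Kullback–Leibler divergence, equivalently a
conditional mutual information between X's past state and Y's future,
given Y's past state. Because interactions in real systems act with a
delay, the predicted sample sits a *prediction time* `u` ahead of the
conditioning states: `TE(X→Y) = I(y_{t+u} ; x_t^d | y_t^d)`. `u` is an
estimator parameter, not an embedding parameter; sensitivity is
maximal when `u` matches the true interaction delay, so applications
with unknown delays should scan `u` on pilot data.

Assumptions worth stating explicitly:

* **State reconstruction is adequate.** Scalar series are mapped to
  delay vectors `x_t^d = (x(t), x(t−τ), …, x(t−(d−1)τ))`. Too small a
  `d` leaves the state ambiguous (false neighbours, spurious TE); too
  large a `d` makes neighbourhoods sparse and estimates noisy. Both
  channels of a pair use one common `(d, τ)` so that their TE values
  are commensurable.
* **Distributions are non-singular.** TE is undefined for
  deterministic one-to-one mappings; constant inputs are rejected with
  an error, and time points whose joint k-th-neighbour distance is
  exactly zero (duplicated states) are dropped from the average with a
  count kept.
* **Trials are exchangeable realizations.** Surrogate construction and
  the permutation tests rest on trials being independent draws of the
  same process.
* **Absolute TE values are not interpreted.** Nearest-neighbour
  entropy estimators carry a finite-sample bias — estimates may be
  negative and are returned unclipped — so inference is exclusively
  via the surrogate/permutation machinery.

## 2. The estimator

The Kraskov–Stögbauer–Grassberger (KSG) construction fixes a neighbour
mass `k` only in the highest-dimensional space. For each time point
the distance to its k-th nearest neighbour in the joint space
`(y_{t+u}, y_t^d, x_t^d)` becomes the radius for strict (`<`) counts
in the three marginal spaces, and

`TE = ψ(k) + ⟨ψ(n_y + 1) − ψ(n_{y⁺y} + 1) − ψ(n_{yx} + 1)⟩_t`

in nats. Errors of the four implicit entropy terms largely cancel
because all counts live on the same spatial scale. Mutual information
uses the same fixed-mass construction on the simultaneous sample pairs
`(a_t, b_t)` — the companion MI reported with every TE run — with
`MI = ψ(k) + ⟨ψ(N_t)⟩ − ⟨ψ(n_a + 1) + ψ(n_b + 1)⟩`, `N_t` counting the
admissible neighbours of point t. For Gaussian data TE is equivalent
to the Granger variance-ratio form `½·log(σ²_restricted/σ²_full)`; the
test suite verifies both estimators against their Gaussian closed
forms and against independent O(n²) brute-force implementations
(agreement to 1e-12).

Numerical choices:

* **Maximum norm everywhere.** The standard choice for KSG (counts and
  radii then refer to the same geometry in every subspace); it is also
  used inside the Cao and Ragwitz criteria for consistency. The
  neighbour search is a compiled KD-tree with early-abandoning
  distance evaluation, degrading to a plain scan below 64 points.
* **Theiler correction.** Neighbours closer in time than a Theiler
  window are excluded (the point itself included), preventing serial
  correlation from masquerading as recurrence. Default window: the
  channel's autocorrelation decay time (ACT). Points never cross trial
  boundaries, since TE is estimated per trial.
* **ACT definition.** First lag at which the biased-normalised
  autocorrelation falls below 1/e. A series whose autocorrelation does
  not decay within `maxlag` gets a flagged "undefined" ACT rather than
  a silently capped one.

## 3. Choosing the embedding

Two data-driven criteria are implemented, selected by
`optimizemethod`:

* **Cao criterion** (`'cao'`, for deterministic-leaning dynamics).
  For each scanned dimension the mean ratio `a(t, d)` of the k-th
  neighbour's distance evaluated in d+1 versus d dimensions gives
  `E(d)`; the growth ratio `E1(d) = E(d+1)/E(d)` saturates once the
  attractor is unfolded, and the chosen dimension minimises the
  discrete second difference `E1(d−1) + E1(d+1) − 2·E1(d)` over the
  interior of the scanned range (the boundary dimensions cannot be
  selected — the second difference does not exist there). The k-th
  rather than single nearest neighbour is used (`caokth_neighbors`,
  default 4), trading a little locality for robustness. τ is supplied
  in ACT units (`tau`, default 1.5).
* **Ragwitz criterion** (`'ragwitz'`, default, for stochastic data).
  Scans a `(d, τ)` grid and minimises the mean squared error of the
  local constant predictor: each point's future is predicted by the
  mean future of its neighbourhood — either the `sizeNei` nearest
  neighbours (`flagNei = 'Mass'`) or all neighbours within radius
  `sizeNei` (`'Range'`, ties at the boundary included, `≤`). The error
  is evaluated on the `repPred` latest valid points, which are common
  to all grid cells, making cells directly comparable and the scan
  deterministic. Exact ties go to the smallest d, then the smallest τ.
  Delays are given as ACT multiples (`ragtaurange`, `ragtausteps ≥ 5`)
  and converted to samples by `round(multiple × ACT)`, floored at 1.

Honest caveats, verified against brute-force oracles in the test
suite: on weakly noisy low-dimensional signals the local-constant MSE
is nearly flat in d beyond the minimal embedding, so the Ragwitz
argmin can wander upward among near-equivalent dimensions; and Cao's
E1 saturates as a jump from near 0 to a high plateau rather than
converging exactly to 1. Neither affects the downstream statistics —
over-embedding costs variance, not validity — but users comparing
"the chosen d" across datasets should expect scatter. The Cao choice
also drifts with series length on stochastic AR data.

**Per-trial and per-pair reduction.** The criterion runs on
`opt_ntrials` trials per channel (default 5); the per-trial choices
are reduced to the modal dimension (ties towards the larger d — under-
embedding is the harmful direction), with the median companion τ. A
pair's spec takes the larger of its two channels' dimensions, with
that channel's τ, for the same reason. How the original trial-based
tooling reduces per-channel optima to a pair embedding is not
specified anywhere we could find; this rule is our choice.

## 4. Statistics: surrogates, permutation tests, corrections, shift test

**Surrogate data** destroy the cross-channel directed dependence while
preserving each trial's internal structure. Six types: trial shuffling
(channel trial n replaced by trial n+1, cyclically, so the last trial
receives the first and the trial count is conserved), trial reversal,
block resampling (cut at a uniform point c ∈ {1..N−1}, blocks
swapped), and three block-reversal variants (whole resampled trial
reversed / first block reversed in place / second block reversed in
place). Cut points are redrawn per trial, and the three reversal
variants consume the same draws as block resampling under the same
seed, so the family is comparable trial by trial. All block types
conserve each trial's sample multiset; the partner channel is left
bit-identical. In the analysis pipelines the **source** channel of the
direction under test is the manipulated one.

**Permutation testing.** The observed statistic (difference of means,
pooled-variance independent-samples t, or paired t — `permstatstype`)
is compared with its relabelling distribution. When the number of
distinct relabellings is at most `numpermutation` the distribution is
enumerated exhaustively and the p-value is the exact tail fraction;
otherwise `numpermutation` Monte-Carlo draws are used with the
`(1 + b)/(1 + numpermutation)` convention, so the smallest attainable
p is `1/(numpermutation + 1)` — at the default 190 100 permutations,
5.26e-6. Corrections across the tested pair/direction family:
Benjamini–Hochberg step-up (`'FDR'`, the independence variant, via
`p.adjust`) or Bonferroni (`'BONF'`).

**Shift test.** Instantaneously shared signal (volume conduction, MEG
field spread, common line noise) inflates Wiener-type directionality
measures. The test computes, per trial, TE from the original source
and from a time-advanced copy `X'(t) = X(t+u)` (`shifttype
'predicttime'`; `'onesample'` shifts by one sample). A genuinely
delayed coupling loses its predictive samples under the shift;
shared instantaneous signal instead becomes *more* predictive. Both
TE values are computed on a common truncated trial length for
comparability. Two decision rules: `'TEshift > TE'` declares mixing
when the shifted source wins significantly (one-sided, alpha 0.1);
the conservative `'TE > TEshift'` (config default) demands positive
evidence of a real delayed interaction (one-sided, alpha 0.05) and
declares mixing otherwise. A directed pair flagged for mixing is
reported as "instantaneous mixing — no verdict" regardless of its
permutation p-value, so significance and mixing are never co-reported.
Note one asymmetry of the rules: on data with a genuine delayed
coupling analysed in the *reverse* direction at large u, shifting can
effectively re-align the coupling and raise TE, so occasional shift
positives there are expected and harmless — no interaction verdict
existed to veto. The package's own simulation benchmarks use
`'TEshift > TE'`, the rule whose null behaviour (false-positive rate ≈
alpha) matches the benchmark's published operating characteristics;
the conservative rule would instead veto ~95% of genuinely independent
pairs by design.

**Seeding.** One integer `rng_seed` deterministically derives a
sub-seed for every stochastic step (each surrogate draw, each
permutation test, each simulated trial) via an FNV-1a hash of a task
tag — end-to-end runs are bitwise reproducible, and group computations
are order-independent because each dataset's stream depends only on
its own tag.

## 5. Pipelines

* `prepare()` — validation, cropping to the time window, ACT table,
  trial selection (`'no'` / `'range'` / `'ACT'` with threshold
  `actthrvalue` and minimum count `minnrtrials`), embedding
  optimisation, conversion of `predicttime_u` (milliseconds) to
  samples by `round(ms × fsample/1000)`, floored at 1. Its
  configuration fingerprint (a hash of all preparation-relevant
  fields) travels with the result.
* `surrogate_analysis()` — per directed pair: trial-wise TE and MI,
  surrogate TE, shift test, permutation test, correction, verdicts.
* `compare_conditions()` — two prepared datasets of one unit of
  observation; both are recomputed under one shared embedding (the
  larger dimension of the two) so TE values are commensurable, then
  condition labels are permuted.
* `group_pipeline()` — refuses datasets with differing preparation
  fingerprints, derives one common embedding per pair across all
  datasets, summarises each dataset by its mean trial TE, and permutes
  condition labels across datasets (within units for `'depsamplesT'`,
  whose design must contain every unit exactly once per condition).
  Per-dataset computations share no state and merge by position, so
  they can run anywhere in any order.

Datasets travel as a plain-text JSON container (fields `trial`,
`time`, `label`, `fsample`; numbers serialized at 17 significant
digits, so a save/load round trip is bit-exact) or as a per-trial CSV
directory. We chose portable text formats over a binary container
deliberately: the files are diffable, language-neutral, and carry no
library dependency; writing MATLAB-style containers is out of scope.

## 6. The simulators

`simulate_ar_pair()` generates the validation benchmark: two stable
AR(10) processes (committed coefficient vector `ar10_alpha` — ten
seeded standard-normal draws rescaled to companion spectral radius
0.9 — with innovation scale 0.1), where Y additionally receives the
quadratic coupling `γ·X(t+1−δ)²`, δ = 21 samples. γ is calibrated so
the coupling contributes 50% of var(Y): Y is linear in its two inputs,
so the contribution scales as γ² and one 2×10⁵-sample pilot per input
gives γ in closed form (cached; the 50% ± 2% property is asserted in
the tests against an independent decomposition). Defaults are the
study conditions: 40 trials × 3000 samples, 1000 burn-in samples
discarded per trial, trials on independent derived streams, nominal
sampling rate 1000 Hz (1 sample = 1 ms).

`simulate_mixing_case()` covers the robustness scenarios: (A) two
independent unit-variance white-noise channels; (B) one source split
`(ε, 1−ε)` onto two sensors; (C) two independent sources symmetrically
mixed, `X_ε = (1−ε)X + εY + noise` and mirrored; (D) the coupled AR
pair under the same mixing; (E) the coupled pair plus a shared 50 Hz
sinusoid at 500 Hz sampling (the line amplitude, 25% of each signal's
standard deviation, and the sampling rate are our documented constants
— the benchmark leaves them open), optionally removed with a 4th-order
two-pass Butterworth band-stop at 49–51 Hz (`signal::butter` /
`filtfilt`). Sensor noise contributes 25% of each final signal's
variance (ε = 0 degenerates to pure unit-variance sensor noise).
`simulate_group_study()` builds the 15-subject × 2-condition scenario:
four AR(10) channels labelled F3, F4, T7, T8, condition 1 coupling
F3→T8 and condition 2 T7→F4, with the paired design matrix.

What the simulators deliberately do **not** emulate: 1/f spectra,
nonstationarity within trials, artifacts, multi-source volume
conduction with realistic head geometry, or any evoked structure.
Passing the benchmark suite therefore demonstrates estimator and
statistics correctness under controlled couplings — not performance on
any particular recording system.

## 7. Benchmark problem sizes

The acceptance script (`scripts/acceptance.R`) and the benchmark test
file re-derive the headline numbers at desk scale, sizes chosen once
as a compromise the effect sizes support: 10 datasets × 12 trials ×
1500 samples for the embedding scan, prediction-time scan and
detection runs (the coupling carries half of var(Y), so detection
saturates well below the full 40 × 3000); 20-trial datasets wherever a
statistic needs the permutation floor or heavy added noise (the
190 100-permutation mean-p and the 20–200%-noise robustness runs — at
many fewer trials the t statistic cannot exhaust the permutation
distribution, and with cyclic trial shuffling at very small trial
counts the surrogate group shares too many trials with the original
for the exchangeability assumption to be comfortable); full 3000-
sample trials for the mixing scenarios, whose weak-mixing shift-test
rate (ε = 0.05, "about half") is power-sensitive. Scans use 1000
Monte-Carlo permutations (floor 1e-3), ample for decisions at alpha
0.05/0.1.

Two benchmark outcomes deserve flagging. The AR(10) coefficient vector
is a committed reproducible stand-in (the benchmark's own αᵢ are not
published), and the Cao-criterion dimension is sensitive to it: on
these coefficients the modal choice is 3 at 3000-sample trials (4–5 at
shorter ones), not the reference 4 — the criterion itself is verified
independently by exact agreement with a brute-force implementation.
And because a d-dimensional source embedding at delay τ covers lags
0…(d−1)τ, the detection rate in the prediction-time scan saturates on
the whole set `{u : δ − u ∈ {0, τ, …, (d−1)τ}}`, so the scan reports
the median of a small tie set around δ rather than δ alone; the raw
TE maximum still sits at u = δ.

## 8. Limitations

* Bivariate only: no conditional/multivariate TE, so indirect paths
  and common drivers with unequal delays can still produce spurious
  pairwise verdicts.
* TE per trial needs enough samples to populate up to
  (2d+1)-dimensional neighbourhoods; very short trials make estimates
  noisy in ways the permutation test sees as lost power.
* The shift test vetoes; it does not *partial out* mixing. Under
  strong mixing with genuine coupling, the report is "mixing — no
  verdict", by construction.
* Exhaustive permutation enumeration engages only when feasible;
  otherwise Monte-Carlo p-values have resolution
  `1/(numpermutation+1)`.
* Reading MATLAB/FieldTrip binary containers is not supported; convert
  to the JSON or CSV container first.
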