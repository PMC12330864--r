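---
title: "Dynamics fluidity, microstates and resampling statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics fluidity, microstates and resampling statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfluidity)
```

This vignette is the package's own account of its methods: the models and
estimators, the parameters that matter and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
numerical conventions pinned where the underlying literature leaves a
choice open.

## 1. The trajectory view and the extremal index

A multichannel EEG recording, coarse-grained to the behavioral video rate,
is read as a trajectory $u_t \in \mathbb{R}^{C}$ of instantaneous
topographies ($C$ = channels). How long the system lingers near a
configuration is quantified through extreme-value statistics of the
observable

$$ g(t; u_0) = -\log \lVert u_t - u_0 \rVert_2 , $$

which is large exactly when the trajectory is close to the reference
$u_0$. Exceedances of a high threshold $s(q)$ (the empirical $q$-quantile
of $g$) mark returns into a small ball around $u_0$; their excesses follow
an exponential (Generalized Pareto) law with scale $\sigma$, and their
*temporal clustering* is governed by the extremal index
$\theta \in [0, 1]$:

- $\theta = 1$: exceedances arrive as a Poisson process — no clustering,
  the trajectory leaves the neighborhood immediately (fluid dynamics);
- $\theta = 0$: the reference behaves as a fixed point — once entered, the
  neighborhood is never left (complete persistence).

We call $\theta$, estimated per reference point, the **dynamics fluidity**
of the recording; it is known as inverse persistence in the dynamical
systems literature on climate series. One estimate per reference sample
yields a time series of fluidity values.

### 1.1 The Süveges estimator and its conventions

With exceedance times $L_1 < L_2 < \dots$, inter-exceedance gaps
$T_i = L_{i+1} - L_i$, $S_i = T_i - 1$, $p = 1 - q$, $N$ gaps and $N_c$
gaps with $S_i > 0$, the closed-form maximizer of the Süveges likelihood

$$ \ell(\theta) = (N - N_c)\log(1-\theta) + 2 N_c \log\theta
   - \theta\, p \sum_i S_i $$

is

$$ \hat\theta = \frac{p\Sigma S + N + N_c -
  \sqrt{(p\Sigma S + N + N_c)^2 - 8 N_c\, p\Sigma S}}{2\, p\Sigma S} . $$

`suveges_numeric_mle()` maximizes $\ell$ numerically and exists purely as
an independent cross-check; the test suite verifies agreement to $10^{-6}$
over random exceedance patterns.

Conventions pinned here, with the reasoning:

- **Gap convention.** Both $S_i = T_i - 1$ and $S_i = T_i$ circulate in
  the extreme-value literature. The default is $T_i - 1$ — the dominant
  convention in the climate-dynamics papers this methodology descends
  from — with `gap_convention = "T"` exposed as an option. Under the $T$
  convention every gap is positive ($N_c = N$) and the estimator
  degenerates to $\min(1, 2N/p\Sigma T)$, which saturates at 1 for
  unclustered data; the $T-1$ convention retains finite-sample
  sensitivity.
- **Degenerate inputs.** A single contiguous exceedance run gives
  $\Sigma S = 0$ and an indeterminate formula; we return exactly 0, the
  fixed-point limit it converges to. Fewer than two exceedances, or an
  observable shorter than 100 samples, return `NaN` with a recorded
  reason rather than a fabricated number.
- **Self-point exclusion.** $g$ is undefined at the reference itself
  (distance 0); that sample is excluded, as is any other sample at
  exactly zero distance (counted and warned — on continuous data this
  indicates duplicated frames).
- **Threshold quantile.** $q = 0.98$ by default. Higher $q$ reduces bias
  from sub-asymptotic thresholds but leaves fewer exceedances per
  reference; at the 25 Hz coarse rate and recordings of $10^4$–$10^5$
  samples, $q = 0.98$ leaves a few hundred exceedances, enough for a
  stable estimate.
- **Reference stride.** Per-sample estimation is $O(n^2)$. `ref_stride`
  subsamples the reference grid without changing any individual estimate;
  the default 1 keeps the fully resolved contract, and the package's own
  tests and acceptance runs use strides of 25–250 so that suites complete
  at desk scale. The stride sizes used in shipped tests (series of
  3,000–20,000 samples, 80–120 references each) are stated here as the
  package's chosen problem sizes.
- **Scale $\sigma$.** The mean excess over the threshold (the exponential
  GPD scale MLE) is computed and stored per reference because it proxies
  local dimension, but no downstream analysis consumes it.
- **Concatenated phases.** When task phases are concatenated, exceedance
  gaps spanning a phase boundary are kept by default (boundaries are
  recorded in `meta` so a censoring variant can be built); the effect is a
  handful of gaps among hundreds.

Two invariances follow from the construction and are enforced by tests:
global amplitude scaling shifts every $g$ by a constant, so the quantile
threshold shifts identically and $\hat\theta$ is unchanged; and channel
permutation leaves Euclidean distances untouched.

## 2. Microstates

### 2.1 Segmentation

Two extraction routes are implemented, both per animal and per recording
(no group templates, which would blur individual topographic
idiosyncrasies):

- `segment_kmeans()`: Lloyd iterations on all coarse-grained samples under
  the correlation distance $d(x, c) = 1 - r(x, c)$, best of 10 restarts by
  total within-cluster distance. The distance is **signed** by default: the
  polarity-invariance convention of human microstate work (folding $r$ and
  $-r$ together) is not assumed for rodent surface grids, but
  `ignore_polarity = TRUE` provides it.
- `segment_gfp()`: the human-EEG-style route — global field power (the
  across-channel variance per sample), peaks with topographic prominence
  $\ge$ 0.5, k-means on the peak topographies, then backfitting of every
  sample to the best-correlated centroid. The prominence threshold applies
  to the raw variance signal, whose units scale with squared amplitude;
  `zscore_gfp = TRUE` applies it on the z-scored GFP when recordings of
  different gain must be treated uniformly. No installed R routine
  computes topographic prominence, so the standard definition (height
  above the higher of the two minima separating the peak from higher
  terrain) is implemented in-package and tested against a brute-force
  local-maximum scan at prominence 0.
- Empty clusters during Lloyd iterations are re-seeded at the worst-fit
  samples rather than aborting the restart.

### 2.2 Sequence metrics

The **transition matrix** counts consecutive label pairs and row-normalizes,
so the diagonal holds stay probabilities; rows of states never departed
from are `NaN` and are excluded from summaries rather than silently zeroed.
**Microstates fluidity** is the reciprocal of the mean diagonal over
visited states: 1 for a frozen sequence, $\infty$ for strict alternation.
Self-transitions are included in the normalization — the diagonal *is* the
object of interest, so excluding them would make the metric vacuous.

**MDL complexity** compares two token-counted descriptions of the label
sequence. The original description lists each dictionary symbol and every
position where it occurs: $L_{orig} = |\Delta| + N_{words}$. The
compressed description lists, per symbol, its runs as (length, shift)
pairs, the shift giving the offset to that symbol's next run; the final
run of a symbol carries no shift token:
$L_{comp} = |\Delta| + \sum_{\text{symbols}} (2\,n_{runs} - 1)$. The
reported value is $100^{L_{comp}/L_{orig}}$; the base-100 exponential maps
the ratio onto a scale where cohort distributions are close to normal.
Counting *tokens* (not bits or digits) is the simplest consistent unit and
is pinned so that the hand-counted examples ("AAAA" $\to 100^{2/5}$, "A"
$\to 100$, alternation $\to > 100$) are exact test oracles. The metric is
invariant under state relabeling.

**Entropy by fluidity decile** ranks the fluidity series into ten
equal-occupancy bins (ties broken by position — quantile binning of tied
data is otherwise ill-defined) and reports the Shannon entropy (bits) of
microstate occupancy within each bin, using the four-state segmentation by
default; $\log_2 K$ means fluidity level carries no information about
which microstate is active.

**Cluster-count sweeps** (`sweep_k()`, default 3–8) treat $K$ as a
nuisance dimension: metrics are computed per $K$ and averaged
arithmetically, the summary used when comparing animals.

## 3. Spectral analysis

Spectral measures run on the **raw** (non-coarse-grained) signal — the
40 ms averaging that produces the 25 Hz trajectory suppresses exactly the
gamma content the band analysis needs. `multitaper_spectrogram()` uses
Slepian tapers with time–bandwidth product $NW = 3$ and $K = 5$ tapers
(the standard pairing), 10 s windows with 5 s overlap for band power, and
60 s windows with 30 s overlap for the 40 Hz measure, where the long
window buys the frequency resolution needed to separate the entrainment
peak from its neighborhood. Tapers are computed from the symmetric
tridiagonal commuting-matrix eigenproblem (Sturm-sequence bisection for
eigenvalues, inverse iteration with sparse tridiagonal solves for
vectors); they match `scipy.signal.windows.dpss` to machine precision and
are validated in-suite by orthonormality and spectral-concentration
checks.

Relative band power divides the time-averaged spectrum by its total power
per channel, integrates half-open bands (delta 0.5–4, theta 4–12, gamma
30–80 Hz), and averages channels within regions; a band partition of the
full range sums to 1 by construction. The default region map assigns a
30-channel grid front-to-back onto six cortical territories (PFC, MOC,
SSC, PAR, RSC, VIS); real layouts are supplied as a named channel→region
vector. "40 Hz power" is the single bin nearest 40 Hz by default, with a
$\pm$ 1 Hz integration option — with 60 s windows the bin width is
1/60 Hz, so the single-bin reading is already narrow.

## 4. Behavior

Arena normalization translates by the bottom-left corner, rotates the
bottom wall onto the x-axis, and scales each axis by its wall length
(per-axis scaling absorbs non-square arenas and anisotropic pixels). The
corner order convention is pinned: bottom-left, bottom-right, top-right,
top-left. The posture rotation multiplies barycenter-centered coordinates
by $e^{i(\pi/2 - \varphi)}$, $\varphi$ the angle of the neck vector — the
reading under which the correction actually removes heading, sending the
neck onto the $+y$ axis; head movement is then the norm of the
frame-to-frame difference of the stacked egocentric (nose, ears)
coordinates, identically zero under rigid translation and rotation (a
tested invariant, at $10^{-9}$). The barycenter is the neck/body-midpoint
mean; speed is its per-frame displacement norm, in arena units per frame
by default (per-second via `per_second = TRUE`). The memory index
$(t_{new} - t_{fam})/(t_{new} + t_{fam})$ is antisymmetric with chance
level 0. Likelihood-based point filtering of low-confidence DLC points is
deliberately not applied by default; likelihoods are carried through for
the user.

## 5. Resampling statistics

`bootstrap_ks_compare()` models each input sample as a histogram over 200
uniform bins spanning the pooled range (pinned for determinism), redraws
5000 Monte-Carlo observations per group (uniform within a bin, so the
model is continuous), and builds 500-observation bootstrap replicas under
the association hypothesis (per-group) and the null (merged), with the
two-sample KS statistic per replica. The H1 replica mean ± sd is the
effect-size summary. For the p-value, "fraction of overlap between the
two distributions" is read literally: the overlap coefficient
$\sum_b \min(\hat p_b^{H0}, \hat p_b^{H1})$ of the two KS replica
histograms, which is $\approx 1$ when a sample is compared against itself
and $\to 0$ for well-separated groups. A one-sided exceedance reading
(fraction of H0 replicas at or above the H1 mean) is also computed and
reported (`p_exceed`); it was not made the default because the replica KS
distribution is right-skewed, placing its mean above its median, so even
identical inputs would sit near — and half the time below — 0.5 under
that reading. Both are Bonferroni-corrected over the comparisons
requested. The replica count (500) is a package choice — the replica
*size* is part of the procedure's definition but its count only controls
the Monte-Carlo error of the overlap estimate.

`mutual_information_deciles()` quantile-bins both series into deciles and
computes $MI = \sum_{ij} P(i,j)\log_2\frac{P(i,j)}{P(i)P(j)}$ normalized
by the larger marginal entropy, so $MI/H \in [0,1]$ and equals 1 for any
strictly monotone dependence (deciles are rank-invariant). The observed
value is the mean over paired bootstrap resamples (joint indices); the
chance level is the mean over independent resamples of the two series.
The small positive bias of plug-in MI on finite samples is visible in the
null and is the reason the null is reported rather than assuming 0.

`codistribution_deciles()` bins fluidity into 0:10:100-percentile deciles
and reports the median locomotor value per decile, with 200-iteration
bootstrap bands under paired (H1) and independent (H0) resampling;
dependence shows as H1 medians escaping the H0 bands.

Pooled vs per-subject inputs: group fluidity distributions can be compared
by pooling all reference-point thetas within a group (default — keeps the
distributional shape the KS machinery needs) or by per-subject means;
both modes are exposed in `run_group_comparison()` because the averaging
level genuinely changes the hypothesis being tested.

## 6. The synthetic-data generators

The generators provide the statistical structure the analyses assume, with
ground truth:

- `gen_iid_gaussian()`: temporally independent standard-normal vectors —
  the Poisson-return regime where $\theta \to 1$; the package's headline
  validation condition (30 channels, 20,000 samples, 10 seeds).
- `gen_var1()`: per-channel AR(1) with persistence $\phi \in [0,1)$, the
  dial that moves fluidity monotonically; 1000 burn-in samples are
  discarded so outputs are stationary (variance
  $\sigma^2_\epsilon/(1-\phi^2)$, a tested closed form).
- `gen_microstate_hmm()`: a $K$-state Markov chain with stay probability
  $1 - 1/\bar d$ (geometric dwell, mean $\bar d$) and uniform off-diagonal
  switching, emitting unit-norm random templates (redrawn until pairwise
  $|r| < 0.7$, so clusters are identifiable; the criterion is recorded in
  `params`) plus iid channel noise. The default amplitude is
  $\sqrt{C}$, giving unit per-channel signal RMS so that `noise_sd` reads
  directly as a noise-to-signal ratio: at `noise_sd = 0.3` single-sample
  classification is reliable (sample–template $r \approx 0.96$) and dwell
  times are recoverable from segmentation labels, which is the regime a
  clean rodent grid recording with clear microstates occupies.
- `gen_pose_track()`: a smoothed, reflected random walk of the barycenter
  inside the unit arena with heading following motion, a rigid 8-point
  egocentric skeleton, and a known camera transform (rotation, scaling,
  offset) applied last — so normalization can be tested against exact
  ground truth, and egocentric head movement of these rigid-posture
  animals is exactly zero.
- `gen_cohort()`: two groups identical in all parameters except a designed
  persistence gap; subject seeds are `master + index`.

What they do **not** emulate: 1/f spectral shape, volume conduction and
channel covariance, artifacts, non-stationarity across task phases, and
posture dynamics. Passing tests therefore demonstrate the correctness of
the estimators and their contracts — not that real recordings satisfy the
generators' assumptions; on real data the preprocessing (artifact removal
upstream, channel rejection here) carries that burden.

## 7. Problem sizes and runtime choices

The shipped tests and the acceptance script use: fluidity references
subsampled by strides of 25–250 on series of 3,000–20,000 coarse samples;
cohorts of 2–16 subjects; 50 + 20 seeds for the KS calibration and power
runs; K sweeps over 3–8 on 6,000-sample series. These sizes are the
package's own desk-scale choices: each Monte-Carlo estimate they produce
has margins (e.g., null false-positive rates an order of magnitude below
the 10% bound) that make larger runs unnecessary for validation.

## 8. Known limitations

- The extremal-index estimator assumes stationarity within a recording;
  strong drifts bias $\theta$ downward (drifting references look
  persistent). Phase boundaries are recorded but not censored by default.
- Correlation-distance k-means is a local optimizer; 10 restarts are
  enough for well-separated templates but offer no global guarantee at
  high $K$ on weakly structured data.
- The GFP prominence default (0.5) is in raw variance units and thus
  amplitude-dependent; use the z-scored mode across heterogeneous gains.
- The overlap-coefficient p-value is conservative and its resolution is
  limited by the replica count (1/500 at defaults).
- `estimate_extremal_index()` requires ≥100 observable samples and ≥2
  exceedances; short or nearly constant recordings produce `NaN`s that
  propagate (with reasons) rather than numbers.
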