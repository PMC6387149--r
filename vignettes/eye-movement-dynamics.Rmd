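---
title: "Dynamical and fractal analysis of fixational eye movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical and fractal analysis of fixational eye movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(oculodyn)
library(dplyr)
```

## The problem

A high-rate eye tracker pointed at a person fixating a jumping dot records a
scalar time series of horizontal eye rotation: roughly 200 ms of
*saccadic latency* while the stimulus jump is being processed, one ballistic
*saccade* (4--20 degrees in 30--80 ms, peaking below 500 deg/s), and then a
*fixation* that is never truly still --- it carries slow drift, 40--100 Hz
tremor of a couple of arcminutes' amplitude, and occasional corrective
microsaccades. Two questions about such records interest oculomotor
physiologists:

1. **Dynamics.** Does the signal behave like a low-dimensional (possibly
   chaotic) dynamical system, and does that behaviour change across the
   trial --- latency, saccade landing, sustained fixation? The diagnostic is
   the largest Lyapunov exponent (LLE) estimated from a delay-embedded
   reconstruction of the velocity signal.
2. **Self-similarity.** Do fixational velocity fluctuations carry long-range
   correlation? The diagnostic is the scaling exponent of detrended
   fluctuation analysis (DFA) and the Hurst exponent derived from it.

Both diagnostics are sensitive to preprocessing, so the package carries the
position-domain filter bank commonly applied to such data --- running medians
(windows 5, 9, 15), third-degree Savitzky--Golay smoothing (windows 7, 15),
and undecimated Daubechies wavelet denoising (filter lengths 8 and 20, three
levels, hard thresholding) --- and runs every analysis per filter so the
filters' influence can itself be quantified.

Because raw recordings of this kind are not publicly distributable, the
package ships a tested synthetic generator that emulates the study design
(29 stimulus positions x 24 participants x 2 sessions, 3000 samples per
trial at 1000 Hz) and reference signals with known dynamical and fractal
properties (white/Brownian noise, fractional Gaussian noise, the logistic
map, the Lorenz system).

## The pipeline

```{r pipeline, eval = FALSE}
cfg    <- sim_config(seed = 1)
trials <- generate_dataset(cfg) |> exclude_anomalous()
lle    <- analyze_lle(trials, filters = "N")         # per segment
dfa_df <- analyze_dfa(trials, filters = filter_labels())
group_summary(lle, "lambda", group = "segment")
run_tests(dfa_df, "alpha", group = "filter")
```

Each trial is filtered in the position domain, differentiated to velocity by
the forward two-point difference `v[i] = (x[i+1] - x[i]) * rate` (the
filter-then-differentiate order follows the usual processing narrative for
such data; the convention is documented so results are comparable), and cut
into five half-open windows: 0--50, 0--100, 0--200 ms (latency) and
200--700, 700--1500 ms (fixation). At 1000 Hz these contain exactly 50, 100,
200, 500 and 800 samples.

## Delay embedding

The velocity series is embedded as Takens vectors
$y_i = (v_i, v_{i+\tau}, \dots, v_{i+(m-1)\tau})$, giving
$M = N - (m-1)\tau$ reconstructed states.

**Delay $\tau$** is the first prominent local minimum of the time-delayed
mutual information $I(\tau)$, estimated on a joint histogram whose bin width
follows Scott's rule $h = 3.5\,s\,n^{-1/3}$. Two estimator choices deserve
explanation:

* *Robust scale and clipped span.* Saccadic velocity distributions are
  extremely heavy-tailed (a 35 deg/s standard deviation against a 3 deg/s
  fixational scale); a bin width computed from the raw standard deviation
  collapses all fixational samples into one or two bins and leaves the MI
  profile featureless. The estimator therefore uses the robust
  normal-reference scale $\min(\mathrm{sd}, \mathrm{IQR}/1.349)$ in Scott's
  formula and bins an equal-width grid over median $\pm 8$ robust sigmas,
  with two overflow bins catching the saccadic tail. For light-tailed
  signals this reduces to the ordinary rule (`scott_bins()` keeps the
  literal formula).
* *Bin-origin averaging and prominence.* A single histogram's MI profile of
  a smooth signal is jagged purely from bin-edge effects --- the first
  strict local minimum of a noiseless sinusoid's profile lands at a lag of
  2 instead of the quarter period. The estimate at each lag is therefore
  averaged over a 4 x 4 grid of bin-origin shifts, and a local minimum is
  accepted only if the profile afterwards rises by at least 5% of its range
  before any lower value occurs. With `shifts = 1` and
  `min_prominence = 0` the textbook estimator and rule are recovered. When
  no acceptable minimum exists the delay falls back to the first lag with
  $I(\tau) < I(0)/e$, and the trial is flagged rather than dropped.

**Dimension $m$** comes from the false-nearest-neighbour test (Euclidean
metric, ties to the smallest index, Theiler window $\tau$): a neighbour is
false if the added $(m{+}1)$-th coordinate separates the pair by more than
$R = 10$ times their distance in dimension $m$. The standard acceptance
criterion is a fraction at or below 1%. Physiological velocity traces carry
a stochastic FNN floor of a few percent, so `select_embedding()` stops,
flagged, at the knee of the FNN curve (first dimension improving the
fraction by less than 30%) instead of chasing the noise floor into high
dimensions. Note that the pure distance-ratio test does let white noise
"unfold" at high dimensions (sparse embeddings make the ratio small); the
classical noise signature is a high fraction at low dimension only.

## Largest Lyapunov exponent

The nearest-neighbour divergence method: every state is paired with its
nearest neighbour outside a Theiler window (full series: $\tau m$; short
segments: capped at a quarter of the available states so latency windows
remain analysable), pairs with zero initial separation are dropped, and the
curve $\langle \ln d_j(i)/d_j(0) \rangle$ is traced for up to 80 steps. The
LLE is the least-squares slope over steps 1--20 (configurable), reported per
millisecond at 1000 Hz so magnitudes are commensurate across segments; maps
analysed at one step per sample use `dt = 1`. If more than half of the
candidate pairs have zero initial distance --- typical of heavily
median-filtered, constant-rich traces --- the segment is reported infeasible
with reason `zero_distance_pairs`; segments too short for the trial's
embedding report `too_short`. These records are retained, not silently
dropped, so infeasibility accounting per filter is part of the output.

Calibration: on the $r=4$ logistic map the fitted slope matches the
derivative-sum oracle $\frac1n\sum\ln|r(1-2x_i)|$ (analytically $\ln 2$)
within a few tenths of a percent; a contracting map $x \mapsto x/2$ yields
exactly $\ln\frac12$ per step; white noise yields a near-zero slope with
poor fit quality beyond the first steps.

**A caveat the user should know.** For a *stationary stochastic* segment the
strict nearest-neighbour construction is positively biased: the initial
separation is an extreme order statistic, so the mean log-divergence curve
always climbs towards saturation, and quiet states whose near future
contains a velocity pulse (a microsaccade) add further apparent divergence.
On the synthetic corpus this bias is of order $+0.01$ per ms in the late
fixation window --- small against the latency-segment exponents but not
negative. Genuinely convergent episodes (saccade landing, glissadic decay)
do produce negative exponents. Sign claims about near-stationary segments
should therefore be read jointly with the fit quality and the divergence
curve itself (`autoplot()` shows it).

## Detrended fluctuation analysis

The full-trial velocity series (all 3000 samples; segmentation is not
applied, and `analyze_dfa()` can be switched to position) is mean-centred
and cumulatively summed; the profile is cut into non-overlapping boxes of
size $n$ from the start (the trailing remainder is dropped, no reversed
pass); per box the trend is removed --- the least-squares line (`poly1`) or
the first-to-last chord (`bridge`) --- and $F(n)$ is the RMS residual over
all covered points. Box sizes follow the dyadic grid $30 \cdot 2^k$, capped
at 500 (5 scales) or 1000 (6 scales); these two caps, crossed with the two
detrending rules, form the standard four-way parameter grid
(`dfa_param_grid()`). The exponent $\alpha$ is the unweighted least-squares
slope of $\log F(n)$ on $\log n$; $H = \alpha$ on $[0,1]$ and
$H = \alpha - 1$ on $(1,2]$.

Calibration (also enforced by the test suite): white noise gives
$\alpha \approx 0.5$, random walks $\alpha \approx 1.5$ ($H \approx 0.5$),
and circulant-embedding fGn with $H \in \{0.3, 0.7, 0.9\}$ is recovered to
within $\pm 0.1$ at $n = 3000$. On stationary fGn, bridge detrending gives
slightly larger exponents than polynomial detrending (about $+0.01$); on
full trial velocities containing a saccade the chord interacts with the
step and the ordering can reverse.

```{r dfa-example}
set.seed(1)
res <- dfa(generate_fgn(0.7, 3000))
glance(res)
autoplot(res)
```

## The synthetic generator

`generate_trial()` composes, in order: a latency hold (uniform 200--240 ms;
the analysis segments presume the saccade starts at or after 200 ms), one
raised-cosine saccade whose amplitude is uniform on 4--20 degrees and whose
duration is uniform on $[\max(30, 4A), 80]$ ms --- the lower bound is raised
with amplitude $A$ so the raised-cosine peak $2A/D$ never exceeds
500 deg/s --- landing with a 10% undershoot recovered by an exponential
glissade (80 ms time constant), and then fixation. Superimposed throughout
are:

* **drift**: fractional Gaussian *velocity* noise with Hurst exponent
  `fixation_hurst` (default 0.7), low-passed at 10 Hz (within the
  sub-40 Hz band expected of drift), scaled to a uniform 6--25 arcmin/s RMS
  and integrated to position through a weakly mean-reverting control loop
  (250 ms time constant) --- drift is modelled on velocity precisely so that
  the Hurst exponent DFA must recover is directly controllable;
* **tremor**: a sinusoid with uniform frequency 40--100 Hz, fixed amplitude
  0.0017 degrees, random phase;
* **microsaccades**: Poisson-placed corrective events (default 1.5/s) with
  uniform 10--40 arcmin amplitude, duration coupled so peak velocity stays
  below 50 deg/s, a 150 ms refractory interval, direction opposing the
  accumulated fixational offset, and miniature-saccade kinematics (10%
  dynamic overshoot gliding back with the same 80 ms constant);
* an optional **chaotic component** (default on): a Lorenz-system trajectory
  (RK4, 0.02 time units per sample) scaled to 0.02 degrees RMS and active
  during the pre-saccadic period only, ramped off across the saccade. The
  physiological picture is an open-loop oculomotor drive before the new
  target is acquired, supplanted by visually guided stabilisation
  afterwards; it makes the latency segments genuinely chaotic while the
  landing is convergent;
* **measurement artefacts**: additive white sensor noise (default
  $10^{-4}$ degrees RMS, well below the physiological per-sample movement so
  the embedding statistics remain signal-driven) and an optional LSB
  quantization step (default off; switching it on reproduces the
  zero-velocity runs of digitised oculography, at the cost of lattice
  artefacts in the neighbour statistics);
* a **settling envelope**: drift, tremor and corrective amplitudes decay
  after landing towards 50% of their initial level with a 500 ms time
  constant, emulating the quieting of fixation after target acquisition.

Every trial derives its own RNG substream from the dataset seed and the
trial counter, so single trials are bit-reproducible regardless of
generation order. Anomalous recordings are emulated by *flagging* the
trials of designated participant-session pairs --- exclusion by inspection
is a bookkeeping fact, not an algorithm --- and `exclude_anomalous()`
removes them with logged counts: the full design gives
$29 \times 24 \times 2 = 1392$ trials, flagging two participants' second
sessions removes 58 and leaves 1334.

**What the generator does not emulate**: binocular coordination, blinks and
pupil artefacts, sensor-specific noise physics, vertical rotation, and any
dependence of the response on the actual stimulus geometry (all positions
are statistically identical). Passing tests on this corpus therefore
demonstrate that the estimators recover known dynamics planted in
realistically structured signals --- not that real oculomotor recordings
have those dynamics.

```{r trial-example}
cfg <- sim_config(n_participants = 1, n_sessions = 1, n_positions = 1,
                  seed = 42)
autoplot(generate_trial(cfg, 1, 1, 1))
```

## Numerical and design choices

* **Wavelet denoiser**: translation-invariant (undecimated) transform with
  periodic boundary handling, computed in the Fourier domain; detail levels
  1--3 are hard-thresholded with the universal threshold
  $\hat\sigma\sqrt{2\ln N}$, $\hat\sigma = \mathrm{MAD}(d_1)/0.6745$,
  applied at every level (whether only the finest level should be
  thresholded is ambiguous in practice; all-levels is this package's
  choice). "Filter length 8/20" maps to the Daubechies families with 4 and
  10 vanishing moments. With threshold zero the transform pair is exact to
  machine precision, which the tests assert.
* **Running median endpoints**: Tukey-style shrinking symmetric windows, so
  endpoints are kept; Savitzky--Golay evaluates off-centre fits at the
  edges; both match their brute-force oracles on the interior exactly.
* **Two-point differentiation** is the forward difference; half-open
  segment windows use 0-based sample arithmetic, so adjacent segments share
  no sample.
* **Ties and windows**: nearest-neighbour ties resolve to the smallest
  index; the Theiler window is $\tau m$ on full series and
  $\min(\tau m, (M-2)/4)$ within segments.
* **Degenerate inputs** signal conditions rather than crash the pipeline:
  zero-variance series (`oculodyn_degenerate`), all-zero-distance
  embeddings (`zero_distance_pairs`), segments shorter than the embedding
  (`too_short`); flagged fallbacks for the delay and dimension are carried
  as columns in every result table.
* **Problem sizes** used by the packaged checks: DFA calibrations use 200
  replicates of length 3000 (100 per Hurst value for fGn recovery); the
  map-based LLE checks use 20 logistic seeds of length 3000; the
  qualitative corpus is 4 participants x 2 sessions x 29 positions. These
  sizes give stable means (Monte-Carlo SE well under the asserted
  tolerances) while keeping the whole suite to a few minutes.

## Known limitations

* The LLE estimator's positive bias on stationary stochastic segments
  (discussed above) means sign classifications in quiet windows lean
  chaotic; treat near-zero exponents with low $r^2$ as "neutral" regardless
  of sign.
* DFA here is first order with dyadic scales and forward partitioning only;
  multifractal extensions and higher detrending orders are out of scope.
* The statistical layer follows the source field's conventions (Shapiro-Wilk
  gate, ANOVA + Tukey HSD or Kruskal--Wallis, one-sided t-tests per
  segment) and applies no multiple-testing correction beyond Tukey's HSD.
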