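---
title: "Methods: inferring functional synaptic connectivity from single-cell optogenetic mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring functional synaptic connectivity from single-cell optogenetic mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synaptomap)
```

# The mapping problem

In a single-cell optogenetic connectivity-mapping experiment, one neuron is
held in whole-cell voltage clamp while candidate presynaptic neurons
expressing a soma-targeted opsin are stimulated one at a time with brief
two-photon pulse trains. If a stimulated cell is synaptically connected to
the recorded cell, each stimulus tends to evoke one or more excitatory
postsynaptic currents (EPSCs) a few milliseconds later. The analysis
problem is to decide, for every stimulated cell, whether such evoked EPSCs
exist on top of the ongoing spontaneous EPSC barrage, and how strong the
connection is. `synaptomap` implements the full chain: EPSC detection and
decomposition, Bayesian connected/not-connected classification, connection
strength, artifact handling, intrinsic-property extraction, a sparse
regression for the determinants of connectivity, and map-level geometric
summaries — plus a synthetic-data generator with known ground truth that
makes the whole chain testable without any recordings.

# EPSC detection and decomposition

The detector works on the inverted trace (inward currents positive),
resampled to 5000 Hz, in six steps.

1. **Detrending.** A baseline is estimated with a 10th-percentile filter
   of 50 ms width, smoothed on a 200 Hz grid with a 15 ms median filter,
   and interpolated back. Subtracting it and shifting to zero median gives
   the zero-baseline trace $S$; the noise scale is the robust
   $\widehat{SD} = 1.4826 \times \mathrm{MAD}$. Evaluating the percentile
   filter directly on the 200 Hz grid is numerically equivalent to
   filtering at full rate and decimating, and 25 times cheaper.
2. **Deconvolution.** $S$ is deconvolved against the canonical EPSC
   kernel $k(t) = e^{-t/\tau_d}(1 - e^{-t/\tau_r})$
   ($\tau_d = 3.5$ ms, $\tau_r = 0.7$ ms, scaled to unit peak so heights
   are in pA) by solving the nonnegative sparse problem
   $\min_{x\ge 0} \tfrac12\|k*x - S\|^2 + \lambda\|x\|_1$ with
   $\lambda = 0.8\,\widehat{SD}$, using FISTA with FFT convolutions in up
   to 10 outer blocks. The kernel is ill-conditioned at high frequencies,
   so the iteration is stopped when the deconvolved trace stabilizes; the
   remaining early stopping acts as mild additional regularization of
   frequencies the kernel barely carries. The denoised trace is defined as
   the exact convolution of the deconvolved trace with the kernel, which
   the test suite verifies to $10^{-9}$.
3. **Detection.** Peaks of the triangle-filtered (2.5 ms) deconvolved
   trace with height and prominence at least $0.5\,\widehat{SD}$ and at
   least 2.0 ms apart give provisional onsets $\hat o$; the deconvolved
   mass in $[\hat o - 0.4, \hat o + 0.8]$ ms gives provisional heights
   $\hat h$. An absolute floor of $10^{-3}$ pA keeps numerically silent
   traces from producing ripple detections.
4. **Clustering.** Segments where the denoised trace exceeds
   $1.8\,\widehat{SD}$, extended by $-10/+20$ ms and by $\pm 10$ ms around
   events, are merged where they overlap; each merged segment is one
   cluster. Events outside every segment (possible for small events) get
   singleton segments spanning $[\hat o - 10, \hat o + 30]$ ms.
5. **Fitting.** Each cluster is fit with a sum of kernels plus offset,
   minimizing $\mathrm{RMS}(S - \tilde s)/\widehat{SD} +
   \mathrm{RMS}(o - \hat o)/5$ with heights and time constants on the log
   scale inside the boxes $h \in [\hat h/15, 3\hat h]$,
   $o \in \hat o \pm 10$ ms, $\tau_d \in (0.5, 50)$,
   $\tau_r \in (0.1, 10)$, $\tau_d > \tau_r$. A simulated-annealing global
   search whose evaluation budget grows linearly with the cluster's event
   count is refined by a Nelder–Mead polish; the annealing stream is
   seeded from the configuration so fits are reproducible.
6. **Thresholding.** Events with fitted height $\le 2.5\,\widehat{SD}$
   are discarded.

On a 60 s synthetic benchmark (5 kHz, 2 Hz spontaneous events of ~15 pA,
$\widehat{SD} = 2$ pA) this pipeline reaches F1 above 0.9 with sub-ms
median onset error; the acceptance suite recomputes this end to end.

# Connected or not: Bayesian model comparison

For each stimulated target the recording is segmented into **evoked**
windows (90 ms after each stimulus, the last 10 ms before the next pulse
disregarded) and **spontaneous** reference pieces of at most 90 ms taken
within ±5 s of the target's trains where nothing was being stimulated.
Counts and within-window event times feed three pairs of models:

* **rate-and-time** (both Poisson count likelihoods and the latency
  mixture), the main comparison;
* **time-only** (latency mixture alone; the connected variant puts a
  Beta(2,2) prior on the bump weight, the null is a parameter-free
  uniform);
* **rate-only** (Poisson counts alone).

The connected variants add an `Evoked_per_trial` parameter $e_p$ and mix a
latency bump (Gamma with mean 12.96 ms and sd 6.33 ms, the moments of the
population latency fit) with the uniform; the mixture weight is
$w = e_p/(e_p + \mathrm{rate}\times 90)$. Spontaneous rates are inferred
per protocol repetition, in events/ms (the Poisson means are rate × time).
Posteriors are sampled with the package's Hamiltonian Monte Carlo sampler
(dual-averaging step size, diagonal mass adaptation, jittered trajectory
lengths, analytic gradients verified against finite differences in the
tests). Each pair is scored by PSIS-LOO and converted to model weights
with Bayesian-bootstrap pseudo-BMA; both components were validated
numerically against an independent reference implementation on frozen
fixtures. A target is called connected when
$(w_{rt} \ge 0.5) \wedge (w_t \ge 0.4) \wedge (w_r \ge 0.4)$, all
inclusive.

Priors not determined by the data follow these defaults, all exposed in
`connectivity_priors()`: the spontaneous-rate prior is centered on the
pooled empirical spontaneous rate of the recording (all events outside
every evoked window over all unstimulated time) with sd equal to the mean
— a deliberately weak prior that nevertheless stabilizes targets whose
local ±5 s context is short; $e_p$ has prior mean 0.5 and sd 0.5. For the
variable-bump model (used only after a positive call) the bump is normal
with a Gamma(mean 13 ms, sd 5 ms) prior on its center and a Gamma(mean
5.5 ms, sd 2 ms) prior on its width truncated to [3, 8] ms. The width
prior's mean is set to the middle of its bounds (5.5 ms); tying it to
the center prior instead is available in configuration.

Degenerate data are handled explicitly: a target with no event times gets
$w_t = 0.5$ (the time-only comparison carries no information), and
empty-window stimulations contribute zero to connection strength,
consistent with treating absent responses as zero in the weighted-input
summaries.

Connection strength is the per-stimulation bump-weighted average of EPSC
heights in a 2–30 ms post-stimulus window, using the posterior-median
normal bump as the weight function, averaged over stimulations.

## Sampler profiles and problem sizes

The reference (`paper`) profile uses 5000 tuning steps, 2000 draws, 4
chains and an acceptance target of 0.95; the `fast` profile
(1000 tuning steps, 500 draws, 2 chains) is the package default for
routine work and is what the test and acceptance suites use. The
acceptance suite runs 40 simulated targets (20 connected at $e_p = 0.5$
with a normal 13 ± 5 ms bump, 20 unconnected, 20 stimulations each), a
60 s detection benchmark, a 150,000-latency mixture recovery, and ten
selection-recovery plus ten null runs of the Horseshoe regression at
n = 5000 — sizes chosen to exercise every stage at full fidelity while
keeping a complete run on a single core comfortably under an hour.

# The pooled latency mixture and the connected-cell budget

Pooling all stimulus-aligned EPSC latencies across a dataset gives a
peristimulus density that is uniform except for an early bump of evoked
events. `fit_psth_mixture()` fits
$f(t) = w\,\mathrm{Gamma}(t; k, \theta) + (1-w)/90$ by maximum
likelihood, with the gamma renormalized to the 90 ms window so $f$
integrates to exactly one, and confidence intervals from the observed
information. With $E$ pooled events of which a fraction $f$ sit in the
bump, $N$ stimulated cells, $n$ stimulations per cell and an assumed
$e_p$, the fraction of connected cells is
$\hat c = E f/(N\,n\,e_p)$ (`estimate_connected_fraction()`).

# Determinants of connectivity

Cell-pair features are variance-stabilized (log for strictly positive
features, logit for the sag ratio), standardized robustly, and whitened
with a robust ZCA transform: the correlation matrix is estimated by the
minimum covariance determinant (subset fraction 0.75 by default),
eigendecomposed, and $W = U\Lambda^{-1/2}U^\top$ applied, so coefficients
are comparable in per-SD units and multicollinearity is removed while
each whitened feature stays maximally similar to its original.

Feature selection uses Bayesian logistic regression with Horseshoe
priors in the non-centered formulation
($\beta = z\,\lambda\,\tau$ with $z \sim N(0,1)$, local scales
$\lambda = r_l\sqrt{\rho_l}$, $r_l \sim N(0,1)$,
$\rho_l \sim \mathrm{InvGamma}(1.5, 1.5)$, global scale
$\tau = r_g\sqrt{\rho_g}$, $\rho_g \sim \mathrm{InvGamma}(0.5, 0.5)$, and
$\beta_0 \sim N(-3.67, 1)$, i.e. centered near a 2.5% base rate), sampled
with the same HMC machinery; inverse-gamma parameters are shape/rate,
with the shape/scale reading available in configuration. Features whose
posterior-median coefficient exceeds 0.05 in absolute value — about a 5%
change in odds per SD — are selected.

Predictive information is quantified with unregularized logistic
regression under stratified cross-validation (exactly one connected pair
per fold, negatives split evenly, folds a deterministic function of the
seed so different feature subsets can be compared pairwise) and the
cross-entropy $H$ in nats with probabilities clipped to
$[10^{-12}, 1-10^{-12}]$. Controls: shuffled labels (default 200
shuffles; raise for publication-grade nulls) and a constant-probability
predictor.

# Artifact handling, intrinsic properties, geometry

Direct photocurrents (opsin current in the recorded cell itself) are
recognized in stimulus-aligned snippets by minimal latency (< 2 ms),
minimal jitter (< 0.5 ms), high reliability (≥ 90% of trials) and a
reproducible waveform (mean trial-to-trial correlation ≥ 0.9). In
practice this identification is often done by eye; our thresholds
operationalize the same hallmarks, each configurable, with a
manual-override hook.
Targets with photocurrent above 20 pA are excluded; smaller ones are
removed by subtracting the mean of EPSC-free trials (or
blocker-condition trials when available). Compound-response amplitudes
are baseline([-20, +2] ms) minus minimum([+2, +25] ms).

Intrinsic properties from current steps follow the standard definitions
(input resistance from the smallest hyperpolarizing step; $\tau_m$ from
an exponential fit over the 10–90% rise; $C_m 	= \tau_m/R_{in}$; sag
ratio $(V_{min}-V_{ss})/(V_{min}-V_{bl})$ with $V_{min}$ in the first
30% of the pulse; gain as the f-I regression slope; bursting and
adaptation as ISI ratios on the sweep nearest 80% of the maximal rate,
ties toward lower current). The spike threshold has no single standard definition; we take the
point where dV/dt first exceeds 20 mV/ms before the peak
(configurable); amplitude is peak minus threshold and the half-width is
measured at half that amplitude. Per-stimulus fluorescence validates
spiking: a cell is kept when the lower 95% confidence bound of the OLS
fluorescence slope across its train is nonnegative. On noisy zero-slope
input this excludes about half of cells by construction — the documented
boundary behavior of a one-sided rule at its null.

Map geometry builds three mutually orthogonal planes (least-squares
slice surface; midline through its two ends orthogonalized to the
surface; dorsal-end plane orthogonal to both); signed distances give AP
(depth in slice), ML and DV. Map summaries: connection probability among
responsive cells within 300 µm; mean strength over connected cells (no
radius cap); weighted input counting non-connected cells as zero (over
responsive cells — non-responsive cells are excluded from analysis, the
natural reading of "all cells in the map"); directional inputs split by
ML/DV offset sign. The co-stimulation ellipsoid uses full-axis = FWHM
semantics (defaults 55.9 µm axial, 24.2 µm radial; the semi-axis reading
is a switch), and the implied probability bias is $1 - 1/(1+f_{co})$.
Light-power compensation is $e^{depth/\tau}$ with $\tau = 147.6$ µm an
input parameter — the tissue light-propagation model behind it is not
re-implemented.

# The synthetic generator: what it emulates and what it does not

`make_stim_schedule()` reproduces the protocol skeleton (10-pulse trains
at 10 Hz, 7.2 ms pulses, 1–3 repetitions, non-overlapping trains, 500 ms
inter-train gaps, targets scattered in a 420 × 420 × 300 µm³ volume).
`simulate_event_stream()`/`simulate_trace()` draw spontaneous EPSCs as a
homogeneous Poisson process (default 2 Hz), evoked events per stimulus
as Poisson($e_p$) with latencies from the configured bump (default the
gamma moments 12.96 ± 6.33 ms), render every event with the unit-peak
kernel, and add white noise (default $\widehat{SD}$-scale 2 pA), optional
sinusoidal drift and optional per-target photocurrents. Event amplitudes
are lognormal around 15 pA — a configurable modeling assumption chosen
for realism (miniature-EPSC amplitude distributions are right-skewed),
not a fidelity claim about any particular dataset. One master seed derives every sub-stream
deterministically.

What the generator does *not* emulate: bursty or correlated spontaneous
activity, synaptic rundown and short-term plasticity across a train,
electrode-series-resistance filtering, detailed opsin kinetics, or
calcium-indicator photophysics beyond a per-stimulus scalar. Passing
tests therefore demonstrate correctness of the algorithms under the
stated statistical model, not robustness to every pathology of real
recordings.

# Numerical choices

* Gamma distributions are parameterized by (mean, sd) where the models
  are written that way and by (shape, scale) where the latency mixture
  is; both constructors exist.
* All bounded parameters are sampled through smooth transforms (log,
  logit-box) with exact Jacobians; gradients of every hand-written
  log-posterior are tested against finite differences.
* The deconvolution kernel is truncated where it falls below $10^{-4}$
  of peak, bounding convolution support.
* PSIS-LOO tail fits use the empirical-Bayes generalized-Pareto
  estimator with the standard weak prior; tails shorter than 5 samples
  are left unsmoothed.
* Probabilities are clipped at $10^{-12}$ before logs; cross-entropy is
  in nats.
* Ties in the 80%-of-max-rate sweep go to the lower current; `>=` is
  used in all three decision thresholds.

# Known limitations

* The connected/not-connected decision inherits the noise of its
  spontaneous-rate reference: targets whose ±5 s context contains little
  unstimulated time get noisy rate estimates, and chance clusters of
  early spontaneous events can still produce a false positive; with
  paper-like rates the suite bounds the false-positive rate at 10%.
* The 0.05 posterior-median selection threshold is an effect-size cut
  (~5% change in odds per SD), not an error-rate guarantee. When the
  positive class is rare (a few hundred positives or fewer), chance
  sample correlations of 2.5–3 SE among genuinely null features are
  routinely left above 0.05 by the Horseshoe's shrinkage — behavior we
  confirmed against an independent Gibbs-sampler implementation of the
  identical prior stack — so exact support recovery should not be
  expected at such data sizes; the all-null case, by contrast, selects
  nothing almost always.
* The HMC sampler is a compact fixed-trajectory implementation, not a
  full tree-building sampler; for the funnel-shaped Horseshoe posterior
  it relies on the non-centered parameterization and conservative step
  sizes, and convergence diagnostics (split-R̂, divergence counts) are
  reported so unreliable fits are visible.
* Trace I/O is plain CSV/JSON; container-format export is out of scope.
* Atlas registration beyond the three-plane geometry, spike detection in
  current clamp, and inhibitory-connection modeling are out of scope.
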