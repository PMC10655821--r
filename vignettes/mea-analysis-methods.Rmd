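---
title: "Models and methods behind meadev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meadev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

meadev analyzes spontaneous activity of developing neuronal cultures recorded
on multiwell microelectrode arrays (MEA): 24-well plates with 12 substrate
electrodes per well, recorded 5 minutes per day across days in vitro (DIV)
4–42. This vignette documents the models, the defaults and why they were
chosen, what the synthetic generator does and does not emulate, and the
numerical choices that affect results.

## 1. Detection pipeline

**Spike detection.** Extracellular spikes are threshold crossings of the
band-filtered voltage. The threshold is adaptive per electrode:
`noise_multiplier` (default 5) times the standard deviation of the baseline
noise, estimated from the first `baseline_window` (default 1 s) of each
trace. A spike is registered at each negative-going crossing; its time is the
extremum within the `dead_time` (2 ms) window after the crossing, its
amplitude the absolute extremum, and later crossings inside the dead time are
absorbed. Choices the underlying description leaves open, fixed here:

* *Polarity.* Extracellular somatic spikes are negative-leading, so only
  negative crossings are used by default; `polarity = "both"` is available.
* *"1 s binning."* Interpreted as the bin width for rate computation (rates
  are mean counts over 1-s bins), not as a property of thresholding.
* *Baseline estimator.* Plain sample SD of the first second; a MAD-based
  robust option (`robust = TRUE`) exists for spike-contaminated baselines.
* *Dead time.* 2 ms; a standard refractory assumption that prevents double
  counting of one biphasic waveform. Not part of the original description.

**Activity filtering.** An electrode is *active* if it fires ≥ 10 spikes/min
and registers at least one spike ≥ 20 µV; a well is *active* if ≥ 1 electrode
is active, and only active wells enter analysis. The amplitude phrase
("minimum amplitude of 20 µV") is ambiguous between per-spike filtering and
per-electrode gating; meadev gates the electrode (any spike ≥ 20 µV) and does
not discard individual spikes.

**Burst detection** uses the max-interval method with the standard
parameters: max ISI to start 50 ms, max ISI to end 50 ms, min interburst
interval 100 ms, min duration 50 ms, min spike count 4. The three phases run
in the fixed order *detect → merge → filter*; the order materially changes
results and this is the convention under which the five parameters are
usually quoted. Burst boundaries are first/last spike times.

**Network bursts** are maximal intervals during which ≥ 3 of the well's 12
electrodes are simultaneously inside a single-electrode burst.
"Simultaneously" is operationalized as overlapping burst intervals
(half-open, exact interval sweep; a 1-ms occupancy grid is the test oracle).
Network bursts closer than the 100 ms merge gap are merged; no separate
minimum network-burst duration is imposed. A network burst's spike count
includes only spikes inside the interval.

**Features.** Nine per-well features: % active electrodes, spike rate, mean
ISI, burst rate, burst duration, % spikes in bursts, mean IBI (end of one
burst to start of the next), network-burst rate and duration. Per-electrode
features are computed per electrode and then averaged over the well's
*active* electrodes (the "well average"); network features are well-level
quantities and are not re-averaged. Features whose defining events are
absent are reported missing rather than zero — except % spikes in bursts,
which is a true 0 when spikes exist but no burst does.

## 2. The synthetic culture generator

The generator exists because the recordings behind the published
trajectories are not public: it produces ground-truth-annotated spike trains
(and optionally voltage traces) whose *pipeline-recovered* statistics match
the published developmental curves, so every stage is testable end to end.

Each electrode superposes

* a homogeneous Poisson *tonic* train,
* *own bursts*: Poisson-arriving events, each a regular train at the
  intra-burst ISI, with a 150 ms minimum gap between burst intervals
  (> the 100 ms merge parameter) so generated bursts map one-to-one to
  detected bursts,
* *network events*: well-level Poisson events recruiting every healthy
  electrode, onsets jittered uniformly within ±10 ms (well inside any
  plausible synchrony window).

Electrodes are independently *silent* with probability
`1 − active_electrode_prob`; silent electrodes scale tonic and burst rates
by 0.02, draw spike amplitudes below the 20 µV activity criterion
(Normal(14, 3²) µV truncated to [5, 18]) and do not join network events.
The sub-criterion amplitudes are a deliberate addition: at high-rate days a
0.02-scaled rate alone can still exceed 10 spikes/min, and the activity rule
must cleanly separate silent electrodes for the %-active calibration to
hold. Healthy amplitudes are Normal(60, 10²) µV truncated at 25 µV —
comfortably above both the 20 µV criterion and the 5σ detection threshold at
the default 8 µV noise. Voltage rendering adds a biphasic negative-leading
template (1.5 ms width) at each spike over white Gaussian noise; the first
second is kept spike-free so the baseline-noise window is uncontaminated,
and rates are rescaled by `T/(T − 1)` so expected counts over the full
recording are unchanged.

**Calibration.** The two shipped profiles (`"cln3"`, `"corrected"`) are
stored as piecewise-linear *measured-feature* trajectories anchored to the
published peaks and phase means (e.g. corrected spike rate peaking at
15.02 Hz on DIV 25, network-burst rate peaking at 3.09/min on DIV 15), and
are inverted day by day into generator parameters in closed form:

* per-electrode network participation rate = network event rate (all healthy
  electrodes participate);
* own-burst rate = burst rate − network rate; own-burst duration from the
  burst-duration mixture (own and network-participation bursts);
* intra-burst ISI solved so the expected in-burst spike rate matches
  `spike rate × %-in-bursts`; the tonic rate absorbs the small
  discretization residual, so the *total* spike rate is matched exactly;
* `active_electrode_prob` from the printed %-active by inverting the
  active-well conditioning `E[X/12 | X ≥ 1]`, X ~ Binomial(12, p) — wells
  with no active electrode are excluded by the inclusion rule, which floors
  the conditional mean at 1/12.

Feasibility constraints shape the trajectories where the publication is
silent: the own-burst duty cycle is kept below ~0.7% so coincidental
3-electrode overlaps stay negligible against true network events; tonic
rates stay ≲ 2 Hz so spurious max-interval bursts from tonic spikes remain
rare; the intra-burst ISI stays in [3, 45] ms with ≥ 4 spikes per own burst.
Within those constraints some printed non-anchor summaries are knowingly not
reproduced: mean ISI and spike rate are reciprocally tied in the generator
(the publication reports them as independent summaries), IBI is emergent
rather than calibrated, the corrected %-spikes-in-bursts away from its
DIV-19 anchor runs higher than printed at high-rate days, and the CLN3
burst-duration trajectory after DIV 11 is inflated by network participation.
Anchors not printed anywhere are authored once as plausible developmental
shapes and frozen.

**What a green recovery test establishes** — that detection, burst logic,
activity filtering, averaging and phase summaries jointly recover known
ground truth from data with realistic rates, burstiness, synchrony and
noise. It does not establish robustness to features real MEA data have and
the generator lacks: electrode drift, LFP and oscillatory backgrounds,
waveform overlap/multi-unit activity, inter-electrode correlation outside
network bursts (assumed independent), and non-Poisson interval statistics.

## 3. Longitudinal trajectory model (gamma GAM)

Each well-day feature value is modeled as gamma-distributed with log link,
smoothed over DIV with a cubic regression spline per genotype plus a
genotype intercept (the published curves have genotype-specific shapes, so a
shared smooth plus offset would be misspecified). The penalty is the natural
cubic spline second-derivative penalty plus a *shrinkage* term: ε = 10⁻³
(relative to the penalty's largest eigenvalue) times the identity on the
penalty null space, so that as λ → ∞ the smooth shrinks to zero rather than
to an arbitrary line. Knots (k = 10 by default) sit at quantiles of the
observed days; smooths are centered (sum-to-zero over the data) by
reparameterization, keeping the intercept identifiable.

Fitting is penalized IRLS — for the gamma/log (and gaussian/identity)
family the IRLS weights are identically 1, so each step is a penalized
least-squares solve. λ is selected by GCV, `n·D/(n − edf)²`, on a 40-point
log-spaced grid (10⁻⁴–10⁶), shared across the genotype smooths; REML would
also be defensible but GCV is simpler to implement to tolerance and the
choice is configurable via fixed λ. Dispersion uses the Pearson estimator;
pointwise 95% bands are link-scale fit ± 1.96 SE (penalized-information
covariance scaled by dispersion), exponentiated — no simultaneous-band
correction, matching the pointwise intervals reported alongside such
curves. Genotype comparison is the link-scale difference curve with SEs from
the joint covariance, flagging days where the 95% interval excludes zero.

Zeros: the gamma family excludes them. Well-days with a zero feature value
(e.g. no network bursts) are dropped with a message, mirroring the
active-well inclusion philosophy; the original analysis does not state its
zero handling. Batch is not modeled in the GAM (the description mentions no
random effects there); the well is the analysis unit.

## 4. Bounded-proportion model (zero-inflated beta)

For assays measured as a proportion of cell area in [0, 1) — fluorescent
puncta area per cell — the package fits a two-part model: a logistic model
for exact zeros (optionally conditioned on DIV) and a beta model for
positive values in the mean–precision parameterization Beta(µφ, (1 − µ)φ)
with logit(µ) linear in group, DIV and their interaction. The
parameterization is chosen to match the logit-scale mean description; the
original names none. An optional Gaussian random intercept for culture batch
enters the mean model only (a one-dimensional effect over few batches) and
is integrated out by adaptive Gauss–Hermite quadrature, 9 nodes per batch,
with the conditional mode found by Newton iterations on analytic
derivatives. Maximization is multi-start (3) L-BFGS-B with φ and σ_b on the
log scale; with no random intercept the analytic score is supplied. Wald
standard errors come from the inverse observed information; no profile
likelihood. Numerical guards: the zero-model intercept is bounded at −20
(data with no zeros would push it to −∞), responses equal to exactly 1 are
clipped to 1 − 10⁻⁶ with a warning, and µ is kept inside (10⁻¹², 1 − 10⁻¹²).
The zero process is tested by a likelihood-ratio test between nested fits
(zero model: intercept vs intercept + DIV), χ² with df equal to the
parameter-count difference.

## 5. Numerical details and degenerate inputs

* Spike times are 0-based seconds; burst intervals are half-open
  [t_start, t_end) in storage and overlap logic; boundary comparisons use
  1e-12 tolerances.
* `floor(duration/isi + 1e-9) + 1` guards intra-burst spike counts against
  floating-point underestimation at exact multiples.
* Empty trains, burst-free electrodes and network-burst-free wells
  propagate as empty tables / missing values, never as errors.
* The GCV grid search refits from scratch at each λ; IRLS stops on a
  relative deviance change of 10⁻⁹ (cap 200 iterations, warning on
  non-convergence).
* All simulation is driven by one integer seed; identical seeds give
  bit-identical output. Sub-seeds are derived arithmetically and kept below
  2³¹.

## 6. Known limitations

* The generator's network events recruit all healthy electrodes of a well;
  partial-participation events are supported
  (`network_participation < 1`) but the shipped profiles do not use them.
* Coincidence network bursts (≥ 3 own bursts overlapping by chance) are not
  part of the closed-form ground truth; profile calibration keeps them
  negligible for the corrected line, but for the CLN3 line at peak burst
  rates they make the *measured* network-burst rate exceed the generator
  rate. Only non-anchored quantities are affected.
* The gamma GAM assumes independent well-days; serial correlation within a
  well across days is not modeled.
* Tweedie-type handling of exact zeros in trajectory features is out of
  scope.
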