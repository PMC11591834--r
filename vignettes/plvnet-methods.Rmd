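---
title: "Methods: phase-locking brain networks from multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-locking brain networks from multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plvnet` characterizes how functional brain networks reorganize between two
within-participant conditions — here labelled *comfort* and *fatigue* —
from multichannel resting-state EEG. The pipeline is: zero-phase
preprocessing, phase-locking-value (PLV) connectivity per frequency band
(delta 0.5–4 Hz, theta 4–8 Hz, alpha 8–13 Hz), absolute-threshold network
construction on a grid T ∈ {0.72, …, 0.76}, graph metrics (betweenness
centrality BC, nodal efficiency NE, clustering coefficient CC,
characteristic path length CPL), and paired statistics with
Benjamini–Hochberg false-discovery control. A synthetic EEG generator with
a closed-form expected PLV makes every stage testable without data
downloads. This vignette records the model, the numerical choices, and the
design decisions that were genuinely open.

## The PLV and its two estimators

For two channels with instantaneous phases $\varphi_x(t), \varphi_y(t)$,
the phase-locking value is the modulus of the time-averaged unit phasor of
the phase difference,

$$\mathrm{PLV} = \Big|\tfrac1S \sum_{t=1}^{S} e^{\,i(\varphi_x(t) -
\varphi_y(t))}\Big| \in [0, 1],$$

0 meaning no phase synchrony and 1 perfect locking. With epoched data two
estimators coexist:

* **epoch** (default, the conventional estimator): compute the modulus per
  2-s epoch, then average moduli across epochs;
* **pooled**: one modulus of the grand mean phasor over all samples of all
  epochs.

The epoch estimator carries a finite-sample *modulus bias*: for a true
value $P$ estimated from $n_\mathrm{eff}$ effectively independent samples,
$E|\hat m| \approx \sqrt{P^2 + (1 - P^2)/n_\mathrm{eff}}$, an upward bias
of roughly $(1-P^2)/(2 P n_\mathrm{eff})$. When the phase difference is
temporally autocorrelated (it always is for band-limited signals),
$n_\mathrm{eff}$ per 2-s epoch can be a few dozen, and the bias reaches
several hundredths — identical in both conditions, hence harmless for
paired inference, but material when *absolute* PLV levels are compared
against a fixed threshold grid. The pooled estimator pools
$n_\mathrm{eff}$ across the whole recording and its bias is negligible.
Consequently: inference defaults to the epoch estimator
(`plv_matrix(..., pooling = "epoch")`), while the bundled synthetic-study
configuration and the acceptance script use `pooling = "pooled"` because
they read PLV values on an absolute scale.

Both estimators are invariant to channel amplitude and to any common phase
offset, and epoch-mean-of-moduli ≥ pooled modulus (Jensen). For
independent uniform phases the single-epoch estimate concentrates at the
Rayleigh floor $\sqrt{\pi}/(2\sqrt{S}) \approx 0.04$ at $S = 500$.

## Preprocessing numerics

All filters are cascaded biquads (second-order sections) applied
forward–backward, i.e. zero phase: phase estimates downstream must not be
time-shifted. Direct-form high-order polynomials are numerically unusable
at a 0.5 Hz edge on 1000 Hz data, which is why sections are used.

* broadband: 4th-order Butterworth band-pass 0.5–30 Hz plus an RBJ notch
  biquad at 50 Hz with Q = 30. The designed forward–backward response at
  60 Hz passes ~2% RMS; the test suite asserts agreement with the designed
  response rather than a round number.
* reflection padding: ~9 time constants of the slowest pole, so
  zero-initial-condition transients decay below 1e-4 before the retained
  segment.
* resampling to 250 Hz is Fourier-domain (spectrum truncation), inherently
  anti-aliased for decimation; upsampling is rejected.
* epoching: non-overlapping 2-s windows, trailing remainder discarded.
* artifact rejection: an epoch is dropped when any sample of any channel
  exceeds ±100 µV *strictly* (samples at exactly 100 µV are kept, reading
  "exceeding" literally). ICA-based artifact removal used by EEGLAB-style
  pipelines is intentionally out of scope; amplitude rejection is the only
  cleaning step, a documented fidelity gap.
* common average reference: subtract the across-channel mean per sample.
  CAR is instantaneous and linear, so it commutes exactly with epoching
  and with any linear time-invariant filter; the pipeline applies it after
  rejection, before band filtering.

## Where the analytic signal is computed

The instantaneous phase is the argument of the FFT analytic signal.
`preprocess_phases(..., analytic = "epoch")` computes it per 2-s epoch
(the conventional route); `analytic = "continuous"` band-filters and
Hilbert-transforms the continuous recording and then cuts the *phase*
traces into epochs. The two differ materially only in the delta band: a
2-s epoch holds ~4 carrier cycles, and short-window edge bias deflates
delta PLV by ~0.05, whereas the continuous route recovers all three bands
within ±0.01 of ground truth on synthetic data. The epoched route stays
the default for fidelity to common practice; the bundled study
configuration uses the continuous route.

## The synthetic world

Per band $b$ and channel $c$ the generator emits

$$x_c(t) = \sum_b s_c A_b \sin\big(2\pi f_b t + \psi_b(t) +
\eta_{b,c}(t)\big) + \varepsilon_c(t) + \text{artifacts},$$

with band carriers at 2, 6 and 10.5 Hz and amplitudes 12, 8, 10 µV,
broadband Gaussian noise with SD 2 µV, a shared slow random-walk base
phase $\psi_b$ (cancels in every phase difference), and fixed alternating
source polarities $s_c = \pm 1$. The polarities matter: if all channels
shared one coherent carrier, the common average would *be* that carrier
and CAR would subtract the signal itself, leaving degenerate
noise-dominated phases. With balanced polarities the common average is
nearly signal-free and CAR behaves as it does on real data, where sources
project with mixed orientations.

**Ground truth.** The jitters $\eta_{b,c}$ are zero-mean stationary
Gaussian processes. For any channel pair the phase difference is Gaussian
with variance $v_{xy}$, so the population PLV is the wrapped-normal
characteristic-function modulus $\exp(-v_{xy}/2)$ — exactly, not
asymptotically. With independent channels
$v_{xy} = \sigma_x^2 + \sigma_y^2$ (`expected_plv()`); in general
$v_{xy}$ is any conditionally negative definite kernel, realized exactly
by a latent mixing matrix $A$ with $\|a_x - a_y\|^2 = v_{xy}$ (classical
multidimensional scaling, `coupling_mixing()`).

**Temporal structure.** Idealized i.i.d. per-sample phase jitter cannot be
used for the waveform: it makes the signal broadband FM, and the Hilbert
phase of such a signal does not recover the injected jitter (the analytic
signal adds a Rice-distributed phase perturbation; at $\sigma = 0.5$ the
recovered PLV would overshoot the wrapped-normal value by ~0.08 even
before band filtering, and band filtering clips the jitter sidebands
entirely). The generator therefore smooths the jitter with a Gaussian
kernel of SD 0.2 s, normalized by its exact $\ell_2$ norm so marginal
variances are exact. At that bandwidth the jitter sidebands sit well
inside every analysis band and the full
generate → filter → Hilbert → PLV chain recovers the analytic group-mean
PLV within ±0.015 up to $\sigma = 0.9$. `jitter_kernel_s = 0` restores the
i.i.d. model, which the phase-level statistical tests use.

**The coupling kernel.** The default study world sets, per band and
condition,

$$v_{xy} = a\,(1 - e^{-d_{xy}^2/\tau}) + r\,[\text{different region}] +
b_0,$$

with $d_{xy}$ the 2D scalp distance between electrodes and the region
partition of the 24-channel montage (frontal / temporal / central /
parietal / occipital). The three terms are each conditionally negative
definite, so the kernel is exactly realizable. Comfort calibrates
$(a, \tau)$ to two stated summary levels: the band's mean pair PLV
(0.50–0.51) and the mean of the top 20% of pairs (0.72). Fatigue applies a
uniform synchrony gain $v \mapsto (1-\varepsilon) v$ with
$\varepsilon = 2.5 \times$ the band's condition gap in mean PLV
(0.02–0.04), and relaxes the cross-region penalty $r$ until the fatigue
mean matches its target (0.52–0.54). Every pair therefore strengthens
under fatigue, with a preferential boost of long-range, cross-region
coupling; the fatigue top-20% mean lands at 0.74–0.75, inside the 0.72–0.76
window that motivates the threshold grid.

This structure is the minimal one we found that reproduces the qualitative
network phenomenology of interest: comfort networks at the grid thresholds
are regionally organized and fragment across regions (small CPL, non-zero
CC, low BC), while fatigue networks add near-threshold long-range edges
that bridge regions, raising NE and CC and — because newly *connected*
pairs enter the CPL average at multi-hop distances — raising CPL as well.
A rank-one per-channel coupling profile cannot do this: its threshold
graphs are nested and clique-like, and a denser fatigue graph then always
has a *shorter* characteristic path length.

**Participants and artifacts.** Each participant scales all jitter by a
log-normal factor (SD 0.08 on the log scale) shared across conditions,
preserving the paired design. Artifact windows occur independently per
2-s epoch with probability 0.05 and carry a 0.2-s, 200 µV square pulse on
one random channel; 200 µV (not less) because the 0.5 Hz zero-phase
high-pass attenuates pulse plateaus, and a 150 µV full-epoch pulse would
come out *below* the ±100 µV rejection limit.

**What the generator does not emulate** — hence what a green test does not
establish: volume conduction and reference-dependent zero-lag leakage, the
1/f background spectrum, non-stationarity and state drift within a
recording, ocular/cardiac artifact morphology, per-participant electrode
geometry, and any physiological meaning of the frequency bands. Green
tests establish that the estimators, graph algorithms and inference
machinery do what their definitions say, at effect sizes matching the
published summary levels.

## Graph metric conventions

Edges exist where PLV ≥ T (ties retained). Three edge-length conventions
are supported; the default is `one_minus_w` (length 1 − PLV), the only one
consistent with characteristic path lengths of 0.1–0.7 on networks
thresholded at ~0.75, where a hop costs ~0.25. Clustering is computed on
the binary adjacency exactly as its formula is written; BC, NE and CPL use
the selected distance mode.

* Distances and shortest-path multiplicities come from one Floyd–Warshall
  pass; two path lengths tie when they differ by less than 1e-10
  (relative), needed for counting under floating-point weights.
* BC is normalized by $(N-1)(N-2)/2$ so a star hub scores exactly 1;
  endpoints are excluded.
* NE gives unreachable nodes a zero contribution ($1/\infty$); with
  weighted distances below 1 it may legitimately exceed 1 and is reported
  unclamped (the [0, 1] bound applies in binary mode).
* CPL averages *finite* off-diagonal distances only and errors on a fully
  disconnected graph; `metrics_for_graph()` maps the edgeless case to
  `NA`.
* The whole metric layer is verified against an exhaustive
  simple-path-enumeration oracle (all graphs ≤ 8 nodes, three densities,
  binary and weighted) to 1e-12.

## Statistics

Paired comparisons gate on a Shapiro–Wilk test of the *paired differences*
at α = 0.05 (the differences are what the paired t-test assumes normal):
normal → paired t, otherwise Wilcoxon signed-rank. The signed-rank
implementation uses Pratt zero handling and the normal approximation with
implicit midrank tie correction at n ≥ 10, the exact null distribution
below. Descriptives follow the chosen test: mean (SD) under t,
median (Q1–Q3) otherwise.

Edge-wise maps run a paired t-test per electrode pair regardless of
normality — the convention for mass-univariate maps — with
Benjamini–Hochberg adjustment at q = 0.05 over the 276 pairs ("FDR"
without qualification is read as BH, which is order-invariant). The
threshold-grid and per-channel comparisons use the gated rule.
Significance stars encode p < 0.05 / 0.01 / 0.001. One-tailed variants
test fatigue > comfort. The degenerate all-zero-difference case reports
p = 1; a (numerically) constant nonzero shift reports an infinite t with
p = 0.

Null calibration: across 200 simulated null studies (equal coupling, 18
participants) the mean fraction of BH-significant edges stays at or below
the nominal 0.05 within Monte-Carlo error — this is asserted in the
acceptance suite.

## Known limitations

* The printed condition gaps in mean PLV (0.02–0.04) are small relative to
  18-participant sampling noise. The strict acceptance check "fatigue mean
  ≥ comfort mean in every band × metric × threshold cell" therefore sits
  at the edge of resolvability: at the default seed a handful of cells
  whose true effects are near zero (betweenness at high thresholds) come
  out as statistically null inversions, and that acceptance test reports
  the failure rather than loosening the check. The qualitative finding —
  fatigue values generally higher — holds in every band.
* The epoch-mode PLV estimator's modulus bias means absolute PLV levels
  depend on the estimator; only the pooled mode should be compared against
  absolute thresholds.
* EDF input is not supported (no reader available offline); recordings use
  the plain matrix + JSON sidecar dialect.
* Electrode interpolation and ICA cleaning are not implemented.
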