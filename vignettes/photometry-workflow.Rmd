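---
title: "Methods: behavior-coupled photometry preprocessing, alignment and maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior-coupled photometry preprocessing, alignment and maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fipho)
```

This vignette documents the scientific and numerical choices behind
`fipho`: the signal model, the preprocessing chain, event alignment and
quantification, the spatial maps, and what the synthetic-session
generator does and does not emulate.

## Signal model and preprocessing chain

A fiber photometry rig with three multiplexed excitation wavelengths
yields, after demodulation, three time series on one uniform clock: a
dopamine-dependent channel (465 nm), a calcium-dependent channel
(565 nm) and an isosbestic control (405 nm) that is insensitive to
ligand binding and therefore reports only non-neuronal fluctuations —
motion of the patch cord, coupling-efficiency changes, slow
photobleaching. The preprocessing chain applied to each sensor channel
is:

$$F_{\mathrm{fit}} = a \cdot F_{\mathrm{iso}} + b, \qquad
  \Delta F/F = \frac{F_{\mathrm{filtered}} - F_{\mathrm{fit}}}{F_{\mathrm{fit}}}, \qquad
  z = \frac{\Delta F/F - \mu}{\sigma}$$

with $(a, b)$ the ordinary-least-squares fit of the filtered sensor on
the filtered isosbestic. Both sensor channels are regressed against the
*same* isosbestic trace, matching dual-color rigs that multiplex a
single 405 nm control. The isosbestic channel itself is filtered but
carries no ΔF/F.

Key parameters (all config-exposed):

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `cutoff` | 10 | Hz | Sensor kinetics live well below 10 Hz; higher frequencies are demodulation noise. |
| `order` | 2 | — | Gentle rolloff avoids ringing on fast transients; the order is deliberately low. |
| `zero_phase` | TRUE | — | Forward–backward filtering has no group delay, so "time point 0" is not biased by the filter. A single-pass mode exists for strictly causal use. |
| `zscore_window` | `"full"` | s | Self-paced exploration has no clean pre-stimulus baseline; normalizing over the whole recording is the robust default. A `[t0, t1]` baseline window is available when a stimulation-free period exists. |
| `dff_floor` | `1e-12 · median(|F_fit|)` | raw units | ΔF/F is undefined at a zero baseline; demodulated signals are strictly positive, so the floor only trips on pathological inputs. |

Numerical choices:

* **Z-score uses the population SD** (divide by $n$), so the
  full-window Z-score is exactly mean 0 / SD 1 (to $10^{-9}$), a
  property the tests assert.
* **Zero-phase filtering** subtracts the endpoint-matched line,
  odd-reflects the residual at both ends (pad length
  $\lceil 15 f_s / f_c \rceil$ samples, enough for the zero-state
  transient to decay below machine precision), filters forward and
  backward, and adds the line back. A zero-phase symmetric filter with
  unit DC gain passes linear trends exactly, so constants and slow
  bleaching trends are preserved without edge plateaus. Like all
  reflection-padded schemes, a short settling stretch (a few filter
  time constants) at the extreme ends remains for signals whose local
  mean differs sharply from the endpoint value; steady-state quantities
  are therefore measured away from the first and last second in the
  tests.
* **Whether μ/σ include the home-cage connection period** is a genuine
  design fork; the default normalizes over the entire recording
  (connection period included), and a `zscore_window` restricted to the
  trial reproduces the trial-only convention. Neither is asserted as
  canonical.
* Percent change (`dff_percent()`, $100 \cdot \Delta F/F$) is provided
  as the only alternative relative measure.

## Event referencing, selection and alignment

Events are referenced retrospectively in a one-row spreadsheet whose
headers are the frozen contract: `start`/`end` for the trial,
`start1`/`end1`, … per event (suffix order is event order), metadata
columns `odorant`, `hedonics`, `condition`, and an optional `type` (or
per-event `typeN`) label such as `"hole"` (olfactory investigation) or
`"edge"` (escape). Headers are case-insensitive; CSV and xlsx are both
accepted. Times are seconds on the photometry clock — all devices are
assumed started together; a constant `time_offset` covers rigs where
they are not. Event intervals are closed-open `[t_start, t_end)` when
mapped to samples, so adjacent events never double-count a boundary
sample.

Alignment maps each onset to the *nearest sample at or before*
`t_start` (floor, no interpolation): causality is preserved because no
post-onset information can leak into pre-onset samples, at the cost of
at most one sample of quantization — negligible at tens of Hz against
behavioral timescales. Windows are fixed `[-pre, +post]` (default 2 s
each side; only the AUC sub-windows are prescribed by the analysis,
the display window is free); events whose window leaves the recording
are dropped and counted, never padded, because sentinel padding would
distort ensemble means. Duration-normalized (time-warped) alignment is
deliberately not offered.

Group averages can pool **by event** (sessions with more events weigh
more) or **by animal** (average within session first). Both are
provided because the weighting genuinely changes group means when event
counts are unequal; neither is asserted as the canonical choice, and
`before_during()` likewise accepts either unit (per-event rows of one
ensemble, or per-animal mean traces), defaulting in the CLI to the
animal-mean path.

## AUC windows and the gated paired test

Responses are quantified as the trapezoidal integral of the Z-score
over a *before* window (−0.6 to −0.3 s) and a *during* window (0 to
+0.3 s); the 300 ms length corresponds to the duration of a single
sniff, and the before window is deliberately offset from onset so that
pre-onset anticipation does not contaminate it. The trapezoid is
computed on the sample grid with linear interpolation of the trace at
the exact window endpoints: exact for piecewise-linear traces,
additive over adjacent windows to $10^{-12}$, and free of
grid-dependent bias when 0.3 s windows meet arbitrary sampling rates.

Paired comparisons are gated by a Shapiro–Wilk test on the paired
differences at $\alpha_{\mathrm{normality}} = 0.05$ (config-exposed): a
paired t-test when normality is not rejected, a paired Wilcoxon
signed-rank test otherwise. Sidedness is always caller-specified — the
CLI refuses to default it. Degenerate inputs are flagged rather than
fatal: all-zero differences report $p = 1$ with a warning; constant
non-zero differences have zero variance, so the t statistic is
reported as $\pm\infty$ with $p = 0$ in the direction of the shift
(1 against it). No multiple-testing correction is applied.

## Board coordinates, zones and occupancy-normalized maps

Two reference points at the bottom corners of the (square) board fix an
affine transform — translation, rotation, uniform scale — from pixel to
board-normalized coordinates: P1 → (0, 0), P2 → (1, 0), y increasing
upward (pixel coordinates are image-style, y down). The transform is
invariant to rigid camera motion, which is the point of the reference
marks. Points outside the unit square are clamped and flagged.

Zones are a disc (`zone_disc()`, default center (0.5, 0.5), radius
0.08 — the odorized hole) or a border band (`zone_edge()`, default
width 0.1 — escape posture at the board edge). The exact hole radius
and band width used with any particular apparatus are not recoverable
from coordinates alone, so these are declared defaults, not inferred
values. Zone-entry detection turns maximal runs of in-zone frames of at
least `min_duration` into frame-accurate events
(`[first/rate, (last+1)/rate)`); tracking gaps and missing frames break
runs, and a single out-of-zone frame separates two events.

Maps bin the trajectory on a `grid_n × grid_n` grid (default 32;
half-open bins with the top/right edge closed so every point falls in
exactly one bin). Occupancy accumulates `1/frame_rate` per non-gap
frame, so total occupancy equals tracked time exactly. Each photometry
sample is assigned to the bin of its temporally nearest tracking frame;
`signal_sum` accumulates Z-scores and `signal_norm` is the per-sample
mean Z in the bin — the occupancy-normalized map, independent of dwell
time by construction. (On commensurate clock rates this equals
`signal_sum / (occupancy × sampling_rate)`; the per-sample-mean
definition keeps the normalization exact for any rate pair.) Unvisited
bins are `NA`, never zero-filled, so empty board regions cannot be
mistaken for zero signal.

## What the synthetic generator emulates

`simulate_session()` draws a complete session: a 2-min home-cage
connection period followed by a 2-min trial (250 s total at 100 Hz
photometry / 25 Hz video), 8 hole-investigation events of 0.3–3 s
separated by ≥ 2 s, and channels composed as

`baseline · exp(−t/τ_bleach) + s_ch · artifact + Σ transients + noise`

* **Photobleaching** `τ_bleach = 3000 s`: prebleached patch cords and
  short sessions give only a slow within-session decline (~8 % over
  250 s).
* **Shared motion artifact**: Gaussian noise low-passed at 2 Hz,
  SD 0.05 raw units, entering each channel with a scaling proportional
  to its baseline (1, 1, 0.75 for baselines 2, 2, 1.5). Coupling
  fluctuations scale with the fluorescence each channel carries, which
  is also the regime in which isosbestic regression is exactly the
  right correction — the generator is the model the method assumes.
* **Transients**: double-exponential kernel
  $e^{-t/\tau_d} - e^{-t/\tau_r}$ with $\tau_r = 0.05$ s,
  $\tau_d = 0.4$ s (peak ≈ 0.12 s), the standard phenomenological shape
  for dopamine/calcium indicator responses; amplitudes 0.05 raw units
  (≈ 2.5 % ΔF/F) with lognormal event-to-event variation (CV 0.3) so
  amplitude-ordering recovery is testable. Sensors only; the isosbestic
  carries none.
* **Noise**: white, SD 0.005 raw units per channel.
* **Trajectory**: reflected random walk (step SD 0.02 per frame)
  pinned inside the hole zone exactly during scheduled events, with 2 %
  of frames lost as tracking gaps; written out in pixel coordinates of
  a 400-px board with image-style y.

`recovery_report()` closes the loop: artifact correlation before/after
regression, onset-alignment lag, and Spearman correlation between
injected amplitudes and per-event during-window AUCs. The alignment lag
is estimated by cross-correlating the ensemble mean with the
ground-truth kernel template (with parabolic sub-sample refinement)
rather than by the raw argmax: the mean of a few noisy events has a
flat top, so a single-sample argmax is ill-conditioned while the
matched-filter lag integrates the whole transient shape.

What the generator does **not** emulate: biophysical sensor kinetics
and bleaching of the sensor distinct from the fluorophore, hemodynamic
contamination, photon shot noise (noise here is additive Gaussian),
spectral cross-talk between the two sensors, and real posture (the
"escape" edge posture cannot be expressed in point coordinates).
Passing tests therefore demonstrate that the pipeline is correct under
its own model assumptions — shared, linearly-coupled artifacts and
additive transients — not that those assumptions hold for any
particular rig.

## Statistical validation sizes

The operating characteristics of the gated paired test are measured on
miniature sessions (36 s at 40 Hz, 6 events, unit = event) so that the
full loop — simulate, preprocess, align, integrate, test — runs in a
few tens of milliseconds per replicate: 500 null replicates for the
type-I error (expected near the nominal 0.05; the gate makes it only
approximately nominal at n = 6) and 200 replicates per amplitude
(1×/2×/4× of 0.001 raw units) for the power curve, which spans the
informative range between floor and ceiling at these sizes. Artifact
rejection is checked on 20 full-size sessions.

## Known limitations

* No spectral demixing or cross-talk correction between the two sensor
  channels; residual cross-excitation biases ΔF/F identically to any
  single-isosbestic workflow.
* The isosbestic regression removes exactly the artifact component that
  is linearly shared with the 405 nm channel; artifacts with
  channel-specific dynamics (e.g. wavelength-dependent bending loss)
  leave residuals.
* Event transients that chance-correlate with the artifact within a
  short session perturb the fitted slope slightly; on synthetic
  sessions the residual |corr(ΔF/F, artifact)| is ~0.05 on average and
  can approach 0.1 on unlucky seeds.
* The board is assumed square; non-square boards would need a third
  reference point, which is not implemented.
* HDF5 vendor exports are not read directly; convert to CSV/TSV first.
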