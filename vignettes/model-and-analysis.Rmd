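---
title: "An embryonic preBötC pacemaker neuron: model, measurement pipeline and virtual experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An embryonic preBötC pacemaker neuron: model, measurement pipeline and virtual experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Inspiratory pacemaker neurons of the preBötzinger complex burst rhythmically
even when chemically isolated from their network. Two conductances dominate
their burst generation: the persistent sodium current `I_NaP` (blocked by
riluzole), which favours short, oscillatory drive potentials, and the
calcium-activated nonspecific cation current `I_CAN` (blocked by flufenamic
acid or 9-phenanthrol), which favours long plateau drive potentials with
depolarization block. `prebotsim` implements a single-compartment
conductance-based model of such a neuron, the measurement pipeline that turns
voltage or ΔF/F traces into per-burst statistics and phenotype labels, and
the virtual experiments built on both.

## The model

The membrane equation balances seven currents (outward positive):

$$C_m \dot V = -(I_{Na} + I_K + I_L + I_{NaP} + I_{Ca} + I_{CAN} + I_h) + I_{app}$$

with

* $I_{NaP} = g_{NaP}\, m_\infty(V)\, h\, (V - V_{NaP})$ — persistent sodium,
  activation instantaneous on a sigmoid with midpoint −40 mV and slope
  −6 mV, slow inactivation $h$ with midpoint −48 mV, slope 5 mV and a
  bell-shaped time constant peaking at 10 s;
* $I_{Ca} = g_{Ca}\, m_\infty(V) (V - V_{Ca})$ — a small non-inactivating
  calcium current sharing the NaP activation function (it tracks average
  calcium entry during a burst);
* $I_{CAN} = g_{CAN} \frac{[Ca]_i}{[Ca]_i + K_{CAN}} (V - V_{NaP})$ —
  calcium-activated, half-active at 0.74 µM;
* $I_{Na} = g_{Na}\, m_{\infty,Na}^3(V) (1-n)(V-V_{Na})$ and
  $I_K = g_K n^4 (V - V_K)$ — the fast spiking pair, with the standard
  reduction that uses $1-n$ for sodium inactivation;
* $I_L = g_L (V - V_L)$ — leak; $I_h$ exists in the interface but defaults
  to zero conductance because no parameter value is available for it.

All gating steady states are the sigmoid
$x_\infty(V) = 1/(1+\exp((V-V_x)/s_x))$ and all gating time constants the
even function $\tau_x(V) = \bar\tau_x / \cosh((V-V_x)/2s_x)$, applied to
both $h$ and $n$.

Calcium is handled by a two-pool model: cytosol and endoplasmic reticulum
exchange through IP3-receptor release (a cubic gate in IP3, cytosolic
calcium and the slow inactivation gate $l$) plus a passive leak, and SERCA
re-uptake; the plasma membrane adds influx proportional to $I_{Ca}$
($J_{PM,in} = -\alpha I_{Ca}$) and PMCA extrusion. The state tracks
$[Ca]_i$ and the total calcium content $[Ca]_{tot}$, with
$[Ca]_{ER} = ([Ca]_{tot}-[Ca]_i)/\sigma$. With IP3 fixed at 1 µM the ER
subsystem is an intracellular oscillator in its own right: the IP3-receptor
gate slowly recovers, a release episode raises cytosolic calcium for a few
seconds, and SERCA/PMCA clear it. `I_CAN` converts this calcium rhythm into
plateau-shaped depolarizations, while `I_NaP` supports faster bursting of
the classic square-wave-relaxation type. The balance of `g_NaP` and `g_CAN`
therefore decides the discharge phenotype.

### Design choices in the model equations

Three points of the published description required a decision, made once
and kept:

* **Spiking subsystem.** The printed minimal membrane equation lists only
  `I_NaP`, `I_K`, `I_Ca`, `I_CAN`, `I_h`, yet the parameter table supplies
  full fast-sodium and leak parameters and every model trace shows action
  potentials. We implement the membrane equation with the classic
  Butera-style spiking pair above ("reconciled" mode). The activation
  midpoint/slope of the fast sodium current and of the delayed rectifier
  (−34/−5 mV and −29/−4 mV) follow that antecedent model, since the table
  gives none; using the shared NaP activation for the fast sodium current
  instead leaves the membrane pinned at a stable depolarized fixed point
  with no spikes at any conductance balance. The literal printed equation
  is retained as `spiking_mode = "as_printed"`; it has no spike-generating
  mechanism and is silent at the reference conductance balances — a
  discrepancy the test suite asserts explicitly rather than hiding.
* **Sign of ER release.** $J_{ER,in}$ is defined as flux *into the cytosol*;
  we apply it with that sign in the $[Ca]_i$ balance. The opposite sign
  would make IP3-receptor release *lower* cytosolic calcium, destroying the
  calcium-induced-calcium-release feedback on which the plateau regime
  rests.
* **Units and the flux scale.** Electrical units are mV/ms/nS/pF/pA (so
  nS·mV = pA and pA/pF = mV/ms) and calcium is in µM. The published pump
  and permeability rates carry mutually inconsistent units, so they are
  folded into one effective cytosolic rate scale: the flux terms are
  multiplied by $f_i/V_i$ and one global dimensionless factor `flux_scale`.
  That factor is the model's only calibrated constant. Calibration
  criterion: with every other parameter at its published value and
  $g_{NaP} = 2.5$ nS, the model must express the three canonical regimes at
  the published anchors — plateau at $g_{CAN} = 2.5$ nS, mixed at 1 nS,
  oscillatory at 0 nS. The anchors are reproduced for `flux_scale` anywhere
  in [0.45, 0.53]; the default is the window centre, 0.5, and the anchor
  labels are insensitive to ±2% perturbation of every conductance.

## Numerical integration

`simulate()` integrates the six-state system with `lsoda` (adaptive,
stiff-capable) at relative/absolute tolerances 1e−8/1e−10, samples the
solution every 0.5 ms (fine enough to resolve action potentials), and
discards the first 6 s as initialization transient; the default run is 46 s
of model time, leaving a 40 s analysis window. The right-hand side is
compiled C for speed, with a pure-R reference implementation
(`model_rhs()`) kept in exact agreement — the test suite cross-checks both
against frozen independent evaluations and along trajectories. Runs are
deterministic. The default initial state rests at −60 mV with gates at
their fixed points, 0.05 µM cytosolic calcium and a loaded ER (≈10 µM);
classifications are insensitive to ±5 mV perturbations of the initial
voltage, and doubling the discarded transient changes no regime label.
Under tolerance halving the burst period moves by well under 1%.

## Burst measurement and phenotype classification

The drive-potential (DP) pipeline mirrors how an electrophysiologist would
quantify these recordings, with every convention explicit in
`classifier_config()`:

1. **Spikes**: upward crossings of −20 mV separated by ≥2 ms.
2. **Envelope**: 50 ms running median — long enough to remove riding
   spikes, short enough to keep DP edges; near-identity on spike-free
   traces.
3. **Baseline**: the histogram mode of the envelope, searched in the lower
   half of its range (so high-duty-cycle discharge cannot promote the
   plateau level to "baseline"), refined to the local mean to remove bin
   quantization.
4. **Events**: maximal intervals with envelope ≥ baseline + 20% of the
   peak-above-baseline, merged across gaps <0.2 s; excursions under 5 mV
   are treated as noise, so a flat or noisy-flat trace yields no events
   rather than an error. DP duration is the time spent above that
   threshold; DP amplitude is the envelope peak over the event, estimated
   as the mean of the envelope's top 20% band (for the flat-topped DPs in
   question this equals the plateau height while averaging out residual
   filtered noise; synaptic-current envelopes, which are smooth bumps, use
   the raw per-event maximum instead).
5. **Per-event class**: plateau-like if duration ≥1.5 s — between the two
   canonical duration means (0.79 s and 2.9 s), several per-cycle SDs from
   either — or if the event shows depolarization block (all spikes within
   the first 40% of the event and a suprathreshold envelope persisting ≥1 s
   beyond the last spike). Otherwise oscillatory-like.
6. **Trace label**: `silent` (no events, no sustained spiking), `tonic`
   (spiking with no quiescent inter-burst period), `plateau` or
   `oscillatory` (≥80% of events in one class), `mixed` (both classes at
   ≥20%), or `indeterminate` for an active trace with fewer than 3 events
   in the window — kept as its own category rather than forced into a
   phenotype.

Classification is invariant to DC offset, uniform time shift and
resampling at twice the rate.

## The regime map

`classify_point()`, the two sweeps and `compute_regime_map()` chain
simulation and classification over the $g_{NaP} \times g_{CAN}$ plane
(default grid 0–3 × 0–4.5 nS at 0.25 nS, one 46 s run per point; the
points are independent, and per-point solver failures would be recorded as
indeterminate rather than aborting the map). With the calibrated defaults:

* the three anchors classify plateau / mixed / oscillatory;
* the $g_{CAN}$ sweep at $g_{NaP} = 2.5$ nS orders the bands oscillatory →
  mixed → plateau with no re-entry;
* the $g_{NaP}$ sweep at $g_{CAN} = 1.5$ nS reproduces the plateau → mixed
  progression with increasing $g_{NaP}$, but its two extremes deviate from
  the published description: at low $g_{NaP}$ the cell is weakly active
  (one or two ICAN-driven events per 40 s window → indeterminate, not
  silent), and a purely oscillatory regime never appears by 5 nS, because
  the ER calcium oscillator — and with it occasional ICAN plateau events —
  persists no matter how strong `I_NaP` becomes at this `g_CAN`. The
  corresponding acceptance check is deliberately left failing rather than
  weakened; we consider the discrepancy informative about the published
  figure's boundary conventions, which are not described.

## Synthetic data: what it emulates and what it does not

`generate_trace()` builds voltage traces as baseline + square DPs +
stereotyped triangular spikes + white noise (1 mV SD by default, a typical
magnitude for filtered whole-cell recordings), with per-cycle draws:

* plateau template — amplitude N(30.5, 6.6) mV, duration N(2.9, 0.35) s,
  baseline −52.7 mV, spikes confined to the first 35% of each event
  (depolarization block);
* oscillatory template — amplitude N(12.8, 3.8) mV, duration
  N(0.79, 0.12) s, baseline −49.2 mV, spikes throughout;
* mixed template — a two-component mixture of the above with plateau weight
  0.45, which reproduces the published mixed-phenotype means (≈14.5 mV,
  ≈1.74 s); each trace realizes the weight exactly (rounded count, seeded
  shuffle), so per-trace ground truth is never itself a random variable.

Where the source statistics are SEMs over known cycle counts, per-cycle SDs
were back-computed or fixed at a value consistent with the published
per-cycle histograms (duration SD 0.35 s for plateau, 0.12 s for
oscillatory); the amplitude spreads are used directly as per-cycle SDs.
Cycle periods are not reported quantities; 8 s (plateau), 4 s
(oscillatory) and 5 s (mixed) are fixed realistic choices. Amplitude draws
are floored at max(6 mV, mean − 2.8 SD) so that every generated event stays
above the pipeline's detection threshold (the floor moves the plateau mean
by <0.1 mV); periods are stretched where necessary so consecutive DPs stay
≥0.6 s apart. One caveat is intrinsic to the single global onset threshold
(20% of the trace's peak): in *mixed* traces the plateau events set that
threshold, and a small oscillatory event (≈ below 9 mV) can fall under it —
with the default templates about 3–5% of mixed-trace events go unmeasured,
which is why the per-event accuracy checks match measured events to ground
truth by onset.

Every artifact ships its ground truth and all randomness flows from one
seed. These traces emulate the *statistical* structure of the recordings —
amplitudes, durations, periods, spike placement, noise floor — not their
biophysics: no real afterhyperpolarizations, no slow drift, no electrode
artifacts, no cell-to-cell correlation. A passing round trip therefore
validates the measurement pipeline's conventions and estimators, not the
model, and says nothing about performance on recordings whose envelopes
are not approximately flat-topped.

`generate_dff()` renders a burst rhythm as an indicator trace: unit
impulses at burst onsets convolved with a 1 s single-exponential decay,
sampled at 0.1 s frames with additive noise — a deliberately minimal
photophysics. `generate_drive_current()` produces smooth synaptic-envelope
bumps with drawn amplitudes for the drive-current estimator.

The packaged populations fix the stage compositions: 3 plateau / 9 mixed /
23 oscillatory of 35 cells at E18.5 (published counts; 23/35 = 65.7%
oscillatory), and 13/1/13 of 27 at E16.5 — an interpolation consistent
with "plateau and oscillatory nearly equally present" and the published
total, since no per-subtype breakdown is available for that stage. The
E16.5 composition is synthetic in that specific sense and is labelled as
such in the documentation.

## Imaging classification

The original rhythmicity software behind the calcium-imaging decision tree
is not described anywhere, so this module is a functional stand-in with
declared conventions: rhythmicity is the height of the best non-zero-lag
autocorrelation peak of the detrended ΔF/F trace within periods 1–20 s
(threshold 0.3); phase locking is a peak normalized cross-correlation ≥0.3
within ±0.5 s of lag (signed by default; an absolute-value mode exists for
inverted indicators). The decision tree is: inspiratory = rhythmic AND
phase-locked in control; pacemaker = still rhythmic under synaptic
blockade, where phase locking is *not* required (isolated pacemakers run
at their own frequency); riluzole then splits pacemakers into
`ril_sensitive` (I_NaP-dependent) and `ril_resistant` (presumed
I_CAN-dependent). FFA is excluded from imaging classification because the
blocker itself degrades the calcium signal.

## Virtual pharmacology and population statistics

Drugs act as pure conductance scaling — riluzole on `g_NaP`, FFA and
9-phenanthrol on `g_CAN`, each by a configurable efficacy (default: full
block); the synaptic-blockade cocktail is a documented no-op on a
single-cell model. There is no kinetics and no off-target action. On the
model this reproduces the observed selectivity: riluzole silences the pure
`I_NaP` oscillator, CAN block silences the pure `I_CAN` configuration, and
on the mixed configuration FFA leaves a purely oscillatory discharge while
riluzole leaves no oscillatory-class events. One nuance: riluzole on the
mixed configuration silences the cell entirely within the 40 s window,
because at `g_CAN = 1` nS the calcium events are themselves paced by
spiking-driven calcium influx — the per-event census tests therefore assert
that the *matching* class disappears, not that the other class persists.

Stage compositions are compared with Pearson's chi-square on the stage ×
phenotype table, without continuity correction; expected counts below 5
are flagged rather than suppressed.

## Problem sizes and reproducibility

The validation and acceptance computations use the published cycle counts
(343 plateau, 1296 oscillatory, 739 mixed cycles; 35- and 27-cell
populations), one 46 s simulation per conductance point, and the 0.25 nS
sweep resolution. All results quoted above are computed by the scripts
under `analysis/`, the test suite, and `scripts/acceptance.R`; none are
asserted by hand. Every stochastic step takes an explicit seed and is
bit-reproducible.

## Known limitations

* Single compartment, no synaptic input, no channel noise; network-level
  phenomena (developmental changes in network rhythm pharmacology,
  synaptic drive growth) are outside the model and only their measurement
  operators are provided.
* The flux-scale calibration pins the calcium-oscillation timescale to the
  regime anchors; absolute calcium concentrations should be read as model
  units, not measurements.
* The discharge classifier's split (1.5 s), minority fraction (0.2) and
  window conventions are explicit but necessarily somewhat arbitrary at
  regime boundaries; boundary points can flip with small parameter changes
  and few-event windows are reported indeterminate.
* The imaging module approximates an undescribed original analysis; its
  thresholds were chosen for clean separation on synthetic data, not
  fitted to recordings.
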