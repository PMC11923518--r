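---
title: "Models and methods behind fretfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretfp)
```

## The problem

Fiber photometry of genetically encoded FRET sensors reports metabolite
dynamics in vivo — here, neuronal cytosolic ATP (an ATeam-family sensor,
FRET efficiency rising with ATP) and astrocytic cytosolic pyruvate (a
PYRS-family sensor with inverted polarity) — during electrically evoked
epileptic after-discharges (ADs) in the hippocampus. The measured
fluorescence is confounded: blood vessels shadow the tissue, so local
brain blood volume (BBV) changes modulate *every* channel
multiplicatively, and cytosolic pH modulates YFP emission. `fretfp`
implements the full analysis chain (demultiplexing, artifact
correction, event detection, statistics) together with a biophysical
forward simulator, so that every stage can be validated against known
ground truth without animal data.

## Sensor forward model

Ligand binding follows a Hill curve,
$\theta = L^h/(K_d^h + L^h)$, and FRET efficiency interpolates linearly
between the sensor's efficiency bounds:
$E = e_{\min} + (e_{\max}-e_{\min})\theta$ for positive polarity,
mirrored for inverted polarity. The three measured channels are
$f_{CFP} \propto (1-E)$, $f_{YFP} \propto E$, and $d_{YFP}$ (direct
acceptor excitation) independent of $E$. Presets: the ATP sensor uses
$K_d = 1.2$ mM, $h = 1$; the pyruvate sensor $K_d = 26$ µM, $h = 1.2$,
polarity $-1$.

Two constants are not identifiable from the recordings and are
simulator choices: the efficiency bounds ($e_{\min}=0.15$,
$e_{\max}=0.60$, a plausible range for CFP/YFP FRET pairs) and the
resting ligand levels (2.3 mM ATP; 15 µM pyruvate, placing the
pyruvate sensor below its $K_d$ on the steep part of its curve). All
four are exposed in `sensor_params()`.

Transients are parameterized in *fluorescence-%* space and mapped
through the inverse sensor model
(`% change -> efficiency -> occupancy -> concentration`), because the
reported quantities are percentages of basal fluorescence, not
concentrations. This keeps simulator inputs and analysis outputs in the
same units; the round trip is exact up to the $8\tau$ truncation of the
saturating-exponential decline (&lt; 0.04% of the amplitude).

## Demultiplexing

Excitation is time-division multiplexed ("gallop" mode): short pulses
of Blue (~440 nm), Teal (~510 nm) and optionally Yellow (~575 nm)
within each 1 s cycle. `demux()` averages the PMT output within each
pulse window and subtracts the channel's dark level, producing 1 Hz
channel traces. Choices:

* **Edge guard** (default 1 ms per pulse edge): the acquisition
  description averages the whole pulse; trimming the LED rise/fall
  transient is safer and configurable (`edge_guard_ms = 0` restores
  whole-pulse averaging).
* Timestamps at the cycle midpoint; partial trailing cycles dropped.
* Dark-subtracted values may be slightly negative and are preserved —
  they carry noise information.

## Artifact correction: ratio and difference methods

The **ratio method** divides the two FRET channels
($f_{YFP}/f_{CFP}$ for ATP; $f_{CFP}/f_{YFP}$ for pyruvate, so both
proxies rise with ligand). A multiplicative artifact common to both
channels cancels exactly.

The **difference method** subtracts the %-normalized direct-excitation
channel: $f_{YFP}\% - d_{YFP}\%$ (ATP) or $d_{YFP}\% - f_{YFP}\%$
(pyruvate). An artifact acting equally on both YFP channels cancels *to
first order*: if the ligand factor is $\ell$ and the artifact factor
$1+c$, then $f_{YFP}\% - d_{YFP}\% = g + g\,c$ where
$g = 100(\ell - 1)$. The second-order residue $g\,c$ is the method's
intrinsic bias; with artifacts of a few percent and a 20% drop it is a
fraction of a percentage point in magnitude but can shift the *time* of
a flat trough by a few seconds. The simulation studies quantify exactly
this (see `recovery_study()`).

Normalization is applied *before* subtraction (normalize-first), since
raw channel volts have arbitrary, gain-dependent scales. The default
per-episode baseline window is $[-120, -10]$ s relative to stimulation
onset — the acquisition protocol defines no per-episode window, so this
is a documented, configurable choice.

To compare the two methods in shared units, the ratio proxy can be
calibrated into *fYFP-equivalent percent*: given the baseline
efficiency $E_0$ implied by the sensor parameters and resting ligand
level, $r(t)/r_0$ inverts exactly to $E(t)$, and the proxy is reported
as $100\,(E-E_0)/E_0$. This is a model-based calibration — it uses the
sensor constants, not the data being corrected.

## Event detection

* **AD duration** was determined manually in the original workflow;
  `detect_ad_duration()` automates it as an envelope threshold: RMS in
  0.5 s bins, 1 s trailing smoothing, threshold $k = 3\times$ the
  pre-stimulus RMS of the 1–100 Hz band-passed EEG, with a 1 s
  sustained-run requirement. The AD ends at the last supra-threshold
  run. $k$ has no counterpart in the source protocol and is exposed in
  the configuration; a manual `ad_end` annotation always overrides
  detection. The band-pass is a zero-phase FFT-domain filter with
  raised-cosine transitions ($[f_{lo}/2, f_{lo}]$ and
  $[f_{hi}, 1.2 f_{hi}]$); input is padded to a highly composite length
  to avoid the $O(n^2)$ FFT pathology for prime lengths.
* **ATP onset** is the negative peak of the second derivative of the
  proxy (the inflection point), computed after a 5 s centered moving
  average — raw second differences at 1 Hz are noise-dominated. The
  search is restricted to before the negative peak. On the analytic
  sigmoid $-A/(1+e^{-(t-t_0)/\tau})$ this estimator lands at
  $t_0 - 1.317\tau$, which the tests verify.
* **Peak times and magnitudes** are located by exhaustive scan
  (`find_extremum()`, ties to the earliest sample; a monotone trace
  yields the window edge). The episode pipeline locates peaks on a
  lightly smoothed (5 s) copy of the proxy: the argmin of a noisy trace
  is biased deep and temporally jittery, and at 1 Hz a 5 s moving
  average reduces both without displacing the troughs, which are flat
  on that time scale.
* **Pyruvate onset** is a baseline-crossing rule (mean + 2 SD for 2
  consecutive samples); the source analysis states only "exceeds the
  baseline", so the margin and run length are documented defaults.
* **Triphasic segmentation** finds the end of the rapid first phase
  (slope falls below 25% of its maximum), then the plateau start as the
  first sustained ($\ge$ 30 s) near-zero-slope run using a 5 s-lag
  slope, refined by a two-segment least-squares change-point fit. The
  second phase is classified "rise" when the proxy gains more than 5%
  of the first-phase amplitude after its initial peak.
* **Cumulative Texas Red** integrates the detrended dye trace (linear
  fit over the pre-stimulus window plus data from 300 s post-stimulus,
  excluding the evoked transient) between stimulation onset and either
  the ATP negative peak or the AD end.

## The synthetic world

The simulator's defaults are the stated conditions of the recordings it
emulates: 2 kHz PMT sampling, 1 s excitation cycles (dual
configuration: Blue 20 ms, 10 ms gap, Teal 20 ms; triple: 10/10/30 ms
with 10 ms gaps), 50 Hz / 10 s stimulation trains, early ADs of 5–20 s,
ATP drops of −20.88% (early), −14.72% (fully kindled) and −38.04%
(terminal, non-recovering), ATP-reduction onset 13.5 s after
stimulation onset with the trough near 32 s, pyruvate onset at 2.7 s
with the first peak at 20.75 s and, in "rise" mode, a global maximum
about 60 s after stimulation onset, with a plateau decaying on a
tens-of-minutes scale (Texas Red dye decay constant 45 min).

Values the source does not state were fixed once at desk-scale
realistic levels and are not revisited: the BBV shadow gain (1, with
bump amplitudes of ±5–8% fractional volume, constriction early /
dilation when kindled), a pH (alkalinization) transient of +2–4% on
YFP emission, channel noise of 0.3% of baseline per 1 Hz sample, EEG
background RMS 0.05 with AD oscillations at 10× that RMS across mixed
2–20 Hz components. pH quenching defaults to YFP-only — this produces
the residual mismatch between dYFP and inverted Texas Red seen in real
recordings — with an "equal" mode (same factor on CFP) available, which
is the regime in which both correction methods are unbiased and which
the method-comparison study uses.

What the generator does **not** emulate: photobleaching kinetics,
photon shot noise (noise is additive Gaussian after the PMT/amplifier
chain), hemoglobin absorption spectra, motion artifacts, and spontaneous
(non-evoked) seizures. A green test therefore establishes correctness
of the pipeline's arithmetic and its robustness to the modeled
confounds — not robustness to every artifact of real recordings.

## Statistics

Welch's $t$ is computed from summaries as
$t = (m_1 - m_2)/\sqrt{sem_1^2 + sem_2^2}$; the sample-based version
agrees with it exactly by construction. Two degrees-of-freedom variants
are reported: Welch–Satterthwaite (drives the p value) and pooled
$n_1+n_2-2$, because published legends sometimes print the pooled df
under a Welch label (e.g. df = 8 for groups of 3 and 7, where
Welch–Satterthwaite gives ≈ 6.1; the t statistic is unaffected). All
tests are two-sided; no multiple-testing correction is applied (none is
described in the source workflow); a Shapiro–Wilk gate is provided for
the normality assumption.

## Known limitations

* The difference method's second-order residue ($g\,c$) is inherent to
  subtracting percentages of a multiplicative artifact; with the
  default confound scales the origin-constrained slope between
  difference- and ratio-method peak *times* sits near 0.91 — within the
  documented 0.9–1.1 equivalence band, but close to its edge.
* The ratio calibration to fYFP-equivalent percent depends on the
  assumed baseline efficiency; mis-specifying $E_0$ rescales (but does
  not re-time) the calibrated proxy.
* AD detection assumes the stimulation artifact is confined to the
  annotated stimulation interval.
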