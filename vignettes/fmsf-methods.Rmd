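---
title: "Methods: FMSF trace analysis, cohort statistics and the synthetic-data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FMSF trace analysis, cohort statistics and the synthetic-data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmsf)
```

## The measurement and its model

Flow-Mediated Skin Fluorescence (FMSF) records the autofluorescence of
reduced NADH emitted from forearm skin, sampled at 25 Hz, while a brachial
cuff imposes a transient ischemia. NADH fluorescence rises when oxygen
delivery falls and falls during reoxygenation, so the trace is an optical
readout of the coupling between skin microcirculation and mitochondrial
redox state. The canonical protocol has four phases:

1. **baseline** (180 s): resting fluorescence with low-frequency
   microcirculatory oscillations (*flowmotion*);
2. **occlusion** (180 s): cuff at 60 mmHg above systolic; fluorescence
   rises toward an ischemic plateau;
3. **hyperemic window** (first 30 s after release): rapid undershoot below
   baseline as reactive hyperemia floods the tissue with oxygen;
4. **reperfusion** (remaining 150 s): exponential-like recovery toward the
   resting level with resumed oscillations.

`segment_phases()` cuts a trace into these four contiguous half-open
sample intervals; they partition the protocol span exactly. The hyperemic
window defaults to 30 s (the transient lasts roughly 20–30 s in practice)
and is configurable in `fmsf_protocol()`.

## Oscillation analysis

Within an analysis window (baseline, or reperfusion after the hyperemic
window) the signal is decomposed as *level + linear trend + oscillation*:

* `estimate_baseline()` – the resting level is the arithmetic mean of the
  baseline window.
* `detrend_window()` – a least-squares straight line is removed. Linear
  detrending was chosen over polynomial or spline alternatives because its
  two key properties are exactly testable: it annihilates any linear
  drift, and it is idempotent. Content slower than the window can resolve
  is thereby treated as trend, not oscillation.
* `band_decompose()` – a rectangular-window periodogram is computed from a
  single FFT of the whole window (no tapering, no segment averaging).
  This makes Parseval's identity exact: the one-sided bin contributions
  sum to the mean square of the residual, which the test suite verifies
  to 1e-6 relative. A bin with center frequency $f$ is assigned to a band
  when $f_{lower} < f \le f_{upper}$, so the three bands partition
  $(f_{low}, 0.15]$ Hz. Whether device software tapers or averages before
  band integration is not documented anywhere we know of; the single-FFT
  periodogram is this package's documented choice.

The band edges are the conventional attributions of skin flowmotion:
endothelial (NO-mediated) below 0.021 Hz, neurogenic (sympathetic)
0.021–0.052 Hz, myogenic (vascular smooth muscle) 0.052–0.15 Hz. No lower
bound is conventionally quoted for the endothelial band; we use
`low_cut = 0.005` Hz. The rationale: a 180 s window has a fundamental of
≈0.0056 Hz, so slower content is indistinguishable from trend and is
handled by the detrending step. The minimum-window check tied to
`low_cut` is therefore opt-in in `detrend_window()` — the canonical
windows themselves (180 s and 150 s) are shorter than two periods of
0.005 Hz, and insisting on that precondition would reject the protocol's
own windows.

## The derived parameters

With $r(t)$ the detrended baseline residual and $B$ the resting level:

* $\mathrm{FM} = \overline{r^2}$ — mean-square flowmotion, a.u.²;
* ENDO, NEURO, MYO — band components of the baseline periodogram, a.u.²;
* $\mathrm{NOI} = 100\,(\mathrm{ENDO} + \mathrm{NEURO}) /
  (\mathrm{ENDO} + \mathrm{NEURO} + \mathrm{MYO})$ — percent, in [0, 100];
* $\mathrm{IR}_{max} = 100\,(\max_{occl} F - B)/B$ — percent; negative
  values mean the ischemic rise never cleared baseline, the
  mitochondrial-dysfunction flag used for exclusion;
* $\mathrm{HR}_{max} = 100\,(B - \min_{post} F)/B$ — percent, over the
  whole post-release span, floored at 0;
* $\mathrm{RHR} = \mathrm{IR}_{max} + \mathrm{HR}_{max}$. No closed
  formula for RHR is published with the parameter set; the peak-sum
  definition is adopted here because the published pooled patient column
  satisfies it exactly (12.5 + 16.1 = 28.6) and the subgroup columns agree
  within rounding. Whether the device instead integrates an area under
  the excursion cannot be resolved from the available description; the
  peak-sum is recorded as an assumption.
* $\mathrm{FM(R)}$ — mean-square flowmotion of the detrended reperfusion
  window (hyperemic transient excluded); $\mathrm{HS}$ — its myogenic
  band component. HS is reported as an absolute magnitude in a.u.², not
  as a percent of FM(R): published group values of 62–84 with SDs up to
  78 are incompatible with a bounded proportion. The percent version is
  still computed (`HS_pct`) for users who want the proportional reading.
* `logFM`, `logNEURO`, `logHS` — base-10 logs. FM-family magnitudes are
  strongly right-skewed while their logs are approximately normal, so the
  log scale is the natural comparison scale. Base 10 is a readability
  choice; any fixed base preserves normality.

Missing-value policy: a non-computable quantity (log of a non-positive
value, NOI when all three bands are zero) yields `NA` with a warning.
Subjects are never silently dropped; only the explicit exclusion filter
removes them, with a logged reason.

A note on FM(R): after linear detrending, the reperfusion window retains
the curvature of the recovery tail (the exponential return to baseline is
not a straight line). FM(R) therefore includes a trend-residual
contribution alongside genuine oscillation; HS is much less affected
because the curvature's power lies overwhelmingly below the myogenic
band. This is an inherent property of the linear-detrend design, shared
by any implementation that uses it, and is why HS rather than FM(R) is
the primary reperfusion parameter.

## Cohort statistics

`apply_exclusions()` implements the published exclusion rule — remove
subjects with IRmax < 0 (or unmeasurable), then optional sex and
comorbidity restrictions, in order, each removal logged.

`choose_test()` gates on the Shapiro–Wilk test at $\alpha = 0.05$ in both
groups: the two-sample *t*-test when neither group rejects normality, the
Mann–Whitney U test otherwise. `compare_groups()` uses Welch's *t* by
default — group SDs of FMSF parameters commonly differ by a factor of two
or more, which makes the equal-variance assumption indefensible as a
default — with the classical pooled-variance test available by flag. The
Mann–Whitney p-value uses exact enumeration when both groups have ≤ 8
subjects and the normal approximation with tie and continuity correction
otherwise, which keeps results reproducible across implementations at
typical cohort sizes. The gate is applied on the scale actually compared
(e.g. `logFM`, not FM). Seven parameters are compared without
multiple-testing adjustment, and the report says so in a footnote.
`correlate()` applies the same gate to both marginals to pick Pearson
versus Spearman.

Under the null, the full gate-then-test procedure is a mixture of the
*t*-test and Mann–Whitney conditional on a normality pre-test; its size
stays within 2 percentage points of 0.05 at n = 24 vs 17 (verified over
2000 simulated pairs). The gate itself selects the *t*-test at rate
$(1-\alpha)^2 \approx 0.90$ for Gaussian pairs. Against one strongly
skewed group of n = 20 the Shapiro–Wilk test has power ≈ 0.84, so the
fallback rate to Mann–Whitney is ≈ 0.84 with one skewed group and ≈ 0.98
with two; the test suite asserts the rates at these calibrated values.

`summarize_groups()` reports n, mean and sample SD (n − 1) per group plus
a pooled patient column; the pooled mean is by construction the
n-weighted mean of subgroup means, which is what makes the published
pooled column arithmetically checkable. SD for a single-subject group is
reported missing (a sample SD is undefined at n = 1, and 0 would be a
fabrication).

## The synthetic-data model

`simulate_trace()` builds the canonical morphology from interpretable
parts:

* **baseline**: level + tones + white noise. The default level is
  1000 a.u.: skin NADH fluorescence rides on a large DC offset, and
  oscillation amplitudes of order 5–15 a.u. (band powers of tens of
  a.u.²) on that offset give the ~1% relative modulation depth seen in
  real recordings.
* **occlusion**: saturating-exponential rise toward
  $level \times (1 + \mathrm{rise})$ with a 20 s time constant, so the
  plateau is reached well within the 180 s occlusion. A negative rise
  fraction produces a trace that sinks during occlusion and a (slightly)
  negative extracted IRmax.
* **hyperemic window**: an exponential decline calibrated so the minimum
  $level \times (1 - \mathrm{dip})$ is attained *exactly* at the last
  sample of the window. Calibrating the asymptote rather than trusting a
  fixed time constant makes the HRmax ground truth exact instead of
  approximate, which the recovery tests rely on.
* **reperfusion**: exponential recovery (40 s time constant) toward the
  level, with reperfusion tones ramping in under a
  $1 - e^{-t/15\,\mathrm{s}}$ envelope. The envelope reflects the gradual
  resumption of flowmotion after the hyperemic transient and guarantees
  that the global minimum of a noiseless trace stays inside the hyperemic
  window (it keeps the early oscillation amplitude below the recovery
  head-room whenever the summed tone amplitude is below
  $0.375 \times dip \times level$, comfortably true at the defaults).

**Tone placement.** Band content is simulated as 1–3 discrete tones per
band, frequencies drawn uniformly over the band's bins on the Fourier
grid of the analysis window (1/180 Hz for baseline, 1/150 Hz for
reperfusion), restricted to ≥ 2 cycles per window. On-grid tones leak no
power across band edges, so the injected mean square *is* the band-power
ground truth; below two cycles per window, linear detrending absorbs a
large, phase-dependent fraction of a tone (61% worst-case at one cycle),
which would make "ground truth" meaningless. Tone phases are drawn
uniformly. Amplitudes split the drawn band power at random proportions.

**Group draws.** `group_sim_spec()` targets are given as mean ± SD on the
reported scale. Positive, right-skewed magnitudes (ENDO, NEURO, MYO, HS)
are drawn log-normal with moment matching
($\sigma^2 = \log(1 + s^2/m^2)$, $\mu = \log m - \sigma^2/2$), consistent
with the observed normality of the log-transformed parameters. Excursion
percentages (IRmax, HRmax) are drawn normal — IRmax must admit negative
values to reproduce dysfunctional subjects; simulated HRmax is floored at
0. `default_group_specs()` encodes three groups (AA n = 18, AU n = 6,
control n = 17, all female) at values typical of an alopecia areata
case–control cohort. ENDO and MYO, which are not reported separately in
such tables, are apportioned from the FM and NOI targets
(ENDO + NEURO = NOI/100 × FM) with coefficients of variation matched to
FM's. Reperfusion non-myogenic power defaults to 30% of HS so FM(R)
exceeds HS. Per-subject and per-trace seeds derive deterministically from
the master seed, so a cohort is bit-reproducible.

**What the simulator does not emulate** — and hence what passing
recovery tests do and do not show: noise is white (real traces likely
carry correlated 1/f noise, which would bias band estimates low-frequency
upward); there are no cardiac or respiratory components above 0.15 Hz,
no motion artifacts, no skin-temperature or hormonal covariates; band
content in real skin is broadband, not tonal, so real spectral leakage
across band edges is larger than in these simulations. Recovery results
therefore demonstrate the correctness of the analysis chain, not its
robustness to every artifact of real recordings.

## Numerical choices and problem sizes

* Periodogram bin assignment is half-open on the low side; the DC bin is
  excluded (the residual is zero-mean to machine precision anyway).
* `band_decompose()` refuses sampling rates ≤ 0.3 Hz (twice the myogenic
  edge); spectral tests run at 1–5 Hz for speed, which the analysis
  accepts since all bands lie below 0.15 Hz.
* Verification sizes, chosen to make Monte-Carlo checks decisive while
  keeping the whole suite fast: 20 noiseless seeds for parameter
  recovery; a 50-subject cohort at 0.2% relative noise for rank-agreement
  checks; 2000 replicates for the size of the gated test and 100 for its
  power; 400/200 replicates for gate-selection rates. The brute-force DFT
  oracle used against the FFT path runs at N = 600.
* Exclusion-rule checks use the internally consistent recruited roster of
  22 AA + 8 AU women (4 + 2 with negative ischemic response), which
  reproduces the retained counts 18 + 6 = 24.

## Known limitations

* FM(R) includes recovery-tail curvature (see above); comparisons of
  FM(R) across protocols with different recovery kinetics are not
  meaningful.
* The RHR peak-sum definition and the absolute (non-percent) HS scale are
  documented assumptions, not published formulas.
* No age or sex adjustment, no normative ranges, no diagnostic
  classification: the package quantifies traces and compares groups, and
  stops there.
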