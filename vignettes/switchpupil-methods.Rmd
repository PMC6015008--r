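---
title: "switchpupil: methods, parameter choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{switchpupil: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

An infant switch-paradigm session has a familiarization phase (4 blocks of 4
nine-second trials presenting two audio-visual pairings) and a test phase
(five 8-second trials: 2 familiar, 2 switched, 1 novel, with the trial's
sound starting at 3680 ms). A remote eye tracker records both pupils at
120 Hz, so a test trial holds at most 960 samples, and the 4320 ms after
sound onset hold the response of interest.

The analysis treats the baseline-corrected pupil diameter as

\[
y_{ict}(b) = \beta_{ict} + \sum_{r} k_r(b)\,a_{ir}\,[c \in C_r] + \varepsilon,
\]

participant \(i\), condition \(c\), trial \(t\), 50-ms bin \(b\): a
per-trial baseline level \(\beta\) (removed by baseline correction), plus
smooth dilation components \(r\) with participant-specific amplitudes
\(a_{ir}\), each attached to a subset of conditions \(C_r\) — a fast
*perceptual novelty* component in the novel condition and a slow
*association novelty* component in the switched condition. Per bin, the
participant-by-condition means feed a one-way repeated-measures ANOVA; the
within-subject decomposition makes the test invariant to any
participant-level offset, which the permutation machinery preserves (and the
tests verify).

## Preprocessing choices the source description leaves open

The enumerated pipeline order (inclusion, interpolation, 4-Hz low-pass,
binocular averaging, baseline correction, binning) is fixed, but several
details had to be decided:

* **Missing-rate denominator.** Computed *before* interpolation against the
  nominal sample count (960 for test trials); a sample with at least one
  valid eye counts as present, since binocular averaging later uses
  whichever eye is available. Exclusion uses the strict inequality
  (rate < 40% is kept).
* **Leading/trailing gaps** have no flanking sample on one side; they are
  filled by nearest-value hold rather than extrapolation and still count as
  missing for inclusion.
* **Filter realization.** "4-Hz low-pass" is realized as a 2nd-order digital
  Butterworth (bilinear transform, cutoff at −3 dB) applied forward and
  backward: zero phase lag (no latency distortion of onsets beyond symmetric
  smoothing), effective 4th-order magnitude. It is applied per eye over the
  whole trial, so baseline statistics see the same smoothing as the
  response. Edge transients are absorbed by ~1 s of odd-reflection padding;
  DC gain is exactly 1 by construction. The implementation is validated
  against the analytic transfer function \(|H(e^{i\omega})|^2\).
* **The 520-sample window.** At exactly 120 Hz only 518 sample instants of a
  960-sample trial fall at or after the 3680-ms onset, yet the documented
  convention is 520 post-onset samples → 86 bins of 6 samples with 4
  discarded. We honour the documented count by letting the window start up
  to 2 samples (~17 ms) before nominal onset. Trials that cannot supply 520
  samples are excluded (no padding policy could be justified).

## The statistics

Per bin: \(F = (SS_\mathrm{cond}/2)\,/\,(SS_\mathrm{err}/2(n-1))\) and
\(\eta_p^2 = SS_\mathrm{cond}/(SS_\mathrm{cond}+SS_\mathrm{err})\), verified
against a brute-force loop oracle at relative tolerance 1e−10. The
*consecutive-bin rule* (a bin counts only when both neighbours are also
below \(\alpha\)) mirrors common practice but does not control the
family-wise error when bins are smooth — the test suite demonstrates its
null family-wise rate well above 0.05 — hence the cluster-based Monte-Carlo
correction:

* cluster-forming threshold = the parametric critical value at
  \(\alpha = .05\) (F for the omnibus test, two-sided t for pairwise
  contrasts, positive and negative excursions clustered separately);
* cluster mass = statistic summed over the cluster; the null distribution is
  the maximum mass per permutation;
* within-participant label shuffling (all \(k!\) orders for the omnibus,
  sign flips for pairwise contrasts, enumerated exhaustively when
  \(2^n \le\) `n_perm`);
* \(p_{mc} = (1 + \#\{\text{perm max} \ge \text{observed}\})/(1+n_\mathrm{perm})\),
  so p-values have resolution \(1/(n_\mathrm{perm}+1)\) and the attained
  level sits just below \(\alpha\).

The description of the original nonparametric procedure lives in
supplementary material we do not have; the scheme above is the canonical
max-cluster-mass form used for EEG/MEG time series, and Monte-Carlo p-values
are reported *per cluster* (the source's phrasing is ambiguous between
per-cluster and per-bin). Degenerate zero-variance bins contribute statistic
0 rather than propagating NaN.

Effect sizes: Hedges' \(g_{av}\) (paired; average-SD denominator,
\(J = 1 - 3/(4(n-1)-1)\)) and \(g_s\) (independent; pooled SD,
\(J = 1 - 3/(4(n_1+n_2-2)-1)\)). At \(n = 2\), \(J = 0\) and \(g_{av} = 0\)
regardless of the raw difference — a documented degeneracy of the
correction. Planned one-tailed looking-time comparisons are *not*
Bonferroni-corrected (the directional predictions are stated in advance);
per-bin post-hoc t-tests are (×3).

## The synthetic generator: a stated world

The generator is first-class, tested code; its defaults are fixed once and
describe the cohort the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| participants | 18 (10mo), 16 (15mo) | tested cohort sizes; 5 test trials each give the 90/80 trial totals |
| sampling rate | 120 Hz | tracker rate |
| timeline | 8000 ms test, onset 3680 ms; 9000 ms familiarization | trial design |
| baseline pupil | 4.5 ± 0.4 mm (between participants) | typical infant pupil diameter in a dim room |
| sample noise | 0.08 mm SD per eye, independent between eyes | video-based tracker precision; both eyes share the signal |
| drift | 0.002 mm/sample random walk, shared by both eyes | slow arousal/accommodation wander, removed by baseline correction |
| gaps | Poisson onsets at 2/s; exponential lengths, mean 32.3 ms (10mo) / 37.4 ms (15mo); 1% long gaps (mean 600 ms); both eyes hit with p = .8 | measured gap-length laws; ≥ 98% of gaps < 500 ms |
| dropout trials | 20% (10mo) / 25% (15mo) get a contiguous gap covering 45–70% of the trial | reproduces the reported inclusion levels (~72/90, ~60/80) and retained cohorts (~14, ~11) via the 40% rule, rather than hard-coding them |
| kernels | gamma-density bumps (shape 3), zero before onset | standard smooth causal pupil-response shape; no functional form is given in the source |
| 15mo components | perceptual: onset 1300 ms, rise 800 ms, amplitude 0.14 mm, CV 0.65; association: onset 3950 ms, rise 500 ms, amplitude 0.10 mm, CV 0.5 | onsets from the reported effect windows; see calibration below |
| 10mo components | perceptual only: onset 2000 ms, rise 750 ms, amplitude 0.10 mm, CV 0.7 | younger infants show no association effect |
| looking | two-state on/off-screen Markov chain; logit-normal per-trial targets around the reported block/condition means | reproduces declining familiarization looking and the novel > familiar looking preference |

**Amplitude calibration.** Amplitudes and their between-participant CVs
(lognormal, mean-preserving) were calibrated once, before the tests were
frozen, so that (i) per-bin effect sizes at the *edges* of the significant
windows sit near the reported floor values (\(\eta_p^2 \approx\) 0.25–0.28
at \(n\) = 11–14 — the source prints only window minima, which by
construction sit at the significance threshold), and (ii) the
novel-vs-familiar cluster is recoverable in ≥ 90% of replicate cohorts at
\(n = 11\), as the structure-recovery acceptance criterion presupposes. Peak
per-bin \(\eta_p^2\) (~0.6–0.7) is unconstrained by any printed value. The
association rise time is 500 ms so the slow response develops *inside* the
recorded window (the reported effect runs from 3950 ms to the end of the
trial); with a longer rise the component would peak after the recording
stops and be undetectable at any realistic sample size.

**What the generator does not emulate.** On-screen (looking) state and
pupil-validity gaps are generated independently, whereas in real data
look-aways also produce missing pupil samples; dropout trials stand in for
that coupling at the trial level. There are no gaze positions, saccades,
luminance responses or foreshortening artifacts, no autocorrelated
measurement noise beyond the drift, and familiarization pupil traces carry
no stimulus-locked response (only their looking flags are analysed). A green
test therefore establishes that the *pipeline machinery* is correct and
calibrated under this stated world — not that it would reproduce any
particular infant dataset.

## Numerical and degenerate-input policy

* Timestamps are trial-relative milliseconds at \(k \cdot 1000/120\),
  rounded to 3 decimals; generated diameters are quantised to 1e−6 mm so the
  TSV round-trip is exactly lossless and seeded runs are byte-identical.
* Baseline window mean of every corrected trial is 0 within 1e−9 mm
  (tested).
* Trials with under half the baseline window present, or with no usable eye,
  are excluded with a tagged reason.
* `rm_anova_bin` on all-constant input reports F = 0 with a warning;
  zero-variance paired differences are flagged `degenerate` (t = 0 when the
  mean difference is 0).
* Monte-Carlo seeds are mandatory arguments; the pipeline derives
  per-contrast seeds deterministically from the config seed.

## Known limitations

* The cluster statistic is the summed F/t mass with threshold \(\alpha=.05\);
  no threshold-free cluster enhancement, no mixed-effects growth curves.
* The QC gap-length mean is measured on interpolated runs, which merge
  overlapping Poisson gaps, so it sits somewhat above the configured
  exponential mean (the sampler itself is verified to 2%).
* Exhaustive enumeration is implemented for pairwise sign flips only; the
  omnibus test always samples label permutations.
* Config files are JSON (not YAML), matching the available dependency set.
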