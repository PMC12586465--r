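---
title: "Methods: EEG connectivity, spanning-tree networks and test-retest reliability"
author: "eegReliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG connectivity, spanning-tree networks and test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegReliability)
```

## The problem

Quantitative resting-state EEG measures — functional connectivity, signal
complexity and network topology — are candidate clinical biomarkers, but a
biomarker is only as good as its test-retest reliability. This package
implements a sensor-level reliability pipeline for a study design with three
recordings per subject: an eyes-closed resting-state session (`session1`),
an identical repeat session weeks later (`session2`), and a
*semi-resting-state* recording taken from the task-free intervals of a
stimulus paradigm on the same day as the first session (`semirest`).
Comparing `session1` with `session2` quantifies **temporal** reliability;
comparing `session1` with `semirest` quantifies **state** reliability
(robustness to recording instructions and attentional state). The joint
pattern of the two classifies each measure into four biomarker classes.

Because clinical EEG recordings of this design are not freely available, the
package ships a synthetic cohort generator with known variance components,
so that the whole pipeline can be exercised against ground truth.

## Signal processing

Recordings are band-filtered into the canonical sensor-EEG bands — delta
0.5–4 Hz, theta 4–8 Hz, alpha 8–13 Hz, beta 13–20 Hz (content above 20 Hz
is excluded as muscle-dominated) — and segmented into 15 artifact-free 4-s
epochs (64 channels at 2048 Hz in the reference layout; all of these are
arguments, not constants).

Filtering uses a zero-phase windowed-sinc (Hamming) FIR filter, applied
forward and backward with `signal::filtfilt`. A zero-phase filter matters
here: any phase distortion would directly corrupt the phase lag index. The
order follows the Hamming transition-width rule `n ≈ 3.3·fs/Δf` with the
transition width set to `min(max(low/4, 2 Hz), low)` (mirrored at the upper
edge). For short inputs the order is capped at a third of the signal length
(and the cap logged), which widens the transition bands; when continuous
data are available the pipeline therefore filters *before* segmenting, so
edge transients and order caps are irrelevant to the epochs. The filter
family and order are package choices — they are deliberately exposed through
the band and length arguments rather than hard-wired.

Instantaneous phase and amplitude envelope come from the FFT-based discrete
analytic signal, computed per epoch after mean removal. Ten percent of the
samples at each epoch edge are excluded from phase and envelope statistics
(`edgeTrimFrac = 0.1`) to suppress the transform's edge effects; the
fraction is configurable.

The corrected amplitude envelope correlation can optionally be computed on
concatenated one-minute segments (`concatenateEpochs()`, fifteen 4-s epochs
per segment) instead of separate epochs, since longer segments can
stabilise envelope correlations.

## The measures

For channels $x, y$ with instantaneous phases $\phi_x, \phi_y$ and
envelopes $A_x, A_y$:

* **PLI** (phase lag index):
  $\mathrm{PLI} = \lvert \langle \operatorname{sign}(\Delta\phi_t)
  \rangle_t \rvert$, with $\Delta\phi$ wrapped to $(-\pi, \pi]$. Exact
  zeros of $\Delta\phi$ contribute 0 to the mean, so purely zero-lag
  (volume-conduction-like) coupling maps to 0 and a constant non-zero lag
  to 1.
* **AECc** (corrected amplitude envelope correlation): $y$ is
  orthogonalized with respect to $x$ by removing the least-squares
  projection in the time domain (per epoch, on the band-filtered signals),
  the Pearson correlation of $A_x$ with the residual's envelope is taken,
  the roles are swapped, and the two correlations are averaged — enforcing
  the symmetry a connectivity matrix requires. The signed mean $r$ is
  mapped to $[0,1]$ as $(r+1)/2$ so that all matrix measures share one
  scale; the raw $r$ is kept alongside for transparency. A vanished
  residual (zero-variance envelope) makes the pair-epoch value undefined;
  it is excluded from the epoch average and counted.
* **PE** (permutation entropy): windows of $m$ samples at delay $\tau$ are
  ranked into ordinal patterns (ties broken by order of occurrence, the
  earlier sample ranking lower — a deterministic rule, unlike jitter
  injection); PE is the Shannon entropy of the pattern distribution
  normalized by $\log m!$. A per-channel complexity measure; its
  whole-head mean is the scalar summary.
* **JPE\_INV** (inverted joint permutation entropy): the Shannon entropy of
  the joint distribution of simultaneous pattern pairs, normalized by
  $\log (m!)^2$ and inverted, $1 - \mathrm{JPE}$. The normalization
  constant is chosen so that independent i.i.d. noise attains
  $\mathrm{JPE} = 1$ (hence $\mathrm{JPE\_INV} = 0$); note the useful
  anchor that two identical i.i.d. series give exactly
  $\log m! / \log (m!)^2 = 0.5$.

Defaults are $m = 3$, $\tau = 1$ sample, with $m$ capped at 5 (alphabet
size $m!$). All pairwise measures are computed per epoch and averaged into
a symmetric, zero-diagonal `ConnectivityMatrix`; `wholeBrainMean()` gives
the conventional scalar summary (mean over the upper triangle).

## Maximum spanning tree

Thresholding connectivity matrices introduces an arbitrary parameter; the
maximum spanning tree avoids it by keeping exactly the $N-1$ strongest
edges that connect all $N$ channels without cycles. Extraction is
Kruskal's algorithm on descending weights with a deterministic
lexicographic (row, column) tie-break; tie counts are recorded because tied
weights would make the backbone, and hence the overlap index, arbitrary
(continuous estimates make ties measure-zero). Zero weights are kept as
valid weakest edges so a tree always exists.

The six macroscale metrics, with $m = N - 1$ edges and $L$ leaves, are:
normalized maximum degree $k_{max}/m$; leaf fraction $L/(N-1)$; diameter;
maximum betweenness centrality $BC_{max}$ (a leaf has $BC = 0$, a star
centre $BC = 1$); mean eccentricity; and tree hierarchy
$Th = L / (2\,m\,BC_{max})$. Betweenness uses the unweighted tree topology
(hop counts), consistent with the purely topological definitions of the
other metrics. Two conventions are deliberately surfaced rather than
hidden:

* diameter and eccentricity are divided by $m$ so every metric lives on
  $[0,1]$; the raw hop counts are always emitted alongside
  (`diameter_edges`, `eccentricity_edges`);
* the divisor of the maximum degree is ambiguous in common usage ($m$ or
  $N$); the $m$-normalized value is the default `kmax` and the
  $N$-normalized value is emitted as `kmax_n`.

`mstEdgeMean()` (the `PLI_MST` / `AECc_MST` summaries) averages the
connectivity weights over the tree edges; since the maximum tree picks
maximal edges this always dominates the whole-brain mean. `mstOverlap()`
is the percentage of shared edges between two trees on the same channels,
$100\,\lvert E_A \cap E_B \rvert/(N-1)$ — a direct topological reliability
index; on a 64-channel tree, an overlap of 10.8 % corresponds to
`overlapEdgeCount(10.8, 64)` ≈ 6.8 shared edges. Per-subject overlaps are
computed from the subject's epoch-averaged matrices for the two recordings
being compared, then averaged across subjects (mean ± SD per band, measure
and comparison) — averaging trees before subjects would answer a different
question.

## Reliability quantification

`icc2way()` implements the single-rater two-way mixed-effects ICC from the
two-way ANOVA mean squares ($MS_R$ subjects, $MS_C$ sessions, $MS_E$
residual; $k$ sessions):

* **consistency** (Shrout–Fleiss ICC(3,1), the package default):
  $(MS_R - MS_E)/(MS_R + (k-1)MS_E)$;
* **absolute agreement** (McGraw–Wong ICC(A,1)):
  $(MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$.

"Two-way mixed-effects" does not by itself pin down which of the two is
meant; both are implemented, the default is documented, and the choice is
one argument. The 95 % interval is F-based (exact for consistency,
Satterthwaite for agreement); `iccBootstrapCI()` adds a non-parametric
percentile interval from 1000 resamples of *subjects* (rows resampled with
replacement, sessions kept paired — resampling sessions would break the
design). Subjects missing a session are dropped pairwise and counted.
Negative estimates are reported as computed (truncation at 0 is an
option, off by default). When the residual mean square is exactly zero the
point estimate is still well-defined but the interval degenerates; the
result carries a `degenerate` flag rather than a fabricated interval.

Categories follow the conventional bands: below 0.50 *poor*, 0.50–0.75
*moderate*, 0.76–0.90 *good*, above 0.90 *excellent*; values are rounded
to two decimals first so the (0.75, 0.76) gap cannot swallow an estimate.
Published usage is ambiguous about whether the category should be read off
the point estimate or the lower confidence bound; the package defaults to
the point estimate (matching how such results are usually tabulated) and
exposes `basis = "ci_low"` as the conservative alternative, surfacing the
ambiguity instead of hiding it.

`classifyBiomarker()` combines the temporal and state categories ("high"
meaning moderate or better by default) into: *possible biomarker* (both
high); *possible biomarker, sensitive to resting-state instructions* (high
temporal, low state); *possible cross-sectional marker, sensitive to
time-variable factors* (high state, low temporal); *poor reliability*
(both low).

## The synthetic cohort generator

The generator is the package's ground-truth instrument, not a biophysical
simulator. Each recording's channel-pair coupling is

$$c_{sr} = \operatorname{clip}_{[0,1]}\!\big(c_0 + b_s + d_r +
\varepsilon_{sr}\big), \qquad
b_s \sim N(0, \sigma_{subject}^2),\;
d_r \sim N(0, \sigma_{state}^2),\;
\varepsilon_{sr} \sim N(0, \sigma_{noise}^2),$$

Gaussian components chosen to match the two-way ANOVA model the ICC
assumes. Each channel mixes a phase-shifted copy of a subject-specific
wideband (0.5–20 Hz) common source with private noise,
$x_k = \sqrt{c_{sr}}\,\mathrm{rot}(z, \varphi_k) + \sqrt{1-c_{sr}}\,\eta_k$,
where $\mathrm{rot}(\cdot,\varphi_k)$ is a constant phase rotation through
the analytic representation (an all-pass operation, so it commutes with the
band filters) and the $\varphi_k$ are fixed, distinct channel lags. Phase
rotation with non-zero lags makes the coupling visible to the PLI; the
shared source also drives envelope and ordinal-pattern coupling.

Seeding is counter-based (`childSeed()`): signal innovations are seeded
*per subject only*, while conditions differ only through their coupling.
Two consequences are intended: identical seeds give bit-identical cohorts,
and with $\sigma_{state} = \sigma_{noise} = 0$ a subject's three recordings
are *exactly* identical, so every downstream ICC is exactly 1 and every
backbone overlap exactly 100 % — a sharp end-to-end invariant that a
generator re-drawing signal noise per condition could not provide.

Because the condition shift $d_r$ is drawn once per condition (a column
effect shared by all subjects), the consistency ICC removes it; the
generator therefore reports two theoretical values,
$\sigma_b^2/(\sigma_b^2 + \sigma_e^2)$ (consistency) and
$\sigma_b^2/(\sigma_b^2 + \sigma_{state}^2 + \sigma_e^2)$ (agreement).
Clipping to $[0,1]$ biases these nominal components; the clipping rate is
reported and a warning raised above 1 %.

Default components ($c_0 = 0.4$, $\sigma_{subject} = 0.10$,
$\sigma_{state} = \sigma_{noise} = 0.04$) give a clipping probability well
below 0.1 % and a theoretical agreement ICC of about 0.76 — a
"good"-grade measure, i.e. the regime the reliability analysis is meant to
resolve. `generateScalarTable()` bypasses signal simulation entirely
($y_{sr} = \mu + b_s + g_r + e_{sr}$) to stress-test the ICC layer alone,
e.g. $\sigma_b^2 = \sigma_e^2 = 1$ gives a theoretical consistency ICC of
exactly 0.5.

What the generator does **not** emulate: volume conduction and spatial
leakage (beyond what the shared source induces), realistic 1/f spectra and
band-specific rhythms, artifacts (blinks, muscle), electrode geometry, or
non-stationarity. Passing tests therefore demonstrate estimator and
pipeline correctness under a controlled model — not that any particular
reliability level will be attained on clinical recordings.

## Worked example

A deliberately small cohort (6 subjects, 4 channels, 64 Hz, three 2-s
epochs, alpha band) keeps the example fast while exercising every stage:

```{r example, message = FALSE}
cfg <- cohortConfig(nSubjects = 6, nChannels = 4, fs = 64, nEpochs = 3,
                    epochLenS = 2, bands = canonicalBands()["alpha"],
                    sigmaSubject = 0.12, sigmaState = 0.03,
                    sigmaNoise = 0.03, couplingBase = 0.5, seed = 21)
report <- runStudy(cfg, measures = c("PLI", "PE"))
subset(report@reliability,
       measure == "PLI",
       select = c(measure, band, comparison, n, icc, ci_low, ci_high,
                  category, biomarker_class))
report@overlap
report@groundTruth$iccTheoreticalConsistency
```

## Numerical and design notes

* Problem sizes in the test suite and the acceptance script are scaled
  down (tens of subjects, a handful of channels, 64–256 Hz) as the
  package's own choice of example sizes; every estimator is size-agnostic
  and the defaults retain the full 64-channel / 2048-Hz geometry.
* The measure/band/condition scalar summaries are: whole-brain mean for
  PLI, AECc and JPE\_INV; channel mean for PE; metric value for the
  spanning-tree measures. Temporal = `session1` vs `session2`; state =
  `session1` vs `semirest`. The two comparisons are fixed by the study
  design, not configurable, to avoid silent divergence from it.
* Degenerate inputs are first-class: empty phase series, degenerate bands,
  bands at Nyquist, too-short records (the achievable epoch count is named
  in the error), all-identical reliability tables, and resamples with
  fewer than three distinct subjects (redrawn and counted) all have
  defined behaviour.
* `readRecording()`/`writeRecording()` define a lossless columnar CSV
  dialect (header lines carrying `fs`, subject and condition); EDF is part
  of the reader interface but no EDF backend is bundled.

## Known limitations

Sensor-level only: no source reconstruction, no artifact handling, no
bad-channel interpolation — on real data those stages must precede this
package. Only two-session designs ($k = 2$) are exercised by the study
layout, though `icc2way()` accepts any $k \ge 2$. The AECc leaves open
whether envelopes should be log-transformed before correlating; the
package correlates raw envelopes and exposes the raw signed correlation
for inspection.
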