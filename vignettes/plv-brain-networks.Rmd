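---
title: "Phase-locking-value brain networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking-value brain networks: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

## The analysis in one paragraph

plvnet implements a standard resting-EEG functional-connectivity pipeline.
Each multichannel recording (nominally 30 channels of the 10--20 system at
250 Hz, 4 minutes, eyes closed) is band-pass filtered into the classical
delta (0.5--4 Hz), theta (4--7 Hz), alpha (8--12 Hz) and beta (13--30 Hz)
sub-bands; each band-limited record is cut into 8 non-overlapping 15 s
epochs; instantaneous phases are extracted with the analytic signal, and for
every channel pair the phase-locking value

$$\mathrm{PLV} = \left|\left\langle e^{i\,\Delta\Phi(t)}\right\rangle\right|
  = \sqrt{\langle\cos\Delta\Phi\rangle^2 + \langle\sin\Delta\Phi\rangle^2}$$

is computed per epoch and averaged, giving a symmetric $N \times N$ matrix
per subject and band. Each matrix is thresholded to a *fixed sparsity*
$s = K / [N(N-1)/2]$ (the K strongest pairs become unweighted edges) over a
grid from 12% to 40% in 1% steps, and on every binary network we compute the
characteristic path length $L$, clustering coefficient $C$, global
efficiency $E_{global}$, local efficiency $E_{local}$ and nodal degrees
$k_i$. Group differences (two groups, e.g. a practice group vs. matched
controls) are assessed with two-sided permutation tests on the group mean
difference; brain--behavior association is the within-group Pearson
correlation between mean reaction time and grid-averaged global metrics.

## Why fixed sparsity, and what the sweep reports

Thresholding each subject at the same edge count removes global connectivity
strength as a confound: any surviving group difference reflects *which*
connections are strong, not how strong connections are overall. Because no
single sparsity is canonical, the sweep reports every metric at all 29 grid
points plus a *range-level* summary (the per-subject mean across the grid).
How the original range-level comparison aggregated the grid is not stated in
the source; we default to the across-grid mean and also emit every
per-threshold test, both uncorrected and Benjamini--Hochberg adjusted (the
source reports uncorrected per-threshold significance).

Edge count uses $K = \mathrm{round}(s \cdot N(N-1)/2)$ with round-half-away
-from-zero — the rounding is not pinned by the definition of sparsity, so it
is fixed here and tested. Ties at the cutoff are broken by lexicographic
$(i, j)$ order, which makes binarization deterministic and edge sets nested
along the grid; nestedness in turn forces $E_{global}$ to be non-decreasing
in $s$, which the tests assert.

Degenerate inputs: a fully disconnected network has no finite path, so $L$
errors out rather than returning a silent value; partial disconnection
averages $L$ over *connected pairs only* and reports `n_connected_pairs`
alongside. $E_{global}$ needs no convention ($1/\infty = 0$). Nodes of
degree $< 2$ contribute $C_i = 0$ (the $0/0$ convention stated explicitly
because it shifts $C$ by the isolated-node fraction). Dead (zero-variance)
channels yield masked PLV entries that rank last at binarization.

## Filtering and phase extraction

No pre-installed signal-processing library exists in the supported
environment, so the filter is implemented in-package: the squared magnitude
response of an order-4 Butterworth band-pass (i.e. the forward--backward
response), applied in the frequency domain. This makes the phase response
exactly zero — mandatory upstream of a phase-synchronization estimator,
since a causal filter would add frequency-dependent phase lag. The measured
response of the realized alpha filter is $-114$ dB one octave above the band
and attenuates a 20 Hz tone by a factor $\sim 2\times10^{-5}$; in-band tones
pass within 0.5%. FFT filtering is circular, so the pipeline filters the
full continuous record, then discards a 1 s guard at each end before
epoching — epochs never contain edge transients. Phases come from the
FFT-based analytic signal; 5% of samples at each epoch edge are trimmed
before PLV to suppress transform edge effects.

The epoching of the source protocol ("randomly divided into 8 non-
overlapping epochs") is read as uniformly random non-overlapping placement,
seeded and deterministic; a `contiguous` option gives back-to-back epochs.

## The synthetic cohort: what it emulates and what it does not

The study's raw EEG is not deposited, so every downstream stage is verified
against a generator with analytically known connectivity:

* **Coupled cluster.** All channels of a cluster share a common phase
  $c(t) = 2\pi f_c t + \text{slow random walk}$ (sd 0.02 rad/sample); each
  channel adds independent von Mises$(0, \kappa)$ jitter. The implied PLV
  between two cluster channels is the closed form
  $(I_1(\kappa)/I_0(\kappa))^2$, verified against brute-force Monte-Carlo
  averaging of $e^{i\Delta\Phi}$ over $2\times10^6$ draws before being
  frozen into tests.
* **Jitter correlation time.** The jitter is held constant over
  half-carrier-period blocks ($m = \mathrm{round}(f_s / 2 f_c)$ samples)
  rather than redrawn every sample. This is deliberate: per-sample jitter
  makes the signal non-narrowband, and the analytic-signal operator then
  *discards aliased jitter power*, inflating estimated PLV by up to +0.04 at
  $\kappa = 5$ (measured; the bias is carrier-frequency independent). With
  half-period blocks the phase process stays inside the analytic bandwidth
  and the estimator tracks it; measured recovery biases are $\le 0.01$
  across $\kappa \in \{0, 1, 2, 5\}$. Physically this says a neural
  oscillator's phase noise decorrelates on the timescale of its own cycle.
* **Uncoupled channels** follow their own phase with a faster random walk
  (0.2 rad/sample, a ~1.6 Hz linewidth): band-limited oscillations with no
  stable phase relation to anything.
* **Estimator floors.** The default epoch-mean PLV estimator has an
  irreducible small-sample (Rayleigh) floor
  $\approx \sqrt{\pi}/(2\sqrt{N_{\mathrm{eff}}})$ per epoch — about 0.05 for
  15 s alpha epochs — so true-zero couplings read as small positive values.
  Convergence tests against the closed form therefore use the `pooled`
  aggregation (phasors averaged across all epochs before the modulus),
  which shrinks the floor by $\sqrt{n_{epochs}}$; group inference is
  unaffected by the floor because it is common to both groups.
* **Planted effect.** Both groups share a posterior alpha cluster
  (O1/OZ/O2/P3/Pz/P4, $\kappa = 2$) — the eyes-closed posterior alpha rhythm
  — and the "TC" group additionally receives a frontal/temporal alpha
  cluster (FP1/FP2/F7/F8/F3/F4/FZ/T3/T4) with $\kappa = 1.8$. The default
  $\kappa$ was calibrated once on the reduced power-simulation design
  (8 + 8 subjects, 16 channels, 45 s) to give $\ge 90\%$ range-level power,
  then frozen; the source reports no effect size usable for calibration. A
  per-subject multiplicative coupling factor (uniform 0.5--1.5) supplies
  individual variability.
* **Reaction time** is linear in the subject's ground-truth *weighted*
  global efficiency of the true-PLV graph (equal to the mean true PLV, since
  in-cluster direct links are the weighted shortest paths):
  $rt = 520 - 1500\,E + \varepsilon$, $\varepsilon \sim N(0, 25^2)$ ms.
  The binary-graph reading of "true global efficiency" is degenerate for a
  ground-truth matrix (all background entries tie at zero), hence the
  weighted definition. Slope and noise were chosen once to give a moderate
  negative RT--efficiency correlation and a faster practice group, matching
  the direction (not the values) of the reported behavior.
* **Covariates.** Ages uniform on 20--24, sex Bernoulli(0.7 male) — matching
  the published demographic ranges — and a questionnaire total
  $N(135, 12^2)$ vs $N(125, 12^2)$ for the two groups.

Not emulated: ocular/muscle artifacts, volume conduction, $1/f$ background
spectra, inter-channel amplitude topography. A green recovery test
establishes that the estimators are correct on phase-coupled oscillators,
not that the pipeline is robust to real-world artifacts (the source study
handled those with re-referencing and ICA, both out of scope here; a
`pre_clean` hook is exposed instead).

## Statistics

The permutation statistic is the group mean difference (the source does not
name its statistic), two-sided, with
$p = (\#\{|T^\pi| \ge |T|\} + 1)/(B + 1)$ for $B$ sampled label permutations
and exact enumeration available for small samples. Under exchangeability
$P(p \le \alpha) \le \alpha + 1/(B+1)$, which the suite checks by
simulation, along with nominal type-I error of the full
cohort-to-contrast chain on null cohorts and $\ge 90\%$ power on planted
ones. Demographic checks are the pooled-variance two-sample t-test and the
1-df Pearson chi-square without continuity correction; both are
re-derived from their textbook formulas and cross-checked against base R.
The published demographic table reproduces exactly: TC age
$21.20 \pm 1.190$, control $21.60 \pm 0.577$, $t = -1.512$,
$\chi^2 = 0.397$.

## Montage

Thirty channels in five zones: frontal (FP1, FP2, F7, F8, F3, F4, FZ, FC3,
FCz, FC4), parietal (CP3, CPz, CP4, P3, Pz, P4), temporal (FT7, FT8, T3,
T4, TP7, TP8, T5, T6), occipital (O1, OZ, O2) and central (C3, Cz, C4). The
source lists 27 channels across four lobes but analyzes 30 channels in
"five zones"; the three unlisted channels are taken to be C3/Cz/C4, kept as
full network nodes and reported as their own zone in regional summaries.

## A worked example

```{r example, eval = FALSE}
library(plvnet)
cfg <- run_config(
  out_dir = "demo_run",
  cohort = cohort_spec(n_per_group = 10, duration_s = 60, seed = 1),
  bands = eeg_bands(c("alpha", "beta")),
  n_permutations = 2000,
  seed = 1)
res <- run_pipeline(cfg, verbose = TRUE)
subset(res$contrasts$range_level, band == "alpha")
```

The range-level table shows the planted alpha contrast (higher clustering
and local efficiency, shorter paths in the practice group) while beta stays
null; `demo_run/` holds the per-subject PLV matrices, tidy metric tables,
statistics and a JSON report with the config hash and every consumed seed.

## Known limitations

* PLV estimated after band-pass filtering of broadband mixtures is
  attenuated/inflated relative to the single-band closed form; ground-truth
  recovery is exact only for single-band, noise-free pairs. Group inference
  relies on the ordinal structure, which filtering preserves.
* The EDF writer/reader supports plain 16-bit EDF with equal per-signal
  rates — enough for round-tripping this pipeline's data, not a general
  EDF+ implementation.
* Graph metrics are for undirected, unweighted networks only, matching the
  source design; no small-world indices, modularity or centralities beyond
  degree.
* At 12% sparsity on 30 nodes, networks with concentrated clusters can
  fragment; `n_connected_pairs` flags this, and $L$ then averages connected
  pairs only.
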