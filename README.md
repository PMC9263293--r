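# plvnet

Phase-locking-value (PLV) functional brain networks from resting EEG, with a
verifiable synthetic cohort generator.

## What this is for

A common question in cognitive neuroscience is whether some practice or
condition (meditation, exercise, clinical status) reorganizes resting-state
brain connectivity. A standard answer pipeline: record multichannel resting
EEG from two groups, estimate per-band phase synchronization between all
electrode pairs, threshold the resulting matrices into binary graphs at
matched edge density, and compare graph-theoretic summaries between groups
and against behavior. plvnet implements that pipeline end to end for
30-channel 10--20 recordings and — because studies of this kind rarely
deposit raw EEG — ships a coupled-oscillator simulator with analytically
known ground truth, so every estimator in the chain is testable.

## The core quantities

For band-limited signals with instantaneous phases
$\Phi_x(t), \Phi_y(t)$ (analytic signal / Hilbert transform), the
phase-locking value of the relative phase $\Delta\Phi = \Phi_x - \Phi_y$ is

$$\mathrm{PLV} = \left|\langle e^{i\Delta\Phi(t)}\rangle\right|
 = \sqrt{\langle\cos\Delta\Phi\rangle^2+\langle\sin\Delta\Phi\rangle^2}
 \in [0, 1].$$

Each subject's $30\times30$ PLV matrix (per band: delta 0.5--4, theta 4--7,
alpha 8--12, beta 13--30 Hz) is binarized at sparsity
$s = K/[N(N-1)/2]$ for $s = 0.12, 0.13, \dots, 0.40$, and each binary
network is summarized by:

* characteristic path length $L = \frac{2}{N(N-1)}\sum_{i>j} L_{ij}$ (hop
  counts; connected pairs),
* global efficiency $E_{global} = \frac{1}{N(N-1)}\sum_{i\ne j} 1/L_{ij}$,
* clustering coefficient $C = \frac{1}{N}\sum_i \frac{2E_i}{k_i(k_i-1)}$,
* local efficiency $E_{local} = \frac{1}{N}\sum_i E_{global}(G_i)$ over
  neighbor subgraphs $G_i$,
* nodal degrees $k_i = \sum_j a_{ij}$ with five-zone (lobe) aggregation.

Group inference uses two-sided permutation tests on the group mean
difference (range-level across the sparsity grid, per-threshold, and
per-node), plus Pearson correlations between mean reaction time and
grid-averaged metrics. The synthetic generator plants von Mises phase
coupling with closed-form true PLV $(I_1(\kappa)/I_0(\kappa))^2$.

## Worked example

```r
library(plvnet)
cfg <- run_config(
  out_dir = "demo_run",
  cohort = cohort_spec(n_per_group = 8, n_channels = 16, duration_s = 45,
                       seed = 1, bands = eeg_bands(c("alpha", "beta"))),
  bands = eeg_bands(c("alpha", "beta")),
  n_permutations = 2000,
  seed = 1)
res <- run_pipeline(cfg)
subset(res$contrasts$range_level, band == "alpha")
#>    band  metric observed     p
#> 1 alpha       L   -0.803 5e-04
#> 2 alpha       C    0.249 5e-04
#> 3 alpha Eglobal   -0.226 5e-04
#> 4 alpha  Elocal    0.208 5e-04
```

The simulated "TC" group carries planted frontal/temporal alpha coupling on
top of the shared posterior alpha cluster. At matched edge count its
networks are more clustered ($C$, $E_{local}$ higher, $p = 1/2001$, the
smallest value 2000 permutations can produce) with shorter paths among
connected pairs; edge concentration also fragments the periphery, which
lowers binary $E_{global}$ — with a fixed edge budget a planted cluster
cannot raise clustering and global efficiency at once. The beta band, where
nothing is planted, stays null. Nodal contrasts localize the effect:

```r
head(subset(res$contrasts$nodal, band == "alpha" & lobe == "frontal"), 4)
#>    band channel    lobe observed     p     p_bh
#> 1 alpha     FP1 frontal     3.07 5e-04 0.000888
#> 2 alpha     FP2 frontal     3.24 5e-04 0.000888
#> 3 alpha      F7 frontal     1.99 2e-03 0.002460
#> 4 alpha      F3 frontal     3.15 5e-04 0.000888
```

i.e. the planted frontal electrodes gain ~2--3 edges of mean degree.
`demo_run/` then contains per-subject PLV matrices (TSV + JSON sidecars),
tidy `metrics.tsv` / `nodal.tsv` tables, the statistics tables, and a
`report.json` with the config hash and every consumed seed. Identical
config and seed reproduce every output byte for byte.

A command-line wrapper with `simulate`, `run` and `stats` subcommands is
installed at `inst/cli/plvnet`:

```sh
Rscript inst/cli/plvnet run --seed 1 --n-per-group 8 --duration 45 \
  --bands alpha,beta --n-perm 2000 --out demo_run
```

## Layout

* `R/synthetic.R` — von Mises coupled-oscillator cohorts with ground truth
* `R/preprocess.R`, `R/edf.R` — zero-phase band-pass, epoching, TSV/EDF I/O
* `R/connectivity.R` — analytic-signal phases, PLV matrices
* `R/network.R` — sparsity thresholding and graph metrics
* `R/stats.R` — permutation tests, t / chi-square / correlation
* `R/pipeline.R`, `R/cli.R` — orchestration, reports, CLI
* `vignettes/plv-brain-networks.Rmd` — models, estimator biases, design
  choices and limitations
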