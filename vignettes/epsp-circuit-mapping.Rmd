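---
title: "Quantifying layer- and cell-type-specific synaptic input from optogenetic slice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying layer- and cell-type-specific synaptic input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epspmap)
```

## The measurement problem

Optogenetic circuit mapping asks how strongly a long-range pathway —
here the first-order (VPM) and higher-order (POm) somatosensory thalamic
nuclei — innervates each cell class in each cortical layer of the
whisker barrel cortex. Channelrhodopsin is expressed in thalamic
neurons, axons are stimulated in a brain slice with a 1 ms blue-light
pulse, and the evoked excitatory postsynaptic potential (EPSP) is
recorded in whole-cell configuration from excitatory (EXC) neurons and
PV, SST and VIP interneurons across layers L2–L6. Recordings are made
under TTX + 4-AP (no polysynaptic activity) and picrotoxin (no fast
GABAergic transmission), so the depolarization is the monosynaptic
glutamatergic input; CNQX + APV abolishes it and serves as the negative
control.

Two features quantify input strength on the trial-averaged trace:

* **peak amplitude** $A = \max_{0 < t \le T_\mathrm{peak}} \bar V_m(t) - V_\mathrm{base}$,
  where $V_\mathrm{base}$ is the mean membrane potential over the 100 ms
  before the stimulus, and
* **20–50% rise slope**, the least-squares slope of $\bar V_m(t)$
  between the times the trace first reaches 20% and 50% of $A$ above
  baseline (contiguously below the peak).

Absolute amplitudes depend strongly on per-slice opsin expression. The
design therefore records reference-layer excitatory neurons (L4 for the
VPM pathway, L5A for POm) in every slice and reports each cell's
features divided by the mean feature of those reference cells *in the
same slice*:

$$\tilde A_i = \frac{A_i}{\overline{A}_{\mathrm{ref}(s(i))}},$$

which makes the reference group's mean exactly 1 by construction and
removes the slice-level expression factor. Group differences are then
assessed with two-tailed Wilcoxon rank-sum tests (exact in small
samples), and groups are summarized as mean ± SD, median and n, with
box-plot whiskers at the most extreme data points within 1.5 × IQR of
the quartiles.

## Pipeline

```{r pipeline, eval = FALSE}
cfg        <- simulation_config("VPM", seed = 1)   # or read_dataset(path)
ds         <- simulate_dataset(cfg)
features   <- extract_features(ds$sweeps)          # baseline, peak, slope
normalized <- normalize_dataset(features, ds$meta) # per-slice reference scaling
pooled     <- pool_groups(normalized)              # (pathway, type, layer) groups
build_summary_table(pooled, "VPM", "amplitude")    # layer x cell-type matrix
compare_reference_layer(normalized, "VPM")         # rank-sum p-values
```

`run_pipeline()` chains all stages, writes CSV artifacts plus a JSON
manifest (parameters, hashes, exclusions), and is exposed through a thin
command-line dispatcher in `inst/cli/epspmap.R`.

## The generative simulator

The package ships a full generative model of these experiments so every
downstream stage can be exercised and validated without recorded data.
For a cohort of one pathway:

* **Slice expression level.** Each slice draws an absolute reference
  amplitude $R_s \sim \mathrm{logNormal}$ with median 14.5 mV (VPM) or
  11.7 mV (POm) — the reference-layer excitatory means — and
  $\sigma_{\log} = 0.4$, emulating slice-to-slice variation in opsin
  expression. The log-normal median (not mean) is anchored to the
  printed values; with cohort-scale samples the pooled absolute
  reference mean lands within a few percent of them.
* **Cell strength.** Each cell draws a normalized strength
  $g_i = \max(0, \mathcal N(\mu_g, \sigma_g))$ from its
  (cell type × layer) group; the default $(\mu_g, \sigma_g, n)$ per
  group are the normalized-amplitude summary matrices of the two
  pathways (reference group mean 1). Censoring at zero reflects that
  EPSPs under picrotoxin are non-negative; `group_generative_mean()`
  gives the resulting censored-normal expectation.
* **Trials.** The cell's absolute amplitude is $a_i = R_{s(i)} g_i$;
  each of 20 trials jitters it as $\max(0, \mathcal N(a_i, 0.1\,a_i))$
  and adds a dual-exponential waveform
  $w(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ (normalized to unit
  peak) to a resting potential of −70 mV with stationary
  Ornstein–Uhlenbeck membrane noise (σ = 0.3 mV, τ = 10 ms), digitized
  at 20 kHz. Kinetics presets are τ_r/τ_d = 2/40 ms (EXC, SST),
  0.5/15 ms (PV) and 1/25 ms (VIP): PV kinetics are deliberately fast
  so equal-amplitude inputs yield ~2–3× steeper slopes, the qualitative
  signature of feedforward input to PV cells.
* **Conditions.** `CNQX_APV` forces the synaptic amplitude to zero
  (receptor block); `late_timepoint` scales the mean amplitude by
  `1 + drift_per_hour` (0 by default — a stable preparation).

Every draw is governed by one integer seed; identical configurations
and seeds give identical datasets.

### What the simulator does and does not emulate

It reproduces the *statistical* structure the analysis assumes:
stimulus-locked monosynaptic EPSPs on stationary colored noise, ~20
trials per cell, per-slice multiplicative expression scaling,
group-structured strengths with guaranteed reference cells, cell-type
kinetics, pharmacology and stability conditions. It does **not** model
conductance-based or multicompartment biophysics, dendritic filtering,
per-trial latency jitter, the spatial light-power profile, or
short-term plasticity. Passing tests therefore demonstrate that the
analysis recovers the structure of data *of this statistical form*;
they cannot certify behaviour on pathologies the generator does not
produce (e.g. slow baseline drift or seal degradation).

One structural caveat deserves emphasis: the default group SDs are
taken from summary matrices that were themselves computed *after*
per-slice normalization, so they already contain the sampling noise of
the per-slice reference denominators. Simulating group draws with those
SDs and then re-normalizing adds that denominator noise a second time,
and with only one or two reference cells in a slice the denominator
(a sample mean of strengths with SD 0.37–0.52 around 1) is a
heavy-tailed ratio. Pooled group means of the simulated-and-reanalyzed
cohorts therefore scatter around their generative values noticeably
more than an idealized $\mathrm{SD}/\sqrt{n}$ argument suggests — an
intrinsic property of re-normalized cohort simulations, not an
extraction defect (the noiseless identity tests pin the extraction to
machine precision). Rank-based layer comparisons are insensitive to
this and reproduce the reference layer's dominance in 100/100 seeded
cohorts.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sampling_rate` | 20000 | Hz | acquisition rate of the recordings |
| `n_trials` | 20 | – | trials averaged per cell |
| `stim_onset_s` / `trace_len_s` | 0.12 / 0.3 | s | leaves the full 100 ms baseline plus a 100 ms peak window with margin; EPSPs (τ_d ≤ 40 ms) have essentially decayed by trace end |
| `baseline_ms` | 100 | ms | pre-stimulus window defining V_base |
| `peak_window_ms` | 100 | ms | post-stimulus search window; evoked EPSPs peak well within it (≤ ~8 ms for the slowest preset) |
| `noise$sigma_mV`, `noise$tau_ms` | 0.3, 10 | mV, ms | stationary membrane noise of a synaptically quiescent TTX slice |
| `trial_amp_jitter_cv` | 0.1 | – | across-trial amplitude variability; affects variances, not means |
| `ref_abs_amp` | median 14.5/11.7, sdlog 0.4 | mV | anchors the absolute scale; sdlog chosen as a realistic expression spread |
| `drift_per_hour` | 0 | – | stability condition: no systematic amplitude change over ~1 h |

## Numerical choices

* **Peak search** uses the half-open window (0, 100] ms after stimulus
  onset with ties broken by the earliest sample.
* **Rise crossings** are found *backward-contiguously* from the peak:
  starting at the peak sample the search walks back while the trace
  stays at or above threshold and interpolates linearly at the last
  upward crossing. This ignores pre-stimulus noise excursions above
  threshold. If the supra-threshold run extends to the first
  post-stimulus sample there is no crossing inside the window and the
  crossings — hence the slope — are reported missing rather than 0;
  this is why slope group counts can be smaller than amplitude counts.
* **Slope fit.** The 20–50% window of the fast PV preset spans only a
  handful of 50 µs samples, where a raw sample-OLS is grid-dependent
  (errors up to ~5%). The fit is therefore evaluated on a dense
  201-point linear interpolation of the averaged trace across
  `[t20, t50]`, which agrees with the continuous-time fit to better
  than 0.1% for all presets.
* **Layer bands** are half-open `[lo, hi)` intervals from the pia, so a
  depth on a boundary belongs to the deeper band's upper neighbour
  exactly once; the default boundaries (0, 128, 269, 418, 588, 708,
  890, 1154 µm) are the average mouse barrel-column borders of Lefort
  et al. (2009). An explicit layer label always outranks the
  depth-derived one. L1 depths are classified but flagged
  `analyzed = FALSE` (no L1 recordings).
* **Quartiles** use linear interpolation (type 7), the most common
  convention; the whisker rule is applied to the data points
  themselves.
* **Exact tests.** Exact null distributions are computed by dynamic
  programming over mid-ranks doubled to integers (rank-sum: subset-sum
  counts of size $n_x$; signed-rank: sign-pattern sum counts), which
  handles ties exactly and is polynomial, so "exact" remains cheap well
  beyond the automatic switch at combined n = 20. The normal
  approximations use tie-corrected variances and a continuity
  correction of 1/2; at n = 15 they agree with the exact p to ~0.006
  (rank-sum) and ~0.011 (signed-rank). No multiple-comparison
  adjustment is applied by default, matching the reporting convention
  of this experimental literature; Holm/Bonferroni are available via
  `adjust`.
* **Degenerate inputs.** All-zero paired differences give p = 1 with a
  warning; empty comparison groups yield untestable rows, not errors;
  slices without a usable reference cell are excluded with a warning
  naming the slice and are listed in the pipeline manifest.

## Design choices where the design was open

* **Reference coverage.** The printed cohort sizes put 65 reference
  cells in 33 VPM slices (75 in 43 for POm), i.e. fewer than two per
  slice on average, so the generator guarantees *at least one*
  reference-layer excitatory cell per slice — the minimum normalization
  requires — and errors at configuration time if the sampling rule
  cannot cover every slice. Remaining cells are assigned to slices
  uniformly at random; the within-slice cell-count distribution is not
  otherwise constrained (published examples range ~10–19 cells/slice).
* **Trace container.** Trace payloads live in a hierarchical dataset
  directory — raw little-endian float64 per cell plus a JSON attribute
  table and a separate hand-editable CSV for metadata — keeping bulky
  arrays and metadata apart and making the write→read round trip
  bit-exact.
* **Groups observed once or twice** carry their printed median as the
  generative mean with SD 0.
* **Kinetics defaults** are package choices (configurable), set so the
  slope contrast between PV and EXC matches the qualitative published
  pattern; they are not fitted time constants.

## Problem sizes used by the test-suite

Unit and property tests run on reduced cohorts (3–6 slices, groups
capped at a few cells, 0.25 s traces) where the property under test is
size-independent — normalization identities, determinism, error paths.
The acceptance checks run at the full cohort scale the defaults encode
(33 VPM + 43 POm slices, 388/446 cells), plus 100 seeded
excitatory-only VPM cohorts for the rank-test power check and 100
seeded six-cell stability experiments. The noiseless recovery grid
covers 4 kinetics presets × 10 amplitudes from 0.1 to 30 mV.

## Known limitations

* The pipeline quantifies somatically recorded monosynaptic input; it
  does not correct for dendritic attenuation, liquid junction
  potential (deliberately, matching the recording convention), or
  series-resistance errors.
* Horizontal (column/septum) position is not assigned — only subpial
  depth.
* The per-slice normalization is undefined for slices lacking reference
  cells; such slices are dropped, not imputed.
* Exact-mode rank tests enumerate mid-rank distributions; p-values are
  discrete and conservative in very small samples (the two-tailed
  floor with 8 informative pairs is 2/256 ≈ 0.0078).
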