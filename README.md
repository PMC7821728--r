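# ieegpipe

A headless R pipeline for intracranial EEG (iEEG/ECoG/sEEG) spectral power
analysis, from raw multichannel voltage to group-level mixed-effects
statistics.

Human intracranial recordings are rare, precious and heterogeneous: dozens
to thousands of electrodes per patient, implanted in patient-specific
locations, recorded in blocks across tasks. Labs analyzing such data need
the same computational chain again and again — clean the line noise,
decompose into time-frequency power, re-reference, cut trials around task
events, normalize to baseline, test conditions per electrode, pick
responsive electrodes, and combine subjects without pretending thousands of
trials are independent observations. `ieegpipe` implements that chain as a
scriptable library plus a small CLI, with every stage testable end-to-end
on synthetic recordings with known ground truth.

## The computational core

**Spectral decomposition.** Each channel is convolved with a bank of
complex Morlet wavelets. The default bank has 16 kernels, cycles
interpolated from 3 at the lowest to 16 at the highest frequency (linearly
in log-frequency), kernel durations `cycles / frequency` spanning
0.101–1.433 s. After the wavelet step, coefficients are downsampled to
100 Hz by complex block-averaging (both customizable).

**Referencing after decomposition.** Because referencing is a linear
combination of channels and the wavelet transform is a linear operator,
the order of the two operations does not change the result as long as the
complex coefficients (not just power) are preserved:

    wavelet(v_e - mean_ref(v)) = wavelet(v_e) - mean_ref(wavelet(v))

So the expensive spectral step runs once, and common-average, white-matter
or bipolar re-referencing become cheap arithmetic on stored coefficients.
The package tests this commutation to 1e-8 relative error (it holds to
machine precision).

**Trial analysis.** Epochs are cut time-locked to any event column
(`power = |coef|^2`, `phase = arg(coef)`), baseline-normalized per trial
and frequency as percent power/amplitude change, z-score, or dB from
baseline, collapsed over a time × frequency window to one value per trial,
and contrasted between condition groups (Welch t for two groups, one-way
ANOVA beyond). Per electrode the table reports raw beta weights,
t-statistics, p-values and Benjamini–Hochberg FDR-corrected p-values.

**Selection and group model.** Up to three functional and two anatomical
criteria (conjunction) winnow electrodes. Selected electrodes from all
subjects feed a linear mixed-effects model with electrodes nested in
subjects,

    Power ~ 1 + (1|Subject/Electrode)

optionally with condition fixed effects (REML, Satterthwaite degrees of
freedom), yielding random-effect variances, fixed-effect tests, the
omnibus condition test and all pairwise contrasts — plus per-electrode
univariate tables and post-hoc x/y/z analyses (Pearson/Spearman, paired
t/Wilcoxon, partial regression via residualization).

## Worked example

Simulate one subject (8 electrodes, 48 trials, 1000 Hz; condition A
carries a true +25% power change in 70–150 Hz at 0–0.5 s after onset,
condition B none), run the full chain, and test A vs B per electrode:

```r
library(ieegpipe)

sim  <- simulateDataset(simulationSpec(seed = 42))
sub  <- sim$subjects$S01

bank <- designWaveletBank(designRate = 1000)
bank
#> WaveletBank: 16 kernels @ 1000 Hz design rate
#>   frequencies 2.09-158 Hz, cycles 3-16, durations 0.101-1.433 s

spectra <- waveletTransform(notchFilter(sub$blocks[["001"]]), bank)
spectra <- lapply(spectra, downsampleSpectral, targetRate = 100)
refd    <- applyReference(spectra, buildCAR(sub$electrodeTable))
tensors <- lapply(refd, function(sa)
  buildTrialTensor(list(`001` = sa), sub$epochTable, "Trial", c(-1, 1.5)))
tensors[[1]]
#> TrialTensor electrode 1: 48 trials x 16 frequencies x 250 timepoints
#>   unit: power; locked to 'Trial'; t in [-1.000, 1.490] s; 0 outlier trial(s)

st <- electrodeStatistics(
  tensors, conditionGrouping(list(A = "A", B = "B")),
  timeWindow = c(0.1, 0.4), freqRange = c(70, 150),
  baselineWindow = c(-1, -0.2), baselineUnit = "percent_power",
  baselineMode = "pooled", electrodeTable = sub$electrodeTable)
round(st[, c("Electrode", "beta", "statistic", "p", "p_fdr",
             "mean_A", "mean_B", "n_trials")], 4)
#>   Electrode    beta statistic      p  p_fdr  mean_A   mean_B n_trials
#> 1         1 15.5145    1.6886 0.0982 0.0982 10.1395  -5.3750       48
#> 2         2 27.6846    2.2610 0.0286 0.0381 26.6139  -1.0708       48
#> 3         3 37.7651    3.5064 0.0012 0.0049 28.6495  -9.1156       48
#> 4         4 33.0887    3.1140 0.0033 0.0087 27.8710  -5.2177       48
#> 5         5 22.4479    1.7008 0.0960 0.0982 34.2788  11.8309       48
#> 6         6 28.4251    2.6489 0.0113 0.0227 27.4035  -1.0216       48
#> 7         7 24.7450    2.4929 0.0165 0.0264 29.3160   4.5710       48
#> 8         8 43.9482    4.0458 0.0002 0.0016 27.8254 -16.1229       48
```

`beta` is the A−B difference in percent power change from baseline;
`mean_A` scatters around the injected +25% (per-electrode estimates are
noisy with 24 trials per condition), `mean_B` around 0, and `p_fdr` is the
BH-corrected p-value across the 8 electrodes. From here,
`selectionCriteria()`/`applySelection()` choose electrodes,
`exportLongTable()` + `fitLME()` run the group model.

The same flow is scriptable from a shell via the CLI
(`inst/cli/ieegpipe.R`) with a single YAML config:

```sh
Rscript ieegpipe.R simulate   --config run.yaml
Rscript ieegpipe.R preprocess --config run.yaml
Rscript ieegpipe.R reference  --config run.yaml
Rscript ieegpipe.R epoch      --config run.yaml
Rscript ieegpipe.R analyze    --config run.yaml
Rscript ieegpipe.R select     --config run.yaml
Rscript ieegpipe.R group      --config run.yaml
```

Every stage writes its outputs under the `project/subject/...` tree with a
JSON provenance sidecar (command, config snapshot, package version,
timestamp).

## Not in scope

GUI/visualization layers, 3D brain rendering, electrode localization and
template mapping (anatomical labels are consumed as metadata strings),
EDF/BrainVision/NWB readers, and ICA-style artifact decomposition.
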