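---
title: "Methods: spectral power analysis for intracranial EEG"
author: "ieegpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral power analysis for intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and numerical
choices behind each stage: what is computed, under which assumptions,
which knobs matter, and where the design was genuinely open.

## 1. Data model and storage

Data live in a `project / subject / data-files` tree with `raw/`,
`spectral/`, `referenced/` and `meta/` subfolders per subject. Raw blocks
and spectral coefficients are HDF5; electrode, epoch and statistics
tables are CSV. Spectral storage is one file per electrode per data kind,
with real and imaginary parts as separate datasets and frequencies,
spectral rate and the applied reference as HDF5 attributes. The
per-electrode granularity means a single electrode loads without touching
the rest of the subject, which is what makes interactive re-referencing
and per-electrode exploration cheap.

Conventions fixed across the package:

* all times are seconds, 0-based from block start;
* every window — epoch, baseline, analysis — is half-open `[start, end)`;
* electrode numbers are 1-based integers (clinical convention);
* excluded electrodes and outlier trials are *flags*, never row deletions,
  so every decision is reversible and visible in exports.

The epoch CSV schema is `Block, Trial, Condition, Time` plus any number of
`<EventName>_Time` columns; the electrode CSV schema is
`Electrode, Label, x, y, z, AnatomicalLabel, Group, Excluded`, with unknown
extra columns (e.g. a clinician's epileptiform index) preserved verbatim.
Coordinates are stored but never interpreted geometrically — template
mapping and 3D rendering are out of scope.

## 2. Wavelet decomposition

Kernel *k* is a complex exponential at centre frequency $f_k$ under a
Gaussian envelope, truncated to duration $d_k = c_k / f_k$ seconds and
normalized to unit energy ($\sum_t |w_k(t)|^2 = 1$). Defaults: 16 kernels;
cycles $c_k$ interpolated from 3 to 16 linearly in log-frequency; the
frequency grid is chosen so the duration endpoints are 0.101 s (highest
frequency) and 1.433 s (lowest), i.e. roughly 2.09–158.4 Hz. Only the
durations and cycle endpoints are published configuration facts; the
exact grid and envelope are this package's documented, overridable
choices:

* **Envelope**: Gaussian with standard deviation `duration/6`, truncated
  at `±duration/2` (±3 SD, ~0.3% truncated mass). Documented so a bank is
  reproducible bit-for-bit from its config.
* **Cycle interpolation**: linear in log-frequency, matching common
  wavelet practice and reproducing the monotone 3→16 progression.
* **Convolution**: FFT-based, same-length, zero-padded; an explicit
  per-frequency validity mask marks half a kernel duration at each block
  edge instead of silently trimming, so epoching can warn when a trial
  window touches contaminated samples.

The transform is linear; the test suite asserts
$T(\alpha a + \beta b) = \alpha T(a) + \beta T(b)$ to 1e-10 relative
error, unit kernel energy to 1e-9, and interior power of a stationary
sinusoid constant to < 5% coefficient of variation.

**Downsampling** (default 1000 → 100 Hz) averages consecutive groups of
*complex* coefficients, not power. Averaging in the complex domain keeps
the operation linear, which is exactly what preserves the
referencing/commutation identity after downsampling. Trailing samples
that do not fill a group are dropped; the target must divide the current
rate (the error message suggests the nearest valid rates).

## 3. Referencing in the spectral domain

Referencing is a linear combination of channels; the wavelet transform is
a linear operator; therefore decompose-then-reference equals
reference-then-decompose *provided both real and imaginary parts are
kept*. The package stores complex coefficients throughout and implements:

* **Common average**: subtract the complex mean over all non-excluded
  electrodes (exclusion flags propagate, because concentrated coverage
  over one functional area is otherwise strongly weighted in the mean);
* **White matter**: subtract the complex mean of a user-designated contact
  set (one or several contacts — both are legitimate lab practices, so
  both are supported);
* **Bipolar**: derived channels `anode − cathode`. No single convention
  fixes the pairing rule, so the package pairs numerically
  consecutive contacts within a group (standard sEEG practice), drops the
  last contact of each group, skips gaps with a message, and accepts an
  explicit pairs CSV as an override. Derived channels get synthetic
  electrode numbers above the native range so downstream tables stay
  keyed by one integer.

The commutation is verified to 1e-8 relative error for all three schemes
on random multichannel signals (it holds to ~1e-15; the bound is
deliberately loose to be robust across platforms).

## 4. Epoching and event detection

Trigger onsets are upward threshold crossings (first sample at/above the
threshold after one below) with a refractory `min_separation` that
suppresses pulse chatter; a threshold outside the signal range yields an
empty result with a warning rather than an error, because an empty
proposal is a recoverable state in the semi-automated flow
(detect → write CSV → hand-edit → read back). On noiseless synthetic
triggers, detection is exact at sample resolution.

Epochs are sliced `[event+pre, event+post)` with the event sample at
t = 0. Trials exceeding block bounds, or overlapping the wavelet edge
mask, are excluded with a warning by default (`onEdge = "keep"` retains
the latter). Power is $|coef|^2$, phase is $\arg(coef)$; the
power × phase factorization round-trips the complex coefficient to 1e-10.

## 5. Baseline units and their estimators

With $m$ and $s$ the mean and SD over the baseline window of the trial's
power (or amplitude $=\sqrt{power}$ for amplitude units), per frequency:
percent $= 100(x-m)/m$; z-score $= (x-m)/s$; decibel
$= 10\log_{10}(power/m)$. Two closed-form identities anchor the tests: a
signal whose power exactly doubles reads $10\log_{10} 2 \approx 3.0103$ dB
and +100% power, and dB $= 10\log_{10}(1 + \mathrm{percent}/100)$
cell-wise.

Baselines are computed **per trial** by default, which keeps trials
exchangeable units for the group model. A **pooled** mode (baseline
moments pooled over all non-outlier trials, per frequency) is available
and is what the package's own ground-truth recovery analyses use: the
per-trial ratio estimator $E[x/\hat m]$ carries a multiplicative
inflation of order $k/(k-1)$, where $k$ is the effective number of
independent baseline samples after wavelet smoothing (for a 0.8 s
baseline at ~90 Hz with ~14 cycles, $k \approx 10$, i.e. a ~10% inflation
of recovered percent change). Pooling across ~50 trials makes the
inflation negligible. Whether a given lab baselines per trial or pooled
is a genuine modelling choice; both are exposed, per-trial is the
default, and recovery-against-truth analyses state their use of the
pooled mode.

Condition contrasts: one group → one-sample t against 0 (beta = group
mean, the intercept of a constant-only model); two groups → Welch t
(beta = difference of group means); more → one-way ANOVA omnibus plus
per-group one-sample tests. Identical-value groups are handled explicitly
(t = 0, p = 1) rather than erroring on zero variance. FDR correction is
Benjamini–Hochberg across electrodes within a contrast; the test suite
checks it against a brute-force step-up implementation on vectors up to
length 1000 and verifies the realized false-positive rate on simulated
null electrodes.

## 6. Electrode selection

Up to three functional predicates (statistic, comparator, threshold) and
two anatomical predicates (column, accepted label set) combine by
conjunction only; anatomical matching is exact string membership with no
ontology expansion. Empty criteria are a vacuous conjunction (select
all); an unsatisfiable threshold selects zero electrodes without error.
Tightening any threshold can only shrink the selection (tested as a
monotonicity property).

## 7. Group model

The default model is `Power ~ 1 + (1|Subject/Electrode)`: random
intercepts for subject and electrode-within-subject, REML estimation,
Satterthwaite approximate degrees of freedom for fixed-effect t-tests
(the degrees-of-freedom method was an open choice; Satterthwaite is the
lmerTest default and cheap at these sizes). Condition enters as a fixed
effect on request; the omnibus test is the Type III F (equivalent to the
main effect of condition), per-level tests and all $\binom{levels}{2}$
pairwise contrasts come from estimated marginal means. Pairwise p-values
are unadjusted by default with Bonferroni/Tukey available — the
adjustment policy was unstated upstream, and unadjusted-by-default makes
the bookkeeping transparent.

A single subject (or single electrode) is an *error*, not a silent
degenerate fit: treating thousands of trials from one electrode as
independent creates the illusion of immense statistical power, which the
nested random-effects structure exists to prevent.

Post-hoc x/y/z analyses: Pearson/Spearman correlations and paired
t/Wilcoxon difference tests on per-electrode variables; with a third
variable z, both x and y are residualized on z by OLS first (partial
correlation/difference; verified against the closed-form
$r_{xy\cdot z}$ identity). Derived variables come from a restricted
arithmetic expression language (operators and a short function whitelist
over existing columns) rather than embedded general-purpose code — a
deliberate safety/portability trade-off.

Group power-over-time traces average each electrode's trials first, then
report mean ± SEM **across electrodes** (sample SD, n−1), so the spread
reflects between-electrode variability rather than trial noise.

## 8. What the synthetic generator does and does not emulate

Each channel is 1/f-shaped Gaussian noise (FFT spectrum shaping,
exponent 1 by default, SD 10 µV) plus a 60 Hz sinusoid (5 µV) plus a
condition-locked band-limited power change; a trigger channel carries a
5-unit, 50 ms pulse at every onset, placed exactly on the sample grid.
The effect is injected by scaling the brick-wall in-band component of the
background by $\sqrt{1 + pct/100}$ inside each trial's effect window, so
the true per-frequency percent power change is exactly `pct`, uniform
across the band — which is what makes wavelet-based recovery a sharp
test. Random effects multiply the effect size log-normally
(`pct · exp(η_subject + η_electrode)`), keeping power changes positive;
the SDs are on the log scale.

Default study conditions: one subject, 8 electrodes (a minimal realistic
sEEG shaft), 48 trials at 2.5 s spacing, 1000 Hz, conditions A = +25% and
B = 0% in 70–150 Hz at 0–0.5 s post-onset, no random effects. Block head
padding (2.5 s) exceeds the longest default kernel half-duration
(0.72 s), so first-trial baselines clear the wavelet edge mask.

Recovery analyses measure in the interior window 0.1–0.4 s of the 0–0.5 s
effect (one high-band kernel half-duration inside each edge, avoiding
temporal-smoothing dilution), with a −1 to −0.2 s baseline and the pooled
baseline mode (§5). The Monte-Carlo CI of the recovered percent change is
computed across *per-trial* electrode-mean estimates: under a common
average reference the electrodes share the subtracted reference, so
trials — not electrodes — are the independent units.

What passing these tests does **not** show about real data: the generator
has no epileptiform or movement artifacts, no volume conduction or
between-channel correlation beyond the injected effect, stationary
backgrounds, deterministic trial timing, and rectangular effect
envelopes. It validates the *computational chain*, not robustness to
clinical-recording pathology.

## 9. Problem sizes and numerical tolerances

Test and acceptance analyses use deliberately modest sizes chosen to keep
a full run in minutes on one core while retaining statistical power:
commutation on 4 channels × 10 s × 1000 Hz; FDR behaviour on 100
electrodes × 100–120 replicates of 20-trial nulls; LME recovery on the
8 × 10 × 50 nested design (five replicates, requiring the 2-SE interval
to cover truth in at least four — a single draw fails ~5% of the time by
construction); CI coverage on 100 scaled-down replicates checked against
binomial bounds; end-to-end recovery on the default study conditions.
Floating-point tolerances are graded by mechanism: machine-precision
identities (HDF5 round trip, referencing linearity) at 1e-12 or exact;
FFT-path identities at 1e-8–1e-10; statistical recoveries at Monte-Carlo
CIs.

## 10. Known limitations

* No EDF/BrainVision/NWB/BIDS readers: raw input is numeric matrices or
  HDF5; the import layer is the documented extension point.
* Notch filtering is IIR (zero-phase Butterworth band-stop); a narrow
  notch rings for a few hundred milliseconds at block edges, which the
  edge-mask/padding conventions absorb but very short blocks would not.
* Hilbert/multitaper spectral estimation, Laplacian referencing,
  automatic artifact detection and ICA are out of scope.
* The per-trial baseline inflation (§5) is a property of the estimator,
  not a bug; labs comparing conditions are unaffected (it cancels in
  contrasts), but absolute percent-change readouts with short baselines
  should prefer the pooled mode.
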