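---
title: "Methods: state-dependent stimulus coding in auditory cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent stimulus coding in auditory cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statecoding)
```

## The analysis problem

Head-fixed mice on a treadmill hear 500 ms "tone clouds" centered at one
of 20 frequencies spanning 4–64 kHz while extracellular activity is
recorded from small groups of simultaneously recorded auditory cortical
units. On half of the trials, blue light activates VIP⁺ inhibitory
interneurons (a disinhibitory circuit element); independently, the animal
spontaneously runs on a minority of trials. Crossing the two flags gives
four behavioral/optogenetic conditions — `Still`, `Mvmt`, `Still+VIP`,
`Mvmt+VIP` — and the scientific questions are how movement and VIP
activation, separately and together, change (i) stimulus-evoked spike
rates, (ii) stimulus–response mutual information, (iii) encoding
efficiency, and (iv) the signal/noise structure of pairwise spike-count
correlations.

This package implements that analysis pipeline end to end and ships a
synthetic-session generator with recorded ground truth, because the
recordings themselves are not deposited anywhere. Everything the pipeline
reports on real data it can therefore be shown to recover from data whose
true effects are known.

## Trial annotation

**Movement.** A trial is `Mvmt` when the time-weighted mean treadmill
speed (|velocity|, piecewise-constant interpolation of the possibly
irregular trace) over the stimulus window `[onset, onset + 0.5 s)`
exceeds a threshold set by the noise floor of the optical tracker. The
default is 1 cm/s and it is a per-experiment setting
(`movement_threshold_cm_s`). We average rectified speed; whether the
original hardware reported signed velocity is unknowable from the
description, and for a spherical-treadmill tracker the distinction is
immaterial at the ~8 cm/s vs ~0.2 cm/s separation the data show.

**Windows.** Evoked spikes are counted in `[onset, onset + 0.5)`;
spontaneous spikes in `[onset − 0.7, onset − 0.2)`, i.e. a window of
equal 0.5 s duration ending exactly at LED onset (the LED leads the
stimulus by 200 ms), so optogenetic drive never contaminates the
spontaneous estimate. Windows are half-open so a spike is never counted
twice across abutting windows. The evoked *rate* is the trial-mean evoked
window rate minus the trial-mean spontaneous rate of the same condition.

**Stimulus bins.** The 20 nominal frequencies are collapsed,
order-preserving, into 5 bins of 4 adjacent frequencies. Twenty
single-frequency response distributions cannot be estimated from the
trial counts that remain after conditioning, five can.

**Unit classes.** Units are narrow-spiking (NS, putative inhibitory) when
the waveform trough-to-peak time is under 600 μs, broad-spiking (BS)
otherwise. The trough is the global template minimum (earliest sample on
ties); the peak is the subsequent maximum, and a trough at the final
sample is an error rather than a guess. Classes may also be supplied
directly in `units.tsv` for datasets without templates.

## Trial-count equalization

Because movement is spontaneous, the four conditions occur on very
different numbers of trials, and sample size biases every quantity
downstream (most severely the plug-in information estimate). The pipeline
finds the stimulus-bin × condition cell with the fewest trials — the
minimum is global across all 20 cells, not per condition — and on each of
`n_subsample_iter` iterations draws exactly that many trials without
replacement from every cell. Every reported quantity is the mean across
iterations. A condition with an empty cell is flagged unusable for that
session rather than silently shrinking the subsample to zero. The
production default is 100 iterations; the documented reduced profile used
by the analysis scripts and acceptance checks is 20 iterations, which
leaves the across-iteration mean's Monte-Carlo error well below the
effect sizes of interest at the simulated cohort sizes.

## Information and efficiency

Stimulus–response mutual information is the plug-in estimate

$$I(X;Y) = \sum_{x}\sum_{y} p(x,y)\,\log_2\!\frac{p(x,y)}{p(x)\,p(y)},$$

with \(X\) the 5-level stimulus bin and \(Y\) the raw evoked-window spike
count — raw in two senses: not baseline-subtracted (information is
computed from rates unadjusted for spontaneous activity) and not binned
(the response alphabet is the set of observed counts). The implementation
computes \(H(X)+H(Y)-H(X,Y)\), which is algebraically the same sum.

The plug-in estimator is positively biased at finite trial counts. The
bias is estimated by shuffling: responses are re-paired with stimuli
uniformly at random (`n_shuffles` = 1000 by default, 200 in the reduced
profile), the plug-in estimate of each shuffled table forms a null
distribution, and its mean is subtracted. Corrected values may be
negative and are deliberately not floored at zero — flooring would bias
group means of uninformative units upward. Only the joint entropy changes
under permutation, so the shuffle loop recomputes just that term (a small
C++ kernel driven by R's RNG, so `set.seed()` governs it).

Encoding efficiency is corrected information divided by the mean evoked
count per trial, in bits/spike, computed per subsample iteration and then
averaged; a unit firing no spikes in a condition has undefined efficiency
and is excluded pairwise from efficiency comparisons. The shuffle null is
recomputed inside every subsample iteration, consistent with reporting
across-iteration means of a per-iteration quantity.

## Correlation decomposition

For each simultaneously recorded pair and condition, the total
correlation is the Pearson coefficient between the two units' single
trial evoked-window counts in preserved trial order. The signal
correlation re-pairs trials by permuting each unit's counts independently
*within* each stimulus bin — destroying trial-by-trial co-variability
while preserving tuning — and averages the Pearson coefficient over
`n_signal_shuffles` iterations (default 100; a single shuffle is far too
noisy, and the choice of 100 makes the shuffle error negligible relative
to between-pair spread). Noise correlation is the exact difference
total − signal, so the decomposition identity holds to machine precision
by construction. Pairs are pooled across NS/BS classes, and correlations
are computed on the same equalizing subsamples as the single-unit
metrics, so trial counts match across conditions; a pair in which either
unit has zero count variance in any iteration is undefined for that
condition.

## Group statistics

Paired comparisons between conditions use the two-tailed Wilcoxon
signed-rank test in its normal approximation: zero differences dropped,
midranks with tie-corrected variance, and a continuity correction of 1/2
on the rank-sum deviation (which keeps the approximate p within a few
hundredths of exact enumeration down to five informative pairs — the
package's tests enumerate all \(2^n\) sign patterns to verify this). The
effect size is \(r = |z|/\sqrt{n}\). Within each comparison and unit
class, the three tests on evoked rate, information and efficiency form
one Benjamini–Hochberg family (q = 0.05, m = 3); signal and noise
correlations form a two-test family. Condition means and medians carry
95% percentile bootstrap CIs (1000 iterations), and rate/information
comparisons also report the mean per-unit percent change
\(100\,(b-a)/|a|\) with a bootstrap CI across units; units whose
reference value is exactly zero are excluded from the percent summary
only (an undefined ratio), never from the test. Correlation comparisons
report the mean difference of coefficients instead of a ratio.

## The synthetic-session generator

The generator emulates the study conditions the pipeline assumes: 20
frequencies × 50 repeats × LED on/off (2000 trials) in pseudorandom
order at 2.5 s spacing; movement on a Bernoulli(0.19) subset of trials;
treadmill speeds around 7.83 cm/s (movement) and 0.18 cm/s (still) as a
smoothed step function; per-unit log-Gaussian frequency tuning (center
log-uniform on 4–64 kHz, bandwidth uniform on 0.5–1.5 octaves); NS units
around 12 spikes/s baseline with peak tuned gains of 10–30 spikes/s, BS
units around 4 and 5–15 (NS units fire faster, as in cortex); and
class-consistent waveform templates (400 μs vs ~770 μs trough-to-peak).

Condition effects modulate *rates*, not counts, so information effects
emerge through the estimator rather than being injected: movement
multiplies baseline rates by 1.38 and the tuned evoked component by 0.5
(rate elevation at rest, evoked suppression during movement); VIP
activation multiplies both by 1.5, but only from LED onset, so the
spontaneous window never sees it. A zero-mean Gaussian trial latent
(sd `shared_noise_sd`, default 0.15) multiplies every unit's
evoked-window rate on the same trial, generating noise correlations whose
strength tracks the latent's sd; all rates are floored at zero. Spike
times are an inhomogeneous (piecewise-constant-rate) Poisson process.
Counts are Poisson rather than negative binomial: the pipeline makes no
distributional claim, and an overdispersion knob would not change what
the tests verify. Within-trial tone-pip microstructure is not simulated
because no analyzed quantity depends on it.

What the generator does *not* emulate — slow nonstationarities, bursting,
spike-sorting contamination, state-dependent changes in the shared
latent, across-animal heterogeneity — bounds what green tests mean:
they show the pipeline recovers known effects from data satisfying its
assumptions, not that those assumptions hold in any particular recording.

## Numerical and design choices

* Table I/O is plain TSV with one header line; all times in seconds from
  session start; numeric output carries 6 significant digits, and the
  frequency matcher tolerates 1e−5 relative error so re-read tables bin
  identically (adjacent nominal frequencies differ by ~15%).
* All randomness derives from one seed per pipeline call, consumed in a
  fixed order (equalized estimates, then pair correlations), making runs
  bit-reproducible; the subsample draws are shared across units and pairs
  within an iteration, as the equalization logic requires.
* Analysis scripts and acceptance checks run cohorts of 6 × 10 units
  (parameter recovery) or 3 × 8 units (worked example) at the reduced
  profile; these sizes put Monte-Carlo error comfortably below the
  simulated effect sizes while a full cohort run stays in the minutes
  range on one core.
* For the VIP parameter-recovery experiment the LED baseline gain is set
  to 1 so the prescribed evoked gain of 1.5 is isolated: with the default
  baseline gain of 1.5 the evoked-rate change also absorbs the baseline
  elevation during the LED (the spontaneous window, being pre-LED, cannot
  subtract it), which is a real property of the measurement design, not
  an artifact.

## Known limitations

Plug-in-plus-shuffle is one of several bias corrections; alternatives
(Panzeri–Treves, quadratic extrapolation) are out of scope. The pipeline
treats the stimulus as categorical and codes only spike counts, not
timing. Laminar depth, pupil-linked arousal, and hierarchical
(per-animal) modeling are likewise out of scope; tests and statistics
treat units and pairs as exchangeable within class.
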