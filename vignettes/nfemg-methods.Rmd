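---
title: "Methods: near-fibre EMG metrics, their simulator, and the statistical layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: near-fibre EMG metrics, their simulator, and the statistical layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfemg)
```

## Scope

`nfemg` implements the quantitative layer of a decomposition-based
intramuscular EMG (iEMG) study of motor unit (MU) properties and
neuromuscular-junction (NMJ) transmission stability. It takes decomposed MUP
trains (occurrence times plus one waveform window per discharge, 40 kHz by
default) and produces:

* MUP features: duration, rectified area, turns, SNR, mean inter-discharge
  interval (IDI);
* near-fibre (NF) metrics: NF MUP duration, NF count, jiggle (%), segment
  jitter (microseconds);
* train-level quality control;
* a clustered gamma / inverse-Gaussian GLM layer with BIC link selection and
  Holm-corrected contrasts;
* a Monte-Carlo ensemble around preranked gene-set enrichment with consensus
  leading-edge selection (for the companion transcriptomic arm);
* force-trace scalars (MVC, TTP63%, specific force).

Because no participant data ship with the package, every stage is validated
against a synthetic motor-unit simulator whose ground truth (latency jitter,
blocking probability, amplitude variability, firing statistics) is known
exactly. This document records the modelling and numerical decisions, what
the simulator does and does not emulate, and the problem sizes used in the
validation suite.

## The simulator

**MFP shape.** No fibre model is prescribed by the analysis itself, so the
simulator uses an analytic triphasic kernel — the second derivative of a
Gaussian with characteristic width $w$ — for the muscle-fibre potential
(MFP). Any smooth biphasic/triphasic kernel with distance-dependent
amplitude and width would serve; this one is differentiable everywhere and
cheap to evaluate at jittered, sub-sample latencies.

**Distance attenuation.** Extracellular amplitude decays as a power law,
$A(r) = A_{\mathrm{ref}} (r/r_{\mathrm{ref}})^{-1.5}$ with
$A_{\mathrm{ref}} = 150\ \mu V$ at $r_{\mathrm{ref}} = 0.1$ mm, and width
grows linearly, $w(r) = 0.15 + 0.45\,r$ ms. The exponent and slopes are
configurable; the defaults reproduce the qualitative contrast the NF filter
exploits — distant fibres contribute low-amplitude, low-frequency components
— with amplitudes in the hundreds of microvolts for fibres within ~100
micrometres of the electrode. The 350-micrometre "near-fibre radius" is then
an emergent property of filtering, not a hard-coded cutoff.

**Firing.** Inter-discharge intervals are Gaussian with mean `idi_mean_ms`
(default 100 ms) and CV `idi_cv` (default 0.15), truncated at zero — the
standard renewal model behind IDI summary statistics. A 20-s contraction at
these defaults yields ~200 discharges, comfortably above the 35-occurrence
inclusion threshold.

**NMJ instability.** Jitter is injected at the fibre (endplate) level: each
discharge of each fibre arrives at its mean latency plus a Gaussian offset
with SD `jitter_sd_us`. This is precisely the quantity segment jitter claims
to measure; injecting jitter at the discharge level instead would shift the
whole MUP and cancel out of consecutive-difference statistics. Blocking is a
per-discharge Bernoulli failure with probability `blocking_prob`; amplitude
variability is a log-normal multiplicative factor with unit mean and CV
`amplitude_cv`.

**Noise and seeding.** Baseline noise is white Gaussian with configurable
RMS (default 2 uV); filtered noise is left as a user option. One top-level
seed is split hierarchically (`derive_seed()`) into per-component streams —
discharge times, each fibre's jitter/blocking/amplitude draws, noise — so
adding a fibre never perturbs another fibre's draws, and every generator is
bit-reproducible.

**What the simulator does not emulate.** There is no volume-conductor or
recruitment model, no decomposition errors (trains arrive perfectly
segregated), no electrode movement, and no motor-unit superposition. Passing
the validation suite therefore demonstrates that the *estimators* recover
known ground truth under clean generative conditions; it does not establish
robustness to decomposition artefacts, which in practice are handled by
operator review upstream.

## MUP features

**Template.** Instances are aligned by integer-sample cross-correlation to
a running reference and averaged (median optional). Noise RMS is estimated
from the pre-onset baseline (first 20 % of the window by default).

**Markers.** The study relies on operator-adjusted markers; an automatic,
reproducible rule is required here. Onset/end are placed where
$|v| \ge 3\,\hat\sigma_n$ sustained for at least 0.1 ms; peaks are the
extrema inside the half-open `[onset, end)` window. A flat template raises a
typed `nfemg_marker_failure` condition.

**Turns.** A turn is a direction reversal whose amplitude excursion from the
previously counted turning point is at least 20 uV. The walk keeps a running
extreme in the current direction, counts the extreme as a turn at each
reversal if the excursion condition holds, and then resets the reference to
it; plateaus contribute their last sample. The suite checks exact agreement
with an independently coded extrema-walk recount on 1000 random waveforms.

**SNR.** No definition is printed with the inclusion rule, so the package
uses template peak-to-peak amplitude over baseline noise RMS — monotone in
the obvious inputs and consistent with decomposition-software usage. A
pure-noise train scores far below the threshold of 15.

**IDI mean.** Consecutive differences with a guard against missed or merged
discharges: intervals outside $[0.5, 1.75]\times$ the median interval are
discarded. A single missed discharge (one doubled gap) leaves the estimate
within 2 % of truth.

## Near-fibre metrics

**Filter.** The published pipeline band-passes MUPs with a "second-order
low-pass differentiator" whose exact coefficients are not public. The
package uses the canonical member of that family: a second-derivative-of-
Gaussian FIR kernel (time constant 60 microseconds by default), applied
zero-phase. The sampled kernel is mean-corrected, so its response to
constant input is exactly zero, and by symmetry its response to any affine
input is zero; only the full-overlap region is kept, with the half-kernel
margin zeroed. The validation suite checks affine rejection to 1e-9 relative
tolerance and sinusoid attenuation ratios against the kernel's transfer
function to 1 %.

**NF count and duration.** Contributions are local maxima of the rectified
NF template above $5\times$ the filtered noise RMS (with a 10 % relative
floor so noise-free input behaves sensibly). Because one fibre's filtered
MFP is an oscillatory wavelet with several lobes, peaks closer than 0.8 ms
are merged into the largest; the default separates fibres ~1 ms apart or
more, and the detected count increases statistically with the number of
fibres placed near the electrode. NF duration spans first to last accepted
contribution plus the kernel support margin.

**Jiggle.** Shape variability of consecutive NF MUPs: mean absolute
sample-wise difference between consecutive aligned instances over the NF
window, normalised by the mean rectified NF-window area (the Stalberg-Sonoo
style normaliser, giving a percentage, matching how the metric is reported).
It is exactly zero for a perfectly repeating train, invariant to global
amplitude scaling, and strictly increasing in blocking probability in
simulation.

**Segment jitter.** Temporal variability: one segment per detected
contribution (peak +/- 0.5 ms). Each occurrence's segment latency is the
cross-correlation peak against the template segment, with parabolic
interpolation — at 40 kHz the 25-microsecond sample period is too coarse for
~20-microsecond jitter otherwise. The per-segment statistic is the mean
absolute consecutive difference (MCD); segments average into the final
value. For i.i.d. Gaussian latency jitter with SD $\sigma$, consecutive
differences are $N(0, 2\sigma^2)$, so the expected MCD is
$2\sigma/\sqrt{\pi}$; the suite requires recovery within 10 % at
$\sigma \in \{10, 25, 50\}$ microseconds over 50 seeds, and the estimator
lands within ~2 %. Occurrences whose normalised segment correlation falls
below 0.5 are dropped as contaminated — the automatic stand-in for the
manual exclusion of contaminated NF MUPs.

## Quality control

MUP trains are excluded with fewer than 35 occurrences or SNR below 15; NF
trains require SNR strictly above 15, strictly more than 34 occurrences, and
an NF count of at least 1. Boundary semantics follow the printed wording
exactly (35 occurrences pass the MUP rule; SNR exactly 15 and exactly 34
occurrences fail the NF rules; NF count 1 passes). "Non-physiological
shape" has no printed definition; a heuristic (duration over 40 ms or more
than 25 turns) is available but off by default, documented as a stand-in for
operator review. Reports list every failed rule; batch summaries attribute
each exclusion to its first failing rule so counters conserve the input
count.

## The statistical layer

Each positive-valued MU feature is modelled as
`value ~ time_point` with subject-level clustering, under a gamma or
inverse-Gaussian distribution. The clustering contract — "cluster variable:
subject" — does not pin down a random-effects structure, so the package
fits a subject random intercept (`lme4::glmer`) as the primary estimator
and falls back to a fixed-effect GLM with cluster-robust (CR0) covariance
when the mixed fit errors, is singular, or raises convergence warnings; a
warned `glmer` fit can carry a degenerate covariance, and the robust GLM
honours the same clustering contract. Confidence intervals and p-values use
a t reference with `n_subjects - 1` degrees of freedom: with 11 subjects,
normal-based Wald intervals undercover because the cluster-level variance is
estimated from few units. Under these choices the planted-effect coverage
over 200 simulations at 11 subjects x 20 MUs sits at ~0.97 for a nominal
0.95.

**Family/link selection.** The candidate menu is the set of pairs used in
the analysis design: gamma x inverse, inverse-Gaussian x {identity, inverse,
inverse-squared}; the log link is available but excluded by default.
Selection minimises BIC; fits within ΔBIC < 2 of the minimum (the
conventional equivalence band) resolve to the canonical link of their
family — inverse for gamma, inverse-squared for inverse-Gaussian.
`select_by_bic()` defaults to the fixed-effect GLM for the candidate fits so
that every candidate's BIC comes from the same likelihood: `glmer` cannot
fit the inverse-squared link reliably, and mixing mixed and non-mixed
likelihoods would make the comparison meaningless. The selected family/link
can then be refitted with the mixed estimator for inference.

**Post hoc.** All pairwise time-point contrasts are Wald tests on the link
scale using the stored coefficient covariance, Holm-corrected
(`stats::p.adjust`).

## Ensemble enrichment

The transcriptomic arm ranks all genes by $-\log_{10}(p)$ and tests a small
set of curated pathways. `enrichment_score()` implements the weighted
Kolmogorov-Smirnov running-sum statistic (weight exponent 1 by default, 0
gives the classic KS form) with a gene-permutation null. The permutation
p-value is one-sided against the same-sign half of the null distribution —
the standard GSEA convention — which makes a truly exchangeable null set
select at exactly the nominal level; normalising against the full null
would double the effective level.

Because permutation-based enrichment estimates are themselves stochastic,
`mc_ensemble()` embeds the analysis in a Monte-Carlo ensemble (1000
iterations by default) with independent permutation streams and records
per-set selection frequencies and per-gene leading-edge frequencies.
Consensus significant pathways and consensus leading-edge genes use the
strict > 0.8 frequency rule (a gene at exactly 0.8 is excluded). Whether
the original ensemble varied only permutation streams or also resampled the
upstream data per iteration is not stated; both behaviours are supported via
the `resample_ranking` hook, with permutation-only as the default. Note that
with a fixed ranking the ES and leading edge are deterministic — only the
p-value varies across iterations — so the calibration experiment in the
validation suite uses the resampling hook to draw an independent null
ranking per iteration, where the null set's selection frequency lands within
binomial error of the 0.05 level.

## Force metrics

MVC is the maximum over trials. TTP63% is the time from contraction onset to
the first interpolated crossing of 63 % of MVC; the onset (not defined in
the source protocol) is the last sample at or below baseline mean + 3 SD
before the first sustained (10 ms) supra-threshold excursion — the sustained
run keeps isolated noise spikes from triggering a false onset. On an
exponential rise with $\tau = 150$ ms the estimate matches
$-\tau\ln(0.37) \approx 149.1$ ms within one sample period. Whether the
original analysis took TTP63 from the MVC trial itself or the fastest-rising
trial is unknown; the function takes any trace plus an MVC reference, so
either convention is one call away. Specific force is MVC divided by
cross-sectional area.

## Validation problem sizes

The test suite simulates at the protocol scale — 20-s contractions at
40 kHz, ~200 discharges per train, 11-subject cohorts with 20 MUs per cell —
with these ensemble sizes: 50 seeds per jitter level and per blocking level;
1000 random waveforms for the turns recount; 200 cohort simulations for CI
coverage; 100 for BIC selection; 1000 ensemble iterations x 1000
permutations for enrichment. The acceptance script
(`scripts/acceptance.R`) re-runs the same experiments at moderately reduced
ensemble sizes (25-30 seeds, 500 iterations) chosen to keep a full
from-scratch reproduction in the minutes range on a single core.

## Known limitations

* The NF filter matches the published filter family, not its exact
  (unpublished) coefficients; absolute NF amplitudes are therefore not
  comparable to DQEMG outputs, though all relative and variability metrics
  are.
* Jiggle values depend on the NF window and normaliser; cross-software
  comparisons should compare trends, not absolute percentages.
* The GLM layer treats time as a fixed factor with a subject intercept; it
  does not model MU-level repeated measures across time points (MUs are not
  tracked longitudinally in this design).
* The simulator's geometry (a scalar radial distance per fibre) is a
  modelling choice, not a reproduction of any electrode's recording field.
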