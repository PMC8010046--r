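---
title: "Mass-univariate mixed-model cluster inference for ROI timecourses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-univariate mixed-model cluster inference for ROI timecourses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustlmm)
```

## The statistical problem

`clustlmm` implements the analysis chain used in minimal-contrast MEG
reading studies: single-trial region-of-interest (ROI) source estimates —
signed, noise-normalised activation values on a millisecond grid — are
tested for condition effects while controlling for lexical covariates and
participant-level baseline differences, with family-wise error controlled
non-parametrically over time. The package also provides the spectral
companion analysis (induced vs evoked band power) and the
information-theoretic metrics used to adjudicate between structural and
probabilistic explanations of a timecourse effect. Because trial-level MEG
recordings of this kind are rarely released, the package ships a
synthetic-data generator that reproduces the experimental design's exact
factorial and block structure, so that the entire chain runs — and is
tested — without any recording.

## The model at each timepoint

At every timepoint $t$ of an analysis window, activation is modelled with
two nested Gaussian linear mixed models with a participant random
intercept, fitted by maximum likelihood:

$$y_i(t) = \beta_0 + \mathbf{x}_i^{\top}\boldsymbol\beta
  + b_{p(i)} + \varepsilon_i, \qquad
  b_p \sim \mathcal N(0, \sigma_b^2),\;
  \varepsilon_i \sim \mathcal N(0, \sigma^2).$$

The *full* model contains the variables of interest (for example the
three-level syntactic-structure factor) plus nuisance covariates
(z-scored Zipf frequencies, log trial onset time, optionally gender); the
*reduced* model drops the variables of interest only. The statistic is
the likelihood-ratio $\chi^2(t) = 2\{\ell_{\text{full}}(t) -
\ell_{\text{red}}(t)\}$, asymptotically $\chi^2_{df}$ under the null with
$df$ equal to the number of dropped fixed-effect columns: 2 for the
three-level structure factor, 1 for noun definiteness, 3 for the
block-type-by-definiteness and category-by-definiteness crossings, 11 for
the three-way semantic crossing (`model_preset()` encodes these).

**ML, not REML.** The comparison is between fixed-effect structures, for
which REML likelihoods are not comparable; both models are therefore
fitted by ML. The fits use a profiled likelihood written for exactly this
model class: with $V_\theta = I + \theta ZZ^{\top}$ and
$\theta = \sigma_b^2/\sigma^2$, every quantity reduces to small
cross-product matrices, and $\theta$ is profiled with a coarse
log-grid plus golden-section refinement, evaluating the $\theta = 0$
boundary exactly. This makes a single timepoint fit cost microseconds,
which is what renders $10^4$-permutation Monte-Carlo tests tractable; the
log-likelihoods agree with `lme4::lmer(..., REML = FALSE)` to the
optimizer tolerance (this is asserted in the test suite, where `lme4`
serves as an independent oracle, and the $\theta = 0$ case is checked
against closed-form OLS likelihood ratios).

**Non-convergence.** The profiled 1-D likelihood cannot diverge, but if a
fit produces a non-finite value (e.g. a numerically singular design) the
timepoint falls back to the OLS likelihood-ratio statistic and is
flagged, keeping timecourses gap-free and audits possible. Negative LR
differences — possible only through optimizer tolerance — are clipped to
zero and flagged through the convergence vector.

## Cluster-mass permutation inference

Timepoints whose $\chi^2$ strictly exceeds the 95th percentile of the
$\chi^2_{df}$ reference distribution are clustered by temporal
contiguity; a cluster's *mass* is the sum of its member statistics, and
the biggest observed mass per ROI is the decision statistic. The null
distribution is built by shuffling the variable-of-interest labels across
trials *within each participant* and recomputing the full timecourse;
the p-value is the proportion of permutation masses strictly greater
than the observed one (permutations without suprathreshold samples
contribute mass 0). P-values are then FDR-corrected (Benjamini–Hochberg)
across ROIs.

Numerical and design choices, with rationale:

* **Strictly-greater proportion, no smoothing.** The proportion rule is
  applied literally; `p_smoothing = TRUE` gives the conventional
  $(b+1)/(m+1)$ estimator for users who prefer never-zero p-values.
* **Covariates stay trial-bound.** Only the variables of interest are
  permuted; Zipf frequencies and onset times remain attached to their
  trials, so the test targets the conditional association that the LRT
  measures. (Shuffling whole rows instead is a coarser null; the choice
  matters only when covariates correlate with condition.)
* **Clusters are temporal-only within one ROI**, matching the per-ROI
  averaging design; there is no spatial adjacency structure to exploit.
* **Permutation RNG**: a master seed draws one sub-seed per permutation,
  so results are reproducible and independent of evaluation order. ROIs
  use independent streams.
* **Strict inequality at the cluster-forming threshold** ("exceeding"),
  and closed analysis windows: boundary samples at both window edges are
  included.
* **Reference levels**: treatment coding with the alphabetically first
  level as reference; marginal means downstream are coding-invariant, and
  the LRT is invariant to any full-rank recoding.

Calibration is asserted empirically in the acceptance suite: across 200
replicate null experiments (12 participants, 24 trials/cell, 50
timepoints, 200 permutations) the family-wise false-positive rate must
lie in the binomial 99% band [0.02, 0.10] around 0.05, and an injected
3-SD effect must be detected with its cluster overlapping the true
window in at least 90% of replicates.

## Marginal means within clusters

Activity is averaged over the cluster's timepoints per trial and refit
against the full fixed-effect structure (random intercept per
participant; this single fit uses `lme4` with REML). Estimated marginal
means are predictions on the reference grid — the full cross of factor
levels with covariates at their observed means — averaged with equal
weights over the factors not in the requested family. All pairwise
contrasts within the family are tested with a Tukey (studentized-range)
adjustment by default; Bonferroni and unadjusted are available. When a
planned subset of contrasts is requested, the family size is the number
of requested contrasts and a Bonferroni-type scaling replaces the
studentized range, which does not apply to subsets. Degrees of freedom
are the large-sample residual $n - p$; Satterthwaite/Kenward–Roger
approximations are deliberately out of scope — at hundreds of trials per
fit the difference is negligible relative to the adjustment choice.

## Spectral module

Single-trial epochs are decomposed with complex Morlet wavelets (4 cycles
at every frequency, 8–32 Hz in 1-Hz steps). The wavelet is scaled so a
pure sinusoid of amplitude $A$ yields power $A^2/2$ at its frequency;
samples within the truncated half-support ($3\sigma_t$) of an epoch edge
are flagged rather than corrected. Per epoch and frequency, power is
baselined as $\log_{10}(P / \bar P_{\text{baseline}})$ with the −100–0 ms
pre-onset baseline, literally per epoch before any averaging; the time
axis is then decimated by subsampling (factor 5) and trials are averaged
per subject and condition.

Condition pairs are compared point-wise with one-tailed paired t
statistics across subjects, thresholded at the $t_{n-1}$ 95th percentile
(the reference-distribution reading of the threshold; thresholding at the
empirical map's own 95th percentile is the alternative reading and is not
used). Suprathreshold points are clustered with 4-connectivity on the
time–frequency lattice, and the null is built by random within-subject
condition exchanges — sign flips of the subject difference maps, the
exchangeability-correct scheme for a paired design. FDR is applied across
the requested comparison set (three pairwise comparisons in the shipped
workflow). Log base 10 is a documented constant; the base scales the maps
but cannot change any test statistic.

The *evoked control* repeats the identical analysis on time-domain
averaged responses per subject and condition. A genuinely induced
(non-phase-locked) effect attenuates in the average as $1/\sqrt{n}$ in
amplitude, while phase-locked components survive — so induced effects
must lose their clusters there. Note a subtlety that shapes the synthetic
scenario below: log-ratio baselining is invariant to global scaling, so
with *only* white noise the induced component's within-bin SNR is
unchanged by averaging, and the dissociation cannot appear. It is the
presence of a phase-locked evoked component (as in real recordings) that
dominates the averaged signal and silences induced differences in the
control analysis.

## Information-theoretic metrics

Over a transition table $P(\text{continuation} \mid \text{context})$ —
derived from the design itself or supplied as a corpus CSV — the package
computes, in bits: entropy over continuations, entropy reduction between
successive states (floored at zero following the standard formulation; a
signed variant is available), and surprisal $-\log_2 p$. End of trial is
defined as zero posterior entropy. In the balanced design these have
closed forms: the structure prior is uniform over three, so an
indefinite noun (probability 1/3) carries $\log_2 3 \approx 1.585$ bits
of surprisal and collapses the full 1.585 bits of structure uncertainty,
while a definite noun carries 0.585 bits and leaves 1 bit; an adjective
has zero surprisal only after an indefinite noun. Zero-probability
outcomes raise an error rather than returning infinite surprisal. The
shipped corpus table under `inst/extdata/` is a clearly-labelled
synthetic stand-in for an actual corpus estimate, for interface
illustration only.

## The synthetic world

`generate_design()` reproduces the stated experiment: 36 sets × 20 cells
(12 two-word cells crossing three syntactic structures — indefinite
phrase, sentence, definite phrase — with noun conceptual specificity and
adjectival form typicality; 8 single-word controls), 720 trials per
participant in 10 blocks (6 two-word, 4 single-word), one third task
trials split 1/2 good, 1/4 grammatical violation, 1/4 plausibility
violation, and 300 ms on / 300 ms off presentation with a uniform
466.66–700 ms inter-trial jitter accumulated into onset times. Many Latin squares satisfy the block constraints; the package fixes one
feasible scheme: each set's 12 two-word cells are paired into 6
within-block pairs sharing no word token and rotated across the 6
two-word blocks by set index (mod 6), and analogously 8 one-word cells
over 4 blocks (mod 4); this requires the set count to be a multiple of
12 and guarantees each word token appears at most once per block. Sets
are split half masculine, half feminine. Word tokens are abstract IDs
with attribute bundles — the statistics never consume orthography — and
Zipf frequencies are drawn once per token from $\mathcal N(4.5, 0.7^2)$
truncated to $[1, 7]$, a realistic mid-frequency range whose exact
values are irrelevant to the inferential tests.

`simulate_roi_epochs()` builds activation as participant intercept +
covariate slopes × globally z-scored covariates + condition-effect
kernels + AR(1) noise. Defaults declare the assumed world: 200 Hz
sampling (261 samples over −100–1200 ms; desk-scale loops rather than
the recording's native 1000 Hz), AR(1) coefficient 0.5 (single-trial
source-estimate noise is serially correlated, but its structure is not
well characterised; the AR(1) form is a package assumption surfaced in
the config), residual SD 1 in dSPM-like units with participant-intercept SD
0.5, and injected effect windows mirroring the reported cluster latencies
(254–334 ms after noun onset, 867–964 ms = ~300 ms after adjective
onset). Missing covariates for single-word trials (e.g. an absent
adjective frequency) are mean-imputed to zero after z-scoring, which
leaves two-word estimates untouched in balanced designs. What the
generator does *not* emulate: 1/f background spectra, sensor topographies
and source leakage, eye/heart artefacts, or item-level random variation
beyond the word-frequency covariates. A green test therefore establishes
the *statistical machinery* — calibration, power, recovery — under the
declared noise model, not robustness to real MEG noise.

`simulate_oscillatory_trials()` adds windowed sinusoidal bursts with
shared phase (evoked) or i.i.d. uniform phase per trial (induced) plus
white noise, giving closed-form expectations for every spectral test.

## Degenerate inputs and tie-breaks

Empty analysis windows, out-of-epoch effect windows, fewer trials than
fixed-effect columns, unobserved factor levels, rank-deficient designs
(reported with the aliased column names), frequencies at or above
Nyquist, and invalid probability vectors all raise immediate
`invalid-argument` errors. An observed timecourse with no suprathreshold
sample yields "no cluster", reported as p = 1 with a flag rather than an
undefined value. Clusters are ordered by descending mass with start index
as tie-break.

## Known limitations

* The random-effects structure is a single participant intercept — by
  design: richer random-effects structures routinely fail to converge on
  trial-level source estimates and are out of scope; crossed item effects are not modelled.
* Permutation and FDR corrections assume exchangeability within
  participant and independence of ROI streams; cross-ROI dependence of
  the FDR inputs is not modelled (shared shuffles across ROIs would be
  the alternative).
* EMM standard errors use the large-sample residual-df approximation.
* The spectral module has no sensor dimension; "sensors" are collapsed
  before the package sees the data, matching the all-sensor averaging this
  workflow assumes.
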