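---
title: "tmtstat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tmtstat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Tandem mass tags (TMT) multiplex up to 10–16 biological samples into one
MS run; reporter-ion intensities quantify each sample's share of every
identified spectrum. Experiments larger than one plex spread subjects
across several *mixtures*, each possibly acquired in several *technical
replicate runs*, and the design may be unbalanced. The analysis question
is per-protein differential abundance between conditions, and the
statistical difficulty is that biological variation (between subjects)
and technical variation (between mixtures, between replicate runs, and
residual) enter the data in a nested, split-plot-like pattern that simple
per-channel models conflate.

`tmtstat` implements a four-stage workflow: spectrum-level normalization,
per-run protein summarization, protein-level normalization, and
mixed-model inference, plus a spike-in simulator and an evaluation
harness so that every stage is testable without external data.

# Stage by stage

## Import and feature construction

PSM reports are read from long or wide tables (including
Proteome-Discoverer- and MaxQuant-flavoured headers). The converter
rules are:

* peptide ions mapped to more than one protein are removed entirely;
* spectra with more than `max_missing_fraction` (default 0.5) missing
  channels are removed;
* when several spectra quantify one peptide ion in a run, one *best*
  spectrum is kept — fewest missing channels, then highest summed
  intensity, then lowest interference score, then first spectrum id.
  The summed (not maximal) intensity is used because "highest intensity"
  is otherwise ambiguous for a 10-channel spectrum;
* in fractionated experiments a peptide ion is kept only in the fraction
  with the highest mean intensity, ties broken by highest maximal
  intensity, then fraction id.

Zero and negative raw intensities become missing *before* the log2
transform (they are below any detection limit; keeping them would
produce `-Inf`). All downstream work is on the log2 scale.

## Normalization

**Global median normalization** shifts every (run, channel) column so its
median over observed features equals the median of all column medians.
Anchoring at the median-of-medians (rather than zero) preserves the
overall intensity scale. This step assumes most proteins are unchanged
between conditions; the simulator's default spike fraction (1%) reflects
the regime where that assumption holds. When a large fraction of the
proteome shifts, the step visibly compresses fold changes — that is a
property of the method, not of this implementation.

**Reference-channel normalization** works per protein: the summaries of
the reference ("Norm") channels of each run (averaged on the log2 scale
if a run has several) are equalized to their median across runs, and the
per-run shift is applied to all channels of that run. Runs in which the
protein has no reference summary are left unshifted and flagged. A
subtlety worth recording: injecting arbitrary per-run shifts and
re-normalizing reproduces the normalized data only up to one constant
per protein, because the anchor (the cross-run median of reference
summaries) itself moves with the shifts. The run-dependence — the thing
the normalization exists to remove — is eliminated exactly, and all
within- and between-run contrasts are invariant; the tests assert
exactly that form.

## Summarization

Per protein and run, the feature-by-channel matrix of log2 intensities
is summarized in two steps.

*Imputation.* Missingness in TMT data is predominantly left-censoring of
low-abundance signals. An accelerated-failure-time model (Gaussian
log-location-scale, i.e. a censored linear model on the log2 scale) with
feature and channel main effects is fit with missing cells treated as
left-censored at the matrix's minimum observed value (`censor_mult`
scales this threshold). A cell is imputed only when its feature has at
least one observed channel and its channel at least one observed
feature; whole-missing features or channels stay missing. Predictions
are capped at the censoring threshold — a censored observation cannot
exceed its limit. If the censored fit fails, imputation is skipped for
that protein and run.

*Median polish.* Tukey's median polish alternately sweeps row and column
medians (rows first, `tol` 1e-4 relative on the sum of absolute
residuals, at most 100 sweeps). The channel summary is the overall term
plus the channel's column effect. The median sweeps give the summary a
50% breakdown point per row/column, which is the defence against
interference-corrupted outlier spectra. Single-feature proteins bypass
the polish (a 1×K decomposition is ambiguous); their intensities pass
through directly.

## Modeling and inference

The normalized summaries `Y` of one protein are modeled as

    Y = mu + Mixture + TechRep(Mixture) + Condition + Subject + error

with `Condition` fixed and the other terms independent Gaussian random
effects with variances (sM², sT², sS², s²). The member of this family a
design supports is chosen up front: both mixture-level terms and the
subject term need replication (multiple mixtures; multiple runs per
mixture). With one mixture and one run the model is the fixed one-way
layout. Per protein, any random term with fewer than two observed
levels, or confounded with the residual (every subject observed once),
is dropped. Singular or non-converged fits are retried after dropping
terms in the order TechRep → Mixture → Subject — the smallest-scope
technical term goes first, the biologically meaningful subject term
last.

Fitting is REML via `lme4`. Degrees of freedom for a contrast come from
a Satterthwaite approximation implemented on the variance scale: the
REML deviance is reconstructed as a function of the variance parameters
from `lme4`'s modular deviance function, its finite-difference Hessian
gives the covariance of the variance-parameter estimates, and
`df = 2 (c'Vc)² / Var(c'Vc)` by the delta method. In balanced designs
this reproduces the exact classical stratum df (the tests check the
between-subject df `n_subjects - n_conditions` in a 2-condition ×
8-subject-per-condition × 3-replicate layout); `lmerTest` is not used.
The residual degrees of freedom fed to moderation are obtained the same
way (`2 s⁴ / Var(s²)`), which reduces to `n − p` for fixed models.

**Empirical-Bayes moderation** pools residual variances across proteins:
the first two moments of `log s²` are matched to the log-chi-square
theory (the scaled-F prior of the moderated-t framework), yielding prior
df `d0` and prior variance `s0²`; the moderated variance is the usual
weighted combination and the contrast df is augmented by `d0` (capped at
1e6 when `d0 = ∞`). Moderation applies to the residual variance only —
the subject/mixture/run variance components are protein-specific
biology and technology and are not shrunk. The contrast variance is
re-evaluated with the residual variance replaced by its moderated value
rather than rescaled, so the substitution is exact in the model's own
covariance.

p-values are two-sided t-tests; Benjamini–Hochberg runs within each
comparison label over testable proteins only (a protein is testable when
it has more than one summary in more than one condition). Untestable
proteins are reported with an issue code and excluded from the BH
denominator.

# The simulator

`simulate_controlled_mixture()` emulates a UPS1-style spike-in dilution
series: 5 mixtures × 3 technical replicate runs of a TMT 10-plex, four
conditions at amounts 500/333/250/62.5 (so the true fold changes of the
pairwise comparisons are 2, 4, 8, 5.328, 4/3·…, i.e. ratios of the
amounts) in duplicate, plus two pooled-reference channels at the mean
amount. Defaults (chosen once, as the realistic regime):

* baseline log2 abundance `N(16, 1.5²)`; feature (ionization) effects
  `N(0, 1)`; run shifts `N(0, 0.5²)`; cell noise `N(0, 0.2²)`;
* ~5 features per protein (1 + Poisson(4));
* 1% spiked proteins — the controlled-mixture benchmark has ~0.4%, and
  global median normalization assumes a sparse signal;
* 10% of feature-runs missing completely at random (failed
  identification), plus hard left-censoring below log2 intensity 12
  (a logistic censoring probability is available as an option).

`simulate_protein_summaries()` generates normalized protein summaries
directly, standing in for the published protocol of adding noise to
*real* summaries. Because real summaries are strongly heteroscedastic
across proteins (the very premise of EB moderation), per-protein
residual variances are drawn from a scaled inverse-chi-square (prior df
6, scale 0.2²); a homogeneous base would drive the estimated `d0` to
infinity and distort the far tail of the moderated tests — a regime real
data cannot produce. Mixture and run effects default to `N(0, 0.1²)`
each, the residual technical variation left after reference
normalization.

`add_biological_variation()` implements `Z = Y + e`, `e ~ N(0, sS²)`
drawn once per protein × subject and added identically to all technical
replicates of that subject; reference channels are untouched. The
benchmark grid is `sS ∈ {0.05, 0.1, 0.15, 0.2, 0.4}`; at `sS = 0.2` the
true subject variance is 0.04.

What a green test does **not** establish: the simulator has no
co-isolation interference or ratio compression, no fractionation, no
MS2-vs-MS3 acquisition differences, and uses a parametric base rather
than real summaries — absolute operating characteristics on real data
will differ; relative behavior (e.g. the cost of dropping the subject
term) is what the tests certify.

# Numerical choices and edge cases

* Median polish starts with rows; convergence is relative 1e-4 on the
  sum of absolute residuals; ties inside medians follow R's `median`.
* The Satterthwaite Hessian uses central differences with steps
  `1e-3 · |v|` per variance parameter; components at the zero boundary
  are removed by the term-dropping fallback before this point.
* Variance components are non-negative by the REML parameterization;
  singularity is `theta < 1e-4`.
* A contrast on a condition the protein was never observed in yields
  issue `oneConditionMissing`, no p-value; a protein with no data at all
  `completeMissing`; a zero-variance noiseless null gives p = 1 when the
  estimate is exactly zero, otherwise `unestimableContrast`.
* eFDR of an empty call set is defined as 0; AUC ranks by adjusted
  p-value with midrank tie handling.
* Every stochastic entry point takes an explicit integer seed; the
  pipeline is byte-deterministic given (inputs, config, seed).

# Known limitations

The split-plot model is applied at the protein-summary level only (its
sub-subplot reduction); feature-level mixed models are out of scope.
Time-course and paired designs are not supported. Protein groups pass
through as opaque identifiers. The moderated df rule `df + d0` is the
standard moderated-t augmentation; when a contrast's variance is
dominated by the (unmoderated) subject component and `d0` is large, the
augmented df overstates certainty slightly — with heteroscedastic data
(finite `d0`, the realistic case) the effect is negligible, and the
unmoderated pipeline is exactly calibrated in the package's null
simulations.
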