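---
title: "Avalanche statistics and criticality: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Avalanche statistics and criticality: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avalanchr)
```

# The scientific problem

A recurrent neural circuit can sit anywhere between two extremes: activity
that dies out faster than it propagates (subcritical) and activity that
explodes (supercritical). The criticality hypothesis holds that cortex
operates near the boundary, where propagation is marginally
self-sustaining. Near that point, bouts of elevated population activity —
*neuronal avalanches* — show scale-free statistics: avalanche sizes follow
$P(S) \sim S^{-\tau}$, durations follow $P(D) \sim D^{-\alpha}$, mean size
scales with duration as $\langle S \rangle \sim D^{\beta}$ with
$\beta = (\alpha-1)/(\tau-1)$, and single neurons spike more irregularly
than a Poisson process ($CV_{ISI} > 1$). This package implements the full
chain of analyses needed to evaluate those signatures on population spike
data, together with a simulator that generates ground-truth data in each
dynamical regime.

# The avalanche definition

Network activity is the number of neurons active per time bin (default
0.25 s). With ~100 neurons the population is rarely silent, so avalanches
are defined by threshold crossing rather than by silent gaps: an avalanche
is a maximal run of bins with activity *strictly above the median* of the
activity series. Size is the raw integrated activity over the run
(threshold-subtracted integration is available via `integrate = "excess"`),
duration the run length. Choices fixed here:

- **Strict inequality at the median.** With integer counts and a possibly
  half-integer median, `> median` is unambiguous; bins tied with an integer
  median count as below.
- **Edge runs are discarded.** A run touching the first or last bin has no
  observed crossing, so its size would be censored.
- **Counting rule within a bin.** A neuron contributes 1 to a bin if it has
  at least one spike frame there (`rule = "neuron"`); at the slow imaging
  rates this emulates (~4 Hz, one frame per 250 ms bin) this coincides with
  summing frames (`rule = "sum"`), but the rule must be fixed because the
  two differ for fast rasters. The analysis bin must be an integer multiple
  of the raster resolution (1% tolerance); the pipeline realizes "250 ms"
  as the nearest integer number of frames.

# Truncated power-law inference

## Model and estimator

Sizes are modeled by the doubly truncated discrete power law
$$f(S) = \frac{S^{-\tau}}{\sum_{s=S_{min}}^{S_{max}} s^{-\tau}},
\qquad S \in \{S_{min}, \dots, S_{max}\},$$
fitted by 1-D likelihood maximization over $\tau \in (1.01, 5]$ (tolerance
$10^{-4}$; the log-likelihood is concave in $\tau$, so `optimize` is
exact). Fit quality is the KS statistic: the sup-distance between empirical
and model CDFs on the support. The same machinery fits durations
(exponent $\alpha$).

Support selection is iterative: starting from the observed maximum,
exponents are fitted for $S_{min} \in \{1,2,3\}$, the candidate with the
smallest KS wins (ties go to the smaller $S_{min}$, which keeps more
data), and $S_{max}$ is decremented until the KS value falls below a
convergence threshold. Two design choices deserve emphasis:

- **Convergence threshold $1/\sqrt{N_{av}}$.** Empirical-CDF fluctuations
  of a correctly specified sample of size $N$ live on the $1/\sqrt{N}$
  scale, so well-fitting data converge with little or no truncation while
  misspecified data are driven far down the support. A threshold of $1/N$
  (available as `ks_criterion = "literal"`) sits far below sampling noise
  for realistic $N$ and forces every dataset — however well fitting — onto
  a near-minimal support where one parameter can interpolate the empirical
  CDF; we do not recommend it and it is not the default.
- **Excluded-tail guard.** The upper truncation exists to absorb a handful
  of beyond-cutoff events (finite-size effects, outliers). A candidate
  support may only be declared converged while at most `max_tail_fraction`
  (default 10%) of the samples at or above its $S_{min}$ lie beyond its
  $S_{max}$. Without this guard, strongly non-power-law data (e.g.
  spike-time-shuffled controls, whose sizes are near-geometric) "converge"
  onto two or three atoms that interpolate the empirical CDF exactly while
  relegating ~40% of the data to the excluded tail — a formally successful
  but meaningless fit. With the guard such data end flagged
  `converged = FALSE` with a large KS. True power-law samples are
  unaffected: their excluded tails are at the percent level.

Non-convergence is a flagged result, not an exception, so batch runs over
many conditions continue; the flagged fit still carries the best support
found and its exponent.

## Surrogate goodness-of-fit test

1000 surrogate datasets are drawn from the fitted model — matched in
exponent, sample count and support — and each surrogate's KS distance to
that same model is computed *without refitting*. The p value is the
fraction of surrogates whose KS is at least the data's KS; the power-law
hypothesis is rejected when $p < 0.05$. Because the data's exponent and
support were chosen to fit while the surrogates are not refit, the data KS
is stochastically smaller than the surrogate KS under the null: the test
is conservative (its measured rejection rate on truly power-law data, in
the acceptance suite, is below the nominal level). Non-converged fits may
be tested too; their KS typically exceeds every surrogate's and yields
$p \approx 0$.

One limitation is documented rather than patched: data whose minimum lies
inside the candidate range and whose shape is only mildly non-power-law
can still converge legitimately on a strongly reduced support; the
`excluded_tail` and support fields of the fit, not the p value alone,
reveal such collapses.

## Surrogate generation

Surrogates and test samples are drawn from the *discrete* truncated pmf via
its inverse-CDF table (`method = "discrete"`), keeping sampling internally
consistent with the likelihood. The continuous inverse-transform
convention $S = S_{min}(1-r)^{-1/(\tau-1)}$, floored to integers with
above-cutoff draws redrawn (preserving sample size and the renormalized
shape), is available as `method = "inverse"`; for $S_{min} = 1$, where the
plain floor misweights the first atom, that path uses the floored draw as
the envelope of an acceptance–rejection step against the target pmf.

## Bootstrap uncertainty

Exponent uncertainty is the SD of re-fitted exponents over 1000 resamples
of the avalanches with replacement. Resamples on which the fit fails
outright (degenerate support, too few in-range samples) are skipped and
counted; refits that merely miss the KS threshold contribute their best
exponent, because the bootstrap measures the variability of the estimator
as actually used. More than 50% failures raises an error.

# Scaling relation

`scaling_relation()` regresses $\log_{10}$ of the per-duration *mean* size
on $\log_{10}$ duration — one point per distinct duration, unweighted
ordinary least squares, per the convention of plotting mean size against
duration — restricted to durations inside the duration fit's
$[S_{min}, S_{max}]$ window, so the regression is evaluated on the
power-law body only. The predicted exponent uses the two fitted exponents:
$\beta_{pred} = (\hat\alpha-1)/(\hat\tau-1)$. On critical simulator output
the two agree within 15% (acceptance suite); on subcritical output the
discrepancy is systematically larger, which is itself a usable regime
diagnostic (property suite).

# Spiking irregularity and correlations

ISIs are differences of consecutive spike-bin times at native raster
resolution — irregularity is a single-neuron property and must not be
computed on the coarse 250 ms analysis bins. Neurons need `min_isis`
(default 10) intervals to enter the CV summary; the dispersion of the
population mean CV is the SEM across neurons, and the firing-rate
distribution is summarized by its sample skewness.

Pairwise correlations are zero-lag Pearson coefficients of the binary
trains at native resolution. Constant trains yield flagged-undefined
entries, never silent zeros. Significance is assessed per pair against
independent Bernoulli trains matched to the two mean rates (two-sided,
$p < 0.1$, no multiple-testing correction — an exploratory per-pair rule).
The null is sampled exactly without materializing trains: conditional on
the per-train counts $a \sim \mathrm{Bin}(T, p_1)$ and
$b \sim \mathrm{Bin}(T, p_2)$, the co-active count is hypergeometric, and
$r = (Tm - ab)/\sqrt{a(T-a)b(T-b)}$. This is a reformulation, not an
approximation. Clustering uses complete linkage on distance $1 - r$
(anticorrelated pairs are maximally distant; $1 - |r|$ would conflate
them with correlated ones), and `reorder_by_reference()` renders a second
condition's matrix in a reference condition's leaf order, with absent
neurons blank.

# Preprocessing from fluorescence

- **ΔF/F.** Baseline at frame $t$ is the mean of the lowest 50% of the
  samples in the trailing 10 s window; output is $(F-b)/b$. Frames before
  the first complete window reuse the first full window's baseline instead
  of being dropped, keeping outputs aligned with inputs. The result is
  invariant to rescaling the raw trace.
- **Spike inference.** A deliberately simple sparse deconvolution stands in
  for published non-negative deconvolution methods: per neuron, minimize
  $\|y - Ks\|^2 + \lambda \|s\|_1$ over $s \ge 0$, where $K$ is the causal
  exponential kernel with decay constant 0.8 s. Solved by projected FISTA
  with $O(T)$ recursive filters; $\lambda$ defaults to 0.1 times the
  pooled ΔF/F SD. The stage is pluggable — binary rasters can bypass
  inference entirely.
- **Thresholding.** The spike-probability threshold is $k_{sd}$ (default 3)
  times the population deviation *about zero* (root-mean-square pooled
  over all neurons): the threshold concept is "SDs above 0", which anchors
  the deviation at zero rather than at the mean; `about = "mean"` gives
  the centered alternative. Probabilities are pooled *after* per-neuron
  max-normalization (the normalized matrix is what gets thresholded);
  pooling before normalization would let a few bright neurons set the
  population threshold.
- **Exclusion.** Noisy cells are dropped by an explicit label list — an
  auditable replacement for by-eye exclusion.

# The synthetic-data generator

The generator is a probabilistic branching network: a quenched random
directed graph (each neuron projects to `connectivity_degree` fixed
targets drawn once per seed), per-edge transmission probability
$\sigma/k_{out}$, and independent Bernoulli external drive. A neuron is
active at $t+1$ with probability $1-(1-p)^{k}(1-q)$ given $k$ active
presynaptic partners and drive $q$. $\sigma$ is the branching parameter —
the expected number of directly triggered descendants per active neuron —
and parameterizes the regime axis: $\sigma = 1$ is critical. This is the
canonical generative model for avalanche regimes, with analytically known
mean-field exponents, which is exactly what acceptance testing needs.

Default study conditions: 100 neurons, out-degree 10, drive 0.001 per
neuron per 0.25 s bin (low drive keeps avalanches separable), ~13 min per
condition at the pipeline level. The three emulated stimulus conditions
share $\sigma$ and differ only in drive statistics: constant (ongoing /
dark), sinusoidally modulated with a 10 s period (grating-like), and
smoothed log-normal fluctuations (naturalistic movie-like).

The calcium forward model adds, per spike, an instantaneous transient of
fixed ΔF/F amplitude decaying exponentially (0.8 s), sampled at 4.07
frames/s, plus white Gaussian noise, optionally on a positive baseline.
What it deliberately omits: indicator saturation and nonlinearity, shot
noise, neuropil contamination, motion artifacts, frame-shear, bleaching
drift, and spike-to-transient amplitude variability. Passing end-to-end
tests therefore demonstrates the correctness of the analysis logic on
data satisfying the stated forward model, not robustness to every
real-imaging artifact. Likewise the network model contains no cell types,
conductances, or spatial structure; no simulator parameter was tuned to
match any recorded dataset's exponents, and the exponents it produces are
those of its own universality class with a median-threshold, coarse-binned
avalanche definition — not targets.

Spike-time shuffling relocates each neuron's spikes to uniformly random
distinct bins, exactly preserving per-neuron counts while destroying
coordination; it is the negative control for every avalanche statistic.

# Reproducibility and problem sizes

Every stochastic operation takes an explicit seed and is a pure function
of its arguments; the pipeline derives per-stage seeds deterministically
from a master seed and the stage name. Identical configs give bit-identical
results.

Test-suite problem sizes were chosen so each statistical check has clear
resolution at desk scale: 200 datasets × 2000 samples for GOF calibration;
40 trials × 10⁴ samples for exponent-recovery coverage; 100-neuron,
50,000-bin simulations for the CV and scaling checks; 10 seeds for the
shuffle control; 25 neurons × 10⁴ bins for correlation calibration. The
acceptance script regenerates its two headline numbers (GOF rejection
fraction; critical-regime mean CV) from scratch at these scales.

# Known limitations

- The deconvolution stand-in shares only the kernel assumption with
  published spike-inference algorithms; absolute spike-probability values
  are not comparable across methods (the downstream analyses use only the
  thresholded binary trains).
- The GOF test conditions on the fitted support; support collapse must be
  read from the fit's `s_min`/`s_max`/`excluded_tail`, not from p alone.
- Exponents from median-threshold, coarse-binned avalanche definitions
  depend on threshold and bin width; comparisons are meaningful within a
  fixed convention, which the pipeline holds constant across conditions.
- The paired two-sided t-test in `compare_exponents()` assumes
  within-subject pairing across conditions (an unpaired Welch variant is
  available by flag).
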