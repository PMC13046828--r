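---
title: "Serial dependence on a face morph wheel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial dependence on a face morph wheel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdwheel)
```

## The problem

In a facial-identity adjustment task, observers reproduce a target face
(Face 2) drawn from a closed wheel of 141 morphs interpolated between
three anchor identities. Each trial first shows an irrelevant inducer
face (Face 1). Serial dependence (SD) is the systematic pull of the
reproduction toward (attraction) or away from (repulsion) the inducer,
and it varies with the inducer-target separation on the wheel. `sdwheel`
implements the complete analysis pipeline for such designs — the
behavioural bias statistic, nonparametric factorial inference, ERP
cluster statistics, topographic comparison and brain-behaviour
regression — together with a synthetic-data generator that emulates the
design (28 participants, 8 blocks of 24 trials, an even low/high
visibility split, 31-channel EEG epochs from −200 to 1,200 ms at 512
Hz), so that every stage is testable end to end without access to any
recorded data.

## Circular geometry

All stimulus arithmetic lives on the wheel: the signed distance from
index `b` to index `a` is the minimal displacement
`((a - b + 70) mod 141) - 70`, positive clockwise. An odd wheel size is
required — on an even wheel the antipodal displacement has no sign — and
enforced. The adjustment error is the signed distance from target to
response. Inducer-target separations are binned into close (±1–23),
middle (±24–46) and far (±47–69) morph steps; zero separations carry no
direction and separations of ±70 are trimmed so the three bins hold
exactly 23 absolute distances each.

## The bias measure

For every participant × visibility × distance-bin cell the bias measure
is

\[ m = \mathrm{median}(e \mid \delta > 0) - \mathrm{median}(e \mid \delta < 0), \]

the difference of median signed errors between clockwise and
counterclockwise inducer trials. Read literally as "counterclockwise
minus clockwise", the sign of this statistic would label attraction
negative; because the stated convention is that positive values reflect
attraction, the package computes clockwise-minus-counterclockwise (under
which a pull toward the inducer is positive by construction), and
exposes `bias_sign_convention = "literal"` for the reverse reading.
Trials with reaction times above 15 s or absolute errors above 60 steps
are flagged (never deleted) before the statistic is computed.

Group uncertainty is quantified by a percentile bootstrap over
participants (the exchangeable unit in a repeated-measures design),
5,000 resamples by default. Percentile intervals on n = 28 means are
known to undercover mildly (~94% at the 95% level for Gaussian data);
the calibration suite checks coverage within 95 ± 2%.

## Aligned-rank-transform ANOVA and Bayes factors

Factorial inference on the bias measure uses the aligned rank transform:
for each effect, responses are aligned (full fixed-factor cell mean
removed, the effect's own inclusion–exclusion estimate added back),
ranked with average ties, and submitted to a repeated-measures F test
for that one effect with participant error strata
(`Error(participant/(visibility*bin))`). One aligned-rank pass per
effect. With 28 × 2 × 3 cells this yields error dfs of 27/54/54; a
`pooled` option provides the single-residual-stratum convention (error
df 162) seen in some reports. Cells lacking trials in one direction are
undefined; affected participants are dropped with a warning rather than
imputed.

Bayes factors per effect use the BIC approximation
`BF10 = exp((BIC_null - BIC_full)/2)` on maximum-likelihood mixed models
with participant intercepts. Each effect is tested against the model
hierarchy that excludes higher-order terms containing it (dropping a
main effect underneath its own interaction is a reparameterisation, not
a restriction, under R's factor expansion). The BFs are computed on the
raw cell values rather than the ART ranks: the ranks are tied to a
single effect's alignment and no common ranked response exists across
the model pair. Paired contrasts instead use the JZS (Cauchy-prior,
scale √2/2) Bayes factor evaluated by adaptive quadrature; tests compare
it against brute-force Riemann integration to four significant digits.

## ERP pipeline

The package ingests clean epochs (artifact screening, ICA and channel
interpolation are upstream contracts, documented but deliberately not
implemented). Preprocessing contracts: linked-mastoid or common-average
re-referencing (the latter used for the parieto-occipital N170/N250
windows, the former for the centroparietal late positivity), a
zero-phase order-4 Butterworth low-pass at 30 Hz, and baseline
correction over −200–0 ms. The filter is applied forward and backward
with odd end-reflection padding and transient-free initial conditions,
so the effective magnitude response is the squared Butterworth response
and constants pass exactly; the order and two-pass scheme follow common
ERP practice and are configurable. Because referencing, baselining,
filtering and trial averaging are all linear, the pipeline averages per
condition first and filters the averages — numerically equivalent and
considerably cheaper.

### Cluster-based permutation tests

Planned contrasts use the middle distance range as baseline (far vs
middle, close vs middle) plus visibility contrasts within the close and
far ranges, on three ROIs: N170 (140–200 ms) and N250 (230–330 ms) over
left and right parieto-occipital quartets, and the LPP (400–600 ms) over
Cz/CP1/CP2/Pz. Per channel × sample a paired t is computed;
points beyond the two-tailed critical value at α = .05 (df = n−1) are
clustered by temporal adjacency and spatial adjacency, and each
cluster's t values are summed. The null records the maximum absolute
cluster mass over 10,000 random within-participant sign flips; Monte
Carlo p-values use the (b+1)/(m+1) estimator, which cannot return zero,
against that common two-polarity null. ROI channels are treated as fully
adjacent (clusters form per-channel over time with full within-ROI
adjacency; clustering the ROI average instead is a trivial config
variant we considered and rejected as the default because it discards
channel extent). For the whole-scalp exploratory scan (0–400, 400–900,
900–1,200 ms windows partitioning the post-onset epoch) spatial
neighbours are channel pairs within 0.4 head radii on the 2D template
montage — the graph is validated symmetric and connected; the threshold
is configurable since published neighbour templates are toolbox-specific.
Cluster effect size is Cohen's d of the per-participant cluster-mean
differences, and each cluster carries a JZS paired BF on the same
quantity. For n ≤ 10 the Monte Carlo p is checked against exhaustive
sign-flip enumeration.

### Topography

To compare the scalp distribution (rather than amplitude) of the far-vs-
middle and close-vs-middle LPP effects, per-participant difference
topographies over the 18 representative channels (frontocentral
Fz/FC1/FC2/FCz; centroparietal C3/C4/Cz/CP1/CP2/CP5; posterior
Pz/P4/O2/P3/O1/Iz/PO9/P7) are vector scaled — divided by their Euclidean
norm, jointly over all 18 channels (per-region scaling is offered as a
switch) — and analysed with the ART ANOVA over contrast × region ×
hemisphere. Channels are averaged into region × hemisphere cells so the
unequal set sizes do not unbalance the design; the centroparietal set is
left-heavy as printed (CP5 without CP6) and is implemented verbatim.
All statistics are invariant to positive rescaling of any participant ×
contrast topography, which tests assert.

## Brain–behaviour regression

Per participant and contrast, the behavioural difference score
(bin-minus-middle bias, averaged over visibility) is regressed on the
ERP difference score (bin-minus-middle LPP ROI window mean by default; a
cluster-mask mean is available) using iteratively reweighted least
squares with Huber weights, k = 1.345 (95% Gaussian efficiency;
bisquare available). The slope's F test is reported as F(1, n−2) from
the robust standard error — some reports print the df pair in the
reverse order — with a weighted robust R² (the plain R² of the robust
fit is also emitted). With k → ∞ the fit reproduces OLS exactly, which
the tests exploit as a closed-form oracle.

## The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions every acceptance check runs under.

Behaviour: responses are `target + round(bias(delta) * s_i + noise)`
wrapped onto the wheel, with Gaussian adjustment noise (sd 8 steps), a
2% uniform lapse rate, and log-normal reaction times with a 2.5% slow
tail beyond 15 s — together producing the ~3% task-level exclusion rate
the filters expect. The default bias function is per-bin constant pulls
(−1.475, +0.55, +1.27 steps) whose group-level bias measures are −2.95 /
+1.1 / +2.54 steps: close-range repulsion, far-range attraction, a null
middle range. A derivative-of-Gaussian curve is available as a smooth
alternative. Per-participant scales `~ N(1, 2.0)` encode the large
individual differences such tasks show (between-participant bias SDs
near 5–6 steps); because responses are generated on the wheel,
errors beyond ±70 are impossible by construction and Gaussian step
noise is left unwrapped (wrap events are negligible at realistic SDs
and the median statistic is robust to them).

EEG: each trial is a sum of separable component templates — N170-like
and N250-like parieto-occipital negativities and an LPP-like
centroparietal positivity peaking at 500 ms — plus spatially smoothed
white Gaussian sensor noise (sd 7 µV per channel; optional 1/f temporal
colouring, off by default because white noise is the cleaner calibration
reference). The distance bin adds ±2 µV on the late positivity: far
trials on the broad centroparietal topography, close trials (negative)
on a posterior-shifted topography, reproducing the qualitative
topographic dissociation between the two contrasts. Individual
differences are structured as two pathways: the attractive pathway
(middle/far behavioural pulls and the far-range ERP delta, scale sd
0.9) shares a latent with correlation 0.95, while the close-range
behavioural and ERP variations draw independent latents. Under these
defaults the far-vs-middle effect lands at d ≈ 0.9, the far-contrast
robust regression near R² ≈ 0.35, and the close contrast carries no
built-in brain–behaviour association — the regimes the pipeline is
meant to operate in.

What the generator does *not* emulate: biophysical volume conduction,
ocular/muscle artifacts, autocorrelated drifts, non-stationary
component latencies, or any image-level face similarity structure.
Passing tests therefore demonstrate the pipeline's statistical
correctness and calibration under a plausible data-generating process,
not robustness to every pathology of real recordings.

## Numerical and design choices

* Every stochastic operation takes an explicit seed; the pipeline
  derives stage seeds from one master seed by fixed offsets, so a run is
  reproducible end to end from a single integer.
* Zero-distance trials are excluded from the bias statistic: the bins
  start at ±1 and the statistic needs a direction.
* Rank ties get average ranks; zero-variance t-test points are excluded
  from clustering with a warning; zero-norm topographies and
  zero-variance difference vectors are flagged degenerate rather than
  silently propagated.
* The clockwise orientation of the wheel is a convention; any consistent
  choice yields identical |m|, and the attraction-positive contract
  fixes the global sign. A full wheel reflection (deltas and errors both
  mirrored) leaves the bias measure invariant, since it maps attraction
  to attraction.
* Epoch time axes are integer sample grids containing 0 ms; a stated
  window bound may fall up to one sample outside the realised grid
  (−200 ms requested, −199.2 ms realised at 512 Hz) and is accepted
  within that slack.

## Simulation sizes used by the test suite

The calibration and recovery suites are simulation-based; their sizes
are fixed design choices of this package: 500 replications for the ART
and cluster null-rate checks (the cluster null at 14 participants,
4 blocks, a 6-channel montage subset at 128 Hz, 1,000 permutations),
1,000 replications for bootstrap coverage, 100 seeds for the
behavioural sign-recovery check and 40 full coupled studies (reduced
montage, full 192-trial sessions) for the cluster-detection and
regression power checks. The acceptance script runs the complete
pipeline once at the full design scale (28 participants, 31 channels,
512 Hz, 10,000 permutations, 5,000 bootstrap iterations).

## Known limitations

* The ERP branch starts at clean epochs; no continuous-EEG
  preprocessing, source localisation or time-frequency analysis.
* BIC Bayes factors are an approximation with an implicit unit-
  information prior; they are reported alongside, not instead of, the
  JZS paired BFs.
* The pooled-error ANOVA convention is provided for comparability but
  the repeated-measures strata are the package's default and the basis
  of its calibration checks.
* Bias-curve model fitting (e.g. derivative-of-Gaussian fits to the
  bias-by-distance profile) is out of scope; the nonparametric bias
  measure is the unit of analysis throughout.
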