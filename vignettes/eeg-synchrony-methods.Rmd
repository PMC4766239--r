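---
title: "EEG synchrony markers and dementia severity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG synchrony markers and dementia severity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsynch)
```

## The scientific problem

Alzheimer's disease perturbs the functional coupling between cortical areas,
and those perturbations leave traces in the scalp EEG. A recurring finding is
that coupling does not change monotonically with disease severity: synchrony
first *rises* in early disease — commonly read as a cerebral compensation
effect — and falls as the disease advances. `eegsynch` implements a complete
pipeline for quantifying this relationship: from raw multichannel recordings,
through artifact removal and multivariate spectral estimation, to eight
connectivity markers between electrode clusters, a quadratic regression of
each marker on the Mini-Mental State Examination (MMSE, 0--30, lower = more
impaired), and a common-factor analysis of the marker battery.

Because no clinical recordings ship with the package, a first-class synthetic
cohort generator reproduces the statistical structure the analysis relies on.
Every claim the test suite makes about the pipeline is a claim about planted,
known ground truth.

## Signal model

Each preprocessed EEG segment is treated as a window of a real-valued,
wide-sense stationary multivariate process $x(t) \in \mathbb{R}^n$ with an
AR($\infty$) representation $\sum_{s\ge 0} A(s)\,x(t-s) = \varepsilon(t)$,
covariance function $\gamma(s) = \mathbb{E}\,x(t+s)x(t)'$ and spectral
density

$$f(\lambda) = \frac{1}{2\pi}\sum_{s=-\infty}^{\infty} e^{-i\lambda s}\gamma(s),
\qquad \lambda \in [-\pi, \pi],$$

assumed to have full rank. The spectral density is estimated *indirectly*:
the biased sample covariances $\hat\gamma(s) = T^{-1}\sum_t x(t+s)x(t)'$,
pooled across a subject's segments, are tapered with a Parzen lag window
$w(s)$ and Fourier transformed,

$$\hat f(\lambda) = \frac{1}{2\pi}\sum_{s=-c}^{c} w(s)\,\hat\gamma(s)\,
e^{-i\lambda s}.$$

The Parzen window is non-negative definite, so $\hat f$ is positive
semidefinite at every frequency; the biased (1/T) covariance normalization
preserves this. The truncation point defaults to $c = 255$, a window-closing
choice appropriate for 256-Hz, band-limited (2--15 Hz) EEG: smooth enough to
suppress leakage while retaining individual spectral peaks such as the alpha
rhythm. The grid is 1024 equispaced frequencies on $[0, \pi]$ (the mapping to
Hz is $f = \lambda \cdot 256 / 2\pi$); doubling it moves band averages by
well under 1 % (tested), so the grid is not a sensitive tuning.

## The eight markers

For channels (or principal components) $i, j$ and the inverse spectral
matrix $g = f^{-1}$:

| marker | definition | domain | direction |
|---|---|---|---|
| coherence $C_{ij}$ | $|f_{ij}|^2/(f_{ii}f_{jj})$ | per band | symmetric |
| partial coherence $pC_{ij}$ | $|g_{ij}|^2/(g_{ii}g_{jj})$ | per band | symmetric |
| phase shift $n\Phi_{ij}$ | $|\arg f_{ij}|/\pi$ | per band | symmetric |
| Granger causality $G$ | $\|\hat A_{ji}(\cdot)\|_2$, bivariate AR | time | directed |
| conditional Granger $cG$ | $\|\hat A_{ji}(\cdot)\|_2$, full AR | time | directed |
| canonical correlation $\rho^c$ | norm of eigenvalue roots of $\gamma_{II}^{-1/2}\gamma_{IJ}\gamma_{JJ}^{-1}\gamma_{JI}\gamma_{II}^{-1/2}$ | time | symmetric |
| dynamic canonical corr. $d\rho^c$ | same with $f(\lambda)$ blocks, band-averaged | per band | symmetric |
| cross-mutual information $cMI$ | $2I(X,Y)/(H_X + H_Y)$ from a $10\times10$ histogram | time | symmetric |

Frequency-domain markers are averaged within four bands: $\delta$ 2--4,
$\theta$ 4--8, $\alpha$ 8--13 and $\beta_0$ 13--15 Hz (left-closed,
right-open; the last closed at 15 Hz). AR coefficients come from the
multivariate Yule--Walker equations on the pooled covariance sequence with
the order selected by AIC, $T\log\det\hat\Sigma + 2pn^2$; only stable fits
(companion spectral radius below one) are accepted. The Granger norms use
lags $s \ge 1$ only, matching the non-causality characterization
$A_{ji}(s) = 0\ \forall s \ge 1$.

Numerical conventions worth stating: canonical correlations are the *square
roots* of the eigenvalues of the product matrices (the eigenvalues themselves
are squared correlations), computed on the Hermitized product with negative
round-off eigenvalues clipped to zero; phases use the principal value with no
unwrapping, since the band average of $|\Phi|/\pi$ needs no continuity;
ill-conditioned spectral matrices are ridge-regularized
($\delta \cdot \mathrm{tr}/n \cdot I$, $\delta = 10^{-8}$) with a warning;
the cMI histogram uses equiprobable (decile) marginal bins, which bounds the
entropies at $\log_2 10$, stabilizes the normalization, and makes the marker
exactly invariant under strictly monotone transformations — an equal-width
grid is the natural alternative and is deliberately not offered, but the
normalization $I/\max(H_X, H_Y)$ is (`normalization = "max"`).

## Cluster scheme

Single channels are noisy; the analysis therefore groups the 19 scalp
electrodes (10--20 system) into five clusters mirroring the cerebral lobes —
Anterior (FP1, FP2, F3, F4), Temporal/Left (F7, T7, P7), Central (FZ, C3,
CZ, C4, PZ), Temporal/Right (F8, T8, P8), Posterior (P3, P4, O1, O2) — and
measures synchrony between the 10 unordered cluster pairs. For bivariate
markers, per-cluster PCA yields two components (on synthetic data built to
the assumed structure they carry over 90 % of cluster variance, an assertion
the acceptance suite measures), and the marker is evaluated for all four
PC combinations. At cohort level, `select_best_combo()` keeps, per
(marker, pair, band, direction), the combination whose quadratic severity
regression attains the highest $R^2$, with ties broken in lexicographic
combination order. Because this selection step uses the outcome, it is
*optimistically biased*; the package keeps all candidate values so the
fixed-combination path can always be reported alongside. Canonical
correlations bypass PCA and are computed directly between the clusters'
channel blocks. A channel-pair averaging alternative
(`channel_average_marker()`) is provided for comparison with the more common
approach.

Two design choices here were genuinely open. PCA is computed per subject on
the covariance pooled over segments, not per segment: per-segment PCA would
re-estimate (and silently permute or reflect) the component basis every 4 s
and scramble component identity. And partial coherence / conditional Granger
causality condition on the first two PCs of *all five* clusters (10 series)
— conditioning only on the tested pair would collapse partial coherence onto
ordinary coherence. Component signs follow the loading convention (largest
absolute loading positive); polarity of the projected series therefore
follows the polarity of the data, and only sign-insensitive quantities are
compared across recordings.

## Preprocessing chain

The fixed order is: amplitude pre-selection, 2-Hz high-pass, cardiac
template subtraction, ocular regression, 15-Hz low-pass, segmentation,
stationarity screen.

* **Pre-selection.** The study this pipeline models excluded grossly
  corrupted stretches by visual inspection, which cannot be reproduced
  mechanically. The stand-in is deterministic: fixed windows (default 4 s)
  in which any EEG channel exceeds 8 times its own median absolute deviation
  are excluded, and the exclusion accounting (seconds retained) is reported.
* **FIR filtering.** All filters are windowed-sinc (Hamming) designs of
  order 340 with linear phase, applied by FFT convolution and compensated by
  order/2 samples, giving zero-phase alignment. The high-pass additionally
  receives an exact DC null (the Hamming stopband floor alone leaves
  $\sim 2\times10^{-3}$ of a constant input). Border frequencies: 2 Hz
  high-pass, 15 Hz low-pass (muscle artifacts intrude above 15 Hz), 12 Hz
  low-pass on the EOG regressors.
* **Cardiac removal.** R peaks are detected on the co-recorded ECG by a
  Pan--Tompkins style detector (band-pass 5--18 Hz, derivative, squaring,
  150-ms integration, adaptive signal/noise thresholds, 200-ms refractory
  period). Each EEG channel's average waveform in a ±150 ms window around
  the peaks is then subtracted at every peak. With $K$ beats the residual
  artifact power scales like $1/K$ plus the artifact-free floor.
* **Ocular removal.** Blinks and eye movements are removed by static OLS
  regression of each EEG channel on the two EOG channels (plus intercept).
  The EOG is first low-passed at 12 Hz because it also picks up neuronal
  activity; without that step the regression would subtract brain signal.
  Residuals are exactly orthogonal to the regressors (tested at machine
  precision).
* **Segmentation and stationarity.** The band-limited EEG is cut into 4-s
  segments with 2-s overlap (a 180-s recording yields 89). Each segment is
  screened by an augmented Dickey--Fuller test per channel (constant
  included, lag order AIC-selected up to 10, MacKinnon response-surface
  critical values); a segment is kept when at least 90 % of channels reject
  the unit root at the 5 % level. The ADF regression is solved through a
  Cholesky factorization of the augmented normal equations, which yields all
  nested-lag residual sums of squares in a single pass.

## Severity statistics

Each marker (or factor score) is regressed on MMSE by OLS with MMSE entering
linearly and quadratically, plus the covariates age (linear and quadratic),
sex, disease duration (linear and quadratic) and education level 1--6.
Continuous covariates are mean-centered before squaring; $R^2$ and the
overall F-test are invariant to that reparameterization, which exists only
to tame collinearity. Model significance is the F-test against the
intercept-only model; with eight markers tested on the same cohort, the
Bonferroni threshold is $0.05/8 = 0.00625$ (strict inequality). The fitted
vertex $-\beta_1/(2\beta_2)$ (mapped back to the MMSE scale) estimates the
severity at which synchrony peaks. The package also reports the partial
$R^2$ of the MMSE terms given the covariates, since full-model $R^2$ mixes
the two sources of fit.

The two-regime comparison splits the cohort at MMSE 21 — the boundary value
falls in the *upper* group, consistent with a 55/24 split of a 79-subject
cohort over 15--26 — and applies a two-sided Mann--Whitney U test, exact for
combined samples of at most 20 without ties and tie-corrected normal
otherwise.

Common factors are extracted from the standardized marker battery by maximum
likelihood and rotated obliquely with promax; factor correlations come from
the rotation matrix ($\mathrm{cov2cor}((U'U)^{-1})$, verified against a
planted oblique population), and factor scores use the regression (Thomson)
method computed from the structure matrix. The factor count defaults to two,
with a sequential likelihood-ratio alternative (`choose_n_factors()`). A
caution the tests quantify: at cohort-scale samples (n ≈ 80--300) the
promax factor correlation has a sampling scatter of roughly ±0.3, so only
loading patterns — stable already at those sizes (Tucker congruence
≥ 0.95) — should be interpreted there.

## What the synthetic generator emulates — and what it does not

Each of the five clusters mixes two cluster-private AR(2) sources with
distinct resonances (alpha-range and theta-range, 4.5--11 Hz, pole moduli
0.95--0.97) through fixed loading patterns, plus per-channel sensor noise
(SD 0.15 against unit-variance sources) — this makes two PCs dominate each
cluster by construction. A shared AR(2) source at 10 Hz enters every
cluster's first-source pathway with weight
$k(\mathrm{MMSE}) = k_{\max} + \kappa\,(\mathrm{MMSE} - 21)^2$
(defaults $k_{\max} = 0.6$, $\kappa = -0.01$, clipped to $[0,1]$) and a
per-cluster lag of 0--4 samples, so coupling is strongest at MMSE 21 and
every marker, including the directed ones, has a nonzero target. Artifacts
are injected with ground truth retained: near-periodic Ricker-wavelet
cardiac spikes (1.2 beats/s, ±5 % jitter) driving the ECG channel at full
amplitude; Poisson blinks (0.2/s) as 300-ms raised-cosine pulses mixed
frontally into the EEG while the EOG channels carry the pulses plus
attenuated neuronal leakage; band-limited (20--45 Hz) muscle noise in the
temporal channels; and sub-0.5-Hz drift everywhere. Innovation variances are
free parameters of the generator (within-subject segment-to-segment marker
variability is not constrained by any external study), and MMSE enters the
simulation as the exact independent variable, with no cognitive-testing
noise.

The generator is deliberately *not* a biophysical simulation: no volume
conduction or forward head model, no 1/f background or line noise, no
realistic rhythm dynamics beyond AR resonances. Passing tests therefore
demonstrate that the pipeline recovers what it is designed to recover under
its own stationarity and linearity assumptions — not that clinical EEG
satisfies those assumptions.

## Problem sizes used by the tests

The test and acceptance suites choose problem sizes that make the
statistical assertions sharp but cheap: single-subject oracle checks use the
full 180-s resting duration (46 080 samples); the end-to-end
parameter-recovery study uses 20 cohorts of 79 subjects at 60-s recordings,
with the marker computation restricted to the cluster pair that carries the
planted coupling; null calibrations use 500--1000 replicates of the
regression layer only (no EEG simulation needed, since the null hypothesis
concerns the statistics, not the signal chain). The planted-recovery check
of the promax factor *correlation* simulates 2000 subjects for the reason
given above.

## Known limitations

* The best-combination selection is outcome-dependent and optimistic; its
  $R^2$ values should be read as upper bounds and compared against the
  fixed-combination path.
* Partial coherence and conditional Granger causality condition on the PC
  summary of the montage, not on all 19 raw channels (the channel-averaging
  path conditions on all 19).
* The ADF screen has low power against near-unit-root alternatives at 1024
  samples; "stationary" means "not demonstrably integrated".
* The EDF writer/reader covers the simulator's needs (one-second records,
  uniform rate, 16-bit) and is not a general-purpose EDF implementation.
* With fewer subjects than marker columns the factor stage refuses to run
  rather than regularize; choose a smaller marker battery instead.
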