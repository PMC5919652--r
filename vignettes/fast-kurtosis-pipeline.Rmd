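---
title: "Fast-kurtosis (1-9-9) lesion volumetry: models, phantom and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-kurtosis (1-9-9) lesion volumetry: models, phantom and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastkurt)
```

## The signal model

Diffusion kurtosis imaging quantifies non-Gaussian water diffusion through
the second-order term of the cumulant expansion of the diffusion-weighted
signal. For a unit gradient direction $\hat n$ and weighting $b$
(ms/&mu;m&sup2;),

$$\log S(b,\hat n) = \log s_0 - b\, n_i n_j D_{ij}
  + \tfrac{b^2}{6}\,\bar D^2\, n_i n_j n_k n_l W_{ijkl},$$

with $D$ the (symmetric, positive semidefinite) diffusion tensor in
&mu;m&sup2;/ms, $\bar D = \mathrm{Tr}(D)/3$ the mean diffusivity (MD), and
$W$ the dimensionless, fully symmetric rank-4 kurtosis tensor.
Physically $W$ is defined from the fourth-order moments of the spin
displacement distribution over the diffusion time (the excess-kurtosis
combination $\langle R_iR_jR_kR_l\rangle$ minus its Gaussian part,
normalized by $4\bar D^2\Delta^2$); the package never computes it from
displacements — `predictSignal()` takes $W$ as an input and the estimators
below recover scalar summaries of it from signals. Only $b$ enters the
closed forms; the pulse timings $\delta/\Delta$ are carried as scheme
metadata.

The mean of the kurtosis tensor (MKT, $\bar W$) is the spherical average of
the apparent kurtosis $W(\hat n) = n_in_jn_kn_lW_{ijkl}$, which for a fully
symmetric tensor collapses to one fifth of its trace:

$$\bar W = \tfrac15\left(W_{xxxx}+W_{yyyy}+W_{zzzz}
  +2W_{xxyy}+2W_{xxzz}+2W_{yyzz}\right).$$

`mktTrace()` implements the closed form; the test suite checks it against
dense spherical quadrature of `apparentKurtosis()` (10,000 Fibonacci-lattice
directions, tolerance 1e-3) and against 81-term brute-force contractions.

## The 1-9-9 scheme and closed-form estimators

Six distinct apparent-kurtosis values determine $\bar W$, but the mixed
components cannot be read off single directions; nine directions — the
three coordinate axes plus two bisector directions per coordinate plane —
cancel the unwanted cross terms. With weights 1/15 (axes) and 2/15
(bisectors) the weighted direction average of *any* fully symmetric rank-4
tensor equals $\tfrac15\mathrm{Tr}(W)$, and the analogous rank-2 average of
$n^TDn$ equals $\bar D$. `make199Scheme(b1, b2)` builds this 19-volume
protocol (one $b=0$ volume plus the nine directions at each shell).

The published tables of the direction set are not reproduced here; instead
the identity itself is the contract: `certifyScheme()` verifies both trace
identities on random tensors to 1e-10 at construction for any user-supplied
set, so every rotation of a valid set is accepted. This makes the scheme
self-validating rather than table-dependent.

Averaging the log-signals with those weights at each shell gives two
scalars
$A_s = -b_s\bar D + \tfrac16 b_s^2 \bar D^2\bar W$ ($s = 1, 2$), solved in
closed form:

$$\bar D_{199} = \frac{b_1^2A_2 - b_2^2A_1}{b_1b_2^2 - b_1^2b_2},
\qquad
\bar W_{199} = \frac{6\,b_1b_2\,(A_1b_2 - A_2b_1)(b_1 - b_2)}
                    {(A_1b_2^2 - A_2b_1^2)^2}.$$

Because the direction average is exact for arbitrary symmetric tensors,
noiseless signals invert *exactly* — for any PSD $D$ and symmetric $W$,
`estimateVoxel()` returns $\mathrm{Tr}(D)/3$ to 1e-10 and
$\tfrac15\mathrm{Tr}(W)$ to 1e-8 (a property test over 1000 random pairs).
This also fixes the scaling behaviour: rescaling $(b_1,b_2)\to(cb_1,cb_2)$
with $D \to D/c$ leaves every log-signal, hence $\bar W$, unchanged and
scales $\bar D$ by $1/c$.

### Numerical guards

Estimation never throws on bad voxels; it flags them (see `dkiConfig()` and
`flagNames()`):

* **Signal floor.** Under noise a magnitude signal can be arbitrarily close
  to zero; logs are taken after clamping at $\varepsilon s_0$ with
  $\varepsilon = 10^{-6}$, and the voxel is marked `NONPOSITIVE_SIGNAL`.
* **MKT degeneracy.** $\bar W_{199}$ divides by $(A_1b_2^2-A_2b_1^2)^2$,
  which vanishes only for zero signal decay (background). Below a floor of
  1e-12 the voxel is marked `DEGENERATE_DENOMINATOR` and reports NA rather
  than $\pm\infty$.
* **Plausibility.** MD outside [0, 4] &mu;m&sup2;/ms or MKT outside
  [-1, 5] is flagged, never clipped; the bounds are generous envelopes
  around tissue values and are configurable.

## The synthetic stroke phantom

No image data accompanies the study this pipeline reproduces, so
`phantomSpec()`/`generatePhantom()` build a fully synthetic ground truth
that every stage can be validated against:

* a 64 x 64 x 32 grid of 0.25 x 0.25 x 0.5 mm voxels (the protocol's
  geometry at a whole-brain-like extent);
* an ellipsoidal "brain" (semi-axes 7/6.5/6.5 mm) split into hemispheres
  at the mid-sagittal plane;
* a spherical lesion core (radius 3 mm) with reduced diffusivity, nested in
  a confocal shell with elevated kurtosis. Region parameters default to
  normal tissue $\bar D = 0.5$, $\bar W = 0.8$; core $\bar D = 0.35$
  (a 30 % MD drop), $\bar W = 1.3$; shell $\bar D = 0.5$, $\bar W = 1.3$ —
  i.e. the diffusivity drop is confined to the core while the kurtosis
  elevation extends beyond it, the qualitative contrast that produces an
  MKT lesion larger than the MD lesion;
* shell semi-axes equal core semi-axes times $(1.31)^{1/3}$, so the
  *designed* MKT-over-MD lesion volume excess is 31 % in the continuum
  (about 30 % after voxel discretization of the two ellipsoids).

`simulateAcquisition()` evaluates the forward model per voxel (isotropic
tensors by default; an axially symmetric $D$ with configurable FA is
available because exact inversion must hold for anisotropic inputs too) and
applies Rician noise, $S' = \sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$ with
$\epsilon_{1,2}\sim N(0, s_0/\mathrm{snr})$ — the magnitude-MRI noise
model, which the tests verify through the Rayleigh background mean
$\sigma\sqrt{\pi/2}$. A Gaussian mode exists for estimator-theory
experiments. Given a seed the output is bit-reproducible.

The study being emulated did not report its ex-vivo SNR; the default
`snr = 50` is a deliberate, configurable placeholder at the conservative
end of what a long ex-vivo acquisition achieves. What the phantom does
*not* emulate: realistic brain geometry and tissue heterogeneity,
partial-volume mixing at region boundaries, fixation gradients, and
spatially correlated (physiological or hardware) noise. Tests that pass on
the phantom therefore certify the *estimators and bookkeeping*, not
segmentation performance on real brains.

## Lesion segmentation and volumetry

The original workflow outlined lesions manually. A human rater is not
testable, so `segmentLesion()` substitutes an objective rule: voxels more
than $k$ SD (default $k = 2$) below (`md_low`) or above (`mkt_high`) the
mean of the contralateral-hemisphere distribution, followed by
largest-connected-component selection (26-neighbourhood — the standard
choice for 3D blobs). Imported masks can bypass the rule entirely.
A relative guard band of 1e-9 around the threshold breaks 1-ulp ties that
otherwise select half of a perfectly uniform (noiseless) hemisphere;
at any realistic noise level it is inert. Volumes are voxel counts times
the voxel volume (`volumeFromMask()`, exact arithmetic), and
`mismatchPercent()` reports $100\,(V_{MKT}-V_{MD})/V_{MD}$.

### Known limitation: voxelwise thresholds at moderate SNR

Error propagation through the closed forms shows why a voxelwise threshold
treats the two maps very differently. With $\sigma_{A}$ the noise of a
log-sum average, the MD estimate is linear in $(A_1, A_2)$ and is benign
(relative SD of a few percent at SNR 50). The MKT estimate has
sensitivities $\partial\bar W/\partial A_1 \approx -11$ and
$\partial\bar W/\partial A_2 \approx +5$ at the default tissue values and
$b = (1, 2.5)$, and its noise scales like $1/\bar D^2$; at SNR 50 the
per-voxel MKT SD is about 0.2 in normal tissue and 0.35 inside the low-MD
core. The `mkt_high` threshold at $k = 2$ then sits within one SD of the
lesion mean, so a substantial fraction of interior lesion voxels falls
below it and the recovered MKT lesion volume is biased low — the
acceptance experiment (50 seeds, `scripts/acceptance.R`) computes the
resulting recovered excess and reports it as measured. Practical pipelines
counter this with spatial regularization (smoothing, morphological
closing) or ROI-level averaging; those steps are deliberately *not* part
of `segmentLesion()`, which implements the plain threshold rule so that
its behaviour — including this bias — stays transparent and testable. The
MD-based lesion volume, by contrast, is recovered within a few percent
under the same conditions.

## The histology arm: Cavalieri stereology

`sliceSections()` resamples a mask into 40-&mu;m-thick binary sections
(each section takes the voxel plane containing its center; a partial
terminal section is kept iff it spans at least half a thickness).
`systematicSample()` keeps every 15th section from a random start — the
systematic uniform random design — and `cavalieriVolume()` applies

$$V = t\cdot\frac{1}{SSF}\cdot\sum_i a_i$$

with unit conversion to cm&sup3;. Averaged over all $1/SSF$ start offsets
the estimate equals the full-stack Riemann volume *exactly* (each section
is counted once across offsets — an algebraic identity the tests assert to
1e-12), which is the discrete form of Cavalieri unbiasedness.

Two area estimators stand in for the interactive tools used on real
sections, with defaults chosen because the original software settings are
unknown (both are exposed in the API):

* `pointCountArea()`: a square grid of spacing $d$ (count x $d^2$); a grid
  point counts as inside iff the pixel containing it is foreground
  (half-open convention), making rectangle areas exact for aligned grids
  and disk areas unbiased over uniform offsets.
* `nucleatorArea()`: the 2D nucleator, $\pi\,\overline{l(\theta)^2}$ over
  a systematic fan of 64 rays rotated by a single uniform angle. Rays march
  at 0.25-pixel steps and place the boundary midway between the last
  foreground and first background sample. The estimator is exact (in
  expectation) only for sections star-shaped about the reference point;
  any ray that re-enters foreground after its first exit raises
  `NON_STAR_SHAPED` rather than silently returning a biased value. The
  first crossing always defines $l(\theta)$.

## Statistics

`shapiroWilk()` (Royston's approximation via the vetted base-R routine,
with a Monte-Carlo type-I-error calibration test at the study's n = 7),
`pairedT()` (implemented directly so that zero-variance differences have
the documented conventions $x=y \Rightarrow t=0, p=1$; cross-checked
against `t.test`), `anovaOneway()` (classic equal-variance F), and
`iccAbsoluteAgreement()` — the two-way absolute-agreement ICC from the
crossed mean squares,

$$ICC(A,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the F-based confidence interval. Single-measure is the default (the
conservative choice when each cell holds one rating, and the common
statistical-package default); average-measure ICC(A,k) is an option. All
tests are two-sided at $\alpha = 0.05$.

`buildReport()` assembles the study-style comparison from a long-format
volume table: per-method means &plusmn; SD, normality checks, paired t
tests for every method pair, the MKT-over-MD mismatch of the group means,
and ICC tables when repeated ratings exist. Subjects missing any method
are excluded listwise with a warning — mirroring how failed histology
removes the matched MRI data points.

## Problem sizes and reproducibility

The default phantom (131,072 voxels, 19 volumes) fits a full
simulate-fit-segment-measure cycle in about a second, so the shipped
experiments use 50 noise seeds for Monte-Carlo statements and 1000 random
tensors for the algebraic identities; all randomness is seeded, and
`scripts/acceptance.R --seed N --out file.json` re-runs the headline
computations end to end. Heavier checks (10,000-direction quadrature,
10,000-replicate Shapiro-Wilk calibration) keep the whole suite in the
minutes range on one core.
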