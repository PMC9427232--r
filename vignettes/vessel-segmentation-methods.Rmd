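---
title: "Methods: multilevel Otsu vessel segmentation with a PSO-improved salp swarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel Otsu vessel segmentation with a PSO-improved salp swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diabetic retinopathy is diagnosed largely from the retinal vasculature, and
most lesions appear near vessels. Unsupervised vessel segmentation of color
fundus photographs avoids the annotated training sets that supervised
methods require: the image is reduced to a gray-level histogram and
partitioned by thresholds chosen to maximize a class-separation criterion.
`retvessel` implements that pipeline end to end: vessel enhancement,
multilevel Otsu threshold search by swarm optimization, and a ten-indicator
quality report, together with a synthetic phantom generator so every stage
is testable without clinical data.

## Preprocessing

All processing runs on the green channel, where vessel contrast is
strongest in fundus photography.

**Gaussian matched filter (GMF).** Vessels are ridge-like with an
approximately Gaussian cross-section. The kernel is the negative profile
`-exp(-x'^2 / (2 sigma^2))` swept over a segment of `length` pixels along
the vessel direction `theta`, truncated at `|x'| <= 3 sigma`, and
mean-subtracted over its support so that a constant background yields
exactly zero response. Because the kernel is negative at its core, *dark*
vessels produce *positive* responses when the kernel is aligned — no
intensity inversion is needed (an inverted input would flip the sign of
the aligned response and make the orientation maximum meaningless, which is
why the package correlates the raw green channel by default and exposes
`invert` only for bright-vessel imagery). The image is correlated with a
bank of 12 orientations (15° steps, the standard matched-filter bank
density) and the per-pixel maximum is kept, then min-max rescaled to
`[0, 1]`. Defaults `sigma = 1.5` px and `length = 9` px suit vessels of
2–8 px caliber; both are arguments.

**Top/bot-hat detail.** The top-hat (image minus its opening) keeps bright
small-scale structure and the bot-hat residual (image minus its closing,
which is non-positive) marks dark small-scale structure such as terminal
vessels. Their difference equals `closing - opening`, is non-negative, and
is rescaled to `[0, 1]`. The structuring element defaults to a disc of
radius 5 px (configurable shape/radius); borders are handled by reflection
everywhere (filtering and morphology) to avoid rim artifacts that would
otherwise create spurious histogram classes.

**Fusion.** The two maps are min-max normalized and combined as a convex
weighted sum (default weights 0.5/0.5), then quantized to 8-bit. A
constant operand normalizes to zeros by convention. The fusion rule is
deliberately simple and exposed in the configuration; on the synthetic
phantoms the matched-filter channel carries most of the vessel evidence,
while the detail channel mainly matters for thin terminal structure in
real imagery.

## The multilevel Otsu objective

With a 256-bin normalized histogram `g(m)` and thresholds
`t_1 < ... < t_Dim` (class `j` spans `t_j < m <= t_{j+1}`, `t_0 = -1`,
`t_K = 255`, `K = Dim + 1`), the between-class variance is

```
sigma_B^2 = sum_j w_j (mu_j - mu_T)^2
```

with class probabilities `w_j`, class means `mu_j` and global mean `mu_T`;
empty classes contribute zero. The optimizers minimize `-sigma_B^2`, so
reported fitness values are negative, matching the sign convention used in
comparative tables of swarm-segmentation studies. The decomposition
`sigma_B^2 + sigma_W^2 = sigma_T^2` holds identically and is used as a
correctness oracle in the tests.

**Exact oracle.** `brute_force_optimal()` returns the global optimum with
lexicographically-smallest tie-breaking. `Dim <= 2` is enumerated
exhaustively; larger `Dim` uses an exact dynamic program over class
prefix scores (`O(Dim * 256^2)`), reconstructed left-to-right with
smallest-split tie-breaks so the two methods return identical vectors —
an equivalence the test suite verifies against enumeration at `Dim = 3`.
The DP is preferred at higher `Dim` purely for speed; both are exact.

**Search space.** Thresholds live on the integer grid `[0, 254]`. By
default `optimize_thresholds()` restricts the continuous search box to the
occupied gray-level range of the histogram: `sigma_B^2` does not depend on
threshold positions inside unoccupied outer bins (they only create empty
classes), so the restriction removes a large constant-fitness plateau
without excluding any distinct optimum. On narrow-support histograms this
markedly improves every optimizer's reliability; `bounds = "full"`
restores the raw `[0, 254]` box.

## Swarm searches

Continuous positions are repaired to valid threshold vectors (clamp to
`[0, 254]`, round half-up, sort, resolve duplicates upward with downward
overflow) for every fitness evaluation; dynamics stay continuous.

**PSO.** Standard inertia-weight particle swarm,
`V <- w V + c1p r1 (Pp - Z) + c2p r2 (Pg - Z)` with per-coordinate
uniform `r1, r2`, constants `w = 0.729`, `c1p = c2p = 1.49445`
(constriction-equivalent values), velocities clamped to half the box
width, zero initial velocities.

**MSSA.** A chain of 30 salps, the first half leaders (defaults). Leaders
perturb around the best-ever position ("food"):
`x = F ± c1 ((ub - lb) c2 + lb)` with fresh uniforms `c2, c3` per leader
and coordinate, the sign positive when `c3 >= 0.5`; followers move to the
midpoint of themselves and their predecessor. The leader weight decays as
`c1 = 2 exp(-(4 l / L)^2)`.

**PMSSA.** Identical to MSSA except that the leader step-length
coefficients are not fresh uniforms: an inner PSO (20 particles × 30
iterations per outer iteration, configurable, regenerated each outer
iteration by default) maximizes the mean absolute deviation
`f_pso = sum_i |Pc2_i - mean(Pc2)| / n_leader` over `[0, 1]^n_leader`, and
the sorted result supplies one coefficient per leader. The dispersion
objective is *maximized* (its text motivation is that leaders should probe
all step lengths around the food) — the maximum is 0.5, attained by
half-zeros/half-ones vectors.

### A measured limitation

The dispersion-maximal `Pc2` is a two-point set `{0, 1}`: half the leaders
sit exactly on the food position and the other half always take the
maximal step, and because each leader applies a single scalar coefficient
to every coordinate, the hybrid cannot make single-coordinate refinement
moves. On seeded 64-bin mixture histograms with the default budget
(30 agents × 100 iterations) we measure exact-optimum hit rates of roughly
0.92–0.94 at `Dim = 2` but only 0.4–0.6 at `Dim = 3`, where every failure
is a near-miss within a few gray levels of the optimum (relative fitness
gaps `1e-6`–`1e-3`); plain MSSA (~0.85) and PSO (~1.0) do better at
`Dim = 3`, and a reference differential-evolution run solves the same
instances essentially always. The hybrid's claimed robustness advantage
therefore does not materialize in this implementation, and the acceptance
suite records the corresponding check as failing rather than relaxing it.
For practical segmentation the fitness loss is negligible (the thresholds
are within 1–5 gray levels of optimal), but users wanting certified optima
should use `brute_force_optimal()`, which is exact and fast.

## Quality indicators

PSNR, SSIM and FSIM compare the preprocessed image with its class-mean
reconstruction; Dice, Jaccard, sensitivity, specificity and accuracy
compare binary vessel masks; Shannon entropy (class proportions, bits) and
region uniformity describe the labeling itself. Choices where the
formulas admit variants:

* SSIM uses *global* image statistics (single window over the whole
  image, `H*W - 1` variance denominators), the direct reading of the
  defining formulas, not the sliding-window estimator.
* FSIM uses phase congruency from a log-Gabor quadrature bank (4 scales,
  4 orientations, minimum wavelength 6 px, `sigma_onf = 0.55`, scale
  multiplier 2) without noise compensation, gradient magnitudes from the
  Scharr operator, and stability constants `T1 = 0.85`, `T2 = 160` (the
  reference values in the FSIM literature). All are arguments.
* Entropy is computed over segmentation-class proportions (bounded by
  `log2 K`), not over the gray histogram of the reconstruction.
* Region uniformity normalizes by the total pixel count and defines a
  zero contribution for constant regions (degenerate range denominator).
* Conventions: Dice and Jaccard of two empty masks are 1; 0/0 rates are
  `NA` (JSON `null`); PSNR of identical images is `Inf` (JSON `null`).
* The predicted vessel mask defaults to the single brightest class of the
  labeling (vessels are the bright tail after enhancement);
  `vessel_classes` accepts a set. On phantoms, the top class of a
  `Dim = 3` labeling is a high-precision, ~0.5-recall vessel detector
  (Dice 0.56–0.69); adding the second-brightest class raises Dice to
  ~0.9 but also admits more background in noisier imagery, so the
  conservative default is kept.

## The synthetic phantom

`generate_phantom()` emulates green-channel fundus statistics: a bright
background (level 170) with a linear illumination ramp (amplitude 25) and
Gaussian pixel noise (sd 8), and 4 dark vessel trees grown from the border
as random walks with branching (probability 0.02 per step, two levels
deep), rendered as tubes with Gaussian cross-sections (`sigma` 1–2.5 px,
center contrast 70 below background). The ground-truth mask marks pixels
within the profile's FWHM (`|d| <= sigma sqrt(2 ln 2)`) of a centerline —
the standard caliber definition for Gaussian profiles — which yields a
vessel fraction around 5%, the class imbalance typical of fundus
benchmarks. Everything is reproducible bit-for-bit from the seed.

What the phantom does *not* model: the circular field-of-view mask, optic
disc and fovea, lesions, central vessel reflex, and spatially correlated
noise. Passing phantom tests therefore demonstrates the pipeline's
mechanics (enhancement, search, evaluation), not clinical performance on
real fundus images.

The histogram generator (`generate_histogram()`) draws mixtures of
discretized Gaussians (weights 0.2–1 normalized, means across the support,
standard deviations between `n_bins/40` and `n_bins/10`) on the first
`n_bins` of 256 bins; it is the fixture for optimizer-versus-oracle
studies.

## Numerical choices and degenerate inputs

* Rounding is always half-up (`floor(x + 0.5)`) for determinism across
  platforms (base `round()` is banker's).
* Min-max rescaling treats a numerically constant input (range below
  `1e-9` relative) as constant and returns zeros, absorbing FFT roundoff.
* Empty histogram classes are legal everywhere and contribute zero to
  `sigma_B^2`.
* Oracle ties break to the lexicographically smallest threshold vector so
  golden tests are stable.
* All randomness flows from explicit `seed` arguments; the inner PSO of
  PMSSA draws from the outer run's stream, so one seed fixes the whole
  run. Identical configuration and seed reproduce byte-identical JSON
  reports.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run 50 histogram-versus-oracle
pairs per dimension at the default budget, 1000 variance-decomposition
pairs, 10 end-to-end 256×256 phantoms, and 20-seed elitism sweeps —
sizes chosen to make the stochastic rates stable while keeping a full run
in a few minutes on one CPU.
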