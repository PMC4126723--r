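---
title: "Single-case deviation mapping and classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-case deviation mapping and classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casemap)
```

`casemap` answers a question group statistics cannot: given one rare case
(or one family) and two reference cohorts — typical Williams syndrome (WS)
and typically developing controls (TD) — which group does the case
resemble, region by region and measure by measure? This vignette documents
the models, the tunable parameters, the synthetic-data design, and the
numerical choices, so that a user knows exactly what the package computes
and what its validation does and does not show.

## The deviation model

For a case value $x$ and a reference group $g$ with mean $\mu_g$ and
standard deviation $\sigma_g$, the deviation is

$$z_g = \frac{x - \mu_g}{\sigma_g},$$

computed per behavioral measure (scalar) or per voxel (using the cohort's
per-voxel mean and SD). Two conventions matter and are fixed as defaults:

* **SD denominator.** $\sigma_g$ uses $n-1$. The case is external to the
  reference sample, so the sample SD is the natural estimate of the
  population spread it is being compared against.
* **Strict thresholds.** "Exceeds" means $z > \theta$ or $z < -\theta$
  strictly; $|z| = \theta$ does not exceed.

Brain measures use $\theta = 1.96$ two-sided (nominal $p < .05$).
Behavioral scalars use $\theta = 1.65$ one-tailed, with the tail pointing
toward the *other* group: when testing a case against WS on a measure
where TD scores higher, only the upper tail counts, and vice versa. The
per-measure direction is the sign of the known WS$-$TD difference,
recorded in `ws_td_reference()$direction` and overridable there.

The voxel-wise maps are *descriptive*, not inferential: a fixed
$\pm\theta$ threshold is applied per voxel with no correction across
voxels. With an $n = 40$ reference cohort a case drawn from the same
population exceeds $|z| > 1.96$ at rate
$2\,P\!\left(t_{39} > 1.96\sqrt{40/41}\right) \approx 6.0\%$, approaching
the nominal 5% as $n \to \infty$; the tests check this calibration
explicitly. Voxels with zero cohort SD are flagged invalid and excluded
from every exceedance count.

### The resemblance rule

Per measure, or per ROI for maps, the two thresholded deviations combine
into one call: exceeding against WS only is `TD_like`, against TD only is
`WS_like`, both `deviant_from_both`, neither `within_both`. For ROIs the
rule is *any valid voxel exceeds*; alongside the call, the table reports
the ROI's peak signed $z$ (the voxel maximizing $|z|$) and mean $z$
against each group. The peak is reported because a single number per ROI
is how such results are conventionally tabulated, but note that the
any-voxel rule makes the single-case call intrinsically noisy at moderate
effect sizes: detection power at one voxel for a true shift of $2\sigma$
is only $P(z < -1.96 \mid \mu = -2) \approx 0.51$, and enlarging the ROI
raises the false-exceedance probability against the matching group in
step with true detection. The per-ROI call should therefore be read
jointly with the peak/mean $z$ values, and the package's own validation
asserts directional recovery (the deviant group is detected, and decided
calls go the right way) rather than a near-certain single call.

### Family probabilistic maps

For $k$ related cases sharing a deletion, the thresholded maps combine
into per-voxel proportions: `prop_pos(v)` is the fraction of members with
$z > \theta$ at voxel $v$ (likewise `prop_neg`). Values are exact
multiples of $1/k$; the two proportions sum to at most 1.

## Volumetrics

Regional volumes correlate with head size, so before case comparison they
are adjusted for total cranium gray matter. The default is
**pooled-reference residualization**: one linear trend of ROI volume on
total gray matter is fitted over the pooled WS+TD reference, and every
subject — including cases, which never influence the fit — is replaced by
its residual plus the reference grand mean. This preserves units (ml) and
the reference mean, and makes the adjusted reference values exactly
uncorrelated with total gray matter ($|r| < 10^{-10}$ is asserted in the
tests). A ratio adjustment (`method = "ratio"`) is provided because some
labs prefer it; it does not share the exact-decorrelation property. The
choice is a config switch because the adjustment convention is
lab-specific rather than dictated by the model.

Group comparisons use the Welch (unequal-variance) two-sample $t$,
two-sided, with listwise deletion per measure; sex tables use the
continuity-corrected chi-square. The continuity correction is deliberate:
on the reference cohort's 19M/23F vs 16M/24F split it gives
$\chi^2 = 0.07$, matching the published statistic, where the uncorrected
value would be 0.23.

## The multivariate stage

The discriminative question — do many voxels jointly separate WS from TD,
and which side does the case fall on? — is answered with a linear
soft-margin SVM ($C = 1$) under leave-one-out cross-validation (LOO-CV),
on maps down-sampled to 4 mm voxels by block averaging of the
*non-smoothed* maps. Block averaging is volume-preserving for modulated
maps; 4 mm brings the feature count to the scale where an SVM on ~80
subjects is well-behaved.

* **Leakage-free standardization.** Each feature is centered and scaled
  with training-fold statistics only (config flag `standardize`;
  zero-variance features pass through centered). The held-out subject and
  any case never touch the training statistics.
* **RFE.** At each level a full LOO ensemble is trained, its accuracy
  recorded, features ranked by mean $|w|$ across the level's fold
  classifiers (weights live in standardized space, so the ranking is
  scale-free), and the bottom $\lfloor 0.30\,m \rfloor$ (at least 1)
  eliminated; elimination stops before the count would drop below 10.
  The kept level maximizes LOO accuracy, ties going to the fewest
  features. By construction the chosen accuracy is at least the
  full-feature accuracy.
* **Case probability.** Every fold classifier labels the case; $p_{WS}$
  is the fraction of WS votes — an exact multiple of $1/N$ summing to 1
  with $p_{TD}$. This is a vote share across resampled classifiers, not a
  calibrated posterior; no Platt scaling is applied.
* **Tie rule.** A case exactly on a fold's hyperplane ($w\cdot x + b =
  0$) is assigned to TD. The choice is arbitrary but deterministic and
  affects only measure-zero inputs.
* **Permutation null.** `permutation_accuracy_null()` re-runs the whole
  LOO protocol under label permutations and reports
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$. Two properties of
  this statistic are worth knowing: LOO accuracy under permuted labels is
  chance-level with a *pessimistic* bias (each training fold is
  imbalanced against the held-out subject's class, so the null mean sits
  slightly below 0.5), and because accuracy is discrete the p-value is
  conservative (stochastically at least uniform) rather than exactly
  uniform. The tests assert exactly these properties.

Training is fully deterministic; the seed governs only permutations and
simulation.

## The synthetic generator

`synthetic_spec()` fixes every ingredient of a simulated study; identical
specs regenerate identical cohorts. The defaults are the study conditions
the package is validated under, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| grid | $32^3$ @ 2 mm | desk-scale stand-in for a registered volume |
| `n_ws`, `n_td` | 42, 40 | the 1.5T reference cohort sizes |
| `roi_effects` | $\pm 2$ | Cohen's d of WS vs TD per ROI (parietal down, orbitofrontal/fusiform/amygdala up) |
| `noise_sd` | 0.05 | marginal voxel noise SD (baseline 0.5) |
| `smoothing_fwhm` | 8 mm | spatial autocorrelation of the smoothed maps |
| `family_k` | 6 | members of the simulated family |
| behavioral laws | `ws_td_reference()` | published per-group means/SDs |

Each subject gets a **pair of maps from one white-noise draw**, mirroring
VBM preprocessing: the *raw* map adds the white noise directly (the
multivariate stage's input), the *smoothed* map adds the same field
convolved with an isotropic Gaussian kernel (the univariate stage's
input). The smoothed noise is variance-normalized per voxel — the
separable kernel's exact per-voxel variance shrinkage is divided out — so
the marginal SD equals `noise_sd` everywhere while the autocorrelation is
retained. Without this, a planted shift of $d \times$ `noise_sd` would
correspond to a wildly inflated empirical Cohen's d on smoothed maps
(smoothing shrinks the marginal SD roughly 15-fold at these settings).
Effects are crisp boxes added after smoothing; maps are clipped at zero,
which is negligible since baseline $\gg$ `noise_sd`.

Default ROIs are seven disjoint 12 mm boxes named after the regions the
analysis targets. Twelve millimetres is a deliberate choice: it is the
scale of the smaller anatomical structures involved, and it exceeds the
8 mm smoothing kernel so an ROI contains more than one effective
resolution element. Total cranium gray matter is not part of the
published summaries; its generative law (WS 620 ± 60 ml, TD 700 ± 65 ml)
is a realistic default encoding the well-replicated global gray-matter
reduction in WS, and is flagged `synthetic` in `ws_td_reference()`.

### What the generator does and does not emulate

It reproduces the *statistical* character the pipeline assumes: smooth
Gaussian fields with planted mean shifts, group-conditional scalar laws,
family structure. It does not attempt anatomy (no tissue boundaries,
no inter-subject anatomical variability, no scanner or site effects, no
non-Gaussian tails, no correlation between behavioral measures and voxel
patterns). Passing recovery tests therefore demonstrates that the
*pipeline* is correct and well-calibrated under its own model — not that
real scans of these populations would classify at the same accuracies.
The published MRI-based accuracies are in that sense not reproducible
here and are not asserted anywhere; the validation replaces them with
null-calibration and planted-effect recovery at the study's sample sizes
(problem sizes used: one 40+40 null cohort; 50 recovery simulations at
40+40 on the parietal region set; 20 feature-level RFE enrichment
simulations at 40 subjects × 220 features; one 6-member family at
$|d| = 2.5$).

## Numerical and degenerate-input choices

* Down-sampling requires the target edge to be an integer multiple of the
  source spacing; trailing partial blocks are averaged over the voxels
  they cover. Upsampling is refused.
* Grids must match exactly (extents; spacing to $10^{-6}$ mm): no silent
  resampling of images or masks. Masks down-sample by coverage
  (default ≥ 50%).
* 4D NIfTI inputs are rejected loudly; one 3D map per subject.
* Cohorts of fewer than 2 subjects, single-member classes, zero reference
  SDs, zero total-GM variance, and mixed thresholds in a family are all
  hard errors rather than warnings.
* Reports embed the package version, seed, and an md5 hash of the sorted
  configuration, so identical inputs and config yield byte-identical
  report bodies.

## Known limitations

* The ROI-level resemblance call inherits the any-voxel rule's noise at
  moderate effects (see above); at the published case deviations
  ($|z|$ up to ~10) this is immaterial, but users planting small
  synthetic effects should interpret single calls cautiously.
* The fold-vote probability is not calibrated; 100% means unanimity of
  N correlated classifiers, not certainty.
* The permutation null re-trains the full LOO ensemble per permutation
  and is the most expensive operation in the package; budget
  $B \times N$ SVM fits.
* Residual adjustment assumes a common ROI-on-total-GM slope across
  reference groups; no interaction term is fitted.
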