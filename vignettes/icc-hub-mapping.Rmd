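---
title: "Mapping connectivity hubs with the intrinsic connectivity contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping connectivity hubs with the intrinsic connectivity contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icchub)
```

## The metric

Connector hubs are brain regions whose spontaneous activity is coherent with
many distributed systems at once; they are thought to route information
between large-scale resting-state networks (RSNs) and are preferentially
implicated in neurodegeneration. `icchub` implements a voxel-level,
threshold-free measure of overall connection strength, the *intrinsic
connectivity contrast* (ICC): for voxel $i$ within a gray-matter (GM) mask of
$n$ voxels,

$$\mathrm{ICC}(i) \;=\; \frac{1}{n_i}\sum_{j \in S(i),\, j \neq i} r(i,j)^2,$$

where $r(i,j)$ is the Pearson correlation between the denoised BOLD time
series of voxels $i$ and $j$, and $S(i)$ is the included voxel set. Squaring
weights every connection by its strength without choosing a connectivity
threshold, and avoids parcellation bias because everything is computed at the
voxel level. Three strata are supported:

* **whole-brain** — all other mask voxels ($n_i = n - 1$);
* **short-range** — voxels whose center-to-center Euclidean world distance is
  at most $d_{thr}$ (default 75 mm), boundary inclusive;
* **long-range** — voxels strictly beyond $d_{thr}$.

Distances are measured in world mm through the image affine, not in voxel
indices, so anisotropic grids are handled correctly. The self pair is always
excluded. Each map is z-standardized over the mask (population s.d.) before
group analysis; standardization is monotone, so it rescales but never
reorders voxels.

**Denominator convention.** The stratified variants divide by the per-voxel
included count $n_i$, so all three modes live on the same $[0,1]$ scale of a
mean squared correlation and satisfy the exact decomposition
$S_{whole} = S_{short} + S_{long}$ of count-weighted sums. A literal $1/n$
normalization (dividing all strata by the mask size) is available as
`denominator = "global_n"`.

**Engine.** Computing all voxel pairs explicitly needs $O(n^2)$ memory.
`compute_icc()` instead accumulates each voxel's sum of squared correlations
in chunks sized to a memory cap (`mem_mb`), never materializing the pair
matrix. The inner accumulation runs in compiled code with a fixed pair order,
so results are *bit-identical* for every chunk size — a property the test
suite asserts, together with agreement to $10^{-10}$ with a naive all-pairs
oracle. Zero-variance voxel series (possible after aggressive masking)
contribute $r = 0$ to all their pairs and are flagged in the map rather than
dropped, which preserves mask geometry; the whole-brain count stays $n - 1$.

## The denoising chain

The pipeline ingests already-aligned common-space 4-D BOLD images and applies
the standard resting-state nuisance chain, in a fixed order:

1. **Trim** the first 5 volumes (initial signal instability); the motion
   trace is trimmed with the series.
2. **Confound regression** (OLS per voxel, intercept always added): the 24
   motion regressors $[R_t, R_t^2, R_{t-1}, R_{t-1}^2]$ built from the
   6-parameter rigid-body trace, optionally augmented with mean signals from
   4 mm spheres in CSF and WM, the global-mask mean, and their
   backward-difference derivatives. Rank-deficient confound sets (e.g. a
   zero motion trace) are reduced to a maximal independent column set with a
   warning instead of failing.
3. **Band-pass** 0.01–0.1 Hz: an order-4 Butterworth filter applied
   forward-backward (zero phase), so no temporal shift is introduced into
   cross-voxel correlations. The matrix implementation column-wise
   bit-matches `signal::filtfilt`; the contract asserted in the tests is
   that a 0.05 Hz sinusoid at TR 2.5 s survives within 5% and a 0.19 Hz
   sinusoid is attenuated by at least 90%.

Subjects are screened on mean frame-wise displacement,
$FD_t = |\Delta x| + |\Delta y| + |\Delta z| + 50\,(|\Delta\alpha| +
|\Delta\beta| + |\Delta\gamma|)$ mm (backward differences, $FD_1 = 0$, 50 mm
reference sphere for rotations): a subject is excluded iff mean FD is
*strictly* greater than 0.2 mm. Whether nuisance regressors should themselves
be filtered before regression is genuinely ambiguous in the field; the
package regresses first and filters second (the narrative order of the
chain), and this choice is deliberately kept visible here rather than hidden.

## Group inference

Standardized per-subject maps are analyzed voxel-wise:

* **One-sample characterization**: $t = \bar z / (s/\sqrt{N})$ against zero,
  with voxel-level family-wise error (FWE) control from the sign-flip
  permutation distribution of the maximum statistic, followed by a
  cluster-extent filter (clusters below 25 voxels discarded;
  exactly 25 kept).
* **Covariate regression**: OLS on age and ACE-R total score with sex and
  mean FD as nuisance regressors, one-sided contrasts for both signs of each
  effect. Cluster-level FWE uses the cluster-defining threshold (CDT)
  $t$-quantile at $p = 0.001$ one-sided, 26-connectivity components, and the
  permutation null of the maximum cluster extent — sign flipping for
  one-sample designs, Freedman–Lane residual permutation for regression.
  Corrected $p = (1 + \#\{\max k_{null} \ge k\})/(1 + n_{perm})$.

Permutation max-statistic inference is used *instead of* random-field-theory
corrections: it is exact under exchangeability, needs no smoothness
estimation, and its calibration can be verified empirically — the test suite
checks that under null cohorts the fraction of replicates with any
significant cluster stays inside the binomial 95% band around 0.05. Peak
statistics are reported both as $t$ and as the matching-tail-probability $z$
value. The permutation seed is a mandatory argument; identical seeds give
identical tables. Connectivity (6/18/26) and the CDT are configurable.

## Seed-based connectivity and RSN overlap

Seeds are 4 mm spheres (voxel-center distance, boundary inclusive; the
nearest voxel is forced in if the sphere falls between centers) placed at the
peak coordinates of significant clusters. Each subject's ROI-mean series is
correlated with every GM voxel; the per-subject maps are Fisher r-to-z
transformed (variance stabilization; `fisher = FALSE` tests raw r), passed
through the one-sample permutation cluster pipeline, and the significant
voxels form a binary group connectivity mask. Against each of 14 canonical
RSN templates the *overlap ratio*

$$R \;=\; \frac{N_{overlap}}{N_{RSN}}$$

is reported, where $N_{RSN}$ is the template size and $N_{overlap}$ the
number of template voxels inside the corrected map: $R = 1$ means the
template lies fully inside the map, $R = 0$ means no overlap. A connector
hub shows $R$ substantially above zero for several templates at once; a
non-connector voxel for exactly one. Templates on a different grid are
resampled by nearest neighbour, which preserves binary masks.

## The synthetic cohort generator

Real resting-state cohorts of this kind are not redistributable, so the
package ships a generator that plants everything downstream stages must
recover. Per subject,

$$Y \;=\; L_s\,\Lambda \;+\; \varepsilon,$$

where $\Lambda$ holds latent network time-courses, $L_s$ is the subject's
voxel-by-network loading matrix, and $\varepsilon$ is white noise. Latent
courses are Gaussian series smoothed with a moving-average window (~7.5 s, so
their spectrum sits mostly inside the 0.01–0.1 Hz passband at TR 2.5 s),
then sample-centered and orthonormalized. The orthonormalization is a
deliberate design choice: at desk-scale scan lengths the sample correlation
between two genuinely independent smoothed series has s.d. ≈ 0.13, which
would swamp the planted hub contrast; forcing exact in-sample orthogonality
makes the ground truth identifiable and the noise-free hub ranking
deterministic, at the cost of modeling networks as exactly uncorrelated
rather than independent.

Networks occupy compact blocks of the grid separated by background margins
(background voxels carry pure noise and fall below the GM-probability
threshold of 0.2, exercising the masking path; GM is ~12% of the bounding
box, as for a real brain). Connector-hub voxels sit on block borders and
load $1/\sqrt 2$ on two adjacent networks; all other GM voxels load 1 on
exactly one network. One binary RSN template per network (its voxel support)
is emitted, with labels drawn from the canonical 14-label list.

Key defaults, chosen once (all overridable in `cohort_spec()`):

| parameter | default | why |
|---|---|---|
| `grid_shape`, `voxel_size_mm` | 16³, 6 mm | 96 mm field of view, so the 75 mm threshold yields non-trivial short and long strata |
| `n_timepoints`, `tr_seconds` | 120 + 5 trimmed, 2.5 s | ~8 min scan at a typical TR |
| `n_networks` | 4 | enough for distinct hub pairs without crowding the grid |
| `network_amplitude`, `noise_sd` | 1, 0.5 | signal-to-noise in the range where same-network pairs still dominate cross-network pairs |
| `hub_voxel_fraction` | 0.0075 | hubs must be a *limited* set (~5% of GM): with a much larger fraction, per-subject z-standardization converts a planted hub decline into a compensatory positive trend across the rest of the mask |
| `age_effect` | −0.02 per year | no published effect size exists for this slope; sized so the per-voxel hub noncentrality clears the CDT quantile (≈3.3) comfortably at n = 40, making recovery a property of the method rather than a coin flip |
| `age_range` | 21–86 years | an adult-lifespan cohort |
| `motion_sd_mm` | 0.02 | random-walk step giving mean FD ≈ 0.1 mm, a typical compliant subject; rotations scaled by 1/50 so both contribute equally to FD |
| `acer_effect` | 0 | cognition independent of the BOLD model by default (age and cognition effects were disjoint in the motivating analysis); settable for power studies |

Ages are uniform over the range; ACE-R totals are drawn around 96.5
(s.d. 2.2, clipped to [89, 100], matching a cognitively normal cohort). The
hub-coupling age effect scales hub loadings by
$1 + \beta\,(\mathrm{age} - \overline{\mathrm{age}})$.

What the generator does *not* emulate: hemodynamic response convolution,
physiological (cardiac/respiratory) noise, scanner drift, and spatial
autocorrelation beyond the block structure. Passing tests therefore
demonstrate the correctness and calibration of the pipeline's computations
and inference under a known truth — not robustness to every artifact of real
scanner data.

## Numerical choices

* Pair inclusion at exactly $d_{thr}$ goes to the short stratum ("within"
  read as inclusive); squared distances are compared to $d_{thr}^2$ with
  per-axis differences, which is bit-stable under chunking.
* z-standardization uses the population (divide-by-N) s.d., so tests can be
  exact; it standardizes over the GM mask (the only voxels with defined
  values), not the full image box.
* Infinite t statistics (zero residual variance) are capped at $10^6$ with
  their sign; zero-variance voxels in one-sample tests get statistic 0 and a
  flag.
* The CDT is the analytic Student-t quantile, matching the usual semantics
  of a cluster-defining threshold; only the FWE correction is
  permutation-based.
* Permutation p values use the add-one estimator, so the smallest reachable
  p is $1/(1 + n_{perm})$.

## Problem sizes used in the shipped test suites

The replicated inference suites run 20 cohorts for signed parameter recovery
(40 subjects, 16³ grid, 120 retained volumes, planted negative hub effect)
and 40 null cohorts for type-I calibration, each analyzed with 500
permutations — sizes at which the suites complete on a single desktop core
in a few minutes while leaving the binomial calibration band meaningful.
The oracle-equivalence suite uses random masks of up to ~450 voxels, where
the naive $O(V^2)$ reference is still quick.

## Known limitations

* Freedman–Lane exchangeability assumes i.i.d. errors across subjects;
  heteroscedastic cohorts (e.g. age-dependent noise) are not specifically
  handled.
* The generator's block networks make short-range/long-range strata
  meaningful but geometrically simple; gradients of hubness within a region
  are not modeled.
* Anatomical labeling of cluster peaks (an atlas lookup) is out of scope;
  tables report world coordinates only.
* Graph-theoretic hub metrics (degree, betweenness, modularity) are
  intentionally not implemented; the ICC is the package's single hub
  measure.
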