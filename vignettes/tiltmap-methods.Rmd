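---
title: "Methods: tilt-dependent body-axis errors and lesion-deficit inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tilt-dependent body-axis errors and lesion-deficit inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, conventions,
numerical choices and the design of the synthetic test world. It states no
empirical result that the test suite does not itself compute.

## 1. Behavioural model

A participant adjusts a visual line to their perceived body longitudinal
axis; the **SVBA error** of a trial is the signed angular deviation
(degrees) of that line from the true body axis, rightward-positive. Errors
are averaged over the trials of each posture (upright, 10° left roll, 10°
right roll; ten trials each in the reference protocol — fewer are accepted
with a warning, since the mean is still defined).

**Sign conventions.** For stroke patients all three per-posture means are
re-signed so that positive means *ipsilesional*: left-sided lesions flip
every sign, right-sided lesions and controls are untouched. Tilt
directions are then relabelled: direction 1 is the leftward tilt for
controls and the ipsilesional tilt for patients; direction 2 the opposite.

**Tilt-dependent error.** With oriented per-posture means,

$$\mathrm{TDE}_1 = -(\mathrm{SVBA}_1 - \mathrm{SVBA}_{up}), \qquad
  \mathrm{TDE}_2 = \mathrm{SVBA}_2 - \mathrm{SVBA}_{up},$$

and a participant's score is the mean of the two. The direction-1 sign
reversal follows the stated convention of the source analysis (positive =
shift in the tilt direction for the leftward/control case). Both TDEs are
invariant under adding a common constant to the three inputs — a property
the suite asserts over random draws. Angles are treated linearly (no
circular statistics): all quantities live well inside (−90°, 90°].

**Group tests.** One-sample *t* of the upright error against zero per
group; paired *t* between tilt directions per group; pooled-variance
(Student) two-sample *t* between groups. The pooled form is forced by the
reference degrees of freedom (55 = 20 + 37 − 2); Cohen's *d* uses the
pooled SD. Two published inconsistencies are deliberately *not* chased:
the control upright *t* printed as −0.19 is irreproducible from the
printed summary (−0.3 ± 2.6, n = 20 gives −0.516); and the printed
cut-off 0.04° differs from the 0.05° implied by the rounded control
statistics 25.7/17.1. The package computes from unrounded inputs and the
tests assert the formula values.

**Abnormality cut-off.** `cutoff = control mean − k · control SD`
(k = 1.5, a conservative neuropsychological convention); *abnormal* is
strictly below the cut-off, so a tie classifies as normal ("below the
mean" read strictly). The abnormal count is non-increasing in k.

## 2. Lesion data and maps

Masks are binary NIfTI-1 volumes on a common grid; values are binarized
by `> 0` on load, 4-D inputs and non-finite values are rejected, and
mismatched grids/affines abort (resampling is out of scope — masks must
arrive normalized). Voxel indices are 0-based; world coordinates come only
through the affine (sform preferred, qform decoded otherwise). The package
carries its own minimal NIfTI-1 reader/writer because the supported
environment provides no R NIfTI package; round-trips are tested
bit-consistently for masks and to float32 precision for maps.

Overlap maps are percentages (100 × lesioned members / group size), and
the subtraction map is the voxel-wise difference of percentages
(abnormal − normal), not raw counts, so the very unequal group sizes
(5 vs 32 in the reference cohort) remain comparable. Display thresholding
is strict (`> 40` percentage points). Peak voxels break ties by lowest
lexicographic (i, j, k) index so reports are reproducible.

The coverage filter retains voxels damaged in at least 3 patients; the
voxel-wise test additionally needs at least 2 patients on each side, so
`min_intact` defaults to 1 at the matrix level and the BLDI run enforces
≥2 per group, marking anything else `not_tested` rather than failing the
map.

## 3. JZS Bayes factor

At each retained voxel the TDEs of lesioned vs intact patients are
compared with the default Bayesian two-sample *t*-test: Cauchy(0, rscale)
prior on the standardized effect δ (rscale = 0.707 exposed as a
parameter), Jeffreys priors on location and scale. Writing
N = n₁n₂/(n₁+n₂) and ν = n₁+n₂−2, the Cauchy is represented as a normal
scale mixture with inverse-χ²(1) mixing density and

$$\mathrm{BF}_{10} = \int_0^\infty (1+Ngr^2)^{-1/2}
 \left(\frac{1 + t^2/\nu\,(1+Ngr^2)^{-1}}{1 + t^2/\nu}\right)^{-(\nu+1)/2}
 p(g)\,dg$$

is evaluated with adaptive quadrature after the substitution
g = u/(1−u) (relative tolerance 1e−10, absolute 1e−12; deterministic, no
sampling). The exact Bayes-factor formulation of the reference toolkit is
not restated in its methods text, so the standard JZS default is adopted.
Lesion size is deliberately not a covariate, following the source
analysis. The suite checks the implementation against an *independent*
brute-force oracle — Simpson quadrature of the noncentral-*t* density over
the Cauchy prior via a tangent substitution — to ≤1e−6 relative error over
a (t, n₁, n₂, rscale) grid, plus the qualitative properties: BF₁₀(t=0) < 1
for all group sizes, strict monotonicity in |t|, decay to 0 as the prior
widens, and monotone decrease of the null BF with n. Identical voxel
damage patterns are deduplicated before testing; a test asserts bitwise
identity with the naive per-voxel loop.

Evidence categories follow the substantial-evidence thresholds: BF₁₀ ≥ 3
for H₁, BF₁₀ < 1/3 for H₀, inconclusive between; the boundaries map to
`substantial_H1` and `inconclusive` respectively.

## 4. Correlation analysis

Pearson correlations use the exact *t* transform for two-tailed p-values;
partial correlations are residual-based (least-squares projection on
[1, covariates], df = n − 2 − k) and reduce exactly to Pearson with no
covariates. Complete cases only, per row (the reference cohort had
missing postural and neglect data; listwise deletion reproduces its
per-analysis n's). Rank-deficient covariate sets error naming the
collinear columns.

The correlation Bayes factor tests ρ = 0 against a stretched-beta prior
ρ = 2β−1, β ~ Beta(1/κ, 1/κ), using the exact sampling density of the
observed correlation (Gauss hypergeometric factor summed as a series; the
test oracle re-derives it from the Euler integral representation). The
source analysis reports "Cauchy priors with a scale of 0.707 for Pearson
correlation", which is not a standard correlation prior — its published
BF values are therefore not reproduction targets; the package exposes the
prior width (default κ = 0.707 to mirror the printed scale; κ = 1 is the
common uniform default) and documents the ambiguity. κ → 0 collapses the
prior onto the null and drives BF₁₀ → 1, which the suite checks.

## 5. The synthetic world

The generator's defaults are the stated conditions of the reference
cohort; they were fixed once and are not tuned to test outcomes.

| Parameter | Default | Why |
|---|---|---|
| grid, voxel | 32³ at 5 mm | 160 mm field of view; keeps tests in seconds. Statistics do not depend on grid resolution |
| n controls / patients | 20 / 37 | reference group sizes |
| control TDE | N(25.7, 17.1²) | printed control statistics |
| normal-patient TDE | N(19.2, 14.8²) | printed normal-TDE subgroup |
| abnormal TDE | N(−4.1, 1.8²) | printed abnormal-TDE subgroup |
| right-lesion fraction | 22/37 | reference lesion-side split |
| lesions per patient | 2 spheres, radius U(10, 30) mm | union volumes ≈ 40–75 cm³, typical middle-cerebral-artery stroke scale; gives voxel coverage comparable (after rescaling) to the ~110 cm³ the reference analysis tested |
| critical region | sphere, centre (40, 10, 10) mm, r = 12 mm | right temporo-parietal locus on this grid |
| seeded hits | 5 patients, sphere congruent with the region | plants the rare abnormal subgroup (5/37 ≈ 13%) |
| overlap threshold | 0.5 | half the region damaged induces abnormality |
| trial noise | 2° SD | plausible adjustment scatter; recovered mean TDE then has ~0.45° SD of measurement error |
| upright bias | 4° SD | between the printed control (2.6°) and stroke (6.6°) upright SDs |
| covariate slopes | 0 | the reference correlations are null |

Abnormality is a deterministic function of lesion geometry (critical-
region overlap ≥ threshold), the simplest mechanism consistent with
"lesions can introduce the reduction", and gives unambiguous ground truth.

**Cut-off-calibrated subgroup draws.** The printed subgroup statistics
are statistics of *cut-off-defined* groups: in the source cohort, every
abnormal patient lies below the control-referenced cut-off by
construction. Drawing subgroup scores unconditionally from N(−4.1, 1.8²)
and N(19.2, 14.8²) loses that property: the cut-off itself is re-estimated
from each synthetic control sample (SD ≈ 5.6° across cohorts at n = 20),
so unconditioned draws let planted abnormal patients land above the
cohort's cut-off and normal patients below it — the classification stage
then no longer has a ground truth to recover (measured: the subtraction
peak found the planted region in only 11/30 seeds). With
`calibrate_to_cutoff = TRUE` (default) the generator draws the control
latents first, computes the cohort's own cut-off, and draws abnormal
latents truncated below `cutoff − 1°` and normal-patient latents above
`cutoff + 1°` (the 1° margin is >2 SD of the trial-noise error on a
recovered mean TDE). In the typical cohort the truncation removes ~1% of
the abnormal and ~10% of the normal density, leaving the subgroup
distributions essentially as printed while making classification
consistent with the planted truth. Unconditioned draws remain available
(`calibrate_to_cutoff = FALSE`) and define the null-calibration world
(together with `tde_abnormal = tde_normal_patient`, i.e. a genuinely
zero effect — the overlap threshold is *not* moved out of range).

**What a green test establishes — and what it does not.** The synthetic
world has spherical, hemisphere-clipped lesions with uniform spatial
density, a single spherical critical region, Gaussian behaviour, and an
abnormality mechanism that is exactly the analysis's own classification
rule. Green recovery tests therefore establish that the pipeline's
machinery (orientation, classification, matrix assembly, subtraction,
Bayes factors, peak reporting) is self-consistent and recovers planted
structure; they say nothing about anatomical realism, vascular-territory
lesion correlations, registration error, or behaviour that violates the
Gaussian/linear assumptions. Null-calibration fractions are heavy-tailed
per cohort because neighbouring voxels share damage patterns (a single
chance cluster of co-lesioned low-TDE patients lights up its whole
territory); the ≤5% claim is about the rate over seeds, and the suite
asserts it as such.

## 6. Numerical choices

- Quadrature tolerances: 1e−10 relative (JZS and correlation marginals);
  oracle grids 40001 (Simpson, tangent substitution) and 4001 points.
- Strict inequalities: abnormality (`< cutoff`), display threshold
  (`> min_value`).
- Tie-breaks: peak voxel at the lowest lexicographic 0-based index.
- Degenerate voxels (n < 2 per side, zero pooled variance) are
  `not_tested`, never errors mid-map.
- Maps are written float32 (NA as NaN), masks uint8; affines as sform
  code 2. NIfTI reading supports both byte orders and scl scaling.
- Determinism: all generator randomness flows from one integer seed
  (R's default Mersenne Twister; behaviour and covariates use fixed
  offsets seed+1000/seed+2000), so identical configs give byte-identical
  JSON summaries — asserted in the suite.

## 7. Known limitations

- No lesion delineation, registration or MNI normalization; masks must
  arrive on a common grid.
- No anatomical labelling of coordinates (no atlas lookup).
- No frequentist voxel-wise mapping with permutation correction; the
  pipeline mirrors the descriptive-subtraction-plus-BLDI design.
- The SVBA trial clamp at ±90° can shave extreme synthetic latents
  (rare at default scales).
- The correlation-BF prior family is a documented choice, not a
  reproduction of the source software's (ambiguous) specification.
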