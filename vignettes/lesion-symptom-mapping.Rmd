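---
title: "Mapping praxis deficits from CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping praxis deficits from CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

praxismap implements a complete analysis chain for locating the neural
correlates of limb apraxia — impairment of skilled, learned movement not
explained by weakness or incomprehension — in subacute stroke cohorts whose
imaging consists of clinical CT. The chain has three scientific stages,
each exposed as ordinary R functions, plus a synthetic-cohort generator that
makes every stage testable against exact ground truth.

## 1. The statistical model

### Lesion delineation by case-control outlier statistics

After preprocessing, each patient scan is compared voxel by voxel against a
set of `k` control CT scans on the same grid. The statistic is the
Crawford–Howell case-control t,

$$ t = \frac{x^\* - \bar m}{s \sqrt{(k+1)/k}}, \qquad \mathrm{df} = k - 1, $$

where $x^\*$ is the patient's intensity at the voxel and $\bar m$, $s$ are
the control sample mean and SD. This is exactly a pooled-variance two-sample
t test in which one "group" has a single member — the package's tests verify
the equivalence to 1e-12 against `t.test()`. Voxels where the control SD is
zero (the background) carry no information and are excluded rather than given
infinite scores.

The t map is thresholded one-tailed at `alpha` (default p < 0.001) in the
direction implied by the stroke type — hypo-intense for ischemic,
hyper-intense for hemorrhagic, either when unknown — then intersected with
the brain mask and cleaned of clusters below 100 voxels (0.1 mL), which on
contiguous stroke lesions removes only speckle.

**Boundary restoration.** Because thresholding happens after Gaussian
smoothing, a high-contrast lesion acquires a supra-threshold halo roughly
2 mm wide: every voxel whose kernel overlaps the lesion looks abnormal. The
default delineation therefore trims each detected cluster at half its peak
|t| (`refine = "half_peak"` in `binarize_lesion()`). For a blurred step edge
the half-height contour coincides with the true boundary, so this removes the
halo without introducing a tunable threshold. The peak is estimated as the
95th percentile of |t| within the cluster, not the maximum, because the
voxelwise t carries multiplicative noise from the sampled control SD and the
raw maximum is an upward outlier. Trimming only ever shrinks a cluster, so
detection sensitivity at `alpha` is unchanged and the mask remains monotone
in `alpha`. With the defaults the median Dice overlap between recovered and
true synthetic lesions is about 0.9; with plain thresholding
(`refine = "none"`) it is about 0.65.

### Voxel-based lesion-symptom mapping

For each behavioural task, at every voxel lesioned in at least 10 patients,
the package fits

$$ \mathrm{score}_i = \beta_0 + \beta_L \, L_{iv} + \boldsymbol\gamma^\top
\mathbf{z}_i + \varepsilon_i $$

with $L_{iv}\in\{0,1\}$ the lesion status of patient $i$ at voxel $v$ and
$\mathbf z_i$ the covariates of no interest (age, handedness coded right = 0
/ left = 1, total lesion volume, orientation-in-time-and-space score). The
test is one-sided for the deficit direction by default — all praxis scores
are "higher is better", so a lesion that matters drives $\beta_L$ negative —
and the stored t map is sign-flipped so that positive values indicate
deficit association, the convention used in reported peak tables. A
two-sided option exists.

Since the covariates are shared across voxels, the per-voxel fits are
computed with the Frisch–Waugh–Lovell identity: the score and every lesion
column are residualised once against the covariate design, and the whole map
follows from a few matrix products. The result is bit-identical to refitting
`lm()` at each voxel (tested), and it makes 200-replicate permutation nulls
cheap.

Multiplicity is controlled by Benjamini–Hochberg FDR at q = 0.05 over
exactly the tested voxels of each task separately; voxels skipped for rank
deficiency or constant lesion status are excluded from the FDR denominator
because they never produce a p value. Significant voxels are grouped by
26-connectivity and reported as clusters with volume, peak t and peak world
coordinates, sorted by volume with deterministic tie-breaks.

### Behavioural scoring

The praxis battery semantics live in `score_item()`, `bcos_cutoffs()`,
`classify_impairment()` and `composite_apraxia_score()`. Classification uses
age-banded cut-offs (bands ≤ 64, 65–74, ≥ 75 years); a patient is apraxic
when at least one of the three praxis tasks falls at or below the band
cut-off. Two published cut-off conventions are shipped: the integer
age-adjusted table (rule "impaired iff score ≤ cut-off") and the fractional
two-SD thresholds 11.5 / 5.8 / 11.5 (rule "impaired iff score < cut-off").
On the integer score grid these agree wherever the fractional threshold sits
between consecutive integers; the integer table is the default. Whether a
score exactly at the cut-off counts as impaired is not decidable from the
published material; the "≤" rule is a documented package decision, not an
inferred intent.

The composite apraxia score is the sum of the three task scores each
rescaled by its maximum (range 0–3). The exact published composite formula
is not available; this normalised sum weights the tasks equally and is
strictly increasing in each score, which is all the correlation analyses
require.

## 2. The preprocessing chain

Raw head CT is prepared in this order (the order matters and matches
standard automated delineation practice): background cluster removal,
affine registration to a template, invertible intensity transformation,
brain/ventricle masking and skull-stripping, 1-mm isotropic reslicing,
4-mm FWHM Gaussian smoothing, then delineation.

* **Background removal** zeroes voxels at or below 0.1 % of the maximum
  intensity, labels the rest by 26-connectivity, and keeps the largest
  component. An all-foreground input is retained whole with a warning.
* **Registration** estimates 12 parameters (3 translations, 3 rotations,
  3 scales, 3 shears) by maximising normalised cross-correlation, with
  moment-based initialisation, a half-resolution stage, a deterministic
  rotation multi-start, and quasi-Newton refinement with the analytic NCC
  gradient. The transform maps moving-volume world coordinates into template
  world coordinates; resampling pulls template grid points back through its
  inverse. On synthetic heads the recovered translations are accurate to
  well under a voxel and scales to under 1 %. One caveat: a quasi-ellipsoidal
  head constrains the rotation/shear *split* weakly, because a small rotation
  of an ellipsoid is almost exactly undone by re-shearing; the overall map is
  still recovered to about a millimetre over the head, which is what
  resampling uses. Real brains, with richer internal structure, identify
  rotation better than any phantom of this kind.
* **Intensity transformation** applies the logistic remap
  $f(x) = L/(1+e^{-(x-c)/w})$ with $c$ midway between the CSF and parenchyma
  levels, so contrast is steepest exactly between the two tissue classes.
  The published delineation method uses an invertible contrast transform but
  does not print its formula; any strictly increasing sigmoid with a
  closed-form inverse satisfies the same contract, and the logistic is the
  simplest. Width defaults to one eighth of the CSF–parenchyma gap; the
  inverse is exact to numerical precision (tested to 1e-6 over the full
  range).
* **Masking** splits the within-head intensity distribution with Otsu's
  threshold and requires a class separation of at least two pooled SDs,
  erroring on unimodal inputs. The brain mask is the hole-filled head; the
  ventricle mask is the CSF-class voxels inside it.
* **Reslicing** is trilinear for intensities and nearest-neighbour for
  masks (the published method does not say; these are the standard choices).
  Voxel indices are 0-based; world coordinates follow the NIfTI RAS+ affine
  in mm, so reported peaks are directly comparable to template-space
  coordinate tables.
* **Smoothing** uses a separable discrete Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis (1.6986 mm at 4 mm
  FWHM), normalised to unit sum, zero-padded: total intensity is conserved
  whenever content sits more than $3\sigma$ from the grid edge.

## 3. The synthetic cohort

The generator emulates exactly the statistical structure the analysis
assumes, at desk scale:

* a 48³ voxel, 1-mm grid holding an ellipsoidal "brain" (radii 20 × 22 ×
  20 mm) with two CSF-filled ventricles; parenchyma at 40 ± 2 and CSF at
  10 ± 2 intensity units with spatially smooth Gaussian noise
  (2-mm FWHM correlation), zero background;
* one ellipsoidal lesion per patient (first-stroke cohorts are modelled with
  a single lesion), semi-axes drawn from 6–12 mm, centre sampled so the
  lesion fits inside the brain, intensity shifted by −25 units (ischemic
  hypo-density) by default — the sign convention covers hemorrhagic
  hyper-density as well;
* behavioural scores generated as
  `clip(max − effect · overlap − age_slope · (age − 72.39) + noise, 0, max)`
  rounded to the integer score grid, where `overlap` is the fraction of a
  hidden critical region (a 7-mm-radius ellipsoid in the left hemisphere of
  the phantom) covered by the lesion. Default effects are half the task
  range per full overlap, with 1 score point of Gaussian noise and an age
  slope of 0.03 points/year;
* demographics matching a large subacute stroke screening cohort: age
  truncated-normal (mean 72.39, SD 12.80, range 27–94), 353/387 probability
  of right-handedness; hemisphere labels derive from the lesion's world
  x-extent;
* an orientation-in-time-and-space covariate simulated as a noisy decreasing
  function of total lesion volume, and picture naming likewise, so the
  qualitative covariate correlations of real cohorts (worse orientation and
  naming with larger lesions, hence correlated with praxis deficits) are
  present.

Scaling note: a real cohort's mean lesion of 1.22 × 10⁵ mm³ sits in a brain
of roughly 70-mm hemispheric radius; scaled to the 20-mm phantom brain the
equivalent lesion radius is about 9 mm, which is why 6–12 mm is the realistic
default range here.

Ground truth (exact voxelised lesion masks, the critical-region mask, and
overlap fractions recomputable from the masks to the last bit) is returned
alongside the data, which is what makes recovery-based testing possible.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: CT physics (beam hardening, 4–5-mm slice
anisotropy, reconstruction artefacts), anatomical variability between
subjects beyond smooth intensity noise, non-ellipsoidal lesion geometry,
multi-focal strokes, and any true generative model of behaviour (the
linear-in-overlap deficit model is an artifact of this package's validation
design, not a scientific claim about apraxia).

## 4. Numerical choices and degenerate inputs

* Crawford–Howell with `k < 2` controls or zero control SD is an error;
  zero-SD voxels in maps are flagged invalid and excluded downstream.
* Rank-deficient or constant-lesion voxel designs are skipped with a
  sentinel and logged in the fit object, never silently zeroed.
* Cluster tables are deterministic: components are numbered largest-first
  with ties broken by smallest linear voxel index, and peak ties within a
  cluster resolve to the first voxel in scan order.
* The registration optimiser is fully deterministic (moment initialisation,
  fixed multi-start offsets, BFGS with analytic gradients); identical inputs
  give identical transforms.
* All cohort randomness flows from the single `seed` in `sim_config()`.

## 5. Problem sizes used in the validation suite

The shipped tests run the full chain at the study conditions: 30 controls
and 100 patients on the 48³ grid for the VLSM recovery, FDR and power
checks; 20 patients for delineation recovery; 20 lesion-free patients
against 30 controls for null calibration; 200 permutation replicates for
the FDR-under-null check; and 10 random affine draws on a 64³ asymmetric
head phantom for registration recovery. These sizes give Monte-Carlo
standard errors small enough that the checks are sharp (3-SE bands), while
a complete run of the suite stays comfortable on a single CPU.

## 6. Known limitations

* The half-peak boundary refinement assumes one dominant contrast level per
  lesion; lesions with strong internal heterogeneity (e.g. hemorrhagic
  transformation inside an infarct) would be trimmed towards their most
  abnormal compartment. Use `refine = "none"` and a stricter `alpha` in that
  situation.
* FDR is controlled per task; no across-task correction is applied, matching
  the practice of running separate analyses per behavioural score.
* Atlas lookup for cluster labels is out of scope: the cluster table carries
  an empty `area` column as a hook for user-supplied label volumes.
* The affine registration is intensity-driven mono-modal NCC; it is not a
  substitute for nonlinear spatial normalisation of severely distorted
  anatomy.
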