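#' Configuration of the synthetic stroke cohort
#'
#' Describes a desk-scale CT-like phantom cohort: an ellipsoidal brain with
#' CSF-filled ventricles on a common template grid, control scans drawn from a
#' smooth Gaussian intensity law, patient scans carrying one ellipsoidal
#' stroke lesion (hypo-intense for ischemic, hyper-intense for hemorrhagic),
#' and behavioural praxis scores driven by the fractional overlap of the
#' lesion with a hidden critical region plus an age effect and noise.
#'
#' Demographic defaults follow a large subacute stroke screening cohort:
#' age ~ Normal(72.39, 12.80) truncated to 27-94 years, 353/387
#' right-handed. Task score ranges are Gesture Production 0-12, Gesture
#' Recognition 0-6, Gesture Imitation 0-12, Picture Naming 0-14.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_size_mm isotropic spacing (mm).
#' @param n_controls,n_patients cohort sizes (`n_controls >= 2`).
#' @param parenchyma_mean,parenchyma_sd,csf_mean,csf_sd intensity law of the
#'   two tissue classes (arbitrary CT-like units).
#' @param noise_smoothness_mm spatial correlation scale (Gaussian FWHM, mm) of
#'   the intensity noise field.
#' @param lesion_intensity_shift signed intensity shift inside the lesion;
#'   negative = hypo-intense (ischemic), positive = hyper-intense
#'   (hemorrhagic).
#' @param lesion_radius_range_mm min and max lesion semi-axis (mm).
#' @param brain_radii_mm semi-axes of the brain ellipsoid (mm, world frame).
#' @param ventricle_radii_mm semi-axes of each of the two ventricles (mm).
#' @param ventricle_offset_mm lateral world offset of each ventricle centre.
#' @param critical_region list with `center` (world mm) and `radii` (mm) of
#'   the hidden region whose damage produces the deficit.
#' @param effect_per_task score points lost per unit fractional overlap with
#'   the critical region, named per task.
#' @param age_slope score points lost per year of age above the cohort mean.
#' @param noise_sd_behavior behavioural noise SD (score points).
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param right_handed_prob probability of right-handedness.
#' @param seed RNG seed governing the whole cohort.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(48L, 48L, 48L),
                       voxel_size_mm = 1,
                       n_controls = 30L,
                       n_patients = 100L,
                       parenchyma_mean = 40, parenchyma_sd = 2,
                       csf_mean = 10, csf_sd = 2,
                       noise_smoothness_mm = 2,
                       lesion_intensity_shift = -25,
                       lesion_radius_range_mm = c(6, 12),
                       brain_radii_mm = c(20, 22, 20),
                       ventricle_radii_mm = c(4, 7, 4),
                       ventricle_offset_mm = 7,
                       critical_region = list(center = c(-9, -4, 2),
                                              radii = c(7, 7, 7)),
                       effect_per_task = c(gesture_production = 6,
                                           gesture_recognition = 3,
                                           gesture_imitation = 6),
                       age_slope = 0.03,
                       noise_sd_behavior = 1,
                       age_mean = 72.39, age_sd = 12.80,
                       age_range = c(27, 94),
                       right_handed_prob = 353 / 387,
                       seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
              n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
              parenchyma_mean = parenchyma_mean, parenchyma_sd = parenchyma_sd,
              csf_mean = csf_mean, csf_sd = csf_sd,
              noise_smoothness_mm = noise_smoothness_mm,
              lesion_intensity_shift = lesion_intensity_shift,
              lesion_radius_range_mm = lesion_radius_range_mm,
              brain_radii_mm = brain_radii_mm,
              ventricle_radii_mm = ventricle_radii_mm,
              ventricle_offset_mm = ventricle_offset_mm,
              critical_region = critical_region,
              effect_per_task = effect_per_task,
              age_slope = age_slope,
              noise_sd_behavior = noise_sd_behavior,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              right_handed_prob = right_handed_prob,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (any(cfg$grid_shape <= 0)) stop("grid_shape must be positive")
  if (cfg$n_controls < 2) stop("need n_controls >= 2 (the case-control t needs df >= 1)")
  if (cfg$n_patients < 0) stop("n_patients must be non-negative")
  if (any(cfg$lesion_radius_range_mm <= 0) ||
      diff(cfg$lesion_radius_range_mm) < 0)
    stop("lesion_radius_range_mm must be positive and ordered")
  if (any(cfg$effect_per_task < 0)) stop("effect_per_task must be >= 0")
  fov <- cfg$grid_shape * cfg$voxel_size_mm / 2
  if (any(cfg$brain_radii_mm >= fov))
    stop("grid too small to contain the brain ellipsoid")
  if (any(cfg$ventricle_radii_mm + cfg$ventricle_offset_mm >= cfg$brain_radii_mm[1]))
    stop("ventricles do not fit inside the brain ellipsoid")
  if (max(cfg$lesion_radius_range_mm) >= min(cfg$brain_radii_mm))
    stop("lesion radii exceed the brain ellipsoid")
  invisible(cfg)
}

#' Score ranges of the four behavioural tasks
#' @return named integer vector of task maxima.
#' @export
task_maxima <- function() {
  c(gesture_production = 12L, gesture_recognition = 6L,
    gesture_imitation = 12L, picture_naming = 14L)
}

sim_affine <- function(cfg) centered_affine(cfg$grid_shape, cfg$voxel_size_mm)

# world coordinates of all voxels for a config (cached per call site)
sim_coords <- function(cfg) grid_world_coords(cfg$grid_shape, sim_affine(cfg))

ellipsoid_mask <- function(coords, center, radii, dims) {
  d <- sweep(coords, 2, center)
  inside <- (d[, 1] / radii[1])^2 + (d[, 2] / radii[2])^2 + (d[, 3] / radii[3])^2 <= 1
  array(as.double(inside), dims)
}

# analytic tissue template: brain / ventricle masks shared by all subjects
sim_anatomy <- function(cfg) {
  coords <- sim_coords(cfg)
  dims <- cfg$grid_shape
  brain <- ellipsoid_mask(coords, c(0, 0, 0), cfg$brain_radii_mm, dims)
  vent <- ellipsoid_mask(coords, c(-cfg$ventricle_offset_mm, 0, 0),
                         cfg$ventricle_radii_mm, dims) +
          ellipsoid_mask(coords, c(cfg$ventricle_offset_mm, 0, 0),
                         cfg$ventricle_radii_mm, dims)
  vent <- pmin(vent, 1) * brain
  vent <- array(vent, dims)
  list(brain = brain, ventricles = vent, coords = coords)
}

# smooth unit-variance Gaussian field; exact variance normalisation through
# the squared-kernel sum of the separable smoother
smooth_noise_field <- function(cfg) {
  white <- array(stats::rnorm(prod(cfg$grid_shape)), cfg$grid_shape)
  if (cfg$noise_smoothness_mm <= 0) return(white)
  sigma_vox <- fwhm_to_sigma(cfg$noise_smoothness_mm) / cfg$voxel_size_mm
  k <- gaussian_kernel(sigma_vox)
  out <- white
  for (ax in 1:3) out <- convolve_axis(out, ax, k)
  out / sqrt(sum(k^2))^3
}

#' Generate one control CT-like volume
#'
#' An ellipsoidal brain at parenchyma-level intensity with two CSF-level
#' ventricles, zero background, and spatially smooth Gaussian noise inside the
#' brain. Deterministic given the RNG state at the time of the call.
#'
#' @param cfg a [sim_config()].
#' @return a `volume` in template space.
#' @export
generate_control_volume <- function(cfg) {
  validate_sim_config(cfg)
  anat <- sim_anatomy(cfg)
  base <- anat$brain * cfg$parenchyma_mean +
          anat$ventricles * (cfg$csf_mean - cfg$parenchyma_mean)
  noise_sd <- anat$brain * cfg$parenchyma_sd +
              anat$ventricles * (cfg$csf_sd - cfg$parenchyma_sd)
  img <- base
  if (cfg$parenchyma_sd > 0 || cfg$csf_sd > 0)
    img <- base + smooth_noise_field(cfg) * noise_sd
  volume(array(img, cfg$grid_shape), sim_affine(cfg), space = "template")
}

#' Generate one patient volume with a ground-truth lesion
#'
#' A control-law volume plus one ellipsoidal stroke lesion whose centre is
#' sampled so the lesion lies inside the brain; intensities inside the lesion
#' are shifted by `lesion_intensity_shift` (negative = ischemic hypo-density,
#' positive = hemorrhagic hyper-density).
#'
#' @param cfg a [sim_config()].
#' @param max_retries resampling attempts for a lesion centre inside the brain.
#' @return list with `image` (`volume`) and `lesion` (binary `volume`, the
#'   exact voxelised ellipsoid).
#' @export
generate_patient_volume <- function(cfg, max_retries = 50L) {
  validate_sim_config(cfg)
  ctrl <- generate_control_volume(cfg)
  anat <- sim_anatomy(cfg)
  les <- sample_lesion_mask(cfg, anat, max_retries)
  img <- ctrl$data + les * cfg$lesion_intensity_shift
  list(image = volume(array(img, cfg$grid_shape), ctrl$affine, space = "template"),
       lesion = volume(les, ctrl$affine, space = "template"))
}

sample_lesion_mask <- function(cfg, anat, max_retries = 50L) {
  B <- cfg$brain_radii_mm
  for (try in seq_len(max_retries)) {
    radii <- stats::runif(3, cfg$lesion_radius_range_mm[1], cfg$lesion_radius_range_mm[2])
    margin <- B - max(radii)
    if (any(margin <= 0)) next
    # sample centre uniformly in the shrunken ellipsoid that guarantees
    # containment of the lesion's bounding sphere
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    r <- stats::runif(1)^(1 / 3)
    center <- u * r * margin
    les <- ellipsoid_mask(anat$coords, center, radii, cfg$grid_shape)
    les <- les * anat$brain
    if (sum(les) > 0) return(array(les, cfg$grid_shape))
  }
  stop("failed to place a lesion inside the brain after ", max_retries, " attempts")
}

#' Generate behavioural scores from lesion overlap and age
#'
#' `score = clip(max - effect * overlap - age_slope * (age - mean_age) +
#' noise, 0, max)`, rounded to the task's integer grid. Covers the three
#' praxis tasks named in `cfg$effect_per_task`.
#'
#' @param overlap fractional overlap of the lesion with the critical region,
#'   in `[0, 1]`.
#' @param age age in years.
#' @param cfg a [sim_config()].
#' @return named numeric vector of integer scores.
#' @export
generate_behavior <- function(overlap, age, cfg) {
  if (overlap < 0 || overlap > 1) stop("'overlap' must be in [0, 1]")
  maxima <- task_maxima()[names(cfg$effect_per_task)]
  raw <- maxima - cfg$effect_per_task * overlap -
         cfg$age_slope * (age - cfg$age_mean) +
         stats::rnorm(length(maxima), sd = cfg$noise_sd_behavior)
  out <- round(pmin(pmax(raw, 0), maxima))
  names(out) <- names(cfg$effect_per_task)
  out
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- stats::qnorm(stats::runif(n,
                                 stats::pnorm(lower, mean, sd),
                                 stats::pnorm(upper, mean, sd)), mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Generate a complete synthetic cohort
#'
#' Draws `n_controls` control volumes, `n_patients` lesioned patient volumes
#' and a behavioural table, together with the ground truth (true lesion masks,
#' critical-region mask, true overlap fractions) needed to score recovery.
#' The whole cohort is reproducible from `cfg$seed`.
#'
#' The orientation-in-time-and-space covariate is simulated as a noisy
#' decreasing function of total lesion volume, and picture naming carries a
#' small lesion-volume effect, so the covariate correlation structure of a
#' real cohort (worse orientation and naming with larger lesions) is
#' qualitatively present.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `controls` (list of `volume`s), `patients`
#'   (list of `volume`s), `behavior` (data.frame), and `truth` (list with
#'   `lesions`, `critical_region`, `overlap`, `config`).
#' @export
generate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  anat <- sim_anatomy(cfg)
  aff <- sim_affine(cfg)
  crit <- ellipsoid_mask(anat$coords, cfg$critical_region$center,
                         cfg$critical_region$radii, cfg$grid_shape)
  crit_vol <- volume(crit, aff, space = "template")
  n_crit <- sum(crit)

  controls <- lapply(seq_len(cfg$n_controls), function(i) generate_control_volume(cfg))

  patients <- vector("list", cfg$n_patients)
  lesions <- vector("list", cfg$n_patients)
  overlap <- numeric(cfg$n_patients)
  rows <- vector("list", cfg$n_patients)
  vox_vol <- prod(voxel_size(crit_vol))
  for (i in seq_len(cfg$n_patients)) {
    pat <- generate_patient_volume(cfg)
    patients[[i]] <- pat$image
    lesions[[i]] <- pat$lesion
    overlap[i] <- sum(pat$lesion$data * crit) / n_crit
    age <- rtruncnorm1(1, cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
    scores <- generate_behavior(overlap[i], age, cfg)
    lesion_mm3 <- sum(pat$lesion$data) * vox_vol
    # orientation: noisy, monotonically decreasing in lesion volume (max 16)
    orientation <- round(pmin(pmax(
      16 - 4 * lesion_mm3 / max_lesion_volume(cfg) + stats::rnorm(1, sd = 1), 0), 16))
    naming <- round(pmin(pmax(
      14 - 3 * lesion_mm3 / max_lesion_volume(cfg) + stats::rnorm(1, sd = 1), 0), 14))
    cx <- lesion_world_extent(pat$lesion)
    hemisphere <- if (cx[2] < 0) "L" else if (cx[1] > 0) "R" else "B"
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i),
      age_years = age,
      handedness = if (stats::runif(1) < cfg$right_handed_prob) "R" else "L",
      hemisphere = hemisphere,
      gesture_production = scores[["gesture_production"]],
      gesture_recognition = scores[["gesture_recognition"]],
      gesture_imitation = scores[["gesture_imitation"]],
      picture_naming = naming,
      orientation_score = orientation,
      lesion_volume_mm3 = lesion_mm3,
      stringsAsFactors = FALSE)
  }
  behavior <- if (cfg$n_patients > 0) do.call(rbind, rows) else
    data.frame(patient_id = character(), age_years = numeric(),
               handedness = character(), hemisphere = character(),
               gesture_production = numeric(), gesture_recognition = numeric(),
               gesture_imitation = numeric(), picture_naming = numeric(),
               orientation_score = numeric(), lesion_volume_mm3 = numeric(),
               stringsAsFactors = FALSE)

  list(controls = controls, patients = patients, behavior = behavior,
       truth = list(lesions = lesions, critical_region = crit_vol,
                    overlap = overlap, config = cfg))
}

max_lesion_volume <- function(cfg) {
  4 / 3 * pi * max(cfg$lesion_radius_range_mm)^3
}

# world x-extent of a lesion: c(min x, max x); used to assign hemisphere
lesion_world_extent <- function(lesion) {
  idx <- which(lesion$data > 0, arr.ind = TRUE) - 1
  w <- voxel_to_world(lesion, idx)
  range(w[, 1])
}
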