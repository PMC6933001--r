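#' Crawford-Howell case-control t statistic
#'
#' Compares a single case observation against a small control sample:
#' `t = (x - mean(controls)) / (sd(controls) * sqrt((k + 1) / k))` with
#' `df = k - 1`, where `k` is the number of controls and `sd` is the sample
#' standard deviation (divisor `k - 1`). The statistic is positive when the
#' case exceeds the control mean, and is exactly equivalent to a
#' pooled-variance two-sample t test with group sizes `(k, 1)`.
#'
#' @param case_value scalar case observation.
#' @param control_values numeric vector of at least two control observations
#'   with non-zero variance.
#' @return list with elements `t` and `df`.
#' @export
crawford_howell_t <- function(case_value, control_values) {
  k <- length(control_values)
  if (k < 2) stop("need at least 2 controls (df = k - 1 >= 1)")
  s <- stats::sd(control_values)
  if (s == 0) stop("control sample has zero variance: t is undefined")
  list(t = (case_value - mean(control_values)) / (s * sqrt((k + 1) / k)),
       df = k - 1L)
}

#' Build a control set from aligned control volumes
#'
#' Stacks `k >= 2` preprocessed control volumes on one grid and precomputes
#' the per-voxel mean and sample standard deviation maps that define the
#' normal intensity range at every voxel.
#'
#' @param volumes list of `volume`s on identical grids.
#' @return object of class `control_set` with elements `mean`, `sd`
#'   (`volume`s), `k` and `df`.
#' @export
control_set <- function(volumes) {
  k <- length(volumes)
  if (k < 2) stop("need at least 2 control volumes")
  for (v in volumes[-1]) stopifnot_same_grid(volumes[[1]], v)
  dims <- dim(volumes[[1]]$data)
  mat <- vapply(volumes, function(v) as.numeric(v$data), numeric(prod(dims)))
  mu <- rowMeans(mat)
  sdv <- sqrt(rowSums((mat - mu)^2) / (k - 1))
  aff <- volumes[[1]]$affine
  structure(list(mean = volume(array(mu, dims), aff, space = volumes[[1]]$space),
                 sd = volume(array(sdv, dims), aff, space = volumes[[1]]$space),
                 k = k, df = k - 1L),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("<control_set> k = %d controls (df = %d), grid %s\n",
              x$k, x$df, paste(dim(x$mean$data), collapse = " x ")))
  invisible(x)
}

#' Voxelwise outlier t-score map of a patient against controls
#'
#' Applies [crawford_howell_t()] at every voxel where the control standard
#' deviation is positive; other voxels (e.g. the zero background) are marked
#' invalid (`NA`) and excluded downstream.
#'
#' @param patient a preprocessed `volume` on the control grid.
#' @param controls a [control_set()].
#' @return object of class `tscore_map`: elements `t` (a `volume` with `NA`
#'   at invalid voxels), `df`, `valid` (binary `volume`).
#' @export
tscore_map <- function(patient, controls) {
  stopifnot(inherits(controls, "control_set"))
  stopifnot_same_grid(patient, controls$mean)
  valid <- controls$sd$data > 0
  t <- array(NA_real_, dim(patient$data))
  scale <- sqrt((controls$k + 1) / controls$k)
  t[valid] <- (patient$data[valid] - controls$mean$data[valid]) /
              (controls$sd$data[valid] * scale)
  structure(list(t = volume(t, patient$affine, space = patient$space),
                 df = controls$df,
                 valid = volume(array(as.double(valid), dim(patient$data)),
                                patient$affine, space = patient$space)),
            class = "tscore_map")
}

#' @export
print.tscore_map <- function(x, ...) {
  cat(sprintf("<tscore_map> df = %d, %d valid voxels, t range [%.2f, %.2f]\n",
              x$df, sum(x$valid$data), min(x$t$data, na.rm = TRUE),
              max(x$t$data, na.rm = TRUE)))
  invisible(x)
}

#' Threshold a t-score map into a binary lesion map
#'
#' A voxel is marked lesioned when its one-tailed Student p value
#' (`df = k - 1`) falls below `alpha` in the requested direction: `"hypo"`
#' (negative tail; ischemic hypo-density), `"hyper"` (positive tail;
#' hemorrhagic hyper-density), or `"both"` (either tail at `alpha` each).
#' The map is intersected with the brain mask and clusters smaller than
#' `min_lesion_cluster` voxels are removed.
#'
#' Because thresholding follows Gaussian smoothing, a high-contrast lesion is
#' surrounded by a supra-threshold halo of blurred boundary voxels. With
#' `refine = "half_peak"` each detected cluster is trimmed to the voxels
#' whose |t| reaches half the cluster's peak |t|: for a blurred step edge the
#' half-height contour coincides with the true boundary, so this restores the
#' pre-smoothing lesion extent without introducing a new tunable threshold.
#' Trimming only ever shrinks a cluster, so detection sensitivity at `alpha`
#' is unchanged and enlarging `alpha` still never shrinks the map.
#'
#' @param refine `"none"` (pure thresholding) or `"half_peak"` (trim each
#'   cluster at half its peak |t|).
#' @param tmap a [tscore_map()].
#' @param direction `"hypo"`, `"hyper"` or `"both"`.
#' @param alpha one-tailed significance level, in `(0, 0.5)`.
#' @param brain_mask optional binary `volume` restricting the search.
#' @param min_lesion_cluster minimum connected-component size (voxels).
#' @return binary `volume` lesion map.
#' @export
binarize_lesion <- function(tmap, direction = c("hypo", "hyper", "both"),
                            alpha = 0.001, brain_mask = NULL,
                            min_lesion_cluster = 100L,
                            refine = c("none", "half_peak")) {
  direction <- match.arg(direction)
  refine <- match.arg(refine)
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must be in (0, 0.5)")
  tcrit <- stats::qt(1 - alpha, df = tmap$df)
  t <- tmap$t$data
  hit <- switch(direction,
                hypo = t < -tcrit,
                hyper = t > tcrit,
                both = abs(t) > tcrit)
  hit[is.na(hit)] <- FALSE
  if (!is.null(brain_mask)) {
    stopifnot_same_grid(tmap$t, brain_mask)
    assert_binary(brain_mask, "brain_mask")
    hit <- hit & brain_mask$data > 0
  }
  if (min_lesion_cluster > 0 && any(hit)) {
    lab <- label_components(hit, connectivity = 26)
    sizes <- component_sizes(lab)
    hit <- lab > 0L & lab %in% which(sizes >= min_lesion_cluster)
  }
  if (refine == "half_peak" && any(hit)) {
    lab <- label_components(hit, connectivity = 26)
    at <- abs(t)
    for (l in seq_len(max(lab))) {
      lin <- which(lab == l)
      # robust peak height: the voxelwise t carries multiplicative noise from
      # the sampled control SD, so the raw maximum is an upward outlier
      peak <- stats::quantile(at[lin], 0.95, names = FALSE)
      hit[lin] <- at[lin] >= peak / 2
    }
  }
  volume(array(as.double(hit), dim(tmap$t$data)), tmap$t$affine,
         space = tmap$t$space)
}

#' Lesion volume in cubic millimetres
#'
#' @param lesion binary `volume`.
#' @return nonzero voxel count times the voxel volume from the affine (mm^3).
#' @export
lesion_volume <- function(lesion) {
  assert_binary(lesion, "lesion mask")
  sum(lesion$data) * prod(voxel_size(lesion))
}
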