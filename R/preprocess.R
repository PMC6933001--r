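#' Remove background clusters by threshold-based clustering
#'
#' Zeroes voxels at or below a fraction of the maximum intensity, labels the
#' remaining suprathreshold voxels by 26-connectivity, and keeps only the
#' largest connected component (the head); disconnected specks (scanner bed,
#' cables, reconstruction artefacts) are removed. With `min_cluster_voxels`
#' set, every component of at least that size is kept instead.
#'
#' @param v a `volume` with non-negative intensities.
#' @param frac threshold as a fraction of the maximum intensity (default 0.001,
#'   i.e. 0.1 percent).
#' @param min_cluster_voxels optional minimum component size to retain; `NULL`
#'   keeps only the largest component.
#' @return a `volume` with background and speck clusters zeroed.
#' @export
remove_background_clusters <- function(v, frac = 0.001, min_cluster_voxels = NULL) {
  if (any(v$data < 0)) stop("intensities must be non-negative")
  if (frac <= 0 || frac >= 1) stop("'frac' must be in (0, 1)")
  mx <- max(v$data)
  if (mx <= 0) stop("no foreground: volume is all zero")
  fg <- v$data > frac * mx
  if (all(fg)) {
    warning("all voxels are above threshold; retaining the full volume")
    return(v)
  }
  labels <- label_components(fg, connectivity = 26)
  keep <- if (is.null(min_cluster_voxels)) {
    labels == 1L  # components are size-ordered; 1 is the largest
  } else {
    sizes <- component_sizes(labels)
    labels > 0L & labels %in% which(sizes >= min_cluster_voxels)
  }
  out <- v$data
  out[!keep] <- 0
  volume(out, v$affine, space = v$space)
}

#' Parameters of the CSF/parenchyma contrast transform
#'
#' Defines a strictly increasing logistic remap
#' `f(x) = L / (1 + exp(-(x - c) / w))` with the centre `c` midway between the
#' CSF and parenchyma intensity levels, so the steepest contrast enhancement
#' falls exactly between the two tissue classes. The map has the closed-form
#' inverse `f^-1(y) = c + w * log(y / (L - y))`.
#'
#' @param csf,parenchyma intensity levels of the two tissue classes
#'   (`parenchyma > csf`).
#' @param width logistic width `w` (intensity units); default one eighth of the
#'   CSF-parenchyma gap.
#' @param L output ceiling; default `2 * parenchyma`.
#' @return a list of class `intensity_params`.
#' @export
intensity_params <- function(csf, parenchyma, width = (parenchyma - csf) / 8,
                             L = 2 * parenchyma) {
  if (!is.finite(csf) || !is.finite(parenchyma) || parenchyma <= csf)
    stop("need parenchyma > csf for a monotone contrast transform")
  if (width <= 0 || L <= 0) stop("'width' and 'L' must be positive")
  structure(list(center = (csf + parenchyma) / 2, width = width, L = L),
            class = "intensity_params")
}

#' Invertible intensity transform emphasising CSF/parenchyma contrast
#'
#' @param v a `volume`.
#' @param params an [intensity_params()] object.
#' @return transformed `volume` (values in `(0, L)`).
#' @export
transform_intensity <- function(v, params) {
  stopifnot(inherits(params, "intensity_params"))
  out <- params$L / (1 + exp(-(v$data - params$center) / params$width))
  volume(out, v$affine, space = v$space)
}

#' Inverse of [transform_intensity()]
#'
#' @param v a transformed `volume` with values strictly inside `(0, L)`.
#' @param params the [intensity_params()] used for the forward map.
#' @return `volume` on the original intensity scale.
#' @export
inverse_transform_intensity <- function(v, params) {
  stopifnot(inherits(params, "intensity_params"))
  y <- v$data
  if (any(y <= 0 | y >= params$L))
    stop("values outside (0, L): not in the range of the forward transform")
  out <- params$center + params$width * log(y / (params$L - y))
  volume(out, v$affine, space = v$space)
}

#' Brain and ventricle masks from the intensity distribution
#'
#' Splits the within-head intensity distribution into CSF-level and
#' parenchyma-level classes (Otsu threshold), fills interior holes to obtain
#' the brain mask, and takes the CSF-class voxels inside the brain as the
#' ventricle mask. Requires a clearly bimodal distribution.
#'
#' @param v a background-removed `volume`.
#' @param min_ventricle_voxels drop CSF components smaller than this.
#' @return list with binary `volume`s `brain` and `ventricles`
#'   (`ventricles` is a subset of `brain`).
#' @export
make_masks <- function(v, min_ventricle_voxels = 10L) {
  head <- v$data > 0
  if (!any(head)) stop("empty volume: no foreground voxels")
  vals <- v$data[head]
  if (diff(range(vals)) <= 0)
    stop("intensity distribution is unimodal: cannot separate CSF from parenchyma")
  thr <- otsu_threshold(vals)
  lo <- vals[vals <= thr]; hi <- vals[vals > thr]
  if (length(lo) < 2 || length(hi) < 2)
    stop("intensity distribution is unimodal: cannot separate CSF from parenchyma")
  sep <- (mean(hi) - mean(lo)) / sqrt((stats::var(lo) + stats::var(hi)) / 2)
  if (!is.finite(sep) || sep < 2)
    stop("intensity distribution is unimodal: cannot separate CSF from parenchyma")

  brain <- fill_holes(head)
  csf <- (v$data <= thr) & (brain > 0) & head
  if (any(csf)) {
    lab <- label_components(csf, connectivity = 26)
    sizes <- component_sizes(lab)
    keep <- which(sizes >= min_ventricle_voxels)
    csf <- lab > 0L & lab %in% keep
  }
  list(brain = volume(array(as.double(brain), dim(v$data)), v$affine, space = v$space),
       ventricles = volume(array(as.double(csf), dim(v$data)), v$affine, space = v$space))
}

#' Skull-strip a volume with a brain mask
#'
#' @param v a `volume`.
#' @param brain_mask binary `volume` on the same grid.
#' @return `volume` with voxels outside the mask zeroed.
#' @export
skull_strip <- function(v, brain_mask) {
  stopifnot_same_grid(v, brain_mask)
  assert_binary(brain_mask, "brain_mask")
  volume(v$data * brain_mask$data, v$affine, space = v$space)
}

#' Convert a Gaussian FWHM to its standard deviation
#'
#' `sigma = FWHM / (2 * sqrt(2 * log(2)))`; a 4-mm FWHM gives
#' `sigma = 1.6986` mm.
#'
#' @param fwhm full width at half maximum (mm).
#' @return standard deviation in the same units.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Gaussian smoothing of a volume
#'
#' Separable convolution with a discrete Gaussian of the requested FWHM,
#' converted to voxel units per axis through the affine spacing. The kernel is
#' normalised to sum 1 and boundaries are zero-padded, so total intensity is
#' conserved away from the grid edge.
#'
#' @param v a `volume`.
#' @param fwhm_mm kernel full width at half maximum (mm); 0 is the identity.
#' @return smoothed `volume`.
#' @export
smooth_gaussian <- function(v, fwhm_mm) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be non-negative")
  if (fwhm_mm == 0) return(v)
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  vs <- voxel_size(v)
  out <- v$data
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / vs[ax]
    out <- convolve_axis(out, ax, gaussian_kernel(sigma_vox))
  }
  volume(out, v$affine, space = v$space)
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3.5 * sigma_vox))
  g <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  g / sum(g)
}

# convolve along one axis via a banded kernel matrix (zero-padded edges)
convolve_axis <- function(arr, axis, kernel) {
  dims <- dim(arr)
  n <- dims[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (d in -r:r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[d + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  p <- aperm(arr, perm)
  m <- matrix(p, nrow = n)
  res <- K %*% m
  out <- array(res, dim = dims[perm])
  aperm(out, order(perm))
}

#' Reslice a volume onto an isotropic template-space grid
#'
#' Resamples `v` through the inverse of an affine transform (pull-back) onto a
#' regular isotropic grid covering `bounding_box`. Intensities are interpolated
#' trilinearly; masks should use `interpolation = "nearest"`.
#'
#' @param v a `volume`.
#' @param transform an [affine_transform()] mapping `v`'s world coordinates to
#'   template world coordinates; `NULL` means identity.
#' @param resolution_mm isotropic output spacing (mm).
#' @param bounding_box 2 x 3 matrix, rows = template-space world min and max
#'   (mm); default is the transformed field of view of `v`.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return a `volume` tagged `space = "template"`.
#' @export
reslice_isotropic <- function(v, transform = NULL, resolution_mm = 1,
                              bounding_box = NULL,
                              interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  M <- if (is.null(transform)) diag(4) else transform$matrix
  if (abs(det(M)) < .Machine$double.eps) stop("transform is not invertible")
  if (is.null(bounding_box)) {
    d <- dim(v$data)
    corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
    w <- t(M %*% v$affine %*% rbind(t(corners), 1))[, 1:3, drop = FALSE]
    bounding_box <- rbind(apply(w, 2, min), apply(w, 2, max))
  }
  out_dims <- pmax(2L, as.integer(floor((bounding_box[2, ] - bounding_box[1, ]) /
                                          resolution_mm)) + 1L)
  out_affine <- diag(c(rep(resolution_mm, 3), 1))
  out_affine[1:3, 4] <- bounding_box[1, ]

  # output voxel -> template world -> moving world -> moving voxel
  A <- solve(v$affine) %*% solve(M) %*% out_affine
  vox <- grid_world_coords(out_dims, A)
  vals <- if (interpolation == "trilinear") trilinear_sample(v$data, vox)
          else nearest_sample(v$data, vox)
  out <- volume(array(vals, out_dims), out_affine, space = "template")
  if (sum(abs(out$data)) == 0 && sum(abs(v$data)) > 0)
    warning("bounding box excludes all foreground; output is empty")
  out
}

# sample a 3-D array at fractional 0-based voxel coordinates (outside -> 0)
trilinear_sample <- function(arr, vox) {
  dims <- dim(arr)
  i0 <- floor(vox)
  fr <- vox - i0
  acc <- numeric(nrow(vox))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- i0[, 1] + dx; cj <- i0[, 2] + dy; ck <- i0[, 3] + dz
    w <- (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (dz == 1) fr[, 3] else 1 - fr[, 3])
    ok <- ci >= 0 & ci < dims[1] & cj >= 0 & cj < dims[2] & ck >= 0 & ck < dims[3] & w > 0
    if (any(ok)) {
      lin <- ci[ok] + cj[ok] * dims[1] + ck[ok] * dims[1] * dims[2] + 1
      acc[ok] <- acc[ok] + w[ok] * arr[lin]
    }
  }
  acc
}

nearest_sample <- function(arr, vox) {
  dims <- dim(arr)
  r <- round(vox)
  ok <- r[, 1] >= 0 & r[, 1] < dims[1] & r[, 2] >= 0 & r[, 2] < dims[2] &
        r[, 3] >= 0 & r[, 3] < dims[3]
  out <- numeric(nrow(vox))
  lin <- r[ok, 1] + r[ok, 2] * dims[1] + r[ok, 3] * dims[1] * dims[2] + 1
  out[ok] <- arr[lin]
  out
}
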