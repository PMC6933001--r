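#' Construct a volume
#'
#' A `volume` is the package's carrier for 3-D scalar images: CT intensities,
#' t-score maps and binary masks. It couples a numeric 3-D array with a 4x4
#' voxel-to-world affine (mm, RAS+ orientation as in the NIfTI convention) and
#' a space tag recording whether the image is in native or template space.
#' Voxel indices are 0-based when mapped through the affine, matching NIfTI.
#'
#' @param data numeric 3-D array.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to 1-mm isotropic
#'   RAS+ with the world origin at the grid centre.
#' @param space `"native"` or `"template"`.
#' @return An object of class `volume`.
#' @export
volume <- function(data, affine = NULL, space = c("native", "template")) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (is.null(affine))
    affine <- centered_affine(dim(data), 1)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("'affine' must be invertible")
  structure(list(data = data, affine = affine, space = space),
            class = "volume")
}

#' @export
is_volume <- function(x) inherits(x, "volume")

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, space: %s\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], x$space))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

# 1-mm-scaled RAS affine with world origin at the grid centre
centered_affine <- function(dims, voxel_mm) {
  voxel_mm <- rep(voxel_mm, length.out = 3L)
  a <- diag(c(voxel_mm, 1))
  a[1:3, 4] <- -voxel_mm * (dims - 1) / 2
  a
}

#' Voxel spacing of a volume
#'
#' @param v a `volume`.
#' @return length-3 numeric, mm per voxel along each axis.
#' @export
voxel_size <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param v a `volume`.
#' @param idx n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(v, idx) {
  idx <- rbind_coords(idx)
  t(v$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' Map world coordinates to 0-based (fractional) voxel indices
#'
#' @param v a `volume`.
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates (mm).
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- rbind_coords(xyz)
  t(solve(v$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x
}

#' World coordinates of every voxel centre, in grid order
#' @noRd
grid_world_coords <- function(dims, affine) {
  ijk <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                               j = seq_len(dims[2]) - 1L,
                               k = seq_len(dims[3]) - 1L))
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

stopifnot_same_grid <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)))
    stop("volumes are on different grids: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (max(abs(a$affine - b$affine)) > 1e-6)
    stop("volumes have different affines")
  invisible(TRUE)
}

assert_binary <- function(v, what = "mask") {
  if (!all(v$data %in% c(0, 1)))
    stop(what, " must be binary (values in {0,1})")
  invisible(TRUE)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; returns `NA` when both masks are empty.
#'
#' @param a,b binary `volume`s on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot_same_grid(a, b)
  assert_binary(a); assert_binary(b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a$data * b$data) / (na + nb)
}

#' Read a NIfTI file as a volume
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param space space tag to attach.
#' @return a `volume`.
#' @export
read_volume <- function(path, space = c("native", "template")) {
  space <- match.arg(space)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  volume(arr, matrix(as.numeric(aff), 4, 4, dimnames = NULL), space = space)
}

#' Write a volume as NIfTI-1
#'
#' @param v a `volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
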