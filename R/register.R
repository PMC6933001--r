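#' A 12-parameter affine transform
#'
#' Composes translation (mm), rotation (rad, applied z-y-x), shear and
#' anisotropic scale into a 4x4 world-to-world matrix:
#' `M = T %*% Rz %*% Ry %*% Rx %*% Shear %*% Scale`. By convention the
#' transform maps moving-volume world coordinates into template world
#' coordinates; resampling pulls template grid points back through its
#' inverse. Identity parameters compose to the identity matrix.
#'
#' @param translation,rotation,scale,shear length-3 numeric parameter blocks.
#' @return object of class `affine_transform` with a `$matrix` element.
#' @export
affine_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                             scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 3, length(shear) == 3)
  if (any(scale <= 0)) stop("scales must be positive")
  M <- trans_mat(translation) %*% rot_mat(rotation) %*%
       shear_mat(shear) %*% scale_mat(scale)
  structure(list(translation = translation, rotation = rotation,
                 scale = scale, shear = shear, matrix = M),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  cat("  translation (mm):", sprintf("%.3f", x$translation), "\n")
  cat("  rotation (rad):  ", sprintf("%.4f", x$rotation), "\n")
  cat("  scale:           ", sprintf("%.4f", x$scale), "\n")
  cat("  shear:           ", sprintf("%.4f", x$shear), "\n")
  invisible(x)
}

trans_mat <- function(t) { m <- diag(4); m[1:3, 4] <- t; m }
scale_mat <- function(s) diag(c(s, 1))
shear_mat <- function(sh) {
  m <- diag(4)
  m[1, 2] <- sh[1]; m[1, 3] <- sh[2]; m[2, 3] <- sh[3]
  m
}
rot_mat <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- diag(4); Rx[2:3, 2:3] <- matrix(c(cx, sx, -sx, cx), 2)
  Ry <- diag(4); Ry[c(1, 3), c(1, 3)] <- matrix(c(cy, -sy, sy, cy), 2)
  Rz <- diag(4); Rz[1:2, 1:2] <- matrix(c(cz, sz, -sz, cz), 2)
  Rz %*% Ry %*% Rx
}

params_to_transform <- function(p) {
  affine_transform(translation = p[1:3], rotation = p[4:6],
                   scale = exp(p[7:9]), shear = p[10:12])
}

#' Push a volume through an affine transform
#'
#' Resamples `v` onto the grid of `reference` (default: its own grid) so that
#' the output at world coordinate `x` equals `v` at `T^-1 x` - i.e. the image
#' content is moved forward through the transform. Registering the result
#' back to `v` recovers the inverse transform.
#'
#' @param v a `volume`.
#' @param transform an [affine_transform()].
#' @param reference `volume` providing the output grid and affine.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return a `volume` on the reference grid.
#' @export
apply_transform <- function(v, transform, reference = v,
                            interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  A <- solve(v$affine) %*% solve(transform$matrix) %*% reference$affine
  vox <- grid_world_coords(dim(reference$data), A)
  vals <- if (interpolation == "trilinear") trilinear_sample(v$data, vox)
          else nearest_sample(v$data, vox)
  volume(array(vals, dim(reference$data)), reference$affine, space = v$space)
}

#' Affine registration by normalised cross-correlation
#'
#' Estimates the 12-parameter affine mapping `moving` into the space of
#' `template` by maximising the normalised cross-correlation between the
#' template and the pulled-back moving image. Initialisation is by intensity
#' moments (centroid and per-axis spread matching), followed by quasi-Newton
#' refinement at half resolution and then at full resolution. The procedure is
#' fully deterministic.
#'
#' @param moving,template `volume`s with overlapping fields of view.
#' @param coarse_maxit,fine_maxit optimiser iteration caps for the two stages.
#' @return an [affine_transform()] (moving world -> template world).
#' @export
register_affine <- function(moving, template, coarse_maxit = 200, fine_maxit = 150) {
  if (stats::sd(moving$data) == 0 || stats::sd(template$data) == 0)
    stop("degenerate (flat) image: registration is undefined")

  # moment initialisation of the pull-back map (template world -> moving
  # world): centroid and per-axis spread matching, rotation/shear zero
  mM <- image_moments(moving); mT <- image_moments(template)
  s0 <- pmin(1.5, pmax(0.67, mT$spread / mM$spread))
  t0 <- mT$centroid - s0 * mM$centroid
  p0 <- c(-t0 / s0, 0, 0, 0, -log(s0), 0, 0, 0)

  # unit steps per parameter scaled to comparable mm displacement at the
  # head periphery (~25 mm), so the quasi-Newton metric is well conditioned
  pscale <- c(1, 1, 1, rep(0.04, 9))
  ctrl <- function(maxit) list(maxit = maxit, reltol = 1e-12, parscale = pscale)
  tm_c <- downsample2(template); mv_c <- downsample2(moving)
  obj_c <- make_ncc_objective(mv_c, tm_c, max_voxels = 4000L)
  fit1 <- stats::optim(p0, obj_c$fn, obj_c$gr, method = "BFGS",
                       control = ctrl(coarse_maxit))
  # deterministic rotation multi-start: nearly ellipsoidal heads leave
  # shallow local optima where rotation trades off against shear and scale,
  # so single- and all-axis rotation offsets are each tried from the coarse
  # optimum and the best local solution is kept
  starts <- rbind(diag(3) * 0.06, diag(3) * -0.06)
  for (j in seq_len(nrow(starts))) {
    ps <- fit1$par; ps[4:6] <- ps[4:6] + starts[j, ]
    alt <- stats::optim(ps, obj_c$fn, obj_c$gr, method = "BFGS",
                        control = ctrl(80))
    if (alt$value < fit1$value) fit1 <- alt
  }
  obj_f <- make_ncc_objective(moving, template, max_voxels = 8000L)
  fit2 <- stats::optim(fit1$par, obj_f$fn, obj_f$gr, method = "BFGS",
                       control = ctrl(fine_maxit))
  # restarting resets the Hessian approximation, which helps the last
  # fraction of a degree in the shallow rotation/shear valleys
  fit_rs <- stats::optim(fit2$par, obj_f$fn, obj_f$gr, method = "BFGS",
                         control = ctrl(fine_maxit))
  if (fit_rs$value < fit2$value) fit2 <- fit_rs
  if (!is.finite(fit2$value) || fit2$value > -0.1)
    stop("registration failed: similarity did not improve (NCC ~ 0); ",
         "check field-of-view overlap and image contrast")
  matrix_to_transform(solve(params_to_transform(fit2$par)$matrix))
}

# NCC objective (fn) and its analytic gradient (gr) over the dilated head
# region of the template. The parameter vector encodes the pull-back map
# (template world -> moving world), so an evaluation is one matrix product
# plus trilinear sampling; the gradient chains the interpolation gradient of
# the moving image with the parameter derivatives of the composed matrix.
make_ncc_objective <- function(moving, template, eps = 1e-12, max_voxels = 16000L) {
  dims <- dim(template$data)
  mask <- template$data > 1e-3 * max(abs(template$data))
  if (sum(mask) < 100) mask[] <- TRUE
  mask <- dilate_mask(dilate_mask(mask))
  lin <- which(mask != 0)
  if (length(lin) > max_voxels)  # even stride subsample keeps spatial coverage
    lin <- lin[seq(1L, length(lin), by = ceiling(length(lin) / max_voxels))]
  tvec <- as.numeric(template$data)[lin]
  tc <- tvec - mean(tvec)
  tn <- sqrt(sum(tc^2))
  vw <- rbind(t(grid_world_coords(dims, template$affine)[lin, , drop = FALSE]), 1)
  Ainv_m <- solve(moving$affine)
  fn <- function(p) {
    P <- Ainv_m %*% params_to_transform(p)$matrix
    src <- t(P %*% vw)[, 1:3, drop = FALSE]
    s <- trilinear_sample(moving$data, src)
    sc <- s - mean(s)
    sn <- sqrt(sum(sc^2))
    if (sn < eps) return(0)
    -sum(sc * tc) / (sn * tn)
  }
  gr <- function(p) {
    D <- params_matrix_derivs(p)
    P <- Ainv_m %*% D$M
    src <- t(P %*% vw)[, 1:3, drop = FALSE]
    sg <- trilinear_sample_grad(moving$data, src)
    s <- sg$value
    sc <- s - mean(s)
    sn <- sqrt(sum(sc^2))
    if (sn < eps) return(numeric(12))
    r <- sum(sc * tc) / (sn * tn)
    dn_ds <- tc / (sn * tn) - r * sc / sn^2   # d NCC / d sample value
    # weight the moving-image spatial gradient (in moving voxel units) and
    # map to world units of the moving volume
    Gvox <- sg$grad * dn_ds                   # N x 3
    Gw <- Gvox %*% Ainv_m[1:3, 1:3]           # chain through world->voxel map
    vapply(seq_len(12), function(k) {
      dsrc <- t((D$dM[[k]] %*% vw)[1:3, , drop = FALSE])
      -sum(Gw * dsrc)
    }, numeric(1))
  }
  list(fn = fn, gr = gr)
}

# composed matrix M(p) = T R(z,y,x) Shear Scale and its 12 partial derivatives
params_matrix_derivs <- function(p) {
  t <- p[1:3]; r <- p[4:6]; s <- exp(p[7:9]); sh <- p[10:12]
  cx <- cos(r[1]); sx <- sin(r[1]); cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- diag(4); Rx[2:3, 2:3] <- matrix(c(cx, sx, -sx, cx), 2)
  Ry <- diag(4); Ry[c(1, 3), c(1, 3)] <- matrix(c(cy, -sy, sy, cy), 2)
  Rz <- diag(4); Rz[1:2, 1:2] <- matrix(c(cz, sz, -sz, cz), 2)
  dRx <- matrix(0, 4, 4); dRx[2:3, 2:3] <- matrix(c(-sx, cx, -cx, -sx), 2)
  dRy <- matrix(0, 4, 4); dRy[c(1, 3), c(1, 3)] <- matrix(c(-sy, -cy, cy, -sy), 2)
  dRz <- matrix(0, 4, 4); dRz[1:2, 1:2] <- matrix(c(-sz, cz, -cz, -sz), 2)
  T_ <- trans_mat(t); SH <- shear_mat(sh); S <- scale_mat(s)
  R <- Rz %*% Ry %*% Rx
  M <- T_ %*% R %*% SH %*% S
  RS <- R %*% SH %*% S
  dM <- vector("list", 12)
  for (j in 1:3) {
    E <- matrix(0, 4, 4); E[j, 4] <- 1
    dM[[j]] <- E
  }
  dM[[4]] <- T_ %*% Rz %*% Ry %*% dRx %*% SH %*% S
  dM[[5]] <- T_ %*% Rz %*% dRy %*% Rx %*% SH %*% S
  dM[[6]] <- T_ %*% dRz %*% Ry %*% Rx %*% SH %*% S
  for (j in 1:3) {  # d/d log(s_j): scale column j of M's linear part
    E <- matrix(0, 4, 4); E[j, j] <- s[j]
    dM[[6 + j]] <- T_ %*% R %*% SH %*% E
  }
  shear_slots <- list(c(1, 2), c(1, 3), c(2, 3))
  for (j in 1:3) {
    E <- matrix(0, 4, 4); E[shear_slots[[j]][1], shear_slots[[j]][2]] <- 1
    dM[[9 + j]] <- T_ %*% R %*% E %*% S
  }
  list(M = M, dM = dM)
}

# trilinear interpolation value and its spatial gradient (per voxel axis)
trilinear_sample_grad <- function(arr, vox) {
  dims <- dim(arr)
  i0 <- floor(vox)
  fr <- vox - i0
  n <- nrow(vox)
  val <- numeric(n)
  grad <- matrix(0, n, 3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- i0[, 1] + dx; cj <- i0[, 2] + dy; ck <- i0[, 3] + dz
    wx <- if (dx == 1) fr[, 1] else 1 - fr[, 1]
    wy <- if (dy == 1) fr[, 2] else 1 - fr[, 2]
    wz <- if (dz == 1) fr[, 3] else 1 - fr[, 3]
    sx <- if (dx == 1) 1 else -1
    sy <- if (dy == 1) 1 else -1
    sz <- if (dz == 1) 1 else -1
    ok <- ci >= 0 & ci < dims[1] & cj >= 0 & cj < dims[2] & ck >= 0 & ck < dims[3]
    if (!any(ok)) next
    lin <- ci[ok] + cj[ok] * dims[1] + ck[ok] * dims[1] * dims[2] + 1
    a <- arr[lin]
    val[ok] <- val[ok] + (wx * wy * wz)[ok] * a
    grad[ok, 1] <- grad[ok, 1] + sx * (wy * wz)[ok] * a
    grad[ok, 2] <- grad[ok, 2] + sy * (wx * wz)[ok] * a
    grad[ok, 3] <- grad[ok, 3] + sz * (wx * wy)[ok] * a
  }
  list(value = val, grad = grad)
}

# decompose a 4x4 affine matrix into the package's 12-parameter form
# (M = T %*% R %*% Shear %*% Scale) and rebuild the transform object
matrix_to_transform <- function(M) {
  A <- M[1:3, 1:3]
  if (det(A) <= 0) stop("affine has non-positive determinant")
  qr_ <- qr(A)
  Q <- qr.Q(qr_); R <- qr.R(qr_)
  d <- sign(diag(R)); d[d == 0] <- 1
  Q <- Q %*% diag(d); R <- diag(d) %*% R
  scale <- diag(R)
  Sh <- R %*% diag(1 / scale)
  # Euler angles of Q = Rz(g) Ry(b) Rx(a)
  b <- asin(max(-1, min(1, -Q[3, 1])))
  a <- atan2(Q[3, 2], Q[3, 3])
  g <- atan2(Q[2, 1], Q[1, 1])
  affine_transform(translation = M[1:3, 4], rotation = c(a, b, g),
                   scale = scale, shear = c(Sh[1, 2], Sh[1, 3], Sh[2, 3]))
}

image_moments <- function(v) {
  w <- pmax(v$data, 0)
  tot <- sum(w)
  if (tot <= 0) stop("cannot compute moments of a non-positive image")
  dims <- dim(v$data)
  idx <- list(slice.index(v$data, 1) - 1, slice.index(v$data, 2) - 1,
              slice.index(v$data, 3) - 1)
  mu_vox <- vapply(idx, function(ii) sum(w * ii) / tot, numeric(1))
  sd_vox <- vapply(1:3, function(a) sqrt(sum(w * (idx[[a]] - mu_vox[a])^2) / tot),
                   numeric(1))
  R <- v$affine[1:3, 1:3]
  list(centroid = as.numeric(R %*% mu_vox + v$affine[1:3, 4]),
       spread = as.numeric(sqrt((R^2) %*% sd_vox^2)))
}

downsample2 <- function(v) {
  d <- dim(v$data)
  i <- seq(1, d[1], 2); j <- seq(1, d[2], 2); k <- seq(1, d[3], 2)
  aff <- v$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  volume(v$data[i, j, k, drop = FALSE], aff, space = v$space)
}
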