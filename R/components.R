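#' Label connected components of a 3-D binary mask
#'
#' Flood-fill labelling with 26- (default) or 6-neighbourhood connectivity.
#' Components are numbered in decreasing size order (label 1 = largest), with
#' ties broken by the smallest linear voxel index, so labelling is
#' deterministic.
#'
#' @param mask logical/0-1 3-D array or a binary `volume`.
#' @param connectivity 26 (vertices, edges and faces) or 6 (faces only).
#' @return integer array of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (is_volume(mask)) mask <- mask$data
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  dims <- dim(mask)
  fg <- which(mask != 0)
  labels <- array(0L, dims)
  if (length(fg) == 0) return(labels)

  offs <- neighbour_offsets(dims, connectivity)
  inmask <- array(FALSE, dims)
  inmask[fg] <- TRUE

  nxy <- dims[1] * dims[2]
  lab <- 0L
  sizes <- integer(0)
  firsts <- integer(0)
  for (seed in fg) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    size <- 1L
    while (length(frontier) > 0) {
      cand <- rep(frontier, each = length(offs$lin)) + offs$lin
      # reject candidates that wrapped across a grid face
      ci <- rep(((frontier - 1L) %% dims[1]), each = length(offs$lin)) + offs$di
      cj <- rep((((frontier - 1L) %/% dims[1]) %% dims[2]), each = length(offs$lin)) + offs$dj
      ck <- rep(((frontier - 1L) %/% nxy), each = length(offs$lin)) + offs$dk
      ok <- ci >= 0L & ci < dims[1] & cj >= 0L & cj < dims[2] & ck >= 0L & ck < dims[3]
      cand <- cand[ok]
      cand <- cand[inmask[cand] & labels[cand] == 0L]
      cand <- unique(cand)
      labels[cand] <- lab
      size <- size + length(cand)
      frontier <- cand
    }
    sizes <- c(sizes, size)
    firsts <- c(firsts, seed)
  }
  # renumber: largest first, ties by first (smallest) linear index
  ord <- order(-sizes, firsts)
  remap <- integer(lab)
  remap[ord] <- seq_len(lab)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  labels
}

# precomputed neighbour offsets: linear-index deltas plus (di,dj,dk) for
# wrap-around rejection
neighbour_offsets <- function(dims, connectivity) {
  if (connectivity == 26) {
    d <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  } else {
    d <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
    colnames(d) <- c("di", "dj", "dk")
  }
  list(lin = d[, 1] + d[, 2] * dims[1] + d[, 3] * dims[1] * dims[2],
       di = rep(d[, 1], length.out = nrow(d)),
       dj = d[, 2], dk = d[, 3])
}

#' Sizes of labelled components
#' @noRd
component_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0L])
  tab
}

#' Fill interior holes of a binary mask
#'
#' Background components (6-connected) that do not touch the grid boundary are
#' converted to foreground.
#' @noRd
fill_holes <- function(mask) {
  dims <- dim(mask)
  bg <- label_components(mask == 0, connectivity = 6)
  border <- unique(c(bg[1, , ], bg[dims[1], , ], bg[, 1, ], bg[, dims[2], ],
                     bg[, , 1], bg[, , dims[3]]))
  border <- border[border > 0L]
  hole <- bg > 0L & !(bg %in% border)
  out <- mask != 0
  out[hole] <- TRUE
  storage.mode(out) <- "double"
  array(out, dims)
}

#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance on a fixed-width histogram; returns the
#' threshold intensity separating the two classes.
#' @noRd
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) stop("cannot threshold a constant intensity distribution")
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Dilate a binary mask by a number of voxels
#'
#' Chebyshev (26-neighbourhood) dilation applied `iterations` times.
#'
#' @param mask binary `volume` or 3-D array.
#' @param iterations number of one-voxel dilation passes.
#' @return same type as the input.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  v <- if (is_volume(mask)) mask$data else mask
  dims <- dim(v)
  cur <- v != 0
  for (it in seq_len(iterations)) {
    # sequential 1-D dilations compose to the 3x3x3 box (26-neighbourhood)
    for (ax in 1:3)
      cur <- cur | shift_array(cur, ax, 1L) | shift_array(cur, ax, -1L)
  }
  out <- array(as.double(cur), dims)
  if (is_volume(mask)) volume(out, mask$affine, space = mask$space) else out
}

# shift array by one voxel along axis, zero-filled
shift_array <- function(a, axis, by) {
  dims <- dim(a)
  idx_src <- lapply(dims, seq_len)
  idx_dst <- idx_src
  n <- dims[axis]
  if (by > 0) {
    idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1)
  } else {
    idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n
  }
  out <- array(FALSE, dims)
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(do.call(`[`, c(list(a), idx_src, list(drop = FALSE))))))
  out
}
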