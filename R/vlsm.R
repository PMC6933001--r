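#' Voxel inclusion mask for lesion-symptom mapping
#'
#' Sums aligned binary lesion maps into a lesion-overlap count map and keeps
#' the voxels lesioned in at least `min_count` patients (default 10), the
#' usual minimum for a stable per-voxel contrast.
#'
#' @param lesions non-empty list of aligned binary `volume`s.
#' @param min_count minimum number of lesioned patients per tested voxel.
#' @return list with `mask` (binary `volume`) and `counts` (`volume`, the
#'   lesion-overlap map).
#' @export
voxel_inclusion_mask <- function(lesions, min_count = 10L) {
  if (length(lesions) == 0) stop("empty patient list")
  for (v in lesions) assert_binary(v, "lesion map")
  for (v in lesions[-1]) stopifnot_same_grid(lesions[[1]], v)
  dims <- dim(lesions[[1]]$data)
  counts <- Reduce(`+`, lapply(lesions, function(v) v$data))
  aff <- lesions[[1]]$affine
  list(mask = volume(array(as.double(counts >= min_count), dims), aff,
                     space = lesions[[1]]$space),
       counts = volume(array(counts, dims), aff, space = lesions[[1]]$space))
}

#' Per-voxel linear model of a behavioural score on lesion status
#'
#' Ordinary least squares of `score` on an intercept, the voxel's 0/1 lesion
#' status and optional covariates. Returns the lesion coefficient, its t
#' statistic and p value; `alternative = "deficit"` tests the one-sided
#' hypothesis that a lesion lowers the score (negative coefficient).
#'
#' @param score numeric response vector.
#' @param lesion_status 0/1 vector, not constant.
#' @param covariates optional numeric matrix of covariate columns.
#' @param alternative `"deficit"` (one-sided, lesion lowers score) or
#'   `"two.sided"`.
#' @return list with `beta`, `t`, `p`, `df`, and `skipped` (`TRUE` with a
#'   `reason` when the design is rank-deficient or the lesion column is
#'   constant).
#' @export
fit_voxel_model <- function(score, lesion_status, covariates = NULL,
                            alternative = c("deficit", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(score)
  if (length(lesion_status) != n) stop("length mismatch")
  if (length(unique(lesion_status)) < 2)
    return(list(beta = NA_real_, t = NA_real_, p = NA_real_, df = NA_integer_,
                skipped = TRUE, reason = "constant lesion column"))
  X <- cbind(`(Intercept)` = 1, lesion = lesion_status, covariates)
  if (n <= ncol(X))
    stop("need more observations than design columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    return(list(beta = NA_real_, t = NA_real_, p = NA_real_, df = NA_integer_,
                skipped = TRUE, reason = "rank-deficient design"))
  fit <- lm.fit(X, score)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtXinv[2, 2])
  beta <- unname(fit$coefficients["lesion"])
  t <- if (se > 0) beta / se else 0
  p <- switch(alternative,
              deficit = stats::pt(t, df),
              two.sided = 2 * stats::pt(-abs(t), df))
  list(beta = beta, t = t, p = p, df = df, skipped = FALSE, reason = NULL)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up procedure over exactly the tested voxels: p values are sorted
#' ascending, the largest rank `i` with `p_(i) <= i * q / m` is found, and all
#' hypotheses at or below that rank are declared significant. Adjusted
#' q values are the step-up monotonised `p * m / rank`.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return list with `significant` (logical), `q_values` (BH-adjusted), and
#'   `p_cutoff` (largest rejected p value; 0 when nothing is rejected).
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  if (length(p_values) == 0)
    return(list(significant = logical(0), q_values = numeric(0), p_cutoff = 0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  q_values <- unname(stats::p.adjust(p_values, method = "BH"))
  sig <- !is.na(q_values) & q_values <= q
  cutoff <- if (any(sig)) max(p_values[sig]) else 0
  list(significant = sig, q_values = q_values, p_cutoff = cutoff)
}

#' Extract clusters and peaks from a significance mask
#'
#' Labels the mask into 26-connected components and reports, per cluster, the
#' voxel count, volume in mm^3, the peak-|t| voxel and its world (template)
#' coordinates. Clusters are sorted by volume descending; ties, and ties in
#' peak |t| within a cluster, are broken by the smallest linear voxel index,
#' so the table is deterministic.
#'
#' @param sig_mask binary `volume` of significant voxels.
#' @param t_map `volume` of t statistics aligned with `sig_mask`.
#' @return data.frame with columns `cluster`, `n_voxels`, `volume_mm3`,
#'   `peak_t`, `x`, `y`, `z` (empty when the mask is empty).
#' @export
extract_clusters <- function(sig_mask, t_map) {
  stopifnot_same_grid(sig_mask, t_map)
  assert_binary(sig_mask, "significance mask")
  empty <- data.frame(cluster = integer(), n_voxels = integer(),
                      volume_mm3 = numeric(), peak_t = numeric(),
                      x = numeric(), y = numeric(), z = numeric())
  if (sum(sig_mask$data) == 0) return(empty)
  lab <- label_components(sig_mask$data, connectivity = 26)
  nlab <- max(lab)
  vox_vol <- prod(voxel_size(sig_mask))
  dims <- dim(sig_mask$data)
  rows <- lapply(seq_len(nlab), function(l) {
    lin <- which(lab == l)
    tv <- t_map$data[lin]
    peak_lin <- lin[which.max(abs(tv))]  # which.max: first index on ties
    ijk <- arrayInd(peak_lin, dims) - 1L
    w <- voxel_to_world(sig_mask, ijk)
    data.frame(cluster = l, n_voxels = length(lin),
               volume_mm3 = length(lin) * vox_vol,
               peak_t = t_map$data[peak_lin],
               x = w[1], y = w[2], z = w[3], peak_lin = peak_lin)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$n_voxels, tab$peak_lin), , drop = FALSE]
  tab$cluster <- seq_len(nrow(tab))
  tab$peak_lin <- NULL
  rownames(tab) <- NULL
  tab
}

#' Voxel-based lesion-symptom mapping
#'
#' Fits, at every voxel lesioned in at least `min_lesion_count` patients, an
#' ordinary least-squares model of a continuous behavioural score on the
#' voxel's 0/1 lesion status plus the covariates given on the right-hand side
#' of `formula`, then controls the false discovery rate over the tested
#' voxels by Benjamini-Hochberg and extracts significant clusters and peaks.
#'
#' The per-voxel fits share the covariate projection, so the whole map is
#' computed by the Frisch-Waugh-Lovell identity in a handful of matrix
#' operations; results are identical to refitting `lm()` at each voxel.
#'
#' The stored `t` map is signed for the deficit direction (positive = lesion
#' associated with a lower score), the convention used when reporting peak
#' t values; the `beta` map keeps the raw regression sign (negative = lesion
#' lowers the score).
#'
#' @param formula model formula, e.g.
#'   `gesture_production ~ age_years + orientation_score`: the response is
#'   the behavioural score, the right-hand side lists covariates of no
#'   interest. The lesion-status predictor is implicit and added per voxel.
#' @param data data.frame with one row per patient, aligned with `lesions`.
#' @param lesions list of aligned binary lesion `volume`s, one per patient.
#' @param min_lesion_count minimum lesioned patients per tested voxel.
#' @param fdr_q FDR level over the tested voxels.
#' @param alternative `"deficit"` (one-sided) or `"two.sided"`.
#' @param min_patients minimum cohort size to attempt the analysis.
#' @param keep_engine keep the design/lesion matrices in the object (needed
#'   by [vlsm_permutation_fdp()]).
#' @return an object of class `vlsm`; see [summary.vlsm()].
#' @export
vlsm <- function(formula, data, lesions, min_lesion_count = 10L, fdr_q = 0.05,
                 alternative = c("deficit", "two.sided"),
                 min_patients = 10L, keep_engine = TRUE) {
  alternative <- match.arg(alternative)
  n <- nrow(data)
  if (n < min_patients)
    stop("only ", n, " patients; need at least ", min_patients)
  if (length(lesions) != n)
    stop("'lesions' must have one volume per row of 'data'")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank-deficient")

  incl <- voxel_inclusion_mask(lesions, min_lesion_count)
  dims <- dim(incl$mask$data)
  tested_lin <- which(incl$mask$data > 0)
  # a voxel lesioned in every patient has a constant (intercept-collinear)
  # lesion column; drop it from the tested set
  counts <- incl$counts$data[tested_lin]
  tested_lin <- tested_lin[counts < n]
  skipped <- list(all_lesioned = sum(counts >= n))

  aff <- incl$mask$affine
  na_map <- function() array(NA_real_, dims)
  beta_m <- na_map(); t_m <- na_map(); p_m <- na_map(); q_m <- na_map()

  if (length(tested_lin) > 0) {
    Lmat <- vapply(lesions, function(v) v$data[tested_lin],
                   numeric(length(tested_lin)))
    Lmat <- t(Lmat)  # n x V
    eng <- vlsm_engine(y, X, Lmat, alternative)
    ok <- !eng$skip
    skipped$collinear <- sum(eng$skip)
    fitted_lin <- tested_lin[ok]
    fdr <- fdr_threshold(eng$p[ok], fdr_q)
    beta_m[fitted_lin] <- eng$beta[ok]
    t_m[fitted_lin] <- -eng$t[ok]  # deficit-positive sign convention
    p_m[fitted_lin] <- eng$p[ok]
    q_m[fitted_lin] <- fdr$q_values
    sig_lin <- fitted_lin[fdr$significant]
  } else {
    skipped$collinear <- 0L
    sig_lin <- integer(0)
    Lmat <- NULL
  }

  sig <- array(0, dims); sig[sig_lin] <- 1
  sp <- incl$mask$space
  sig_v <- volume(sig, aff, space = sp)
  t_v <- volume(t_m, aff, space = sp)
  clusters <- extract_clusters(sig_v, t_v)

  structure(list(
    call = match.call(),
    task = deparse(formula[[2]]),
    formula = formula,
    n = n,
    min_lesion_count = min_lesion_count,
    fdr_q = fdr_q,
    alternative = alternative,
    beta = volume(beta_m, aff, space = sp),
    t = t_v,
    p = volume(p_m, aff, space = sp),
    q = volume(q_m, aff, space = sp),
    tested_mask = incl$mask,
    count_map = incl$counts,
    significant = sig_v,
    clusters = clusters,
    n_tested = length(tested_lin) - skipped$collinear,
    n_significant = length(sig_lin),
    skipped = skipped,
    engine = if (keep_engine) list(y = y, X = X, Lmat = Lmat,
                                   tested_lin = tested_lin) else NULL),
    class = "vlsm")
}

# mass-univariate OLS of y on [X, l_v] for every lesion column l_v, via
# Frisch-Waugh-Lovell: residualise y and each l_v on X, regress residuals
vlsm_engine <- function(y, X, Lmat, alternative) {
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RL <- qr.resid(qrX, Lmat)
  ss_l <- colSums(RL^2)
  skip <- ss_l < 1e-8
  cross <- colSums(RL * ry)
  beta <- ifelse(skip, NA_real_, cross / ss_l)
  df <- length(y) - ncol(X) - 1L
  rss <- pmax(sum(ry^2) - beta * cross, 0)
  se <- sqrt(rss / df / ss_l)
  t <- ifelse(skip | se == 0, 0, beta / se)
  t[skip] <- NA_real_
  p <- switch(alternative,
              deficit = stats::pt(t, df),
              two.sided = 2 * stats::pt(-abs(t), df))
  list(beta = beta, t = t, p = p, df = df, skip = skip)
}

#' Permutation-null false discovery proportions for a VLSM fit
#'
#' Re-runs the mass-univariate analysis of a fitted [vlsm()] object
#' `n_perm` times with the behavioural scores randomly permuted across
#' patients, applying the same inclusion mask and FDR threshold, and returns
#' the realised false discovery proportion of each replicate. Voxels inside
#' `true_region` (if given, e.g. a dilated ground-truth critical region) are
#' not counted as false; under a full permutation null every discovery is
#' false.
#'
#' @param fit a [vlsm()] object fitted with `keep_engine = TRUE`.
#' @param n_perm number of permutation replicates.
#' @param seed RNG seed for the permutations.
#' @param true_region optional binary `volume` of truly affected voxels.
#' @return numeric vector of length `n_perm` with one FDP per replicate.
#' @export
vlsm_permutation_fdp <- function(fit, n_perm = 200L, seed = 1L,
                                 true_region = NULL) {
  stopifnot(inherits(fit, "vlsm"))
  if (is.null(fit$engine)) stop("fit was created with keep_engine = FALSE")
  eng <- fit$engine
  true_lin <- if (is.null(true_region)) integer(0) else which(true_region$data > 0)
  set.seed(seed)
  vapply(seq_len(n_perm), function(r) {
    yp <- eng$y[sample.int(length(eng$y))]
    res <- vlsm_engine(yp, eng$X, eng$Lmat, fit$alternative)
    ok <- !res$skip
    fdr <- fdr_threshold(res$p[ok], fit$fdr_q)
    sig_lin <- eng$tested_lin[ok][fdr$significant]
    if (length(sig_lin) == 0) return(0)
    sum(!(sig_lin %in% true_lin)) / length(sig_lin)
  }, numeric(1))
}

#' @export
print.vlsm <- function(x, ...) {
  cat(sprintf("Voxel-based lesion-symptom mapping: %s\n", x$task))
  cat(sprintf("  %d patients; %d voxels tested (>= %d lesions); FDR q = %g (%s)\n",
              x$n, x$n_tested, x$min_lesion_count, x$fdr_q, x$alternative))
  cat(sprintf("  %d significant voxels in %d cluster(s)\n",
              x$n_significant, nrow(x$clusters)))
  invisible(x)
}

#' Summary of a VLSM fit
#'
#' @param object a [vlsm()] object.
#' @param ... unused.
#' @return the object invisibly, after printing the cluster/peak table.
#' @export
summary.vlsm <- function(object, ...) {
  print(object)
  if (nrow(object$clusters) > 0) {
    cat("\nClusters (volume mm^3, peak t, peak world coordinates):\n")
    print(format(object$clusters, digits = 4), row.names = FALSE)
  } else {
    cat("\nNo FDR-significant clusters.\n")
  }
  invisible(object)
}

#' Extract a coefficient/statistic map from a VLSM fit
#'
#' @param object a [vlsm()] object.
#' @param map which per-voxel map to return.
#' @param ... unused.
#' @return a `volume` (`NA` outside the tested voxels).
#' @export
coef.vlsm <- function(object, map = c("beta", "t", "p", "q"), ...) {
  map <- match.arg(map)
  object[[map]]
}

#' Plot axial slices of a VLSM t map
#'
#' Grey underlay of the lesion-count map with the deficit-direction t map
#' overlaid on tested voxels and significant clusters outlined.
#'
#' @param x a [vlsm()] object.
#' @param slices voxel k-indices (1-based) of the axial slices to draw;
#'   default picks four slices spanning the tested region.
#' @param ... unused.
#' @export
plot.vlsm <- function(x, slices = NULL, ...) {
  dims <- dim(x$count_map$data)
  if (is.null(slices)) {
    ks <- which(apply(x$tested_mask$data, 3, sum) > 0)
    if (length(ks) == 0) ks <- round(dims[3] / 2)
    slices <- unique(round(stats::quantile(ks, c(0.2, 0.4, 0.6, 0.8))))
  }
  op <- graphics::par(mfrow = c(1, length(slices)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (k in slices) {
    graphics::image(x$count_map$data[, , k], col = grDevices::grey.colors(64),
                    axes = FALSE, asp = 1,
                    main = sprintf("%s  z-slice %d", x$task, k))
    tk <- x$t$data[, , k]
    if (any(is.finite(tk)))
      graphics::image(ifelse(is.finite(tk), tk, NA),
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      add = TRUE)
    sk <- x$significant$data[, , k]
    if (sum(sk) > 0)
      graphics::contour(sk, levels = 0.5, add = TRUE, drawlabels = FALSE)
  }
  invisible(x)
}
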