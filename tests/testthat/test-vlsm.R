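make_lesion_set <- function(n, dims = c(10, 10, 10), seed = 20) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- array(0, dims)
    c0 <- sample(3:7, 3, replace = TRUE)
    m[(c0[1] - 2):(c0[1] + 2), (c0[2] - 2):(c0[2] + 2), (c0[3] - 2):(c0[3] + 2)] <- 1
    volume(m)
  })
}

test_that("inclusion mask implements the minimum lesion count", {
  lesions <- make_lesion_set(12)
  incl1 <- voxel_inclusion_mask(lesions, 1)
  union <- Reduce(`+`, lapply(lesions, function(v) v$data)) > 0
  expect_identical(incl1$mask$data > 0, union)
  expect_equal(sum(voxel_inclusion_mask(lesions, 13)$mask$data), 0)
  counts <- incl1$counts$data
  expect_true(all(voxel_inclusion_mask(lesions, 10)$mask$data ==
                  as.double(counts >= 10)))
  expect_error(voxel_inclusion_mask(list()), "empty")
})

test_that("per-voxel model agrees exactly with lm and the two-sample t", {
  set.seed(21)
  n <- 40
  lesion <- rbinom(n, 1, 0.4)
  covs <- cbind(age = rnorm(n, 70, 10), vol = rnorm(n, 50, 8))
  y <- 10 - 3 * lesion - 0.05 * covs[, "age"] + rnorm(n)
  fit <- fit_voxel_model(y, lesion, covs)
  lmfit <- summary(lm(y ~ lesion + covs))$coefficients
  expect_equal(fit$beta, lmfit["lesion", 1], tolerance = 1e-12)
  expect_equal(fit$t, lmfit["lesion", 3], tolerance = 1e-12)
  expect_equal(fit$p, pt(lmfit["lesion", 3], n - 4), tolerance = 1e-12)
  # no covariates: identical to a pooled two-sample t test
  fit0 <- fit_voxel_model(y, lesion, alternative = "two.sided")
  tt <- t.test(y[lesion == 0], y[lesion == 1], var.equal = TRUE)
  expect_equal(abs(fit0$t), abs(unname(tt$statistic)), tolerance = 1e-12)
  expect_equal(fit0$p, tt$p.value, tolerance = 1e-12)
})

test_that("identical groups give a zero lesion effect", {
  y <- rep(c(2, 10), 10)
  lesion <- rep(c(0, 1, 1, 0), 5)
  g0 <- y[lesion == 0]; g1 <- y[lesion == 1]
  fit <- fit_voxel_model(c(g0, g0), rep(c(0, 1), each = 10))
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$t, 0, tolerance = 1e-12)
})

test_that("a covariate orthogonal to lesion status leaves the effect unchanged", {
  set.seed(22)
  n <- 60
  lesion <- rep(c(0, 1), each = n / 2)
  cov_orth <- rnorm(n)
  cov_orth <- residuals(lm(cov_orth ~ lesion))   # exactly orthogonal
  y <- 8 - 2.5 * lesion + rnorm(n)
  f_no <- fit_voxel_model(y, lesion)
  f_with <- fit_voxel_model(y, lesion, cbind(orth = cov_orth))
  expect_equal(f_with$beta, f_no$beta, tolerance = 1e-10)
})

test_that("degenerate designs are skipped with a sentinel, not an error", {
  y <- rnorm(20)
  expect_true(fit_voxel_model(y, rep(1, 20))$skipped)
  covs <- cbind(a = 1:20, b = 2 * (1:20))
  expect_true(fit_voxel_model(y, rep(c(0, 1), 10), covs)$skipped)
})

test_that("BH thresholding matches the brute-force step-up reference", {
  expect_true(all(fdr_threshold(c(0.01, 0.02, 0.03, 0.04), 0.05)$significant))
  expect_false(any(fdr_threshold(rep(1, 10), 0.05)$significant))
  expect_true(fdr_threshold(0.04, 0.05)$significant)
  set.seed(23)
  for (r in 1:50) {
    m <- sample(1:8, 1)
    p <- sample(seq(0, 1, 0.01), m, replace = TRUE)
    got <- fdr_threshold(p, 0.05)
    ref <- bh_brute_force(p, 0.05)
    expect_identical(got$significant, ref$significant)
    expect_equal(got$q_values, ref$q_values, tolerance = 1e-12)
    expect_true(all(got$q_values >= p - 1e-15))
  }
  expect_length(fdr_threshold(numeric(0), 0.05)$significant, 0)
  expect_error(fdr_threshold(c(0.5, 1.2), 0.05), "0, 1")
})

test_that("cluster extraction reports volumes and world peaks correctly", {
  aff <- diag(4); aff[1:3, 4] <- c(-32, -32, -32)
  sig <- volume(array(0, c(40, 40, 40)), aff)
  tmap <- volume(array(0, c(40, 40, 40)), aff)
  # single-voxel cluster at 0-based index (10,10,10)
  sig$data[11, 11, 11] <- 1
  tmap$data[11, 11, 11] <- 4.2
  tab <- extract_clusters(sig, tmap)
  expect_equal(nrow(tab), 1L)
  expect_equal(unlist(tab[1, c("x", "y", "z")], use.names = FALSE),
               c(-22, -22, -22))
  expect_equal(tab$peak_t, 4.2)
  # second, larger blob: two rows, sorted by volume, counts match
  sig$data[30:32, 30:32, 30:32] <- 1
  tmap$data[30:32, 30:32, 30:32] <- 3
  tmap$data[31, 31, 31] <- 5.5
  tab2 <- extract_clusters(sig, tmap)
  expect_equal(tab2$n_voxels, c(27L, 1L))
  expect_equal(tab2$volume_mm3, c(27, 1))
  expect_equal(tab2$peak_t[1], 5.5)
  empty <- extract_clusters(volume(array(0, c(4, 4, 4))),
                            volume(array(0, c(4, 4, 4))))
  expect_equal(nrow(empty), 0L)
})

test_that("vlsm composes the stages and its maps satisfy the invariants", {
  lesions <- make_lesion_set(30, seed = 24)
  set.seed(25)
  # (4,4,4) is lesioned in roughly half the patients, so the lesion column
  # varies and the simulated deficit is recoverable
  overlap_vox <- vapply(lesions, function(v) v$data[4, 4, 4], numeric(1))
  df <- data.frame(score = 10 - 4 * overlap_vox + rnorm(30, sd = 0.8),
                   age = rnorm(30, 70, 10))
  fit <- vlsm(score ~ age, df, lesions, min_lesion_count = 5, fdr_q = 0.05)
  expect_s3_class(fit, "vlsm")
  tested <- !is.na(fit$p$data)
  expect_true(all(fit$count_map$data[tested] >= 5))
  expect_true(all(fit$q$data[tested] >= fit$p$data[tested] - 1e-15))
  # engine agrees with the scalar per-voxel fit
  idx <- which(tested)[c(1, 7, 19)]
  for (i in idx) {
    status <- vapply(lesions, function(v) v$data[i], numeric(1))
    ref <- fit_voxel_model(df$score, status, cbind(age = df$age))
    expect_equal(fit$beta$data[i], ref$beta, tolerance = 1e-10)
    expect_equal(-fit$t$data[i], ref$t, tolerance = 1e-10)
    expect_equal(fit$p$data[i], ref$p, tolerance = 1e-10)
  }
  # significant voxels found around the driving voxel; deficit t positive
  expect_gt(fit$n_significant, 0)
  expect_true(all(fit$t$data[fit$significant$data > 0] > 0))
})

test_that("vlsm with an unreachable lesion count returns an empty result", {
  lesions <- make_lesion_set(12)
  df <- data.frame(score = rnorm(12), age = rnorm(12, 70, 5))
  fit <- vlsm(score ~ age, df, lesions, min_lesion_count = 13)
  expect_equal(fit$n_tested, 0L)
  expect_equal(nrow(fit$clusters), 0L)
  expect_equal(fit$n_significant, 0L)
})

test_that("vlsm results are byte-identical across reruns", {
  lesions <- make_lesion_set(25, seed = 26)
  set.seed(27)
  df <- data.frame(score = rnorm(25, 8), age = rnorm(25, 70, 9))
  f1 <- vlsm(score ~ age, df, lesions, min_lesion_count = 5)
  f2 <- vlsm(score ~ age, df, lesions, min_lesion_count = 5)
  expect_identical(f1$clusters, f2$clusters)
  expect_identical(f1$t$data, f2$t$data)
})

test_that("vlsm guards its preconditions", {
  lesions <- make_lesion_set(5)
  df <- data.frame(score = rnorm(5), age = rnorm(5))
  expect_error(vlsm(score ~ age, df, lesions, min_patients = 10), "at least")
  expect_error(vlsm(score ~ age, df[1:4, ], lesions, min_patients = 3),
               "one volume per row")
})
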