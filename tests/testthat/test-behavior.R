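test_that("item scoring follows the task rules", {
  expect_equal(score_item("gesture_production", "correct"), 2L)
  expect_equal(score_item("gesture_production", "recognizable_inaccurate"), 1L)
  expect_equal(score_item("gesture_production", "none"), 0L)
  expect_equal(score_item("gesture_recognition", "correct"), 1L)
  expect_equal(score_item("gesture_recognition", "incorrect"), 0L)
  expect_equal(score_item("gesture_imitation", "correct_1st"), 3L)
  expect_equal(score_item("gesture_imitation", "correct_2nd"), 2L)
  expect_equal(score_item("gesture_imitation", "one_error_2nd"), 1L)
  expect_equal(score_item("gesture_imitation", "fail"), 0L)
  expect_error(score_item("gesture_production", "brilliant"), "unknown outcome")
})

test_that("item maxima times item counts give the task ranges", {
  expect_equal(6 * score_item("gesture_production", "correct"), 12)
  expect_equal(6 * score_item("gesture_recognition", "correct"), 6)
  expect_equal(4 * score_item("gesture_imitation", "correct_1st"), 12)
  expect_identical(task_maxima()[c("gesture_production", "gesture_recognition",
                                   "gesture_imitation")],
                   c(gesture_production = 12L, gesture_recognition = 6L,
                     gesture_imitation = 12L))
})

test_that("impairment classification applies the age-banded cut-offs", {
  cuts <- bcos_cutoffs("integer")
  # recognition score 4 against the 65-74 band cut-off of 5: impaired
  r <- list(age_years = 70, gesture_production = 12, gesture_recognition = 4,
            gesture_imitation = 12)
  f <- classify_impairment(r, cuts)
  expect_true(f$gesture_recognition)
  expect_true(f$apraxic)
  # perfect scores are never apraxic
  perfect <- list(age_years = 80, gesture_production = 12,
                  gesture_recognition = 6, gesture_imitation = 12)
  expect_false(classify_impairment(perfect, cuts)$apraxic)
  # tie rule: score equal to the cut-off counts as impaired (>= 75 band cut 4)
  tie <- list(age_years = 80, gesture_production = 12, gesture_recognition = 4,
              gesture_imitation = 12)
  expect_true(classify_impairment(tie, cuts)$gesture_recognition)
})

test_that("a hand-scored 12-patient fixture classifies exactly", {
  fx <- data.frame(
    age_years          = c(50, 50, 50, 50, 70, 70, 70, 80, 80, 80, 64, 75),
    gesture_production = c(12, 10, 11, 11,  9, 10, 12, 12, 12,  9, 10, 12),
    gesture_recognition = c(6,  6,  5,  6,  6,  6,  5,  4,  5,  6,  5,  6),
    gesture_imitation  = c(12, 12, 12,  9, 10, 10, 12, 12, 12,  9,  9, 12))
  expected_apraxic <- c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                        FALSE, TRUE, TRUE, FALSE)
  expected_gp <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, TRUE, TRUE, FALSE)
  cuts <- bcos_cutoffs("integer")
  for (i in seq_len(12)) {
    f <- classify_impairment(fx[i, ], cuts)
    expect_identical(f$apraxic, expected_apraxic[i])
    expect_identical(f$gesture_production, expected_gp[i])
  }
})

test_that("impairment flags are monotone in the scores", {
  cuts <- bcos_cutoffs("integer")
  set.seed(30)
  for (r in 1:30) {
    rec <- list(age_years = runif(1, 30, 90),
                gesture_production = sample(0:12, 1),
                gesture_recognition = sample(0:6, 1),
                gesture_imitation = sample(0:12, 1))
    f1 <- classify_impairment(rec, cuts)
    worse <- rec
    worse$gesture_production <- max(0, rec$gesture_production - sample(1:3, 1))
    f2 <- classify_impairment(worse, cuts)
    expect_true(!f1$gesture_production || f2$gesture_production)
    expect_true(!f1$apraxic || f2$apraxic)
  }
})

test_that("the composite score spans [0, 3] and increases in each task", {
  expect_equal(composite_apraxia_score(list(gesture_production = 12,
                                            gesture_recognition = 6,
                                            gesture_imitation = 12)), 3)
  expect_equal(composite_apraxia_score(list(gesture_production = 0,
                                            gesture_recognition = 0,
                                            gesture_imitation = 0)), 0)
  expect_equal(composite_apraxia_score(list(gesture_production = 6,
                                            gesture_recognition = 3,
                                            gesture_imitation = 6)), 1.5)
  base <- list(gesture_production = 5, gesture_recognition = 2,
               gesture_imitation = 7)
  s0 <- composite_apraxia_score(base)
  for (t in names(base)) {
    up <- base; up[[t]] <- up[[t]] + 1
    expect_gt(composite_apraxia_score(up), s0)
  }
  expect_error(composite_apraxia_score(list(gesture_production = 5,
                                            gesture_recognition = NA,
                                            gesture_imitation = 7)), "missing")
})

test_that("correlation matches the textbook Pearson formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  res <- correlate(x, y)
  # direct evaluation: r = sum(dx dy) / sqrt(sum dx^2 sum dy^2) = 11/sqrt(130)
  expect_equal(res$r, 11 / sqrt(130), tolerance = 1e-12)
  dx <- x - mean(x); dy <- y - mean(y)
  expect_equal(res$r, sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2)),
               tolerance = 1e-12)
  tstat <- res$r * sqrt(2 / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 2), tolerance = 1e-12)
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(x, rep(1, 4)), "zero variance")
  expect_error(correlate(1:2, 1:3), "length")
})

test_that("the shipped cut-off CSVs agree with the in-code tables", {
  for (v in c("integer", "fractional")) {
    path <- system.file("extdata", paste0("bcos_cutoffs_", v, ".csv"),
                        package = "praxismap")
    expect_true(nzchar(path))
    csv <- utils::read.csv(path, stringsAsFactors = FALSE)
    tab <- bcos_cutoffs(v)
    attr(tab, "rule") <- NULL
    expect_equal(csv, as.data.frame(tab))
  }
})

test_that("cohort summary reports moments and impairment counts", {
  fx <- data.frame(
    age_years = c(50, 70, 80),
    gesture_production = c(12, 9, 9),
    gesture_recognition = c(6, 6, 6),
    gesture_imitation = c(12, 12, 9))
  s <- cohort_summary(fx)
  gp <- s$scores[s$scores$task == "gesture_production", ]
  expect_equal(gp$mean, 10)
  expect_equal(gp$min, 9); expect_equal(gp$max, 12)
  expect_equal(gp$n_impaired, 2L)   # ages 70 and 80 at cut-off 9
  expect_equal(s$n_apraxic, 2L)
  expect_message(s1 <- cohort_summary(fx[1, ]), "SD is undefined")
  expect_true(is.na(s1$scores$sd[1]))
  same <- fx[c(1, 1, 1), ]
  expect_equal(cohort_summary(same)$scores$sd, c(0, 0, 0))
  expect_error(cohort_summary(fx[0, ]), "empty")
})
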