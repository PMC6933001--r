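# Shared fixtures. Volumes are generated in code at test time; the heavier
# cohort used by the recovery/null tests is built once per session and cached.

# small, fast phantom for unit tests
tiny_cfg <- function(...) {
  defaults <- list(grid_shape = c(24L, 24L, 24L), brain_radii_mm = c(9, 10, 9),
                   ventricle_radii_mm = c(2, 3, 2), ventricle_offset_mm = 4,
                   lesion_radius_range_mm = c(3, 5), n_controls = 5L,
                   n_patients = 2L,
                   critical_region = list(center = c(-4, -2, 1),
                                          radii = c(3, 3, 3)))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# study-condition cohort shared by the VLSM acceptance checks
acceptance_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11L)
      co <- generate_cohort(cfg)
      del <- delineate_lesions(co$patients, co$controls, fwhm_mm = 4,
                               direction = "hypo")
      beh <- co$behavior
      beh$handedness_num <- as.numeric(beh$handedness == "L")
      cache <<- list(cfg = cfg, cohort = co, lesions = del$lesions, behavior = beh)
    }
    cache
  }
})

vlsm_covariates <- c("age_years", "handedness_num", "lesion_volume_mm3",
                     "orientation_score")

# brute-force Benjamini-Hochberg step-up, the independent reference
bh_brute_force <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= seq_len(m) * q / m)))
  sig <- rep(FALSE, m)
  if (k > 0) sig[o[seq_len(k)]] <- TRUE
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  qv <- numeric(m)
  qv[o] <- pmin(adj, 1)
  list(significant = sig, q_values = qv)
}

# a registration template with internal asymmetries (real heads are not
# rotationally symmetric); margin leaves room for +-10 mm translations
registration_template <- function(seed = 3) {
  cfg <- sim_config(grid_shape = c(64L, 64L, 64L), brain_radii_mm = c(18, 20, 18),
                    ventricle_radii_mm = c(3, 6, 3), ventricle_offset_mm = 6,
                    parenchyma_sd = 0.5, csf_sd = 0.5, n_controls = 2L,
                    n_patients = 0L)
  set.seed(seed)
  tmpl <- generate_control_volume(cfg)
  co <- praxismap:::sim_coords(cfg)
  blob <- function(center, radii, amp)
    amp * praxismap:::ellipsoid_mask(co, center, radii, cfg$grid_shape)
  tmpl$data <- tmpl$data +
    blob(c(7, 9, -5), c(5, 4, 5), 12) + blob(c(-5, -10, 6), c(5, 4, 4), -8) +
    blob(c(-9, 6, -7), c(4, 5, 3), 9) + blob(c(4, -6, 10), c(3, 4, 4), -10)
  tmpl
}

expect_same_mask <- function(a, b) {
  expect_identical(as.integer(a$data), as.integer(b$data))
}
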