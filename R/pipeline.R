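#' Delineate lesions for a set of patients against a control set
#'
#' In-memory composition of the delineation chain: smooth controls and
#' patients with the same Gaussian kernel, build the per-voxel normal range,
#' compute each patient's Crawford-Howell t-score map, and threshold it into
#' a binary lesion map.
#'
#' @param patients list of patient `volume`s on the control grid.
#' @param controls list of control `volume`s (or a prebuilt [control_set()]
#'   of already-smoothed controls).
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 disables smoothing.
#' @param direction lesion contrast direction passed to [binarize_lesion()]:
#'   `"hypo"` for ischemic, `"hyper"` for hemorrhagic, `"both"` if unknown.
#' @param alpha one-tailed threshold on the t-score map.
#' @param brain_mask optional binary `volume`.
#' @param min_lesion_cluster minimum lesion cluster size (voxels).
#' @param refine cluster boundary refinement (see [binarize_lesion()]);
#'   defaults to `"half_peak"`, which undoes the smoothing halo around
#'   high-contrast lesions.
#' @return list with `lesions` (list of binary `volume`s), `tmaps` (list of
#'   [tscore_map()]s) and `controls` (the smoothed [control_set()]).
#' @export
delineate_lesions <- function(patients, controls, fwhm_mm = 4,
                              direction = c("hypo", "hyper", "both"),
                              alpha = 0.001, brain_mask = NULL,
                              min_lesion_cluster = 100L,
                              refine = c("half_peak", "none")) {
  direction <- match.arg(direction)
  refine <- match.arg(refine)
  cset <- if (inherits(controls, "control_set")) controls else
    control_set(lapply(controls, smooth_gaussian, fwhm_mm = fwhm_mm))
  tmaps <- lapply(patients, function(p)
    tscore_map(smooth_gaussian(p, fwhm_mm), cset))
  lesions <- lapply(tmaps, binarize_lesion, direction = direction,
                    alpha = alpha, brain_mask = brain_mask,
                    min_lesion_cluster = min_lesion_cluster, refine = refine)
  list(lesions = lesions, tmaps = tmaps, controls = cset)
}

write_provenance <- function(dir, cfg_list, extra = list()) {
  prov <- c(list(package = "praxismap",
                 version = as.character(utils::packageVersion("praxismap")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            cfg_list, extra)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a cohort to disk
#'
#' Writes NIfTI control and patient volumes, ground-truth lesion masks and
#' the critical-region mask, the behavioural CSV, and a provenance JSON
#' echoing the configuration, package version and seed.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
pipeline_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("controls", "patients", "truth"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  co <- generate_cohort(cfg)
  for (i in seq_along(co$controls))
    write_volume(co$controls[[i]],
                 file.path(out_dir, "controls", sprintf("control_%03d.nii.gz", i)))
  for (i in seq_along(co$patients)) {
    write_volume(co$patients[[i]],
                 file.path(out_dir, "patients", sprintf("patient_%03d.nii.gz", i)))
    write_volume(co$truth$lesions[[i]],
                 file.path(out_dir, "truth", sprintf("lesion_%03d.nii.gz", i)))
  }
  write_volume(co$truth$critical_region,
               file.path(out_dir, "truth", "critical_region.nii.gz"))
  utils::write.csv(co$behavior, file.path(out_dir, "behavior.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, unclass(cfg)[setdiff(names(cfg), "critical_region")],
                   list(critical_region = cfg$critical_region))
  invisible(out_dir)
}

#' Delineate lesions for a simulated (or user-supplied) cohort on disk
#'
#' Reads the control and patient volumes written by [pipeline_simulate()]
#' (or any directory with the same layout), runs [delineate_lesions()],
#' writes one binary lesion NIfTI per patient plus the lesion-overlap count
#' map, and rewrites the behavioural CSV with the delineated
#' `lesion_volume_mm3`. When ground-truth masks are present a per-patient
#' Dice report is also written.
#'
#' @param dir cohort directory.
#' @param fwhm_mm,direction,alpha,min_lesion_cluster see
#'   [delineate_lesions()].
#' @return invisibly, a data.frame with per-patient lesion volumes (and Dice
#'   against ground truth when available).
#' @export
pipeline_delineate <- function(dir, fwhm_mm = 4,
                               direction = c("hypo", "hyper", "both"),
                               alpha = 0.001, min_lesion_cluster = 100L) {
  direction <- match.arg(direction)
  ctrl_files <- sort(list.files(file.path(dir, "controls"), "\\.nii", full.names = TRUE))
  pat_files <- sort(list.files(file.path(dir, "patients"), "\\.nii", full.names = TRUE))
  if (length(ctrl_files) == 0) stop("no control volumes found in ", dir)
  if (length(pat_files) == 0) stop("no patient volumes found in ", dir)
  controls <- lapply(ctrl_files, read_volume, space = "template")
  patients <- lapply(pat_files, read_volume, space = "template")
  res <- delineate_lesions(patients, controls, fwhm_mm = fwhm_mm,
                           direction = direction, alpha = alpha,
                           min_lesion_cluster = min_lesion_cluster)
  dir.create(file.path(dir, "lesions"), showWarnings = FALSE)
  vols <- numeric(length(patients)); dice <- rep(NA_real_, length(patients))
  for (i in seq_along(res$lesions)) {
    write_volume(res$lesions[[i]],
                 file.path(dir, "lesions", sprintf("lesion_%03d.nii.gz", i)))
    vols[i] <- lesion_volume(res$lesions[[i]])
    truth_file <- file.path(dir, "truth", sprintf("lesion_%03d.nii.gz", i))
    if (file.exists(truth_file))
      dice[i] <- dice_coefficient(res$lesions[[i]],
                                  read_volume(truth_file, space = "template"))
  }
  overlap <- voxel_inclusion_mask(res$lesions, min_count = 1L)
  write_volume(overlap$counts, file.path(dir, "lesion_overlap_count.nii.gz"))
  report <- data.frame(patient = seq_along(patients),
                       lesion_volume_mm3 = vols, dice_vs_truth = dice)
  utils::write.csv(report, file.path(dir, "delineation_report.csv"),
                   row.names = FALSE)
  beh_file <- file.path(dir, "behavior.csv")
  if (file.exists(beh_file)) {
    beh <- utils::read.csv(beh_file, stringsAsFactors = FALSE)
    if (nrow(beh) == length(vols)) {
      beh$lesion_volume_mm3 <- vols
      utils::write.csv(beh, beh_file, row.names = FALSE)
    }
  }
  invisible(report)
}

#' Run VLSM for each task on a cohort directory
#'
#' Reads the delineated lesion maps and the behavioural CSV, fits [vlsm()]
#' per task, and writes the beta/t/p/q maps as NIfTI, a cluster CSV per task
#' (columns `area` left blank for user-supplied atlas labels, `volume_mm3`,
#' `t`, `x`, `y`, `z`), and a JSON run log with the numbers of tested and
#' significant voxels.
#'
#' @param dir cohort directory containing `lesions/` and `behavior.csv`.
#' @param tasks character vector of score columns to analyse.
#' @param covariates character vector of covariate columns.
#' @param min_lesion_count,fdr_q,alternative,min_patients passed to [vlsm()].
#' @return invisibly, a named list of [vlsm()] fits.
#' @export
pipeline_vlsm <- function(dir,
                          tasks = c("gesture_production", "gesture_recognition",
                                    "gesture_imitation"),
                          covariates = c("age_years", "handedness_num",
                                         "lesion_volume_mm3", "orientation_score"),
                          min_lesion_count = 10L, fdr_q = 0.05,
                          alternative = "deficit", min_patients = 10L) {
  beh_file <- file.path(dir, "behavior.csv")
  if (!file.exists(beh_file)) stop("no behavior.csv in ", dir)
  beh <- utils::read.csv(beh_file, stringsAsFactors = FALSE)
  missing_tasks <- setdiff(tasks, names(beh))
  if (length(missing_tasks) > 0)
    stop("task(s) not in the behavioural table: ",
         paste(missing_tasks, collapse = ", "),
         "; available columns: ", paste(names(beh), collapse = ", "))
  beh$handedness_num <- as.numeric(beh$handedness == "L")  # right = 0, left = 1
  les_files <- sort(list.files(file.path(dir, "lesions"), "\\.nii", full.names = TRUE))
  if (length(les_files) == 0) stop("no lesion maps found; run pipeline_delineate first")
  lesions <- lapply(les_files, read_volume, space = "template")

  fits <- list()
  log <- list()
  for (task in tasks) {
    f <- stats::reformulate(covariates, response = task)
    fit <- vlsm(f, beh, lesions, min_lesion_count = min_lesion_count,
                fdr_q = fdr_q, alternative = alternative,
                min_patients = min_patients, keep_engine = FALSE)
    fits[[task]] <- fit
    tdir <- file.path(dir, "vlsm", task)
    dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
    for (m in c("beta", "t", "p", "q")) {
      v <- fit[[m]]
      v$data[is.na(v$data)] <- 0
      write_volume(v, file.path(tdir, paste0(m, "_map.nii.gz")))
    }
    cl <- fit$clusters
    out_tab <- data.frame(area = rep("", nrow(cl)),
                          volume_mm3 = cl$volume_mm3, t = cl$peak_t,
                          x = cl$x, y = cl$y, z = cl$z)
    utils::write.csv(out_tab, file.path(tdir, "clusters.csv"), row.names = FALSE)
    log[[task]] <- list(n_tested = fit$n_tested,
                        n_significant = fit$n_significant,
                        n_clusters = nrow(cl))
  }
  jsonlite::write_json(log, file.path(dir, "vlsm", "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fits)
}
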