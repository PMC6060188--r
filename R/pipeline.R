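#' Build a multi-lesion cohort phantom with a synthetic cohort table
#'
#' Places `n_hgg + n_lgg` spherical lesions on interior rings of a brain
#' ellipsoid, all in one hemisphere so that each lesion's contralateral
#' mirror lands in normal brain; a venous (blood-pool) sphere sits at the
#' ring center. Per-lesion plateau SUVs are drawn from grade-specific
#' normal distributions and a synthetic Ki-67 index is generated as an
#' increasing noisy function of the lesion's true tumor-to-background
#' ratio. The returned cohort table is synthetic (phantom-derived), not
#' patient data.
#'
#' @param n_hgg,n_lgg Lesion counts per grade class.
#' @param grid_shape,voxel_size_mm Phantom grid (defaults 64 x 64 x 48 at
#'   2.4 mm).
#' @param lesion_radius_mm Lesion sphere radius.
#' @param psf_fwhm_mm,noise_sigma Degradation parameters (defaults:
#'   4.6 mm final resolution, 0.1 SUV noise).
#' @param hgg_plateau,hgg_sd,lgg_plateau,lgg_sd Grade-specific plateau
#'   SUV distributions.
#' @param brain_kin,venous_kin Kinetics of normal brain and venous blood
#'   pool (defaults: plateaus 1.3 and 1.25 SUV — the two tissues are
#'   deliberately close, as venous and parenchymal uptake do not differ
#'   appreciably for this tracer).
#' @param schedule Frame schedule.
#' @param seed Integer seed (drives lesion draws, Ki-67 noise, and the
#'   phantom noise).
#' @return List with `spec` (a [phantom_spec()]) and `cohort` (synthetic
#'   lesion table with `lesion_id`, `grade_class`, `who_grade`,
#'   `ki67_value`).
#' @export
build_cohort_phantom <- function(n_hgg = 12, n_lgg = 6,
                                 grid_shape = c(64, 64, 48),
                                 voxel_size_mm = 2.4, lesion_radius_mm = 6,
                                 psf_fwhm_mm = 4.6, noise_sigma = 0.1,
                                 hgg_plateau = 4.5, hgg_sd = 0.7,
                                 lgg_plateau = 2.7, lgg_sd = 0.25,
                                 brain_kin = tissue_kinetics(1.3, 0.25),
                                 venous_kin = tissue_kinetics(1.25, 0.6),
                                 schedule = fluciclovine_schedule(),
                                 seed = 1L) {
  n <- n_hgg + n_lgg
  if (n < 1) stop_("phantom needs at least one lesion (n_hgg + n_lgg >= 1)")
  fov <- grid_shape * voxel_size_mm
  center <- fov / 2
  semi <- c(0.42 * fov[1], 0.42 * fov[2], 0.40 * fov[3])
  ring <- 0.6 * min(semi[1:2])
  z_off <- c(0, -0.3, 0.3) * semi[3]
  angles <- seq(-65, 65, length.out = 7) * pi / 180
  slots <- expand.grid(a = angles, z = z_off, KEEP.OUT.ATTRS = FALSE)
  if (n > nrow(slots))
    stop_("too many lesions for the placement grid (max ", nrow(slots), ")")
  worst <- ((ring + lesion_radius_mm) / min(semi[1:2]))^2 +
    ((max(abs(z_off)) + lesion_radius_mm) / semi[3])^2
  if (worst > 0.95)
    stop_("lesions of this radius do not fit inside the brain ellipsoid")

  with_seed_(seed, {
    grade <- sample(c(rep("HGG", n_hgg), rep("LGG", n_lgg)))
    plateau <- pmax(0.5, stats::rnorm(n,
      mean = ifelse(grade == "HGG", hgg_plateau, lgg_plateau),
      sd = ifelse(grade == "HGG", hgg_sd, lgg_sd)))
    tb_true <- plateau / brain_kin$plateau_suv
    ki67 <- round(pmax(0.5, -15 + 12 * tb_true + stats::rnorm(n, sd = 4)), 1)
    lesions <- lapply(seq_len(n), function(i) {
      list(id = 10L + i,
           center = c(center[1] + ring * cos(slots$a[i]),
                      center[2] + ring * sin(slots$a[i]),
                      center[3] + slots$z[i]),
           radius_mm = lesion_radius_mm,
           kinetics = tissue_kinetics(plateau[i], 0.18,
                                      infusion_min = brain_kin$infusion_min),
           grade = grade[i])
    })
    spec <- phantom_spec(
      grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
      brain = list(center = center, semi_axes = semi),
      lesions = lesions, normal_kinetics = brain_kin,
      venous = list(center = center, radius_mm = 6, kinetics = venous_kin),
      psf_fwhm_mm = psf_fwhm_mm, noise_sigma = noise_sigma,
      schedule = schedule, seed = seed)
    cohort <- data.frame(
      lesion_id = as.character(10L + seq_len(n)),
      grade_class = grade,
      who_grade = ifelse(grade == "HGG", "IV", "II"),
      ki67_value = ki67, stringsAsFactors = FALSE)
    list(spec = spec, cohort = cohort)
  })
}

#' Default demonstration configuration
#'
#' A small, fast phantom cohort (4 HGG + 3 LGG lesions on a 48 x 48 x 36
#' grid of 3-mm voxels) exercising every pipeline stage.
#'
#' @param seed Integer seed.
#' @return A configuration list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(phantom = list(n_hgg = 4, n_lgg = 3, grid_shape = c(48, 48, 36),
                      voxel_size_mm = 3, lesion_radius_mm = 6),
       thresholds = c(1.3, 1.6, 1.9), window_min = 30, alpha = 0.05,
       search_margin_mm = 4, bg_diameter_mm = 15, seed = as.integer(seed))
}

log_stage_ <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

fail_stage_ <- function(stage, e) {
  stop_("pipeline stage '", stage, "' failed: ", conditionMessage(e))
}

#' Grade-discrimination and correlation analysis of a metrics table
#'
#' The pure analysis stage of the pipeline: from a per-lesion-per-frame
#' metrics table and a graded cohort it computes group TAC observations
#' and the equilibrium ANOVA/Tukey report, ROC cutoffs for SUVmax and
#' each TBmean threshold, and Ki-67 correlations at the first equilibrium
#' time point. Running it on a metrics CSV re-read from disk reproduces
#' the end-to-end results.
#'
#' @param metrics [compute_uptake_metrics()] table (may include a
#'   `venous` row; rows are matched to `cohort` by `lesion_id`).
#' @param cohort Cohort with `lesion_id`, `grade_class`, and optionally
#'   `ki67_value`.
#' @param thresholds TBmean threshold multiples present in `metrics`.
#' @param window_min,alpha Equilibrium window start and test level.
#' @return List with `equilibrium`, `roc`, `correlations`, `obs`.
#' @export
run_analysis <- function(metrics, cohort, thresholds = c(1.3, 1.6, 1.9),
                         window_min = 30, alpha = 0.05) {
  lesion_rows <- metrics[metrics$lesion_id %in% cohort$lesion_id, , drop = FALSE]
  if (nrow(lesion_rows) == 0) stop_("no metrics rows match the cohort")

  # TAC observations: tumor SUVmax by grade, background sphere SUVmean as
  # normal parenchyma, venous ROI mean if present
  obs <- data.frame(
    lesion = lesion_rows$lesion_id,
    group = cohort$grade_class[match(lesion_rows$lesion_id, cohort$lesion_id)],
    time_min = lesion_rows$time_min, value = lesion_rows$suv_max,
    stringsAsFactors = FALSE)
  obs <- rbind(obs, data.frame(
    lesion = paste0("bg_", lesion_rows$lesion_id), group = "normal",
    time_min = lesion_rows$time_min, value = lesion_rows$background_mean,
    stringsAsFactors = FALSE))
  ven <- metrics[metrics$lesion_id == "venous", , drop = FALSE]
  if (nrow(ven) > 0 && "suv_mean_roi" %in% names(ven)) {
    obs <- rbind(obs, data.frame(
      lesion = "venous", group = "venous", time_min = ven$time_min,
      value = ven$suv_mean_roi, stringsAsFactors = FALSE))
  }
  equil <- equilibrium_anova(obs, window_min = window_min, alpha = alpha)

  metric_names <- c("suv_max", sprintf("tb_mean_%g", thresholds))
  roc <- roc_table(lesion_rows, cohort, metric_names, window_min)

  correlations <- NULL
  if ("ki67_value" %in% names(cohort) && any(is.finite(cohort$ki67_value))) {
    t0 <- min(lesion_rows$time_min[lesion_rows$time_min >= window_min])
    at_t0 <- lesion_rows[lesion_rows$time_min == t0, , drop = FALSE]
    ki <- cohort$ki67_value[match(at_t0$lesion_id, cohort$lesion_id)]
    correlations <- lapply(
      stats::setNames(nm = c("suv_max", sprintf("tb_mean_%g", thresholds[1]))),
      function(m) ki67_correlation(at_t0[[m]], ki))
    attr(correlations, "time_min") <- t0
  }
  list(equilibrium = equil, roc = roc, correlations = correlations, obs = obs)
}

#' Run the full phantom-to-report pipeline
#'
#' Executes simulate, segment, TAC, discriminate, and correlate stages
#' and writes `metrics.csv`, `roc.csv`, `tac_report.json`,
#' `correlation.json`, `synthetic_cohort.tsv`, and a human-readable
#' `summary.txt` into `out_dir`. Fully reproducible: the same
#' configuration and seed give byte-identical outputs. Any stage failure
#' aborts with the stage name.
#'
#' @param config Configuration list (see [demo_config()]) or path to a
#'   JSON file with the same structure. `config$phantom` holds
#'   [build_cohort_phantom()] arguments; `thresholds`, `window_min`,
#'   `alpha`, `search_margin_mm`, `bg_diameter_mm` and `seed` control the
#'   analysis. Set `config$write_images = TRUE` to also write the 4D
#'   NIfTI, label volume, and truth JSON.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the phantom, metrics, and analysis
#'   results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- config$phantom
  if (is.null(ph)) stop_("config lacks a 'phantom' section")
  n_hgg <- if (is.null(ph$n_hgg)) 0 else ph$n_hgg
  n_lgg <- if (is.null(ph$n_lgg)) 0 else ph$n_lgg
  if (n_hgg + n_lgg < 1)
    stop_("configuration error: phantom has no lesions (n_hgg + n_lgg = 0)")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  thresholds <- if (is.null(config$thresholds)) c(1.3, 1.6, 1.9) else config$thresholds
  window_min <- if (is.null(config$window_min)) 30 else config$window_min
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  margin <- if (is.null(config$search_margin_mm)) 4 else config$search_margin_mm
  bg_diam <- if (is.null(config$bg_diameter_mm)) 15 else config$bg_diameter_mm

  stage <- "simulate"
  built <- tryCatch({
    args <- ph[intersect(names(ph),
                         names(formals(build_cohort_phantom)))]
    args$seed <- seed
    if (!is.null(args$grid_shape)) args$grid_shape <- as.numeric(args$grid_shape)
    b <- do.call(build_cohort_phantom, args)
    log_stage_(stage, "phantom: %d lesions (%d HGG, %d LGG), grid %s, seed %d",
               length(b$spec$lesions), n_hgg, n_lgg,
               paste(b$spec$grid_shape, collapse = "x"), seed)
    b
  }, error = function(e) fail_stage_(stage, e))
  rendered <- tryCatch(render_phantom(built$spec),
                       error = function(e) fail_stage_(stage, e))
  img <- rendered$image
  truth <- rendered$truth
  if (isTRUE(config$write_images)) {
    write_dynamic_image(img, file.path(out_dir, "phantom"))
    write_mask(truth$label, file.path(out_dir, "phantom_labels.nii.gz"),
               img$voxel_size_mm)
    write_ground_truth(truth, file.path(out_dir, "phantom_truth.json"))
  }

  stage <- "segment"
  metrics <- tryCatch({
    geom <- image_geometry(img)
    mid_x <- built$spec$brain$center[1]
    ids <- names(truth$lesion_centers)
    searches <- lapply(truth$lesion_centers, function(ctr) {
      sphere_mask(sphere_roi(ctr, 2 * (truth$lesion_radii[1] + margin)), geom)
    })
    backgrounds <- lapply(truth$lesion_centers, function(ctr) {
      sphere_roi(mirror_contralateral(ctr, mid_x), bg_diam)
    })
    if (!is.null(built$spec$venous)) {
      searches$venous <- sphere_mask(
        sphere_roi(built$spec$venous$center, 2 * built$spec$venous$radius_mm), geom)
      backgrounds$venous <- backgrounds[[ids[1]]]
    }
    # post-infusion frames only: background-normalized ratios are not
    # defined while tissue activity is still near zero during infusion
    post_inf <- which(img$schedule$mid_min >=
                        built$spec$normal_kinetics$infusion_min + 0.5)
    m <- compute_uptake_metrics(img, searches, backgrounds, thresholds,
                                frames = post_inf)
    log_stage_(stage, "%d metric rows (%d ROIs x %d frames), thresholds %s",
               nrow(m), length(searches), n_frames(img$schedule),
               paste(thresholds, collapse = "/"))
    m
  }, error = function(e) fail_stage_(stage, e))
  utils::write.csv(format_numeric_(metrics), file.path(out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  write_cohort_synthetic_(built$cohort, file.path(out_dir, "synthetic_cohort.tsv"))

  stage <- "analysis"
  ana <- tryCatch({
    a <- run_analysis(metrics, built$cohort, thresholds, window_min, alpha)
    log_stage_(stage, "%d pooled TAC observations; ROC over %d metrics",
               nrow(a$obs), nrow(a$roc))
    a
  }, error = function(e) fail_stage_(stage, e))

  stage <- "report"
  tryCatch({
    utils::write.csv(format_numeric_(ana$roc), file.path(out_dir, "roc.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(window = ana$equilibrium$window,
           alpha = ana$equilibrium$alpha,
           anova = ana$equilibrium$anova_table,
           tukey = ana$equilibrium$tukey,
           plateau = as.list(ana$equilibrium$plateau)),
      file.path(out_dir, "tac_report.json"), digits = 10, auto_unbox = TRUE,
      na = "null")
    if (!is.null(ana$correlations)) {
      jsonlite::write_json(
        lapply(ana$correlations, function(cr) {
          cr_list <- unclass(cr)
          cr_list
        }),
        file.path(out_dir, "correlation.json"), digits = 10,
        auto_unbox = TRUE, na = "null")
    }
    writeLines(pipeline_summary_(built, ana, thresholds, window_min, seed),
               file.path(out_dir, "summary.txt"))
    log_stage_(stage, "reports written to %s", out_dir)
  }, error = function(e) fail_stage_(stage, e))

  invisible(list(spec = built$spec, cohort = built$cohort, image = img,
                 truth = truth, metrics = metrics, analysis = ana))
}

# Fixed-precision formatting so rewritten CSVs are byte-stable.
format_numeric_ <- function(d) {
  for (nm in names(d)) {
    if (is.numeric(d[[nm]]) && !is.integer(d[[nm]]))
      d[[nm]] <- sprintf("%.10g", d[[nm]])
  }
  d
}

write_cohort_synthetic_ <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

pipeline_summary_ <- function(built, ana, thresholds, window_min, seed) {
  lines <- c(
    "Dynamic PET phantom pipeline summary (synthetic data)",
    sprintf("seed: %d", seed),
    sprintf("lesions: %d (%s)", nrow(built$cohort),
            paste(sprintf("%s %d", names(table(built$cohort$grade_class)),
                          table(built$cohort$grade_class)), collapse = ", ")),
    sprintf("equilibrium window: mid-times >= %g min", window_min),
    "", "ROC cutoffs (positive class = HGG):")
  for (i in seq_len(nrow(ana$roc))) {
    r <- ana$roc[i, ]
    lines <- c(lines, sprintf(
      "  %-12s cutoff > %-8.4g sens %5.1f%%  spec %5.1f%%  AUC %.4f",
      r$parameter, r$threshold, r$sensitivity_pct, r$specificity_pct, r$auc))
  }
  lines <- c(lines, "", "TAC plateau flags (Tukey within group):")
  for (g in names(ana$equilibrium$plateau)) {
    lines <- c(lines, sprintf("  %-8s %s", g,
      if (is.na(ana$equilibrium$plateau[g])) "unavailable"
      else as.character(ana$equilibrium$plateau[g])))
  }
  if (!is.null(ana$correlations)) {
    lines <- c(lines, "", sprintf("Ki-67 correlations at %g min:",
                                  attr(ana$correlations, "time_min")))
    for (m in names(ana$correlations)) {
      cr <- ana$correlations[[m]]
      lines <- c(lines, sprintf("  %-12s R = %.4f, p = %.4g (n = %d)",
                                m, cr$r, cr$p_value, cr$n))
    }
  }
  lines
}
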