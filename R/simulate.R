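#' Simulate pooled equilibrium TB observations for two tumor grades
#'
#' Statistical-level generator (no image rendering): each lesion draws a
#' latent equilibrium tumor-to-background level from its grade's normal
#' distribution, then contributes one noisy observation per equilibrium
#' time point. Defaults emulate a cohort of 12 high-grade and 6 low-grade
#' lesions observed at 30/40/50/60 min with the high-grade TBmean
#' distribution stochastically above the low-grade one, as seen in
#' amino-acid PET glioma scatter data.
#'
#' @param n_hgg,n_lgg Lesion counts per class.
#' @param times Equilibrium time points, minutes.
#' @param hgg_mean,hgg_sd,lgg_mean,lgg_sd Between-lesion distribution of
#'   the latent TB level per class.
#' @param within_sd Within-lesion (frame-to-frame) SD.
#' @param dropout Number of lesions (drawn at random) missing the last
#'   time point, modeling patient attrition.
#' @param seed Optional seed.
#' @return Data.frame `(lesion_id, grade_class, time_min, value)` with
#'   attribute `latent` (named vector of per-lesion latent TB levels).
#' @export
simulate_tb_cohort <- function(n_hgg = 12, n_lgg = 6,
                               times = c(30, 40, 50, 60),
                               hgg_mean = 3.5, hgg_sd = 0.8,
                               lgg_mean = 1.8, lgg_sd = 0.3,
                               within_sd = 0.15, dropout = 0, seed = NULL) {
  stopifnot(n_hgg >= 1, n_lgg >= 1, length(times) >= 1)
  with_seed_(seed, {
    n <- n_hgg + n_lgg
    grade <- c(rep("HGG", n_hgg), rep("LGG", n_lgg))
    latent <- pmax(0.2, stats::rnorm(n,
      mean = ifelse(grade == "HGG", hgg_mean, lgg_mean),
      sd = ifelse(grade == "HGG", hgg_sd, lgg_sd)))
    ids <- sprintf("L%02d", seq_len(n))
    obs <- expand.grid(lesion_id = ids, time_min = times,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    obs$grade_class <- grade[match(obs$lesion_id, ids)]
    obs$value <- pmax(0.05,
      latent[match(obs$lesion_id, ids)] +
        stats::rnorm(nrow(obs), sd = within_sd))
    if (dropout > 0) {
      drop_ids <- sample(ids, min(dropout, n))
      obs <- obs[!(obs$lesion_id %in% drop_ids &
                     obs$time_min == max(times)), , drop = FALSE]
    }
    obs <- obs[order(obs$lesion_id, obs$time_min),
               c("lesion_id", "grade_class", "time_min", "value")]
    rownames(obs) <- NULL
    attr(obs, "latent") <- stats::setNames(latent, ids)
    obs
  })
}

#' Simulate paired uptake/Ki-67 lesions with a known correlation
#'
#' Draws bivariate-normal pairs with population Pearson correlation `r`,
#' scaled to plausible uptake (TB around 2.5) and Ki-67 (percent) ranges.
#' Used for parameter-recovery checks of [ki67_correlation()].
#'
#' @param n Number of lesions (default 13, a typical evaluable subset).
#' @param r True correlation.
#' @param metric_mean,metric_sd,ki67_mean,ki67_sd Marginal scales.
#' @param seed Optional seed.
#' @return Data.frame with columns `metric`, `ki67`.
#' @export
simulate_ki67_pairs <- function(n = 13, r = 0.8, metric_mean = 2.5,
                                metric_sd = 0.7, ki67_mean = 20,
                                ki67_sd = 13, seed = NULL) {
  stopifnot(n >= 3, abs(r) <= 1)
  with_seed_(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    data.frame(metric = metric_mean + metric_sd * z1,
               ki67 = ki67_mean + ki67_sd * (r * z1 + sqrt(1 - r^2) * z2))
  })
}

#' Simulate per-lesion TAC observations around grade-specific kinetics
#'
#' Builds the long observation table used by [equilibrium_anova()]:
#' each lesion's noiseless values are the frame averages of its group's
#' [tissue_kinetics()] (with optional per-lesion level jitter), plus
#' i.i.d. frame noise. With `drift_slope = 0` in every group the null
#' (plateau) holds over the equilibrium window.
#'
#' @param kinetics Named list of [tissue_kinetics()], one per group.
#' @param n_lesions Named integer vector of lesion counts per group.
#' @param schedule Frame schedule.
#' @param lesion_sd SD of the per-lesion multiplicative level jitter.
#' @param frame_sd SD of additive per-frame noise.
#' @param seed Optional seed.
#' @return Data.frame `(lesion, group, time_min, value)`.
#' @export
simulate_tac_observations <- function(kinetics, n_lesions,
                                      schedule = fluciclovine_schedule(),
                                      lesion_sd = 0.1, frame_sd = 0.1,
                                      seed = NULL) {
  stopifnot(is.list(kinetics), all(names(n_lesions) %in% names(kinetics)))
  with_seed_(seed, {
    rows <- list()
    for (g in names(n_lesions)) {
      base <- tissue_frame_averages(kinetics[[g]], schedule)
      for (i in seq_len(n_lesions[[g]])) {
        lev <- exp(stats::rnorm(1, sd = lesion_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          lesion = sprintf("%s_%02d", g, i), group = g,
          time_min = schedule$mid_min,
          value = lev * base + stats::rnorm(length(base), sd = frame_sd))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
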