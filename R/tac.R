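#' Extract a time-activity curve from a dynamic image
#'
#' One metric value per frame, placed at the frame mid-time.
#' Tumor-to-background statistics divide by the background value of the
#' same frame.
#'
#' @param img A [dynamic_image()].
#' @param mask Logical 3D mask (nonempty).
#' @param statistic One of `"suv_mean"`, `"suv_max"`, `"tb_mean"`,
#'   `"tb_max"`.
#' @param bg_series Per-frame background SUVmean (required for TB
#'   statistics; all > 0).
#' @param roi_id,group Labels attached to the curve (group is one of
#'   HGG, LGG, normal, venous, or NA).
#' @return A data.frame of class `tac` with columns `time_min`, `value`
#'   and attributes `roi_id`, `statistic`, `group`.
#' @export
extract_tac <- function(img, mask,
                        statistic = c("suv_mean", "suv_max", "tb_mean", "tb_max"),
                        bg_series = NULL, roi_id = NA, group = NA_character_) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(img, "dynamic_image"), is.logical(mask),
            identical(dim(mask), dim(img$data)[1:3]))
  if (!any(mask)) stop_("'mask' is empty")
  nf <- n_frames(img$schedule)
  is_tb <- statistic %in% c("tb_mean", "tb_max")
  if (is_tb) {
    if (is.null(bg_series)) stop_("'bg_series' is required for TB statistics")
    stopifnot(length(bg_series) == nf, all(bg_series > 0))
  }
  vals <- vapply(seq_len(nf), function(f) {
    v <- img$data[, , , f][mask]
    x <- if (statistic %in% c("suv_max", "tb_max")) max(v) else mean(v)
    if (is_tb) x / bg_series[f] else x
  }, numeric(1))
  tac(img$schedule$mid_min, vals, roi_id = roi_id, statistic = statistic,
      group = group)
}

#' @rdname extract_tac
#' @param time_min,value Time grid (minutes, strictly increasing) and
#'   metric values (missing values allowed and kept).
#' @export
tac <- function(time_min, value, roi_id = NA, statistic = NA_character_,
                group = NA_character_) {
  stopifnot(length(time_min) == length(value))
  if (any(diff(time_min) <= 0)) stop_("'time_min' must be strictly increasing")
  structure(data.frame(time_min = time_min, value = value),
            roi_id = roi_id, statistic = statistic, group = group,
            class = c("tac", "data.frame"))
}

#' Average time-activity curves across lesions
#'
#' Pointwise mean over curves sharing a time grid, ignoring missing
#' values; the per-point number of contributing curves is kept, so that
#' patient attrition (missing late frames) is explicit rather than
#' imputed.
#'
#' @param tacs List of [tac()] objects on the same time grid (within
#'   `tol` minutes).
#' @param tol Time-grid matching tolerance, minutes.
#' @return A `tac` data.frame with columns `time_min`, `value`, `n`.
#' @export
group_average_tac <- function(tacs, tol = 1e-6) {
  stopifnot(is.list(tacs), length(tacs) >= 1)
  t0 <- tacs[[1]]$time_min
  for (tc in tacs) {
    if (length(tc$time_min) != length(t0) || any(abs(tc$time_min - t0) > tol))
      stop_("TACs do not share a common time grid")
  }
  vals <- vapply(tacs, function(tc) tc$value, numeric(length(t0)))
  vals <- matrix(vals, nrow = length(t0))
  n <- rowSums(!is.na(vals))
  avg <- rowMeans(vals, na.rm = TRUE)
  avg[n == 0] <- NA_real_
  out <- tac(t0, avg, roi_id = "group_mean",
             statistic = attr(tacs[[1]], "statistic"),
             group = attr(tacs[[1]], "group"))
  out$n <- n
  out
}

#' Test time-activity-curve equilibrium in the late window
#'
#' Restricts observations to frames with mid-time at or beyond
#' `window_min`, fits an unbalanced two-way ANOVA (factors: time point
#' and tissue group, type-II sums of squares), and runs Tukey HSD
#' comparisons between time points within each group. A group is flagged
#' as plateaued when none of its within-group time-pair comparisons is
#' significant at `alpha`; the per-pair adjusted p-values are returned so
#' callers can apply their own reading of borderline pairs.
#'
#' @param obs Long data.frame with columns `lesion`, `group`, `time_min`,
#'   `value` (missing values dropped).
#' @param window_min Start of the equilibrium window, minutes
#'   (default 30).
#' @param alpha Significance level for the plateau flag.
#' @return An object of class `equilibrium_result`: list with `window`
#'   (time points used), `anova_table`, `tukey` (data.frame: group, pair,
#'   diff, p_adj), `plateau` (named logical, NA when a group has too few
#'   lesions for within-group comparisons), `alpha`.
#' @export
equilibrium_anova <- function(obs, window_min = 30, alpha = 0.05) {
  stopifnot(is.data.frame(obs),
            all(c("lesion", "group", "time_min", "value") %in% names(obs)))
  d <- obs[!is.na(obs$value) & obs$time_min >= window_min, , drop = FALSE]
  times <- sort(unique(d$time_min))
  if (length(times) < 2) stop_("need >= 2 time points in the equilibrium window")
  d$time_f <- factor(d$time_min)
  d$group_f <- factor(d$group)

  # a perfectly fitting model (e.g., all values equal) is a legitimate
  # degenerate input here; the resulting p-values are overridden below
  quiet_anova <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  if (nlevels(d$group_f) > 1) {
    fit <- stats::lm(value ~ group_f + time_f, data = d)
    at <- quiet_anova(car::Anova(fit, type = 2))
  } else {
    fit <- stats::lm(value ~ time_f, data = d)
    at <- quiet_anova(stats::anova(fit))
  }
  anova_table <- data.frame(term = rownames(at), sum_sq = at[["Sum Sq"]],
                            df = at[["Df"]], F = at[["F value"]],
                            p = at[["Pr(>F)"]], row.names = NULL)

  groups <- levels(d$group_f)
  tukey_rows <- list()
  plateau <- stats::setNames(rep(NA, length(groups)), groups)
  for (g in groups) {
    dg <- d[d$group_f == g, , drop = FALSE]
    dg$time_f <- droplevels(dg$time_f)
    # within-group comparisons need residual df and >= 2 time levels
    if (length(unique(dg$lesion)) < 2 || nlevels(dg$time_f) < 2 ||
        nrow(dg) <= nlevels(dg$time_f)) {
      next
    }
    a <- stats::aov(value ~ time_f, data = dg)
    res_ms <- sum(stats::residuals(a)^2) / a$df.residual
    th <- stats::TukeyHSD(a)$time_f
    p_adj <- th[, "p adj"]
    diffs <- th[, "diff"]
    if (!is.finite(res_ms) || res_ms < 1e-24) {
      # degenerate: no residual variation; equal means are trivially
      # non-different, unequal means trivially different
      p_adj <- ifelse(abs(diffs) < 1e-12, 1, 0)
    }
    tukey_rows[[g]] <- data.frame(group = g, pair = rownames(th),
                                  diff = unname(diffs),
                                  p_adj = unname(p_adj),
                                  row.names = NULL)
    plateau[g] <- !any(p_adj < alpha)
  }
  tukey <- if (length(tukey_rows)) do.call(rbind, tukey_rows) else
    data.frame(group = character(), pair = character(), diff = numeric(),
               p_adj = numeric())
  rownames(tukey) <- NULL
  structure(list(window = times, anova_table = anova_table, tukey = tukey,
                 plateau = plateau, alpha = alpha),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium analysis over %s min (alpha = %g)\n",
              paste(x$window, collapse = ", "), x$alpha))
  for (g in names(x$plateau)) {
    cat(sprintf("  %s: plateau = %s\n", g,
                if (is.na(x$plateau[g])) "unavailable" else x$plateau[g]))
  }
  invisible(x)
}
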