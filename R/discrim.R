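#' Pool per-lesion metrics over the equilibrium window
#'
#' Builds the observation set used for grade discrimination: one row per
#' lesion per equilibrium frame, labeled HGG (WHO III/IV) or LGG
#' (WHO II). Observations with a missing metric value are dropped with a
#' message giving the count.
#'
#' @param metrics An [compute_uptake_metrics()] data.frame (columns
#'   `lesion_id`, `time_min`, plus metric columns).
#' @param cohort A [read_cohort()] data.frame (or any data.frame with
#'   `lesion_id` and `grade_class`).
#' @param metric Name of the metric column to pool (e.g., `"suv_max"`,
#'   `"tb_mean_1.3"`).
#' @param window_min Start of the equilibrium window, minutes.
#' @return Data.frame with columns `lesion_id`, `grade_class`, `metric`,
#'   `time_min`, `value`.
#' @export
pool_equilibrium <- function(metrics, cohort, metric = "suv_max",
                             window_min = 30) {
  stopifnot(is.data.frame(metrics), metric %in% names(metrics),
            all(c("lesion_id", "grade_class") %in% names(cohort)))
  miss <- setdiff(unique(metrics$lesion_id), cohort$lesion_id)
  if (length(miss))
    stop_("no grade for lesion(s): ", paste(miss, collapse = ", "))
  d <- metrics[metrics$time_min >= window_min, , drop = FALSE]
  out <- data.frame(
    lesion_id = d$lesion_id,
    grade_class = cohort$grade_class[match(d$lesion_id, cohort$lesion_id)],
    metric = rep(metric, nrow(d)), time_min = d$time_min, value = d[[metric]],
    stringsAsFactors = FALSE)
  n_na <- sum(is.na(out$value))
  if (n_na > 0) {
    message(n_na, " observation(s) with missing ", metric, " dropped")
    out <- out[!is.na(out$value), , drop = FALSE]
  }
  if (nrow(out) == 0) warning("equilibrium window contains no observations")
  rownames(out) <- NULL
  out
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC for discriminating the positive class (HGG)
#' from the negative class (LGG) under the convention that higher metric
#' values indicate higher grade. Candidate thresholds are the midpoints
#' between consecutive sorted unique values plus -Inf/+Inf sentinels; a
#' case is called positive when its value exceeds the threshold. The AUC
#' is the trapezoidal area, which equals the Mann-Whitney concordance
#' probability with ties counted 1/2. The reported cutoff maximizes
#' Youden's J = sensitivity + specificity - 1, breaking ties toward
#' higher sensitivity (then toward the lower threshold).
#'
#' @param values Numeric metric values, or a data.frame from
#'   [pool_equilibrium()] (then `labels` defaults to its `grade_class`).
#' @param labels Class labels, same length as `values`.
#' @param positive Label of the positive class (default `"HGG"`).
#' @return An object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `optimal_threshold`,
#'   `sens_at_opt`, `spec_at_opt`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(values, labels = NULL, positive = "HGG") {
  if (is.data.frame(values)) {
    if (is.null(labels)) labels <- values$grade_class
    values <- values$value
  }
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop_("both classes must be present for ROC analysis")
  u <- sort(unique(values))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  xp <- values[pos]
  xn <- values[!pos]
  sens <- vapply(thr, function(t) mean(xp > t), numeric(1))
  spec <- vapply(thr, function(t) mean(xn <= t), numeric(1))
  fpr <- 1 - spec
  # thresholds ascend, so fpr descends from 1 to 0: trapezoid in that order
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)
  j <- sens + spec - 1
  cand <- which(j > max(j) - 1e-12)
  cand <- cand[sens[cand] > max(sens[cand]) - 1e-12]
  opt <- cand[1]  # lowest threshold among ties
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, optimal_threshold = thr[opt], sens_at_opt = sens[opt],
         spec_at_opt = spec[opt], n_pos = sum(pos), n_neg = sum(!pos)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f | cutoff > %.3g: sensitivity %.1f%%, specificity %.1f%% (n+ = %d, n- = %d)\n",
    x$auc, x$optimal_threshold, 100 * x$sens_at_opt, 100 * x$spec_at_opt,
    x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC summary table across several uptake metrics
#'
#' One row per metric in the style of a clinical cutoff table:
#' parameter, optimal threshold, sensitivity %, specificity %, AUC.
#'
#' @param metrics An [compute_uptake_metrics()] data.frame.
#' @param cohort Cohort with `lesion_id`, `grade_class`.
#' @param metric_names Metric columns to analyze.
#' @param window_min Equilibrium window start, minutes.
#' @return Data.frame with columns `parameter`, `threshold`,
#'   `sensitivity_pct`, `specificity_pct`, `auc`, `n_obs`.
#' @export
roc_table <- function(metrics, cohort,
                      metric_names = c("suv_max", "tb_mean_1.3",
                                       "tb_mean_1.6", "tb_mean_1.9"),
                      window_min = 30) {
  rows <- lapply(metric_names, function(m) {
    obs <- pool_equilibrium(metrics, cohort, m, window_min)
    r <- roc_analysis(obs)
    data.frame(parameter = m, threshold = r$optimal_threshold,
               sensitivity_pct = 100 * r$sens_at_opt,
               specificity_pct = 100 * r$spec_at_opt,
               auc = r$auc, n_obs = r$n_pos + r$n_neg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch's unequal-variance two-tailed t test
#'
#' Two-sided test for a difference in means with Welch-Satterthwaite
#' degrees of freedom. When both samples have zero variance, equal means
#' give p = 1 by convention (and unequal means p = 0), rather than an
#' error.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `statistic` (t), `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop_("each sample needs n >= 2")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  dm <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (abs(dm) < .Machine$double.eps^0.5)
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    return(list(statistic = sign(dm) * Inf, df = NA_real_, p_value = 0))
  }
  t <- dm / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Correlate an uptake metric with the Ki-67 proliferation index
#'
#' Pearson correlation between a per-lesion metric (one time point,
#' typically 30 min) and the Ki-67 labelling index, with the two-sided p
#' for the null hypothesis of zero slope and the least-squares line of
#' Ki-67 on the metric. Pairs with missing values are dropped; a
#' zero-variance metric (or Ki-67) is flagged degenerate rather than
#' silently reported as r = 0.
#'
#' @param metric_values Per-lesion metric values.
#' @param ki67_percent Paired Ki-67 percentages.
#' @return An object of class `correlation_result`: list with `r`,
#'   `p_value`, `n`, `slope`, `intercept`, `degenerate`.
#' @export
ki67_correlation <- function(metric_values, ki67_percent) {
  stopifnot(length(metric_values) == length(ki67_percent))
  ok <- is.finite(metric_values) & is.finite(ki67_percent)
  x <- metric_values[ok]; y <- ki67_percent[ok]
  if (length(x) < 3) stop_("need >= 3 complete pairs for correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one variable; correlation undefined")
    return(structure(list(r = NA_real_, p_value = NA_real_, n = length(x),
                          slope = NA_real_, intercept = NA_real_,
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$degenerate) cat("Correlation: degenerate (zero variance)\n")
  else cat(sprintf("Correlation: R = %.3f, p = %.3g (n = %d)\n",
                   x$r, x$p_value, x$n))
  invisible(x)
}

#' Lasso-logistic predictor relevance
#'
#' Ranks uptake metrics as predictors of tumor grade with an
#' L1-regularized logistic regression. Predictors are standardized to
#' zero mean and unit variance before penalization; the coefficient path
#' is computed over a descending penalty grid, the order in which each
#' predictor first enters the path is recorded, and a predictor is
#' flagged relevant when its coefficient is nonzero at the
#' cross-validated penalty (1-SE rule, seedable folds).
#'
#' @param X Numeric matrix or data.frame of predictors (columns, e.g.,
#'   suv_max, suv_mean, tb_max, tb_mean).
#' @param y Two-level class labels (HGG/LGG or a factor).
#' @param seed Optional seed for the cross-validation folds.
#' @param nfolds Number of CV folds.
#' @return An object of class `relevance_ranking`: data.frame with one
#'   row per predictor (`metric`, `entry_step`, `entry_rank`,
#'   `coefficient_1se`, `relevant`), plus attributes `lambda_1se`,
#'   `lambda_min`.
#' @export
lasso_relevance <- function(X, y, seed = NULL, nfolds = 10L) {
  X <- as.matrix(X)
  stopifnot(!is.null(colnames(X)), nrow(X) == length(y))
  y <- factor(y)
  if (nlevels(y) != 2) stop_("'y' must have exactly two classes")
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("constant predictor(s) excluded: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  Xs <- scale(X[, !const, drop = FALSE])
  if (ncol(Xs) < 2) stop_("need >= 2 non-constant predictors")
  fit <- glmnet::glmnet(Xs, y, family = "binomial", standardize = FALSE)
  beta <- as.matrix(fit$beta)  # predictors x lambda (lambda descending)
  entry <- apply(beta != 0, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  foldid <- with_seed_(seed, sample(rep(seq_len(nfolds), length.out = nrow(Xs))))
  cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", standardize = FALSE,
                          foldid = foldid)
  co <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1, 1]
  res <- data.frame(metric = colnames(X), entry_step = NA_integer_,
                    coefficient_1se = NA_real_, relevant = FALSE,
                    stringsAsFactors = FALSE)
  keep <- colnames(X)[!const]
  res$entry_step[match(keep, res$metric)] <- entry[keep]
  res$coefficient_1se[match(keep, res$metric)] <- co[keep]
  res$relevant <- !is.na(res$coefficient_1se) & res$coefficient_1se != 0
  res$entry_rank <- rank(res$entry_step, ties.method = "first",
                         na.last = "keep")
  attr(res, "lambda_1se") <- cv$lambda.1se
  attr(res, "lambda_min") <- cv$lambda.min
  class(res) <- c("relevance_ranking", "data.frame")
  res
}
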