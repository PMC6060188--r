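# Brute-force Mann-Whitney concordance (ties count 1/2): the AUC oracle.
concordance_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

test_that("equilibrium pooling yields lesion x frame observations", {
  metrics <- expand.grid(lesion_id = sprintf("L%02d", 1:18),
                         time_min = c(30, 40, 50, 60),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  metrics$suv_max <- rnorm(nrow(metrics), 4)
  cohort <- data.frame(lesion_id = sprintf("L%02d", 1:18),
                       grade_class = rep(c("HGG", "LGG"), c(12, 6)))
  obs <- pool_equilibrium(metrics, cohort, "suv_max")
  expect_equal(nrow(obs), 72)
  expect_setequal(unique(obs$grade_class), c("HGG", "LGG"))

  expect_warning(pool_equilibrium(metrics, cohort, "suv_max",
                                  window_min = 100), "no observations")

  # attrition: missing values are dropped with a message
  metrics$suv_max[metrics$time_min == 60][1:2] <- NA
  expect_message(obs2 <- pool_equilibrium(metrics, cohort, "suv_max"),
                 "2 observation")
  expect_equal(nrow(obs2), 70)

  expect_error(pool_equilibrium(metrics, cohort[-1, ], "suv_max"), "no grade")
})

test_that("ROC handles perfect separation and matches the concordance oracle", {
  vals <- c(rnorm(10, 10, 0.5), rnorm(8, 0, 0.5))
  labs <- rep(c("HGG", "LGG"), c(10, 8))
  r <- roc_analysis(vals, labs)
  expect_equal(r$auc, 1)
  expect_equal(r$sens_at_opt, 1)
  expect_equal(r$spec_at_opt, 1)

  set.seed(4)
  for (i in 1:10) {
    pos <- round(rnorm(7, 1), 1)  # rounding forces occasional ties
    neg <- round(rnorm(9, 0.5), 1)
    r <- roc_analysis(c(pos, neg), rep(c("HGG", "LGG"), c(7, 9)))
    expect_equal(r$auc, concordance_oracle(pos, neg), tolerance = 1e-12)
    # complement: AUC(x) + AUC(-x) = 1 on tie-free data
    pos2 <- pos + seq_along(pos) * 1e-6
    r_fwd <- roc_analysis(c(pos2, neg), rep(c("HGG", "LGG"), c(7, 9)))
    r_rev <- roc_analysis(-c(pos2, neg), rep(c("HGG", "LGG"), c(7, 9)))
    expect_equal(r_fwd$auc + r_rev$auc, 1, tolerance = 1e-12)
  }
  expect_error(roc_analysis(1:5, rep("HGG", 5)), "both classes")
})

test_that("ROC is invariant under strictly increasing transforms", {
  set.seed(8)
  vals <- rexp(30) + 0.5
  labs <- sample(rep(c("HGG", "LGG"), 15))
  a <- roc_analysis(vals, labs)
  b <- roc_analysis(log(vals), labs)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$sens_at_opt, b$sens_at_opt)
  expect_equal(a$spec_at_opt, b$spec_at_opt)
  # achieved operating point agrees with an independent ROC implementation
  pr <- pROC::roc(response = labs, predictor = vals, levels = c("LGG", "HGG"),
                  direction = "<", quiet = TRUE)
  expect_equal(a$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("Welch test matches t.test and honors the degenerate convention", {
  set.seed(5)
  a <- rnorm(12, 1, 2); b <- rnorm(9, 0.2, 0.5)
  w <- welch_t(a, b)
  tt <- t.test(a, b)
  expect_equal(w$statistic, unname(tt$statistic))
  expect_equal(w$df, unname(tt$parameter))
  expect_equal(w$p_value, tt$p.value)

  # symmetry under swapping samples
  w2 <- welch_t(b, a)
  expect_equal(w2$statistic, -w$statistic)
  expect_equal(w2$p_value, w$p_value)

  # identical samples: no difference
  expect_equal(welch_t(a, a)$statistic, 0)
  expect_equal(welch_t(a, a)$p_value, 1)

  # zero variance in both samples
  expect_equal(welch_t(rep(2, 3), rep(2, 4))$p_value, 1)
  expect_equal(welch_t(rep(2, 3), rep(3, 4))$p_value, 0)
  expect_error(welch_t(1, 1:3), "n >= 2")
})

test_that("well-separated samples are essentially always detected", {
  set.seed(6)
  hits <- vapply(1:50, function(i) {
    welch_t(rnorm(10, 5), rnorm(10, 0))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.98)
})

test_that("Ki-67 correlation recovers exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  r <- ki67_correlation(x, 10 + 3 * x)
  expect_equal(r$r, 1)
  expect_lt(r$p_value, 1e-8)
  expect_equal(r$slope, 3)
  expect_equal(r$intercept, 10)

  expect_warning(rd <- ki67_correlation(rep(2, 5), c(1, 2, 3, 4, 5)),
                 "zero variance")
  expect_true(rd$degenerate)
  expect_true(is.na(rd$r))

  expect_error(ki67_correlation(c(1, 2), c(1, 2)), "3")

  # missing pairs are dropped before the n >= 3 check
  r2 <- ki67_correlation(c(x, NA), c(10 + 3 * x, 5))
  expect_equal(r2$n, 5)

  # agreement with cor.test on noisy data
  set.seed(9)
  mx <- rnorm(13, 2.5, 0.7); ky <- 5 + 8 * mx + rnorm(13, sd = 6)
  ct <- cor.test(mx, ky)
  rr <- ki67_correlation(mx, ky)
  expect_equal(rr$r, unname(ct$estimate))
  expect_equal(rr$p_value, ct$p.value)
})

test_that("lasso screening flags informative metrics on a seeded draw", {
  set.seed(10)
  n <- 400
  X <- cbind(suv_max = rnorm(n), suv_mean = rnorm(n),
             tb_max = rnorm(n), tb_mean = rnorm(n))
  eta <- 1.6 * X[, "suv_max"] + 1.6 * X[, "tb_mean"]
  y <- ifelse(runif(n) < plogis(eta), "HGG", "LGG")
  rk <- lasso_relevance(X, y, seed = 1L)
  expect_setequal(rk$metric, colnames(X))
  expect_true(all(rk$relevant[rk$metric %in% c("suv_max", "tb_mean")]))
  # informative metrics enter the path before the noise metrics
  expect_true(max(rk$entry_step[rk$metric %in% c("suv_max", "tb_mean")]) <=
                min(rk$entry_step[rk$metric %in% c("suv_mean", "tb_max")],
                    na.rm = TRUE))
})

test_that("duplicated informative predictors do not both enter early", {
  set.seed(11)
  n <- 300
  x <- rnorm(n)
  X <- cbind(suv_max = x, suv_mean = x, tb_max = rnorm(n), tb_mean = rnorm(n))
  y <- ifelse(runif(n) < plogis(2 * x), "HGG", "LGG")
  rk <- lasso_relevance(X, y, seed = 2L)
  steps <- sort(rk$entry_step[rk$metric %in% c("suv_max", "suv_mean")])
  expect_true(is.na(steps[2]) || diff(steps) > 0)
})

test_that("constant predictors are excluded with a warning", {
  set.seed(12)
  X <- cbind(suv_max = rnorm(50), suv_mean = rep(1, 50),
             tb_max = rnorm(50), tb_mean = rnorm(50))
  y <- rep(c("HGG", "LGG"), 25)
  expect_warning(rk <- lasso_relevance(X, y, seed = 3L), "constant")
  expect_false(rk$relevant[rk$metric == "suv_mean"])
  expect_true(is.na(rk$entry_step[rk$metric == "suv_mean"]))
})

test_that("synthetic cohort generators honor their stated structure", {
  obs <- simulate_tb_cohort(seed = 7L)
  expect_equal(nrow(obs), 18 * 4)
  expect_equal(sum(obs$grade_class == "HGG"), 12 * 4)
  expect_true(all(obs$value > 0))

  drop2 <- simulate_tb_cohort(dropout = 2, seed = 7L)
  expect_equal(nrow(drop2), 18 * 4 - 2)
  expect_equal(sum(drop2$time_min == 60), 16)

  big <- simulate_ki67_pairs(n = 5000, r = 0.8, seed = 8L)
  expect_equal(cor(big$metric, big$ki67), 0.8, tolerance = 0.03)
})
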