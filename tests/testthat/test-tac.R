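test_that("TAC extraction reproduces constants and self-ratios", {
  img <- uniform_image(2.2, n_frames = 3)
  mask <- array(FALSE, dim = dim(img$data)[1:3]); mask[2:4, 2:4, 2:3] <- TRUE
  tc <- extract_tac(img, mask, "suv_mean")
  expect_equal(tc$value, rep(2.2, 3))
  expect_equal(tc$time_min, img$schedule$mid_min)

  bg <- rep(2.2, 3)
  tb <- extract_tac(img, mask, "tb_mean", bg_series = bg)
  expect_equal(tb$value, rep(1, 3))
  expect_error(extract_tac(img, mask, "tb_mean"), "bg_series")
})

test_that("lesion SUVmax TAC matches ground truth on clean phantoms", {
  r <- render_phantom(tiny_phantom_spec())
  mask <- r$truth$label == 10L
  tc <- extract_tac(r$image, mask, "suv_max")
  expect_equal(tc$value, unname(r$truth$frame_tacs["10", ]))
})

test_that("group averaging handles attrition by per-point counts", {
  t <- c(30, 40, 50, 60)
  one <- tac(t, c(1, 2, 3, 4))
  expect_equal(group_average_tac(list(one))$value, one$value)

  v <- c(1.5, -0.5, 2, 0)
  zeroed <- group_average_tac(list(tac(t, v), tac(t, -v)))
  expect_equal(zeroed$value, rep(0, 4))

  tacs <- c(lapply(1:9, function(i) tac(t, rep(i, 4))),
            list(tac(t, c(10, 10, 10, NA))))
  avg <- group_average_tac(tacs)
  expect_equal(avg$n, c(10, 10, 10, 9))
  expect_equal(avg$value[4], mean(1:9))
  expect_equal(avg$value[1], mean(1:10))

  expect_error(group_average_tac(list(one, tac(c(1, 2), c(0, 0)))),
               "time grid")
})

test_that("identical values give a trivially plateaued equilibrium result", {
  obs <- expand.grid(lesion = sprintf("L%d", 1:5), time_min = c(30, 40, 50, 60))
  obs$group <- "HGG"
  obs$value <- 2.5
  res <- equilibrium_anova(obs)
  expect_true(all(res$tukey$p_adj == 1))
  expect_true(res$plateau[["HGG"]])
})

test_that("Tukey adjusted p-values dominate unadjusted pairwise p-values", {
  set.seed(21)
  obs <- expand.grid(lesion = sprintf("L%d", 1:8),
                     time_min = c(30, 40, 50, 60))
  obs$group <- "HGG"
  obs$value <- rnorm(nrow(obs), mean = 3, sd = 0.4)
  res <- equilibrium_anova(obs)
  # recompute unadjusted pairwise p from the same one-way fit
  d <- obs
  d$time_f <- factor(d$time_min)
  a <- aov(value ~ time_f, data = d)
  s2 <- sum(residuals(a)^2) / a$df.residual
  ns <- table(d$time_f)
  lv <- levels(d$time_f)
  for (i in seq_len(nrow(res$tukey))) {
    pr <- strsplit(res$tukey$pair[i], "-")[[1]]
    se <- sqrt(s2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    p_unadj <- 2 * pt(-abs(res$tukey$diff[i]) / se, a$df.residual)
    expect_gte(res$tukey$p_adj[i] + 1e-12, p_unadj)
  }
})

test_that("equilibrium analysis is invariant to row order and lesion ids", {
  set.seed(33)
  obs <- expand.grid(lesion = sprintf("L%d", 1:6),
                     time_min = c(30, 40, 50, 60),
                     stringsAsFactors = FALSE)
  obs$group <- rep(c("HGG", "LGG"), each = 3)[match(obs$lesion,
                                                    sprintf("L%d", 1:6))]
  obs$value <- rnorm(nrow(obs), 3)
  res1 <- equilibrium_anova(obs)
  perm <- obs[sample(nrow(obs)), ]
  perm$lesion <- paste0("X", perm$lesion)
  res2 <- equilibrium_anova(perm)
  expect_equal(res1$anova_table$p, res2$anova_table$p)
  expect_equal(res1$tukey$p_adj, res2$tukey$p_adj)
  expect_equal(res1$plateau, res2$plateau)
})

test_that("groups with a single lesion get no within-group comparisons", {
  obs <- expand.grid(lesion = c("only"), time_min = c(30, 40, 50, 60))
  obs$group <- "venous"
  obs$value <- rnorm(4)
  obs2 <- expand.grid(lesion = sprintf("L%d", 1:4),
                      time_min = c(30, 40, 50, 60))
  obs2$group <- "HGG"
  obs2$value <- rnorm(16, 3)
  res <- equilibrium_anova(rbind(obs, obs2))
  expect_true(is.na(res$plateau[["venous"]]))
  expect_false(is.na(res$plateau[["HGG"]]))
})

test_that("a strong late drift defeats the plateau flag", {
  kins <- list(flat = tissue_kinetics(3, 5, infusion_min = 0),
               drift = tissue_kinetics(3, 5, infusion_min = 0,
                                       drift_slope = 0.05,
                                       drift_onset_min = 25))
  obs <- simulate_tac_observations(kins, c(flat = 8, drift = 8),
                                   lesion_sd = 0, frame_sd = 0.05, seed = 2L)
  res <- equilibrium_anova(obs)
  expect_true(res$plateau[["flat"]])
  expect_false(res$plateau[["drift"]])
})
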