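test_that("intercept-only residualization mean-centers; zero covariates are dropped", {
  set.seed(71)
  edges <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  tr <- 1:12
  expect_warning(
    res <- residualize_confounds(edges, y, cbind(zero = rep(0, 20)), tr),
    "constant covariate"
  )
  centered <- sweep(edges, 2, colMeans(edges[tr, ]))
  expect_equal(res$edges, centered, tolerance = 1e-12)
  expect_equal(res$outcome, y - mean(y[tr]), tolerance = 1e-12)
})

test_that("training-fitted residualization decorrelates edges from motion", {
  set.seed(72)
  fd <- runif(60, 0.05, 0.3)
  edge <- 2 * fd + rnorm(60, sd = 0.05)
  res <- residualize_confounds(cbind(edge), rnorm(60), cbind(fd = fd), 1:60)
  expect_lt(abs(stats::cor(res$edges[, 1], fd)), 0.05)
})

test_that("held-out rows are cleaned with training coefficients (normal-equations oracle, no leakage)", {
  set.seed(73)
  n <- 30
  covars <- cbind(fd = runif(n), hc = rbinom(n, 1, 0.5))
  edges <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  tr <- 1:20
  res <- residualize_confounds(edges, y, covars, tr)

  xd <- cbind(1, covars)
  bhat <- solve(crossprod(xd[tr, ]), crossprod(xd[tr, ], edges[tr, ]))
  expect_equal(unname(res$edges), unname(edges - xd %*% bhat),
               tolerance = 1e-10)

  # perturbing held-out rows must not change the fitted coefficients
  edges2 <- edges
  edges2[25:30, ] <- edges2[25:30, ] + 100
  res2 <- residualize_confounds(edges2, y, covars, tr)
  expect_equal(res2$coef_edges, res$coef_edges, tolerance = 1e-12)
  expect_equal(res2$coef_outcome, res$coef_outcome, tolerance = 1e-12)
})

test_that("edge-wise F equals the correlation identity and the classical ANOVA F", {
  set.seed(74)
  n <- 24
  y <- rnorm(n)
  edges <- cbind(same = y, indep = rnorm(n), const = rep(0.3, n))
  out <- edgewise_association(edges, y)

  expect_lt(out$p[1], 1e-12)  # edge identical to the outcome
  # independent oracle: per-edge simple regression through lm()
  fs <- summary(stats::lm(edges[, "indep"] ~ y))$fstatistic
  expect_equal(out$F[2], unname(fs[1]), tolerance = 1e-8)
  expect_equal(out$F[3], 0)
  expect_equal(out$p[3], 1)
  expect_error(edgewise_association(edges, rep(1, n)), "constant")

  # two-group toy, hand-computed one-way ANOVA: groups {1,2,3} vs {6,7,8}
  g <- c(0, 0, 0, 1, 1, 1)
  vals <- c(1, 2, 3, 6, 7, 8)
  hand <- edgewise_association(cbind(vals), g)
  expect_equal(hand$F[1], 37.5, tolerance = 1e-10)  # SSB/1 / (SSW/4)
})

test_that("largest connected component matches the union-find oracle", {
  # toy case: edges (1,2),(2,3) form the 2-edge component; (6,7) is smaller
  p <- rep(1, nrow(edge_pairs(10)))
  p[edge_id(1, 2, 10)] <- p[edge_id(2, 3, 10)] <- p[edge_id(6, 7, 10)] <- 0.01
  comp <- largest_connected_component(p, 0.05, 10)
  expect_equal(comp, sort(c(edge_id(1, 2, 10), edge_id(2, 3, 10))))

  expect_equal(largest_connected_component(rep(1, 45), 0.05, 10), integer(0))
  expect_equal(largest_connected_component(rep(0.01, 45), 0.05, 10), 1:45)

  for (s in 1:50) {
    n <- withr::with_seed(s, sample(5:30, 1))
    pairs <- edge_pairs(n)
    p <- withr::with_seed(s + 1000, runif(nrow(pairs)))
    comp <- largest_connected_component(p, 0.2, n)
    oracle_rows <- uf_largest_component(pairs[p < 0.2, , drop = FALSE], n)
    expect_equal(comp, sort(which(p < 0.2)[oracle_rows]))
  }
})

test_that("component-model penalty selection collapses to OLS at vanishing alpha and shrinks at huge alpha", {
  set.seed(75)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- drop(x %*% c(1, -1, 2)) + rnorm(30, sd = 0.1)
  fit <- fit_component_model(x, y, family = "gaussian", alpha_grid = 1e-10)
  xs <- scale(x)
  xd <- cbind(1, xs)
  ols <- solve(crossprod(xd), crossprod(xd, y))
  expect_equal(fit$beta, unname(ols[-1]), tolerance = 1e-6)

  fit_big <- fit_component_model(x, y, family = "gaussian", alpha_grid = 1e10)
  expect_true(all(abs(fit_big$beta) < 1e-6))
})

test_that("a separable binary component achieves perfect held-in accuracy", {
  set.seed(76)
  x <- cbind(c(rnorm(15, -2), rnorm(15, 2)), rnorm(30))
  y <- rep(c(0, 1), each = 15)
  fit <- fit_component_model(x, y, family = "binomial",
                             alpha_grid = 10^seq(-4, 1, length.out = 5),
                             seed = 1)
  pred <- nbsconn:::predict_component(fit, x)
  expect_equal(as.integer(pred > 0.5), y)
})

test_that("network thresholding keeps the largest positive weights with index tie-breaks", {
  wn <- structure(list(weights = rep(0, 45)), class = "weighted_network")
  wn$weights[1:10] <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.15, 0.1)
  expect_equal(threshold_network(wn, 0.5), 1:5)
  expect_equal(threshold_network(wn, 1.0), 1:10)

  wn$weights <- rep(0, 45)
  wn$weights[c(3, 7, 9)] <- c(0.3, 0.3, 0.1)
  expect_equal(threshold_network(wn, 0.5), c(3, 7))  # ceil(1.5) = 2, tie by index

  wn$weights <- rep(0, 45)
  wn$weights[c(2, 5)] <- c(0.4, -0.2)  # negative weights are never kept
  expect_equal(threshold_network(wn, 1.0), 2)
  wn$weights <- rep(0, 45)
  expect_warning(out <- threshold_network(wn, 0.5), "no nonzero")
  expect_length(out, 0)
})

test_that("discovery is deterministic and never-selected edges have weight exactly 0", {
  st <- generate_study(daily_discovery_design(n_regions = 15, seed = 77),
                       recovery_truth(hc_effect = 1.0))
  cfg <- cv_config("hc", n_iterations = 3, alpha_grid = 10^c(-3, -1, 1),
                   seed = 5)
  wn1 <- run_discovery(st, cfg)
  wn2 <- run_discovery(st, cfg)
  expect_identical(wn1$weights, wn2$weights)
  expect_identical(wn1$iteration_performance, wn2$iteration_performance)
  expect_true(all(wn1$weights[wn1$selection_count == 0] == 0))
  expect_true(any(wn1$selection_count == 0))
})

test_that("cycle-window dropping removes exactly the flagged sessions", {
  st <- generate_study(daily_discovery_design(n_regions = 10, seed = 78))
  expect_message(out <- drop_cycle_window(st, c(12, 16)), "10 session")
  expect_equal(nrow(out$sessions), 50L)  # 5 dropped per 30-day block
  expect_false(any(out$sessions$cycle_day >= 12 & out$sessions$cycle_day <= 16))
  expect_length(out$connectomes, 50L)

  expect_identical(drop_cycle_window(st, NULL), st)

  st$sessions$cycle_day[3] <- NA
  expect_warning(expect_message(drop_cycle_window(st, c(12, 16))),
                 "missing cycle_day")
})

test_that("final models transfer exactly to their own study and survive JSON round trips", {
  st <- generate_study(daily_discovery_design(n_regions = 15, seed = 79),
                       recovery_truth(hc_effect = 1.0))
  cfg <- cv_config("hc", n_iterations = 3, alpha_grid = 10^c(-3, -1),
                   seed = 2)
  wn <- run_discovery(st, cfg)
  sel <- threshold_network(wn, 0.5)
  model <- train_final_model(st, sel, cfg)
  expect_length(model$beta, length(sel))

  self <- transfer_predict(model, st)
  expect_gte(self$performance, wn$performance["mean"] - 0.05)

  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(transfer_predict(back, st)$predicted, self$predicted,
               tolerance = 1e-12)

  one <- train_final_model(st, sel[1], cfg)
  expect_length(one$beta, 1L)
})

test_that("hormone models carry confound structure through discovery and transfer", {
  st <- generate_study(daily_discovery_design(n_regions = 15, seed = 80),
                       ground_truth_spec(e2_effect = 1.0, hc_effect = 0,
                                         p4_effect = 0, motion_effect = 0,
                                         dataset_offset_scale = 0,
                                         noise_scale = 0.05))
  cfg <- cv_config("e2", n_iterations = 3, covariates = c("fd", "hc"),
                   alpha_grid = 10^c(-3, -1), seed = 3)
  wn <- run_discovery(st, cfg)
  expect_gt(wn$performance["mean"], 0.5)  # planted signal is recoverable
  sel <- threshold_network(wn, 0.5)
  model <- train_final_model(st, sel, cfg)
  res <- transfer_predict(model, st)
  expect_equal(res$metric, "spearman_rho")
  expect_gt(res$performance, 0.5)
  expect_lt(res$mse, 0.2)
})
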