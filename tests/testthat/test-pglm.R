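test_that("modulators: hand-computed normalization and monotonicity", {
  tt <- data.frame(t_ms = 200 * (1:5), x_vm = c(0, 100, 200, 300, 400),
                   y_vm = 0, phase = "incoming", trial = 1)
  m <- build_modulators(tt, c(400, 0), "incoming")
  expect_equal(m$integrated_path, c(0, 100, 200, 300, 400))
  expect_equal(m$integrated_path_norm, c(-0.5, -0.25, 0, 0.25, 0.5))
  # straight approach to the goal: distance strictly decreasing
  expect_true(all(diff(m$goal_distance) < 0))

  # stationary phase -> zero integrated path, constant-series warning
  still <- data.frame(t_ms = 200 * (1:4), x_vm = 1, y_vm = 1,
                      phase = "incoming", trial = 1)
  # both series are constant here, so two warnings fire
  expect_warning(expect_warning(
    m0 <- build_modulators(still, c(5, 5), "incoming"), "constant"),
    "constant")
  expect_true(all(m0$integrated_path == 0))
  expect_error(build_modulators(tt, c(0, 0), "outgoing"), "no movement")
})

test_that("integrated path is nondecreasing within phases of simulated trials", {
  run <- mk_glm_run(31, n_trials = 6)
  for (j in seq_len(nrow(run$trials))) {
    tt <- run$trajectory[run$trajectory$trial == j, ]
    for (ph in c("outgoing", "incoming")) {
      # short incoming phases can have a constant goal-distance series,
      # which build_modulators flags; only the path series matters here
      m <- suppressWarnings(
        build_modulators(tt, c(run$trials$goal_x[j], run$trials$goal_y[j]),
                         ph))
      expect_true(all(diff(m$integrated_path) >= -1e-9))
    }
  }
})

test_that("the two-run PI model has 24 base regressors", {
  runs <- lapply(c(41, 42), function(s) {
    ts <- generate_trial_set(s)
    p <- agent_params(heading_noise_sd = 8, cruise_speed = 400)
    # 4 trials of each subtask per run, interleaved
    pick <- unlist(lapply(1:4, function(r) {
      vapply(c("PPI", "BPI", "LPI"),
             function(st) which(ts$subtask == st)[r], integer(1))
    }))
    traj <- list(); trials <- list(); t0 <- 0
    for (j in seq_along(pick)) {
      k <- pick[j]
      sm <- simulate_trial(ts[k, ], p,
                           subtask_arena(as.character(ts$subtask[k])),
                           seed = s * 100 + j, t0_ms = t0)
      sm$trajectory$trial <- j
      traj[[j]] <- sm$trajectory
      t0 <- max(sm$trajectory$t_ms)
      tk <- ts[k, ]
      tk$trial <- j
      trials[[j]] <- tk
    }
    build_design(do.call(rbind, traj), do.call(rbind, trials), "pi_model",
                 "integrated_path")
  })
  sess <- combine_run_designs(runs)
  base <- grep("_x_", colnames(sess$X), invert = TRUE, value = TRUE)
  expect_length(base, 24L)  # 4 families x 3 subtasks x 2 runs
  mods <- grep("_x_integrated_path", colnames(sess$X), value = TRUE)
  expect_length(mods, 12L)  # outgoing + incoming x 3 subtasks x 2 runs
})

test_that("subtask model uses phase boxcars and 1-5 difficulty values", {
  run <- mk_glm_run(43, n_trials = 10)
  d <- build_design(run$trajectory, run$trials, "subtask_model")
  expect_true(all(c("start_PPI", "outgoing_PPI", "incoming_PPI",
                    "feedback_PPI", "outgoing_PPI_x_difficulty") %in%
                    colnames(d$X)))
  expect_true(all(run$trials$n_trees %in% 1:5))
})

test_that("combined model orthogonalizes integrated path against goal
          distance without changing the first modulator's column", {
  run <- mk_glm_run(44, n_trials = 8)
  dc <- build_design(run$trajectory, run$trials, "combined")
  dg <- build_design(run$trajectory, run$trials, "pi_model", "goal_distance")
  gp <- dc$X[, "incoming_PPI_x_goal_distance"]
  ip <- dc$X[, "incoming_PPI_x_integrated_path"]
  expect_lt(abs(sum(gp * ip)), 1e-8)
  expect_equal(gp, dg$X[, "incoming_PPI_x_goal_distance"])
})

test_that("GLM recovers planted betas and flags rank deficiency", {
  run <- mk_glm_run(45, n_trials = 8)
  d <- build_design(run$trajectory, run$trials, "pi_model",
                    "integrated_path")
  nv <- d$n_volumes
  bold <- list(data = matrix(100, nv, 3) +
                 2 * matrix(d$X[, "incoming_PPI_x_integrated_path"], nv, 3),
               tr = 2.5, n_volumes = nv)
  f <- fit_and_contrast(d, bold)
  expect_equal(unname(f$beta["incoming_PPI_x_integrated_path"]), 2,
               tolerance = 1e-8)
  expect_lt(f$residual_sd, 1e-8)

  # zero contrast weights -> zero contrast
  w <- stats::setNames(numeric(ncol(d$X)), colnames(d$X))
  expect_equal(fit_and_contrast(d, bold, contrast = w)$contrast_value, 0)

  # duplicated column is named in the error
  d2 <- d
  d2$X <- cbind(d2$X, dup = d2$X[, 1])
  expect_error(fit_and_contrast(d2, bold), "dup")
})

test_that("noisy beta recovery is unbiased within tolerance", {
  run <- mk_glm_run(46, n_trials = 8)
  d <- build_design(run$trajectory, run$trials, "pi_model", "goal_distance")
  nv <- d$n_volumes
  col <- d$X[, "incoming_PPI_x_goal_distance"]
  est <- vapply(1:200, function(s) {
    set.seed(s)
    bold <- list(data = matrix(100 + 1.5 * col + rnorm(nv, 0, 0.5)),
                 tr = 2.5, n_volumes = nv)
    unname(fit_and_contrast(d, bold)$beta["incoming_PPI_x_goal_distance"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.5), 0.1)
})

test_that("GLM residuals are orthogonal to all design columns", {
  run <- mk_glm_run(47, n_trials = 6)
  d <- build_design(run$trajectory, run$trials, "pi_model",
                    "integrated_path")
  set.seed(2)
  bold <- list(data = matrix(rnorm(d$n_volumes, 100), ncol = 1),
               tr = 2.5, n_volumes = d$n_volumes)
  y <- bold$data[, 1]
  f <- fit_and_contrast(d, bold)
  fitted <- cbind(1, d$X) %*% c(f$intercept, f$beta)
  res <- y - fitted
  expect_lt(max(abs(crossprod(d$X, res))), 1e-7 * max(abs(d$X)) * sqrt(sum(res^2)))
})

test_that("Spearman identities and sign conventions hold", {
  x <- list(cumsum(rnorm(50)))
  mc <- modulator_correlation_test(x, x, n_shuffle = 50, seed = 1)
  expect_equal(mc$rho, 1)
  mc2 <- modulator_correlation_test(x, lapply(x, function(v) -v),
                                    n_shuffle = 50, seed = 1)
  expect_equal(mc2$rho, -1)
  # proximity convention flips the sign
  mc3 <- modulator_correlation_test(x, x, n_shuffle = 50, seed = 1,
                                    proximity = TRUE)
  expect_equal(mc3$rho, -1)
  expect_error(modulator_correlation_test(list(rep(1, 20)),
                                          list(rnorm(20)), 10, 1),
               "constant")
})

test_that("group sign-flip p is well calibrated under the null", {
  set.seed(99)
  ps <- vapply(1:60, function(rep_i) {
    gp <- replicate(15, rnorm(60), simplify = FALSE)
    ip <- replicate(15, rnorm(60), simplify = FALSE)
    modulator_correlation_test(gp, ip, n_shuffle = 200,
                               seed = rep_i)$p_group
  }, numeric(1))
  # surrogate p values are discrete (rank-based), hence the tie warning
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(mean(ps < 0.05) < 0.15)
})
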