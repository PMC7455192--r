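test_that("equal-count bins match the rank oracle", {
  expect_equal(unname(table(quantile_bins(1:100, 5))), rep(20L, 5),
               ignore_attr = TRUE)
  # boundaries fall after ranks 20, 40, 60, 80
  expect_equal(quantile_bins(1:100, 5)[c(20, 21, 80, 81)], c(1L, 2L, 4L, 5L))
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(100 + i)
    k <- sample(3:5, 1)
    oracle <- as.integer(ceiling(k * rank(x, ties.method = "first") /
                                   length(x)))
    expect_identical(quantile_bins(x, k), oracle)
  }
  expect_warning(quantile_bins(c(1, 1, 1, 2), 5), "distinct")
})

test_that("centering: grand-mean between, subject-mean within", {
  d <- data.frame(subject = rep(c("a", "b"), each = 2),
                  w = c(1, 3, 10, 30), b = rep(c(2, 6), each = 2))
  out <- prepare_predictors(d, within = "w", between = "b", n_bins = 2)
  expect_equal(out$w_c, c(-1, 1, -10, 10))
  expect_equal(as.numeric(tapply(out$w_c, out$subject, sum)), c(0, 0))
  expect_equal(sum(out$b_c), 0)
  d$const <- 5
  expect_warning(prepare_predictors(d, between = "const"), "zero variance")
})

test_that("model specs mirror the design table", {
  m1b <- build_model_spec("1b")
  expect_equal(m1b$within, c("subtask", "incoming_distance"))
  expect_equal(m1b$between, "apoe")
  expect_equal(m1b$covariates, c("age", "sex"))
  expect_equal(m1b$random, c("subject", "site"))

  m2c <- build_model_spec("2c")
  expect_equal(m2c$criterion, "mean_move_to_boundary")
  expect_equal(m2c$between, "apoe")
  expect_length(m2c$within, 0)

  m6 <- build_model_spec("6")
  expect_true("pmec_glr" %in% m6$between)
  expect_equal(m6$random, "subject")
  expect_true("pmec_glr:subtask" %in% m6$interactions)
  expect_error(build_model_spec("9z"), "unknown")
})

test_that("fixed-effects fallback reproduces the two-sample t test", {
  set.seed(1)
  d <- data.frame(g = factor(rep(c("a", "b"), each = 12)),
                  y = rnorm(24), subject = 1:24)
  spec <- structure(list(model_id = "t", criterion = "y",
                         within = character(), between = "g",
                         covariates = character(), random = character(),
                         interactions = character()),
                    class = "model_spec")
  f <- fit_lmm(spec, d)
  tt <- t.test(y ~ g, d, var.equal = TRUE)
  expect_equal(f$backend, "lm")
  expect_equal(f$anova$statistic, unname(tt$statistic^2), tolerance = 1e-10)
})

test_that("mixed model recovers a planted slope on a centered predictor", {
  spec <- structure(list(model_id = "r", criterion = "y", within = "x",
                         between = character(), covariates = character(),
                         random = "subject", interactions = character()),
                    class = "model_spec")
  est <- vapply(1:15, function(s) {
    set.seed(s)
    n <- 60; k <- 4
    d <- data.frame(subject = rep(1:n, each = k), x = rnorm(n * k))
    d$y <- 2 * d$x + rep(rnorm(n, 0, 0.5), each = k) + rnorm(n * k)
    f <- fit_lmm(spec, d)
    unname(lme4::fixef(f$fit)["x"])
  }, numeric(1))
  expect_lt(max(abs(est - 2)), 0.2)
})

test_that("type-II tests are invariant to term order", {
  set.seed(9)
  n <- 30; k <- 4
  d <- data.frame(subject = rep(1:n, each = k),
                  apoe = rep(rep(0:1, each = n / 2), each = k),
                  subtask = factor(sample(c("PPI", "BPI", "LPI"), n * k,
                                          TRUE)),
                  incoming_distance = runif(n * k, 800, 7920))
  d$performance <- 500 - 0.01 * d$incoming_distance +
    20 * d$apoe * (d$subtask == "PPI") +
    rep(rnorm(n, 0, 15), each = k) + rnorm(n * k, 0, 30)
  base <- structure(list(model_id = "x", criterion = "performance",
                         within = c("subtask", "incoming_distance"),
                         between = "apoe", covariates = character(),
                         random = "subject",
                         interactions = c("subtask:incoming_distance",
                                          "apoe:subtask",
                                          "apoe:incoming_distance")),
                    class = "model_spec")
  shuf <- base
  shuf$within <- rev(base$within)
  shuf$interactions <- base$interactions[c(3, 1, 2)]
  f1 <- fit_lmm(base, d)
  f2 <- fit_lmm(shuf, d)
  for (tm in f1$anova$term) {
    i2 <- vapply(strsplit(f2$anova$term, ":"),
                 function(tv) setequal(tv, strsplit(tm, ":")[[1]]),
                 logical(1))
    expect_equal(f2$anova$statistic[i2],
                 f1$anova$statistic[f1$anova$term == tm],
                 tolerance = 1e-6)
  }
})

test_that("tukey adjustment is monotone, familywise-correct, and matches
          the marginal-means machinery on balanced designs", {
  expect_equal(tukey_adjust(p = 0.02, df = 30, n_means = 1), 0.02)
  expect_gt(tukey_adjust(p = 0.02, df = 30, n_means = 3), 0.02)

  set.seed(2)
  d <- data.frame(g = gl(3, 20), y = rnorm(60))
  fit <- stats::lm(y ~ g, d)
  ec <- as.data.frame(emmeans::contrast(emmeans::emmeans(fit, "g"),
                                        "pairwise", adjust = "tukey"))
  expect_equal(tukey_adjust(t = ec$t.ratio, df = ec$df, n_means = 3),
               ec$p.value, tolerance = 1e-8)

  # familywise error under the null, three-group one-way design
  set.seed(4)
  fw <- mean(vapply(1:400, function(i) {
    d <- data.frame(g = gl(3, 15), y = rnorm(45))
    fit <- stats::lm(y ~ g, d)
    ec <- as.data.frame(emmeans::contrast(emmeans::emmeans(fit, "g"),
                                          "pairwise", adjust = "none"))
    any(tukey_adjust(t = ec$t.ratio, df = ec$df, n_means = 3) < 0.05)
  }, logical(1)))
  expect_lt(fw, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

gen_m6 <- function(seed, n_sub = 40, n_tr = 12, beta = 40) {
  set.seed(seed)
  sub <- rep(sprintf("S%02d", 1:n_sub), each = n_tr)
  subt <- factor(sample(c("PPI", "BPI", "LPI"), n_sub * n_tr, TRUE))
  inc <- runif(n_sub * n_tr, 800, 7920)
  preds <- sapply(LETTERS[1:5], function(l) rep(rnorm(n_sub), each = n_tr))
  y <- 500 - 0.02 * inc - 30 * (subt == "PPI") + beta * preds[, 1] +
    rnorm(n_sub * n_tr, 0, 50) + rep(rnorm(n_sub, 0, 20), each = n_tr)
  data.frame(subject = sub, subtask = subt, incoming_distance = inc,
             performance = y, preds)
}

test_that("exploratory buildup drops collinear and null candidates", {
  d <- gen_m6(1)
  # perfectly correlated pair: exactly one enters
  d$B <- d$A
  res <- suppressWarnings(model6_buildup(d, candidates = c("A", "B")))
  expect_equal(res$dropped_collinear, "B")
  expect_equal(res$kept, "A")

  # all-null predictors: the final model reduces to the base terms in the
  # clear majority of datasets (each null has an ~alpha-level chance of
  # slipping through screening plus elimination)
  n_base <- 0L
  for (s in 1:5) {
    res0 <- suppressWarnings(model6_buildup(gen_m6(s, beta = 0),
                                            candidates = LETTERS[1:5]))
    expect_true(all(c("subtask", "incoming_distance") %in% res0$final_terms))
    if (length(res0$kept) == 0) n_base <- n_base + 1L
  }
  expect_gte(n_base, 3L)
})

test_that("buildup recovers a single planted predictor in >= 18/20 seeds", {
  ok <- 0L
  for (s in 1:20) {
    res <- suppressWarnings(model6_buildup(gen_m6(s),
                                           candidates = LETTERS[1:5]))
    if (identical(res$kept, "A")) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("the stacked-distance model detects distance-type-specific
          genotype effects", {
  set.seed(12)
  n <- 40; k <- 8
  d <- data.frame(subject = rep(sprintf("S%02d", 1:n), each = k),
                  apoe = rep(rep(0:1, each = n / 2), each = k),
                  age = rep(round(runif(n, 18, 75)), each = k),
                  sex = rep(sample(c("male", "female"), n, TRUE), each = k),
                  subtask = factor(sample(c("PPI", "BPI", "LPI"), n * k,
                                          TRUE)),
                  outgoing_distance = runif(n * k, 2000, 16000),
                  incoming_distance = runif(n * k, 800, 7920))
  # performance depends on incoming distance more strongly in carriers
  d$performance <- 600 - 0.01 * d$incoming_distance -
    0.015 * d$apoe * d$incoming_distance - 0.005 * d$outgoing_distance +
    rep(rnorm(n, 0, 10), each = k) + rnorm(n * k, 0, 25)
  long <- stack_path_distances(d)
  expect_equal(nrow(long), 2 * nrow(d))
  expect_setequal(unique(long$distance_type), c(0, 1))
  f <- suppressWarnings(fit_lmm(build_model_spec("1c"), long))
  i3 <- grepl("apoe", f$anova$term) & grepl("path_distance", f$anova$term) &
    grepl("distance_type", f$anova$term)
  expect_true(any(i3))
  expect_lt(f$anova$p_value[i3], 0.05)
})
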