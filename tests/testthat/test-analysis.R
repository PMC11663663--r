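test_that("accuracy aggregation and error-rate complementarity", {
  tr <- toy_trials()
  agg <- aggregate_accuracy(tr, by = c("type", "block"))
  expect_equal(nrow(agg), 4L)
  expect_true(all(agg$accuracy + agg$error_rate == 1))
  expect_equal(unique(agg$accuracy), 0.5)

  all_right <- tr; all_right$correct <- 1L
  agg1 <- aggregate_accuracy(all_right, by = "type")
  expect_equal(agg1$accuracy, c(1, 1))
  expect_equal(agg1$error_rate, c(0, 0))

  expect_error(aggregate_accuracy(tr, by = character(0)), "at least one")
  expect_error(aggregate_accuracy(tr, by = "nonexistent"), "lacks columns")
})

test_that("subject accuracy pools the capacity grid before comparing models", {
  tr <- rbind(
    data.frame(model = "BRDIVA", beta = rep(c(0.1, 10), each = 4), type = 1L,
               participant = 1L, block = 1L, trial = 1:4,
               stimulus = 1:4, response = 1L,
               correct = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)),
    data.frame(model = "DIVA", beta = NA_real_, type = 1L, participant = 1L,
               block = 1L, trial = 1:4, stimulus = 1:4, response = 1L,
               correct = c(1L, 0L, 1L, 0L))
  )
  s <- subject_accuracy(tr)
  expect_equal(s$accuracy[s$model == "BRDIVA"], 0.5)  # mean of 1 and 0 per beta
  expect_equal(s$accuracy[s$model == "DIVA"], 0.5)
})

test_that("OLS identities: group means, exact fits, rank deficiency", {
  # balanced two-group data: non-reference coefficient = difference in means
  d <- data.frame(y = c(1, 3, 2, 10, 14, 12), g = rep(c("a", "b"), each = 3))
  fit <- fit_ols(y ~ g, d, ref = c(g = "a"))
  expect_equal(ols_coef(fit, "gb"), mean(d$y[4:6]) - mean(d$y[1:3]), tolerance = 1e-12)
  expect_equal(ols_coef(fit, "(Intercept)"), 2, tolerance = 1e-12)

  # exact linear relation recovers slope and intercept with zero residuals
  d2 <- data.frame(x = seq(0, 5, by = 0.5))
  d2$y <- 2 * d2$x + 1
  fit2 <- suppressWarnings(fit_ols(y ~ x, d2))  # exact fit: summary.lm warns
  expect_equal(ols_coef(fit2, "x"), 2, tolerance = 1e-12)
  expect_equal(ols_coef(fit2, "(Intercept)"), 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(attr(fit2, "fit")))), 1e-12)

  # collinear predictors are a loud error naming the aliased term
  d3 <- data.frame(y = rnorm(10), x1 = 1:10)
  d3$x2 <- 2 * d3$x1
  expect_error(fit_ols(y ~ x1 + x2, d3), "collinear.*x2")
  expect_error(ols_coef(fit2, "zzz"), "no term")
  expect_error(fit_ols(y ~ x, d2, ref = c(g = "a")), "no column")
})

test_that("OLS recovers a generating slope within 2 standard errors", {
  set.seed(99)
  hits <- vapply(1:50, function(i) {
    x <- runif(60)
    y <- 1 + 0.8 * x + rnorm(60, sd = 0.3)
    fit <- fit_ols(y ~ x, data.frame(x = x, y = y))
    abs(ols_coef(fit, "x") - 0.8) <= 2 * fit$std_error[fit$term == "x"]
  }, logical(1))
  expect_gte(mean(hits), 0.85)  # nominal 95% coverage
})

test_that("t-tests match the closed-form oracles to 1e-10", {
  set.seed(4)
  a <- rnorm(30); b <- rnorm(30, 0.3)
  pt <- paired_t(a, b)
  po <- paired_t_oracle(a, b)
  expect_equal(pt$statistic, po$statistic, tolerance = 1e-10)
  expect_equal(pt$df, 29)
  expect_equal(pt$p.value, po$p.value, tolerance = 1e-10)

  b_long <- c(b, rnorm(10, 0.3))
  tt <- two_sample_t(a, b_long)
  to <- two_sample_t_oracle(a, b_long)
  expect_equal(tt$df, 30 + 40 - 2)
  expect_equal(tt$statistic, to$statistic, tolerance = 1e-10)
  tt2 <- two_sample_t(a, b)
  to2 <- two_sample_t_oracle(a, b)
  expect_equal(tt2$statistic, to2$statistic, tolerance = 1e-10)
  expect_equal(tt2$p.value, to2$p.value, tolerance = 1e-10)
})

test_that("paired t hand-computed example and degenerate cases", {
  # differences 1, 2, 3: t = 2 / (1/sqrt(3)) = 2*sqrt(3)
  b <- c(5, 5, 5); a <- b + c(1, 2, 3)
  pt <- paired_t(a, b)
  expect_equal(pt$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(pt$df, 2)
  # mean-zero differences with positive variance give t = 0
  expect_equal(paired_t(c(1, 2, 3), c(2, 2, 2))$statistic, 0)
  # constant differences are undefined, not silently zero
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_t(1, 1), "n >= 2")
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("learning curves cover every cell with blocks in order", {
  tr <- shj_experiment(model = "DIVA", types = c(1, 6), n_participants = 3,
                       n_blocks = 5, base_seed = 3)
  lc <- learning_curves(tr)
  expect_equal(nrow(lc), 2 * 5)
  expect_equal(lc$block[lc$type == 1], 1:5)
  expect_true(all(lc$accuracy >= 0 & lc$accuracy <= 1))
  expect_true(all(abs(lc$accuracy + lc$error_rate - 1) < 1e-12))
  expect_error(learning_curves(tr[0, ]), "empty")
})

test_that("hidden geometry of the zero-weight state and trained shapes", {
  m0 <- diva(weight_range = 0, seed = 1)
  g <- hidden_geometry(m0, shj_assignment(4))
  expect_equal(dim(g$coordinates), c(8L, 2L))
  expect_true(all(g$coordinates == 0.5))
  expect_equal(g$exception_distance, 0)

  # no exception metric outside the rule-plus-exception types
  g1 <- hidden_geometry(m0, shj_assignment(1))
  expect_true(is.na(g1$exception_distance))
  expect_equal(dim(g1$coordinates), c(8L, 2L))

  mb <- br_diva(weight_range = 0, seed = 1)
  gb <- hidden_geometry(mb, shj_assignment(3))
  expect_true(all(gb$coordinates == 0))  # mu of the zero-weight encoder
  expect_equal(gb$exception_distance, 0)
})

test_that("rule/exception curves split the trials correctly", {
  tr <- toy_trials()
  tr$type <- 5L
  tr$correct <- 1L
  rc <- rule_exception_curves(tr, 5)
  expect_equal(nrow(rc), length(unique(tr$block)))
  expect_true(all(rc$rule_error == 0))
  expect_true(all(rc$exception_error == 0))
  expect_equal(attr(rc, "convergence_block"), 1L)
  expect_error(rule_exception_curves(tr, 1), "Types 3-5")
})

test_that("analyses are pure functions of the saved trial table", {
  tr <- shj_experiment(model = "BRDIVA", types = c(1, 2), n_participants = 3,
                       n_blocks = 4, betas = c(0.05, 0.2), base_seed = 8)
  path <- tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- read_trials_csv(path)
  f1 <- fit_difficulty(tr)
  f2 <- fit_difficulty(back)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-12)
  expect_equal(aggregate_accuracy(tr, "type"), aggregate_accuracy(back, "type"),
               tolerance = 1e-12)
  unlink(path)
})

test_that("coef, plot and simulate methods round out the S3 surface", {
  d <- data.frame(y = c(1.1, 1.9, 3.2, 4.9), x = c(0, 1, 2, 4))
  cf <- coef(fit_ols(y ~ x, d))
  expect_named(cf, c("(Intercept)", "x"))

  tr <- shj_experiment(model = "DIVA", types = c(1, 4), n_participants = 2,
                       n_blocks = 3, base_seed = 6)
  grDevices::pdf(NULL)
  m <- plot(tr)
  grDevices::dev.off()
  expect_equal(dim(m), c(3L, 2L))
  expect_true(all(m >= 0 & m <= 1))

  mod <- diva(seed = 2)
  r1 <- simulate(mod, nsim = 3, seed = 1)
  r2 <- simulate(mod, nsim = 3, seed = 1)
  expect_identical(r1, r2)  # deterministic model, no learning during simulate
  expect_equal(dim(r1), c(8L, 3L))
  b <- br_diva(seed = 2)
  rb <- simulate(b, nsim = 5, seed = 3)
  expect_true(all(rb %in% 1:2))
})
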