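test_that("r2 and rmse follow their definitions", {
  perf <- evaluate_r2_rmse(c(1, 2, 4), c(1, 2, 3))
  expect_equal(perf$rmse, sqrt(1 / 3), tolerance = 1e-12)  # 0.5774
  expect_equal(round(perf$rmse, 4), 0.5774)
  expect_equal(perf$r2, 0.5)  # SS_res = 1, SS_tot = 2
  exact <- evaluate_r2_rmse(c(1, 2, 3), c(1, 2, 3))
  expect_equal(exact$r2, 1)
  expect_equal(exact$rmse, 0)
  at_mean <- evaluate_r2_rmse(rep(2, 3), c(1, 2, 3))
  expect_equal(at_mean$r2, 0)
  flat <- evaluate_r2_rmse(c(1, 2), c(5, 5))
  expect_true(is.na(flat$r2))
  expect_gt(flat$rmse, 0)
})

test_that("ridge with vanishing penalty equals OLS on full-rank designs", {
  X <- make_design(n = 30, p = 4)
  y <- 3 + X %*% c(1.5, -2, 0.7, 0.1) + rnorm(30, 0, 0.2)
  m <- fit_rt_model(X, y, regression_spec("ridge", 1e-10))
  ols <- lm(y ~ X)
  expect_equal(unname(coef(m)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(predict(m, X), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("noiseless laws are recovered exactly", {
  X <- make_design(n = 25, p = 1, seed = 3)
  mass_sqrt <- sqrt(500 + 10 * abs(X[, 1]))
  Xf <- cbind(mass_sqrt = mass_sqrt)
  y <- 3 + 0.5 * mass_sqrt
  m <- fit_rt_model(Xf, y, regression_spec("ridge", 1e-8))
  expect_lt(evaluate_r2_rmse(predict(m, Xf), y)$rmse, 1e-6)
  expect_equal(unname(coef(m)), c(3, 0.5), tolerance = 1e-5)
  # linear family interpolates a saturated (intercept + p = n) design
  Xs <- make_design(n = 5, p = 4, seed = 8)
  ml <- fit_rt_model(Xs, rnorm(5), regression_spec("linear"))
  expect_equal(ml$training_stats$r2, 1, tolerance = 1e-9)
  expect_lt(ml$training_stats$rmse, 1e-9)
})

test_that("degenerate fits are handled", {
  X <- make_design(n = 10, p = 2)
  expect_error(fit_rt_model(X[1, , drop = FALSE], 1), "insufficient")
  const <- fit_rt_model(X, rep(4.2, 10), regression_spec("lasso", 0.01))
  expect_equal(unique(predict(const, X)), 4.2)
  expect_warning(
    fit_rt_model(matrix(1, 5, 2, dimnames = list(NULL, c("a", "b"))),
                 rnorm(5)),
    "intercept-only")
  # heavy lasso penalty shrinks every slope to zero -> mean prediction
  y <- 3 + X %*% c(1, -1)
  big <- fit_rt_model(X, y, regression_spec("lasso", 1e4))
  expect_equal(unique(round(predict(big, X), 9)), round(mean(y), 9))
})

test_that("lasso support is non-increasing along the penalty path", {
  X <- make_design(n = 40, p = 6, seed = 21)
  y <- X %*% c(2, -1.5, 1, 0.5, 0.2, 0) + rnorm(40, 0, 0.3)
  nz <- vapply(c(0.001, 0.01, 0.1, 0.5, 2), function(a) {
    m <- fit_rt_model(X, y, regression_spec("lasso", a))
    sum(abs(m$coefficients) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("gbt fits nonlinear signal and is seed-reproducible", {
  X <- make_design(n = 60, p = 2, seed = 5)
  y <- 2 + sin(X[, 1] * 2) + (X[, 2] > 0)
  m1 <- fit_rt_model(X, y, regression_spec("gbt", seed = 7))
  m2 <- fit_rt_model(X, y, regression_spec("gbt", seed = 7))
  expect_identical(predict(m1, X), predict(m2, X))
  expect_lt(m1$training_stats$rmse, 0.1)
})

test_that("models survive a JSON save/load round trip", {
  X <- make_design(n = 20, p = 3, seed = 13)
  y <- 1 + X %*% c(0.5, -0.5, 2) + rnorm(20, 0, 0.05)
  for (spec in list(regression_spec("ridge", 0.05),
                    regression_spec("lasso", 0.01),
                    regression_spec("gbt"))) {
    m <- fit_rt_model(X, y, spec)
    f <- withr::local_tempfile(fileext = ".json")
    save_rt_model(m, f)
    m2 <- load_rt_model(f)
    expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  }
})

test_that("learning curves produce one row per family and size, with truncation", {
  db <- generate_rt_database(generator_config("gradient", n_studies = 6,
                                              seed = 2))
  lc <- run_learning_curve(db, regression_spec("linear"), size_step = 3,
                           seed = 1)
  expect_identical(lc$n_datasets, c(3L, 6L))
  expect_true(all(lc$rmse >= 0) && all(lc$r2 <= 1))
  expect_message(
    run_learning_curve(db, regression_spec("linear"), seed = 1,
                       sizes = c(3, 12)),
    "truncated")
  expect_error(run_learning_curve(db[db$study == 1, ],
                                  regression_spec("linear")),
               "at least 2 studies")
})

test_that("rank_models orders by minimal passing size with documented tie-breaks", {
  res <- tibble::tibble(
    family = c("A", "A", "B", "B", "C", "C", "D", "D"),
    n_datasets = c(6, 9, 6, 9, 6, 9, 6, 9),
    r2 = c(0.95, 0.96, 0.5, 0.95, 0.95, 0.96, 0.2, 0.3),
    rmse = c(0.1, 0.09, 0.6, 0.1, 0.2, 0.1, 0.9, 0.8)
  )
  ranked <- rank_models(res, r2_threshold = 0.9, rmse_threshold = 0.25)
  # A and C both pass first at size 6; A wins on lower rmse; D never passes
  expect_identical(ranked$family, c("A", "C", "B", "D"))
  expect_identical(ranked$min_passing_size, c(6, 6, 9, NA))
  expect_false(ranked$passes[4])
})
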