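test_that("univariate initial estimator is textbook OLS", {
  f <- fit_univariate_initial(c(1, 2, 3), c(1, 2, 3))
  expect_equal(f$beta0, 1)
  expect_equal(f$q0, c(1, 2, 3))
  expect_equal(fit_univariate_initial(c(1, 1, 1), c(1, 2, 3))$beta0, 0)
  f2 <- fit_univariate_initial(c(0, 1, 1, 2), c(0, 0, 1, 1))
  expect_equal(f2$beta0, 1)
  expect_equal(f2$q0, c(0.5, 0.5, 1.5, 1.5))
  expect_error(fit_univariate_initial(1:4, rep(2, 4)),
               class = "tmlevim_degenerate_error")
})

test_that("cross-validated lasso recovers a single linear signal", {
  set.seed(3)
  n <- 200; p <- 8
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- 2 * x[, 4] + rnorm(n, sd = 0.5)
  fit <- fit_lasso_learner(x, y, folds = 5, seed = 1)
  slopes <- fit$coef[-1]
  expect_gt(abs(slopes[["x4"]]), 1.5)
  expect_true(all(abs(slopes[setdiff(names(slopes), "x4")]) < 0.3))
})

test_that("full shrinkage gives a constant mean prediction", {
  set.seed(4)
  x <- matrix(rnorm(60), 30, 2)
  y <- rnorm(30)
  fit <- glmnet::glmnet(x, y, lambda = 1e6)
  expect_equal(as.numeric(predict(fit, x)), rep(mean(y), 30), tolerance = 1e-6)
  # and our learner's zero-variance fallback predicts the mean too
  fit0 <- suppressWarnings(fit_lasso_learner(matrix(1, 30, 2), y, folds = 3, seed = 1))
  expect_equal(fit0$fitted, rep(mean(y), 30))
})

test_that("a duplicated column barely changes lasso predictions", {
  set.seed(9)
  n <- 150
  x <- matrix(rnorm(n * 5), n, 5)
  y <- x[, 1] + rnorm(n, sd = 0.5)
  f1 <- fit_lasso_learner(x, y, folds = 5, seed = 1)
  f2 <- fit_lasso_learner(cbind(x, x[, 1]), y, folds = 5, seed = 1)
  expect_lt(mean((f1$fitted - f2$fitted)^2), 0.05 * var(y))
})

test_that("lasso learner is bitwise reproducible for a fixed seed", {
  set.seed(12)
  x <- matrix(rnorm(300), 60, 5)
  y <- rnorm(60)
  f1 <- fit_lasso_learner(x, y, folds = 5, seed = 99)
  f2 <- fit_lasso_learner(x, y, folds = 5, seed = 99)
  expect_identical(f1$coef, f2$coef)
})

test_that("held-out lasso risk on null data stays near the intercept model", {
  set.seed(21)
  n <- 200; p <- 30
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  fit <- fit_lasso_learner(x[1:150, ], y[1:150], folds = 5, seed = 2)
  xnew <- x[151:200, ]
  risk_lasso <- mean((y[151:200] - fit$predict(xnew))^2)
  risk_mean <- mean((y[151:200] - mean(y[1:150]))^2)
  expect_lt(risk_lasso, risk_mean * 1.25)
})

test_that("grand fit supports zero-substitution prediction", {
  set.seed(6)
  n <- 300
  v <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * v[, 1] + rnorm(n, sd = 0.5)
  d <- vim_dataset(v, outcome = y)
  g <- grand_initial(d, learner_lm())
  # zeroing a zero-coefficient column leaves predictions unchanged
  g0 <- g; g0$coef[["b"]] <- 0
  expect_equal(predict_zero(g0, d, "b"), g0$fitted)
  # zeroing the causal column shifts fitted values by about -2 * V1
  shift <- predict_zero(g, d, "a") - g$fitted
  expect_equal(shift, -unname(g$coef[["a"]]) * v[, 1])
  expect_equal(g$coef[["a"]], 2, tolerance = 0.1)
})

test_that("p = 1 grand fit matches a single-predictor fit", {
  set.seed(8)
  v <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "a"))
  y <- v[, 1] + rnorm(50)
  d <- vim_dataset(v, outcome = y)
  g <- grand_initial(d, learner_lm())
  expect_equal(unname(g$coef), unname(coef(lm(y ~ v))))
})

test_that("offset regression slope matches hand least squares", {
  v <- matrix(c(1, 2), 2, 1, dimnames = list(NULL, "a"))
  d <- vim_dataset(v, outcome = c(2, 4))
  g <- list(fitted = c(1, 1), coef = c("(Intercept)" = 1, a = 0))
  class(g) <- "grand_fit"
  f <- offset_initial_for(g, d, 1)
  expect_equal(f$beta0, 1.4)  # (1*1 + 3*2) / (1 + 4)
  expect_equal(f$q0, c(1, 1) + 1.4 * c(1, 2))
  # offset equal to Y exactly gives zero slope
  gy <- list(fitted = c(2, 4), coef = c("(Intercept)" = 0, a = 0))
  class(gy) <- "grand_fit"
  expect_equal(offset_initial_for(gy, d, 1)$beta0, 0)
  # zero offset with Y = 3A recovers slope 3
  g0 <- list(fitted = c(0, 0), coef = c("(Intercept)" = 0, a = 0))
  class(g0) <- "grand_fit"
  d3 <- vim_dataset(v, outcome = c(3, 6))
  expect_equal(offset_initial_for(g0, d3, 1)$beta0, 3)
})

test_that("offset path with an A-blind grand fit mirrors the univariate path", {
  set.seed(10)
  n <- 200
  a <- rnorm(n)
  y <- 0.8 * a + rnorm(n)
  d <- vim_dataset(matrix(a, dimnames = list(NULL, "a")), outcome = y)
  # grand fit that ignores a: intercept-only at mean(y)
  g <- list(fitted = rep(mean(y), n), coef = c("(Intercept)" = mean(y), a = 0))
  class(g) <- "grand_fit"
  f_off <- offset_initial_for(g, d, 1)
  f_uni <- fit_univariate_initial(y, a)
  # same slope up to the intercept convention on mean-centred Y
  expect_equal(f_off$beta0, sum((y - mean(y)) * a) / sum(a^2))
  expect_equal(f_off$beta0, f_uni$beta0, tolerance = 0.05)
})

test_that("confounding fit falls back to the sample mean without confounders", {
  d <- tiny_cluster()
  g <- fit_confounding(d, 1, integer(0))
  expect_equal(g$g, rep(mean(d$v[, 1]), nrow(d$v)))
  expect_equal(g$n_confounders, 0L)
  expect_error(fit_confounding(d, 1, c(1, 2)), class = "tmlevim_input_error")
})

test_that("null confounding yields a nearly constant g", {
  set.seed(14)
  n <- 400
  v <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  d <- vim_dataset(v, outcome = rnorm(n))
  g <- fit_confounding(d, 1, 2:6, learner = learner_lasso(folds = 5))
  expect_lt(sd(g$g), 0.2 * sd(d$v[, 1]))
})

test_that("perfect confounding produces a degenerate clever covariate downstream", {
  n <- 50
  a <- rnorm(n)
  v <- cbind(a = a, w = a)
  d <- vim_dataset(v, outcome = rnorm(n))
  g <- fit_confounding(d, 1, 2L, learner = learner_lm())
  expect_equal(g$g, a)
  init <- fit_univariate_initial(d$y, a)
  expect_error(tmle_single(d, 1, init, g), class = "tmlevim_degenerate_error")
})
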