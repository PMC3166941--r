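test_that("clever covariate is the residual of A on its confounding fit", {
  expect_equal(clever_covariate(c(1, 2, 3), c(0, 0, 0)), c(1, 2, 3))
  expect_equal(clever_covariate(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(clever_covariate(c(2, 4), confounding_fit(c(1, 1))), c(1, 3))
  expect_error(clever_covariate(1:3, 1:2), class = "tmlevim_shape_error")
})

test_that("fluctuation coefficient is the no-intercept least-squares slope", {
  expect_equal(fit_epsilon(c(0, 0, 0), c(1, 2, 3)), 0)
  expect_equal(fit_epsilon(c(1, 2, 3), c(1, 0, 1)), 2)
  expect_equal(fit_epsilon(c(1, -1), c(1, 1)), 0)
  expect_error(fit_epsilon(c(1, 2), c(0, 0)), class = "tmlevim_degenerate_error")
})

test_that("fluctuation matches a generic no-intercept regression oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    r <- rnorm(n)
    c <- rnorm(n)
    oracle <- unname(coef(lm(r ~ c - 1)))
    expect_equal(fit_epsilon(r, c), oracle, tolerance = 1e-10)
  }
})

test_that("update step adds the fluctuation to estimate and fitted values", {
  expect_equal(update_beta(0.5, 0), 0.5)
  expect_equal(update_beta(0, 0.3), 0.3)
  expect_equal(update_beta(1.2, -0.2), 1.0)
  init <- initial_fit(1, c(1, 1))
  expect_equal(update_fitted(init, 0, c(5, 5)), c(1, 1))
  expect_equal(update_fitted(initial_fit(0, c(0, 0)), 1, c(1, 2)), c(1, 2))
  expect_equal(update_fitted(init, 0.5, c(2, -2)), c(2, 0))
})

test_that("influence-curve variance matches hand computation", {
  expect_equal(influence_curve_variance(c(1, 2), c(1, 2), c(1, -1)), 0)
  # n=2, c=(1,-1), residuals (1,1): mean c^2 = 1, IC = (1,-1), sigma2 = 2/4
  expect_equal(influence_curve_variance(c(2, 1), c(1, 0), c(1, -1)), 0.5)
  # doubling residuals quadruples the variance
  v1 <- influence_curve_variance(c(2, 1), c(1, 0), c(1, -1))
  v2 <- influence_curve_variance(c(3, 2), c(1, 0), c(1, -1))
  expect_equal(v2, 4 * v1)
  expect_error(influence_curve_variance(1:3, 1:3, rep(0, 3)),
               class = "tmlevim_degenerate_error")
})

test_that("Wald test follows the standard normal reference", {
  expect_equal(test_statistic(0, 1), list(t_stat = 0, p_value = 1))
  expect_equal(test_statistic(1.959964, 1)$p_value, 0.05, tolerance = 1e-6)
  expect_equal(test_statistic(-2.575829, 1)$p_value, 0.01, tolerance = 1e-6)
  # sigma2 = 0 conventions
  expect_equal(test_statistic(0, 0)$p_value, 1)
  expect_equal(test_statistic(2, 0)$t_stat, Inf)
  expect_equal(test_statistic(2, 0)$p_value, 0)
})

test_that("tmle_single reproduces the four-point hand example", {
  d <- vim_dataset(matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "A")),
                   outcome = c(1, 2, 3, 4))
  fit <- tmle_single(d, 1, initial_fit(2, c(1.5, 1.5, 3.5, 3.5)),
                     confounding_fit(rep(0.5, 4)))
  expect_equal(fit$epsilon, 0)
  expect_equal(fit$beta_star, 2)
})

test_that("OLS initial with constant-mean g gives exactly zero fluctuation", {
  set.seed(11)
  for (i in 1:5) {
    n <- 60
    a <- rnorm(n)
    y <- 1 + 0.5 * a + rnorm(n)
    d <- vim_dataset(matrix(a, dimnames = list(NULL, "A")), outcome = y)
    init <- fit_univariate_initial(y, a)
    fit <- tmle_single(d, 1, init, confounding_fit(rep(mean(a), n)))
    expect_equal(fit$epsilon, 0, tolerance = 1e-8)
    expect_equal(fit$beta_star, init$beta0, tolerance = 1e-8)
  }
})

test_that("rescaling the outcome rescales beta and se but not T or p", {
  set.seed(5)
  n <- 80
  a <- rnorm(n)
  w <- 0.5 * a + rnorm(n)
  y <- a + w + rnorm(n)
  d1 <- vim_dataset(matrix(a, dimnames = list(NULL, "A")), outcome = y)
  d2 <- vim_dataset(matrix(a, dimnames = list(NULL, "A")), outcome = -3 * y)
  g <- confounding_fit(fitted(lm(a ~ w)))
  f1 <- tmle_single(d1, 1, fit_univariate_initial(y, a), g)
  f2 <- tmle_single(d2, 1, fit_univariate_initial(-3 * y, a), g)
  expect_equal(f2$beta_star, -3 * f1$beta_star)
  expect_equal(f2$sigma, 3 * f1$sigma)
  expect_equal(abs(f2$t_stat), abs(f1$t_stat))
  expect_equal(f2$p_value, f1$p_value)
})

test_that("the targeted statistic stays in the normal range under the null", {
  # moderate Monte Carlo guard: |T| < 4 across null replicates
  tmax <- 0
  for (s in 1:200) {
    d <- sim_null(n = 100, p = 1, seed = s)
    init <- fit_univariate_initial(d$y, d$v[, 1])
    fit <- tmle_single(d, 1, init, confounding_fit(rep(mean(d$v[, 1]), 100)))
    tmax <- max(tmax, abs(fit$t_stat))
  }
  expect_lt(tmax, 4)
})
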