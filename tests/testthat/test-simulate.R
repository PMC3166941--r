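test_that("cluster design dimensions and truth flags match the layout", {
  des <- cluster_design(m = 10, rho = 0.5, sigma_e = 5, n = 50, seed = 1)
  expect_equal(des$m_w, 250)
  d <- sim_cluster(des)
  expect_equal(dim(d), c(50L, 275L))
  expect_equal(sum(d$truth), 25)
  expect_equal(sum(startsWith(d$ids, "A")), 25)
  des20 <- cluster_design(m = 20, n = 10)
  expect_equal(des20$m_w, 500)
  expect_error(cluster_design(rho = 1), class = "tmlevim_input_error")
})

test_that("outcome regenerates exactly from flagged columns and stored noise", {
  des <- cluster_design(m = 3, rho = 0.4, sigma_e = 2, n = 80,
                        coefficients = seq(0.5, 2.9, by = 0.1), seed = 9)
  d <- sim_cluster(des)
  y_rebuilt <- as.numeric(d$v[, d$truth] %*% des$coefficients) + attr(d, "noise")
  expect_equal(d$y, y_rebuilt)
})

test_that("generation is reproducible and rho/seed overrides redraw correctly", {
  des <- cluster_design(m = 2, rho = 0.5, n = 40, seed = 3)
  expect_identical(sim_cluster(des)$v, sim_cluster(des)$v)
  d2 <- sim_cluster(des, seed = 4)
  expect_false(identical(sim_cluster(des)$v, d2$v))
  # test set (b): same coefficients, different correlation
  db <- sim_cluster(des, rho = 0.1, n = 60, seed = 5)
  expect_equal(dim(db), c(60L, 75L))
  expect_identical(attr(db, "design")$coefficients, des$coefficients)
})

test_that("empirical correlations match the exchangeable-block closed form", {
  des <- cluster_design(m = 4, rho = 0.5, n = 5000, seed = 11)
  d <- sim_cluster(des)
  cc <- cor(d$v)
  blk <- 5
  within <- unlist(lapply(1:25, function(k) {
    idx <- (k - 1) * blk + 1:blk
    cc[idx, idx][upper.tri(diag(blk))]
  }))
  expect_lt(abs(mean(within) - 0.5), 0.02)
  between <- cc[1:blk, (blk + 1):(2 * blk)]
  expect_lt(abs(mean(between)), 0.02)
  # population covariance of a block is (1-rho) I + rho 11'
  S_emp <- cov(d$v[, 1:blk])
  S_pop <- (1 - 0.5) * diag(blk) + 0.5
  expect_lt(max(abs(S_emp - S_pop)), 0.03 * 3)  # sqrt(n)-rate band
  # rho = 0: off-diagonals vanish on average
  d0 <- sim_cluster(cluster_design(m = 4, rho = 0, n = 5000, seed = 12))
  cc0 <- cor(d0$v[, 1:10])
  expect_lt(mean(abs(cc0[upper.tri(cc0)])), 0.02)
})

test_that("general design with identity correlation reduces to independent noise", {
  C <- diag(10)
  dimnames(C) <- list(paste0("g", 1:10), paste0("g", 1:10))
  des <- general_design(C, causal = 1:2, noise_sd = 1, n = 3000, seed = 21)
  d <- sim_general(des)
  cc <- cor(d$v)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.03)
  expect_equal(which(d$truth), 1:2)
  # default 3:2 sign mix starts with two positive coefficients
  expect_equal(d$y, d$v[, 1] + d$v[, 2] + attr(d, "noise"))
})

test_that("a near-duplicate pair in the correlation matrix is honoured", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.999
  des <- general_design(C, causal = 1, n = 500, seed = 22)
  d <- sim_general(des)
  expect_gt(cor(d$v[, 1], d$v[, 2]), 0.99)
  expect_error(general_design(matrix(c(1, 0.2, 0.4, 1), 2, 2)),
               class = "tmlevim_input_error")  # asymmetric
})

test_that("non-positive-definite matrices are repaired by eigenvalue clipping", {
  C <- matrix(0.9, 3, 3); diag(C) <- 1
  C[1, 3] <- C[3, 1] <- -0.9  # violates PSD
  expect_message(d <- sim_general(general_design(C, causal = 1, n = 200, seed = 23)),
                 "repairing")
  expect_equal(dim(d), c(200L, 3L))
})

test_that("the synthetic correlation matrix hits the target quartiles", {
  C <- synthetic_expression_corr(300, seed = 1)
  qs <- stats::quantile(abs(C[upper.tri(C)]), c(0.25, 0.5, 0.75))
  expect_lt(abs(qs[[1]] - 0.16), 0.05)
  expect_lt(abs(qs[[2]] - 0.26), 0.05)
  expect_lt(abs(qs[[3]] - 0.37), 0.05)
  # achieved empirical quartiles from generated data stay close too
  d <- sim_general(general_design(C, n = 400, seed = 2))
  cc <- cor(d$v)
  qe <- stats::quantile(abs(cc[upper.tri(cc)]), c(0.25, 0.5, 0.75))
  expect_lt(max(abs(qe - c(0.16, 0.26, 0.37))), 0.05 + 0.03)
})

test_that("polynomial outcome uses squares and a pairwise product of causal columns", {
  C <- diag(6); dimnames(C) <- list(paste0("v", 1:6), paste0("v", 1:6))
  des <- general_design(C, causal = c(1, 3), outcome = "polynomial",
                        noise_sd = 0.5, n = 100, seed = 24)
  d <- sim_general(des)
  vc <- d$v[, c(1, 3)]
  expected <- rowSums(vc) + 0.5 * rowSums(vc^2) + vc[, 1] * vc[, 2] +
    attr(d, "noise")
  expect_equal(d$y, expected)
})

test_that("null data are reproducible with outcome independent of the variables", {
  d1 <- sim_null(200, 4, seed = 5)
  d2 <- sim_null(200, 4, seed = 5)
  expect_identical(d1$v, d2$v)
  expect_identical(d1$y, d2$y)
  cors <- abs(cor(d1$v, d1$y))
  expect_true(all(cors < 0.25))
  d3 <- sim_null(1000, 4, rho = 0.6, seed = 6)
  cc <- cor(d3$v)
  expect_lt(abs(mean(cc[upper.tri(cc)]) - 0.6), 0.05)
})
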