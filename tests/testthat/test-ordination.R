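test_that("rda_fit matches the per-column regression oracle and vegan", {
  Y <- random_matrix(30, 4, seed = 21, prefix = "y")
  X <- random_matrix(30, 3, seed = 22)
  fit <- rda_fit(Y, X)
  expect_equal(fit$r2, oracle_rda_r2(Y, X), tolerance = 1e-10)
  vfit <- vegan::rda(Y ~ ., data = as.data.frame(X))
  expect_equal(fit$r2, unname(vegan::RsquareAdj(vfit)$r.squared),
               tolerance = 1e-10)
  expect_equal(fit$r2_adj, unname(vegan::RsquareAdj(vfit)$adj.r.squared),
               tolerance = 1e-10)
  expect_true(all(diff(fit$eig) <= 1e-10))
  # degenerate directions
  x1 <- X[, 1, drop = FALSE]
  expect_equal(rda_fit(x1, x1)$r2, 1, tolerance = 1e-12)
  y_orth <- residuals(lm(Y ~ X))
  expect_lt(rda_fit(y_orth, X)$r2, 1e-20)
  # invariance to invertible recoding of X
  A <- matrix(c(2, 1, 0, 1, 3, 1, 0, 0, 1), 3, 3)
  expect_equal(rda_fit(Y, X %*% A)$r2, fit$r2, tolerance = 1e-10)
  # collinearity errors name the offending column
  expect_error(rda_fit(Y, cbind(X, k = rep(1, 30))), "constant.*k")
  expect_error(rda_fit(Y, cbind(X, x1dup = X[, 1])), "duplicate.*x1dup")
})

test_that("adjusted R2 follows the Ezekiel formula, including negative values", {
  expect_equal(adjusted_r2(0.5, 68, 16), 1 - 0.5 * 67 / 51)
  expect_equal(adjusted_r2(0.5, 68, 16), 0.3431373, tolerance = 1e-6)
  expect_equal(adjusted_r2(1, 40, 7), 1)
  expect_equal(adjusted_r2(0, 20, 5), -5 / 14)
  expect_lt(adjusted_r2(0.3, 25, 4), 0.3)
  expect_error(adjusted_r2(0.5, 10, 9), "n - m - 1")
})

test_that("permutation test is significant for strong signal, valid in range, seeded", {
  X <- random_matrix(25, 2, seed = 23)
  Y <- X %*% matrix(c(1, 2, -1, 0.5), 2, 2) +
    random_matrix(25, 2, seed = 24, prefix = "e") * 0.01
  res <- rda_permutation_test(Y, X, n_perm = 999, seed = 7)
  expect_lte(res$perm_p, 0.005)
  expect_gte(res$perm_p, 1 / 1000)
  res2 <- rda_permutation_test(Y, X, n_perm = 999, seed = 7)
  expect_identical(res$perm_p, res2$perm_p)
  expect_error(rda_permutation_test(Y, X, n_perm = 0), "n_perm")
})

test_that("permutation test has nominal type-I error on noise", {
  rejections <- 0
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    Y <- random_matrix(18, 3, seed = 3000 + s, prefix = "y")
    X <- random_matrix(18, 2, seed = 6000 + s)
    p <- rda_permutation_test(Y, X, n_perm = 199, seed = s)$perm_p
    rejections <- rejections + (p <= 0.05)
  }
  expect_equal(rejections / n_sim, 0.05, tolerance = 0.4) # 0.05 +/- 0.02
  expect_lte(abs(rejections / n_sim - 0.05), 0.02)
})

test_that("partial RDA equals the explicit residualization oracle", {
  Y <- random_matrix(30, 4, seed = 31, prefix = "y")
  X <- random_matrix(30, 3, seed = 32)
  Z <- random_matrix(30, 2, seed = 33, prefix = "z")
  fit <- partial_rda(Y, X, Z)
  # oracle: residualize Y and X on Z, then project
  Yc <- scale(Y, scale = FALSE); Xc <- scale(X, scale = FALSE)
  Zc <- scale(Z, scale = FALSE)
  rz <- function(M) M - Zc %*% solve(crossprod(Zc), crossprod(Zc, M))
  Yr <- rz(Yc); Xr <- rz(Xc)
  ss_exp <- sum((Xr %*% solve(crossprod(Xr), crossprod(Xr, Yr)))^2)
  expect_equal(fit$r2, ss_exp / sum(Yc^2), tolerance = 1e-10)
  # empty conditioning equals plain RDA
  fit0 <- partial_rda(Y, X, NULL)
  expect_equal(fit0$r2, rda_fit(Y, X)$r2, tolerance = 1e-12)
  # X inside span(Z) is an error
  expect_error(partial_rda(Y, Z[, 1, drop = FALSE], Z), "no information")
  # vegan cross-check of the semipartial R2
  vfit <- vegan::rda(Y, X, Z)
  expect_equal(fit$r2, unname(vegan::RsquareAdj(vfit)$r.squared),
               tolerance = 1e-10)
})

test_that("forward selection picks the true driver first and respects stop rules", {
  first_hits <- 0
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    X <- random_matrix(30, 10, seed = 4000 + s)
    # dominant driver x3 plus a weaker secondary signal x5
    Y <- 2 * X[, 3, drop = FALSE] + 0.8 * X[, 5, drop = FALSE] +
      random_matrix(30, 1, seed = 7000 + s, prefix = "e") * 0.2
    sel <- forward_select(Y, X, alpha = 0.05, n_perm = 199, seed = s)
    if (length(sel$selected) && sel$selected[1] == "x3") first_hits <- first_hits + 1
  }
  expect_gte(first_hits, n_rep - 1)
  # pure noise at a tiny alpha: global test rejects the whole selection
  global_ns <- 0
  for (s in seq_len(10)) {
    Y <- random_matrix(25, 2, seed = 8000 + s, prefix = "y")
    X <- random_matrix(25, 5, seed = 8500 + s)
    sel <- forward_select(Y, X, alpha = 1e-6, n_perm = 199, seed = s)
    global_ns <- global_ns + (sel$stop_reason == "global_ns" &&
                                length(sel$selected) == 0)
  }
  expect_gte(global_ns, 9)
  # duplicate columns never both enter
  X <- random_matrix(30, 3, seed = 41)
  Xdup <- cbind(X, x1b = X[, 1])
  Y <- X %*% c(1, 0.5, -1) + random_matrix(30, 1, seed = 42, prefix = "e") * 0.1
  sel <- forward_select(Y, Xdup, alpha = 0.05, n_perm = 199, seed = 2)
  expect_false(all(c("x1", "x1b") %in% sel$selected))
  # cumulative adjusted R2 never exceeds the all-candidate ceiling
  expect_true(all(sel$steps$r2_adj_cum <= sel$global_r2_adj + 1e-12))
  expect_true(all(diff(c(0, sel$steps$r2_adj_cum)) > -1e-12) ||
                nrow(sel$steps) <= 1)
  expect_error(forward_select(Y, X[, 0]), "candidate")
})

test_that("PLS components match an independent NIPALS oracle and mixOmics", {
  Y <- random_matrix(20, 3, seed = 51, prefix = "y")
  X <- random_matrix(20, 5, seed = 52)
  fit <- plsr_fit(Y, X, h = 3)
  oracle <- oracle_nipals(Y, X, 3)
  for (a in 1:3) {
    ratio <- abs(cor(fit$scores[, a], oracle[, a]))
    expect_equal(ratio, 1, tolerance = 1e-8)
  }
  skip_if_not_installed("mixOmics")
  # mixOmics scales the responses too; refit on the same convention
  fit_sc <- plsr_fit(Y, X, h = 3, scale_y = TRUE)
  mo <- mixOmics::pls(X, Y, ncomp = 3, mode = "regression", scale = TRUE)
  for (a in 1:3) {
    expect_equal(abs(cor(fit_sc$scores[, a], mo$variates$X[, a])), 1,
                 tolerance = 1e-6)
  }
})

test_that("PLS explained variance is complete for a noiseless response and cumulative", {
  X <- random_matrix(25, 2, seed = 61)
  # orthogonalize the two columns
  X[, 2] <- residuals(lm(X[, 2] ~ X[, 1]))
  Y <- X[, 1, drop = FALSE]
  fit <- plsr_fit(Y, X, h = 2)
  expect_equal(abs(cor(fit$scores[, 1], X[, 1])), 1, tolerance = 1e-8)
  expect_equal(fit$cum_expl_var[1], 100, tolerance = 1e-6)
  expect_true(all(diff(fit$cum_expl_var) >= -1e-8))
  expect_error(plsr_fit(Y, X, h = 5), "rank")
})
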