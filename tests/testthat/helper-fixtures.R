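# Shared fixture builders: everything is generated in code at test time.

matrix_to_df_for_test <- function(m, id_col = "site_id") {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  tibble::tibble(!!id_col := rownames(m), !!!out)
}

random_community <- function(n = 20, q = 6, seed = 1, prefix = "sp") {
  withr::with_seed(seed, {
    m <- matrix(rlnorm(n * q, sdlog = 1), n, q)
    m[m < 0.8] <- 0
    dimnames(m) <- list(sprintf("site_%02d", 1:n),
                        sprintf("%s%02d", prefix, 1:q))
    m
  })
}

random_matrix <- function(n, p, seed = 1, prefix = "x") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    dimnames(m) <- list(sprintf("site_%02d", 1:n),
                        sprintf("%s%d", prefix, 1:p))
    m
  })
}

random_binary <- function(r, c, fill = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(r * c, 1, fill), r, c)
    dimnames(m) <- list(sprintf("sp%02d", 1:r), sprintf("s%02d", 1:c))
    m
  })
}

# brute-force RDA R2: per-response-column least squares on the predictors
oracle_rda_r2 <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  ss_exp <- 0
  for (j in seq_len(ncol(Yc))) {
    fit <- lm.fit(cbind(1, Xc), Yc[, j])
    ss_exp <- ss_exp + sum((Yc[, j] - fit$residuals)^2)
  }
  ss_exp / sum(Yc^2)
}

# exhaustive mean C-score over all unique pairs, plain loops
oracle_c_score_matrix <- function(m) {
  r <- nrow(m)
  tot <- 0
  np <- 0
  for (i in 1:(r - 1)) {
    for (j in (i + 1):r) {
      s <- sum(m[i, ] & m[j, ])
      tot <- tot + (sum(m[i, ]) - s) * (sum(m[j, ]) - s)
      np <- np + 1
    }
  }
  tot / np
}

# enumerate every binary matrix with the margins of m (tiny matrices only)
enumerate_ff_class <- function(m) {
  rc <- nrow(m) * ncol(m)
  stopifnot(rc <= 16)
  out <- list()
  for (code in 0:(2^rc - 1)) {
    cand <- matrix(as.integer(intToBits(code)[1:rc]), nrow(m), ncol(m))
    if (all(rowSums(cand) == rowSums(m)) && all(colSums(cand) == colSums(m))) {
      out[[length(out) + 1]] <- cand
    }
  }
  out
}

# independent textbook NIPALS PLS2 (X scaled), for cross-checking plsr_fit
oracle_nipals <- function(Y, X, h) {
  Xd <- scale(X)
  Yd <- scale(Y, scale = FALSE)
  Tm <- matrix(0, nrow(X), h)
  for (a in 1:h) {
    u <- Yd[, 1]
    repeat {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      t_ <- Xd %*% w
      c_ <- crossprod(Yd, t_) / sum(t_^2)
      u_new <- Yd %*% c_ / sum(c_^2)
      if (sum((u_new - u)^2) < 1e-14) break
      u <- u_new
    }
    p_ <- crossprod(Xd, t_) / sum(t_^2)
    Xd <- Xd - t_ %*% t(p_)
    Yd <- Yd - t_ %*% t(c_)
    Tm[, a] <- t_
  }
  Tm
}
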