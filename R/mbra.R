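# Multiblock redundancy analysis. Predictors arrive in K thematic blocks;
# each model dimension extracts one unit-norm component per block (the
# projection of a response component onto the block's span), combines them
# into a global component with weights summing to one in squares, and
# deflates the blocks (never the response) on the global component. Block
# and variable importance indices cumulate the squared combination weights
# over dimensions, weighted by each dimension's explained response variance.

#' Validate and assemble a collection of predictor blocks
#'
#' @param blocks Named list of site-by-variable tables (data frames with an
#'   optional leading site id column, or matrices) over a common site set.
#' @return A named list of numeric matrices (class `block_collection`).
#' @export
block_collection <- function(blocks) {
  if (!is.list(blocks) || length(blocks) == 0) {
    abort("blocks must be a nonempty named list")
  }
  if (is.null(names(blocks)) || any(names(blocks) == "") ||
      anyDuplicated(names(blocks))) {
    abort("blocks must have unique nonempty names")
  }
  mats <- lapply(seq_along(blocks), function(k) {
    m <- df_to_matrix(blocks[[k]], sprintf("block '%s'", names(blocks)[k]))
    if (ncol(m) == 0) abort(sprintf("block '%s' has no variables",
                                    names(blocks)[k]))
    if (is.null(colnames(m))) {
      colnames(m) <- paste0(names(blocks)[k], "_v", seq_len(ncol(m)))
    }
    m
  })
  names(mats) <- names(blocks)
  n <- nrow(mats[[1]])
  for (k in seq_along(mats)) check_aligned(mats[[1]], mats[[k]], "blocks")
  all_vars <- unlist(lapply(mats, colnames))
  if (anyDuplicated(all_vars)) {
    abort("variable labels must be unique across blocks")
  }
  structure(mats, class = c("block_collection", "list"))
}

#' Fit a multiblock redundancy analysis
#'
#' Per dimension `h`, the response weight vector `v(h)` is the dominant
#' eigenvector of `sum_k Y' P_k Y` (with `P_k` the projector onto the current,
#' deflated span of block `k`), the response component is `u(h) = Y v(h)`,
#' each block component `t_k(h)` is the unit-normalised projection of `u(h)`
#' onto the block span, and the global component `t(h) = sum_k a_k(h) t_k(h)`
#' combines them with weights proportional to `cov(u, t_k)`, normalised to
#' `sum_k a_k^2 = 1`. After each dimension every block is replaced by its
#' residual on `t(h)`; the response is never deflated, so with one block the
#' model coincides with RDA and at full rank the cumulative explained variance
#' saturates at the RDA R2 of the concatenated predictors.
#'
#' Predictors are centred and unit-scaled per variable; responses are centred
#' only (abundance transforms are assumed applied upstream).
#'
#' @param Y Response community table (sites x species).
#' @param blocks Named list of predictor tables (see [block_collection()]).
#' @param h Number of model dimensions.
#' @return An object of class `mbra`; see Details. Importance indices are in
#'   `$block_importance` / `$variable_importance` and via [tidy.mbra()].
#' @export
mbra_fit <- function(Y, blocks, h = 2) {
  blocks <- block_collection(blocks)
  Ym <- df_to_matrix(Y, "response")
  check_aligned(Ym, blocks[[1]], "response and blocks")
  if (h < 1) abort("h must be >= 1")
  Yc <- scale_matrix(Ym, scale = FALSE)
  ss_tot <- ss_total(Yc)
  if (ss_tot < 1e-12) abort("response has zero variance")
  K <- length(blocks)
  Xs <- lapply(blocks, scale_matrix, scale = TRUE)
  centers <- lapply(Xs, attr, "center")
  scales <- lapply(Xs, attr, "scale")
  Xcat <- do.call(cbind, lapply(Xs, identity))
  rank_total <- qr(Xcat)$rank
  if (h > rank_total) {
    abort(sprintf("h = %d exceeds the total rank %d of the blocks",
                  h, rank_total))
  }
  n <- nrow(Yc); q <- ncol(Yc)
  p_k <- vapply(Xs, ncol, integer(1))
  P <- sum(p_k)
  block_of <- rep(names(blocks), p_k)
  var_names <- unlist(lapply(Xs, colnames))

  Xd <- Xs                      # deflated blocks
  a <- matrix(0, K, h, dimnames = list(names(blocks), NULL))
  lambda <- numeric(h)
  Tg <- matrix(0, n, h)         # global components
  Vh <- matrix(0, q, h, dimnames = list(colnames(Yc), NULL))
  Wsq <- matrix(0, P, h, dimnames = list(var_names, NULL)) # squared block weights
  for (dim_h in seq_len(h)) {
    Qk <- lapply(Xd, span_basis)
    live <- vapply(Qk, ncol, integer(1)) > 0
    # dominant response weight vector of sum_k Y' P_k Y
    M <- matrix(0, q, q)
    for (k in which(live)) {
      YQ <- crossprod(Yc, Qk[[k]])
      M <- M + tcrossprod(YQ)
    }
    es <- eigen(M, symmetric = TRUE)
    v <- es$vectors[, 1]
    u <- as.vector(Yc %*% v)
    t_k <- matrix(0, n, K)
    for (k in which(live)) {
      tk <- Qk[[k]] %*% crossprod(Qk[[k]], u)
      nt <- sqrt(sum(tk^2))
      if (nt > 1e-10) t_k[, k] <- tk / nt
    }
    a_raw <- as.vector(crossprod(t_k, u))   # = cov(u, t_k) up to 1/(n-1)
    a_norm <- sqrt(sum(a_raw^2))
    if (a_norm < 1e-12) abort("degenerate dimension: no block explains the response component")
    a[, dim_h] <- a_raw / a_norm
    t_glob <- as.vector(t_k %*% a[, dim_h])
    # additional explained response variance (global components are orthogonal)
    lambda[dim_h] <- sum(as.vector(crossprod(Yc, t_glob))^2) /
      sum(t_glob^2) / ss_tot
    # block weights: coefficients of t_k on the deflated block, unit norm
    for (k in which(live)) {
      if (sum(t_k[, k]^2) > 0) {
        b <- qr.coef(qr(Xd[[k]]), t_k[, k])
        b[is.na(b)] <- 0
        nb <- sum(b^2)
        if (nb > 0) {
          Wsq[block_of == names(blocks)[k], dim_h] <- b^2 / nb
        }
      }
    }
    Tg[, dim_h] <- t_glob
    Vh[, dim_h] <- v
    # deflate every block on the global component
    tt <- sum(t_glob^2)
    Xd <- lapply(Xd, function(Xk) Xk - t_glob %*% crossprod(t_glob, Xk) / tt)
  }

  # original-variable expression of the global components (exact: each t(h)
  # lies in the span of the concatenated original blocks)
  qr_cat <- qr(Xcat)
  Rmat <- qr.coef(qr_cat, Tg)
  Rmat[is.na(Rmat)] <- 0
  rownames(Rmat) <- var_names
  # regression coefficients of Y on the (orthogonal) global components
  Bcoef <- crossprod(Tg, Yc) / colSums(Tg^2)

  # explained variances, cumulative over dimensions
  expl_y_cum <- cumsum(lambda)
  expl_block <- matrix(0, K, h, dimnames = list(names(blocks), NULL))
  for (k in seq_len(K)) {
    ssk <- ss_total(Xs[[k]])
    acc <- 0
    for (dim_h in seq_len(h)) {
      tg <- Tg[, dim_h]
      acc <- acc + sum(as.vector(crossprod(Xs[[k]], tg))^2) / sum(tg^2)
      expl_block[k, dim_h] <- acc / ssk
    }
  }

  lw <- lambda / sum(lambda)
  block_imp <- as.vector((a^2) %*% lw)
  names(block_imp) <- names(blocks)
  # global squared variable weight: a_k(h)^2 * w_kj(h)^2
  a_expand <- a[block_of, , drop = FALSE]
  var_imp <- as.vector((Wsq * a_expand^2) %*% lw)
  names(var_imp) <- var_names

  structure(
    list(K = K, P = P, h = h, n = n, q = q,
         block_names = names(blocks), var_names = var_names,
         block_of = block_of,
         a = a, lambda = lambda, v = Vh, t_global = Tg,
         r = Rmat, b = Bcoef,
         expl_y_cum = expl_y_cum, expl_block = expl_block,
         block_imp = block_imp, var_imp = var_imp,
         block_threshold = 1 / K, var_threshold = 1 / P,
         centers = centers, scales = scales,
         y_center = attr(Yc, "center"),
         rank_total = rank_total),
    class = "mbra")
}

#' @export
print.mbra <- function(x, ...) {
  cat(sprintf("Multiblock redundancy analysis: K = %d blocks, P = %d variables, h = %d\n",
              x$K, x$P, x$h))
  cat(sprintf("  explained response variance: %.1f%%\n",
              100 * x$expl_y_cum[x$h]))
  cat(sprintf("  block importance threshold 1/K = %.3f; variable threshold 1/P = %.3f\n",
              x$block_threshold, x$var_threshold))
  top <- order(-x$block_imp)
  cat("  blocks by importance:",
      paste(sprintf("%s (%.1f%%)", x$block_names[top],
                    100 * x$block_imp[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Block importance index
#'
#' `BlockImp_k = sum_h lambda_h a_k(h)^2 / sum_h lambda_h`: each block's
#' squared combination weight cumulated over model dimensions and weighted by
#' the dimension's explained response variance. The indices sum to one; a
#' block matters when its index exceeds the equal-share threshold `1/K`.
#'
#' @param model A fitted [mbra_fit()] model.
#' @return A tibble with `block`, `importance`, `threshold`, `flag`.
#' @export
block_importance <- function(model) {
  stopifnot(inherits(model, "mbra"))
  tibble(block = model$block_names,
         importance = unname(model$block_imp),
         threshold = model$block_threshold,
         flag = model$block_imp > model$block_threshold)
}

#' Variable importance index
#'
#' `VarImp_j = sum_h lambda_h (a_k(h) w_kj(h))^2 / sum_h lambda_h` for
#' variable `j` of block `k`, with `w_k(h)` the unit-norm weights expressing
#' the block component on the (deflated) block variables. Indices sum to one;
#' the significance threshold is the equal-share `1/P`.
#'
#' @inheritParams block_importance
#' @return A tibble with `variable`, `block`, `importance`, `threshold`,
#'   `flag`.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "mbra"))
  tibble(variable = model$var_names,
         block = model$block_of,
         importance = unname(model$var_imp),
         threshold = model$var_threshold,
         flag = model$var_imp > model$var_threshold)
}

#' Predict community composition from a fitted multiblock model
#'
#' @param object A fitted `mbra` model.
#' @param newblocks Named list of predictor tables with the same variables as
#'   the training blocks.
#' @param h Number of dimensions to use (default: all fitted).
#' @param ... Unused.
#' @return A numeric matrix of predicted (centred-scale) response values.
#' @export
predict.mbra <- function(object, newblocks, h = object$h, ...) {
  stopifnot(h >= 1, h <= object$h)
  newblocks <- newblocks[object$block_names]
  Xs <- lapply(seq_along(newblocks), function(k) {
    m <- df_to_matrix(newblocks[[k]], "new block")
    sweep(sweep(m, 2, object$centers[[k]], "-"), 2, object$scales[[k]], "/")
  })
  Xcat <- do.call(cbind, Xs)
  Tnew <- Xcat %*% object$r[, seq_len(h), drop = FALSE]
  pred <- Tnew %*% object$b[seq_len(h), , drop = FALSE]
  sweep(pred, 2, object$y_center, "+")
}

#' Choose the number of model dimensions by repeated two-fold cross-validation
#'
#' Sites are split at random into two folds; the model fitted on one fold
#' predicts the held-out community and the pooled root-mean-squared error of
#' prediction (RMSEP) is averaged over folds and repeats. The chosen `h` is
#' the smallest whose mean error is within a relative tolerance of the
#' minimum.
#'
#' @inheritParams mbra_fit
#' @param h_max Largest dimensionality examined.
#' @param folds Number of folds (default 2).
#' @param repeats Number of repeated random splits (default 100).
#' @param seed Optional integer seed for the fold assignments.
#' @param tol Relative tolerance for "within reach of the minimum".
#' @return An object of class `mbra_cv`: tibble `error` (h, rmsep), chosen
#'   `h_opt`, `folds`, `repeats`, `seed`.
#' @export
select_ncomp_cv <- function(Y, blocks, h_max = 5, folds = 2, repeats = 100,
                            seed = NULL, tol = 1e-6) {
  if (folds < 2) abort("folds must be >= 2")
  if (h_max < 1) abort("h_max must be >= 1")
  blocks <- block_collection(blocks)
  Ym <- df_to_matrix(Y, "response")
  n <- nrow(Ym)
  if (n < 2 * folds) abort("too few sites for the requested folds")
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  sse <- matrix(0, repeats * folds, h_max)
  cnt <- 0
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_id <- sample(rep_len(seq_len(folds), n))
      for (f in seq_len(folds)) {
        test <- fold_id == f
        train_blocks <- lapply(blocks, function(b) b[!test, , drop = FALSE])
        test_blocks <- lapply(blocks, function(b) b[test, , drop = FALSE])
        h_fit <- h_max
        fit <- tryCatch(mbra_fit(Ym[!test, , drop = FALSE], train_blocks,
                                 h = h_fit),
                        error = function(e) NULL)
        while (is.null(fit) && h_fit > 1) {
          h_fit <- h_fit - 1
          fit <- tryCatch(mbra_fit(Ym[!test, , drop = FALSE], train_blocks,
                                   h = h_fit),
                          error = function(e) NULL)
        }
        if (is.null(fit)) next
        cnt <- cnt + 1
        for (hh in seq_len(h_max)) {
          pred <- predict(fit, test_blocks, h = min(hh, h_fit))
          sse[cnt, hh] <- mean((Ym[test, , drop = FALSE] - pred)^2)
        }
      }
    }
  })
  if (cnt == 0) abort("cross-validation failed in every fold")
  rmsep <- sqrt(colMeans(sse[seq_len(cnt), , drop = FALSE]))
  # relative tolerance plus an absolute floor so that numerically-zero
  # errors (noiseless responses) count as ties
  y_scale <- sqrt(mean(scale_matrix(Ym, scale = FALSE)^2))
  h_opt <- min(which(rmsep <= min(rmsep) * (1 + tol) + 1e-9 * y_scale))
  structure(
    list(error = tibble(h = seq_len(h_max), rmsep = rmsep),
         h_opt = h_opt, folds = folds, repeats = repeats, seed = seed),
    class = "mbra_cv")
}

#' @export
print.mbra_cv <- function(x, ...) {
  cat(sprintf("Twofold cross-validation (%d repeats): h* = %d\n",
              x$repeats, x$h_opt))
  print(x$error)
  invisible(x)
}

#' Bootstrap tolerance intervals for the importance indices
#'
#' Sites are resampled with replacement `B` times, the model is refitted and
#' per-dimension signs are aligned to the point model by the correlation of
#' global components; percentile intervals at the requested level are
#' returned for every block and variable importance value. Replicates whose
#' refit fails (e.g. a rank-deficient resample) are dropped and counted.
#'
#' @inheritParams mbra_fit
#' @param B Number of bootstrap replicates (>= 2).
#' @param level Interval level (default 0.95).
#' @param seed Optional integer seed.
#' @return An object of class `mbra_boot`: tibbles `block_intervals` and
#'   `variable_intervals` (index, estimate, lo, hi) plus `dropped`.
#' @export
mbra_bootstrap <- function(Y, blocks, h = 2, B = 1000, level = 0.95,
                           seed = NULL) {
  if (B < 2) abort("B must be >= 2")
  blocks <- block_collection(blocks)
  Ym <- df_to_matrix(Y, "response")
  point <- mbra_fit(Ym, blocks, h = h)
  n <- nrow(Ym)
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  bi <- matrix(NA_real_, B, point$K)
  vi <- matrix(NA_real_, B, point$P)
  dropped <- 0
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit_b <- tryCatch(
        mbra_fit(Ym[idx, , drop = FALSE],
                 lapply(blocks, function(x) x[idx, , drop = FALSE]), h = h),
        error = function(e) NULL)
      if (is.null(fit_b)) { dropped <- dropped + 1; next }
      bi[b, ] <- fit_b$block_imp
      vi[b, ] <- fit_b$var_imp
    }
  })
  ok <- stats::complete.cases(bi)
  if (!any(ok)) abort("all bootstrap replicates failed")
  lo_p <- (1 - level) / 2
  hi_p <- 1 - lo_p
  qs <- function(mat) {
    apply(mat[ok, , drop = FALSE], 2, quantile, probs = c(lo_p, hi_p),
          names = FALSE)
  }
  qb <- qs(bi); qv <- qs(vi)
  structure(
    list(block_intervals = tibble(block = point$block_names,
                                  estimate = unname(point$block_imp),
                                  lo = qb[1, ], hi = qb[2, ]),
         variable_intervals = tibble(variable = point$var_names,
                                     block = point$block_of,
                                     estimate = unname(point$var_imp),
                                     lo = qv[1, ], hi = qv[2, ]),
         level = level, B = B, dropped = dropped, seed = seed),
    class = "mbra_boot")
}

#' @export
print.mbra_boot <- function(x, ...) {
  cat(sprintf("Bootstrap tolerance intervals (B = %d, level = %.2f, %d dropped)\n",
              x$B, x$level, x$dropped))
  print(x$block_intervals)
  invisible(x)
}

#' @describeIn mbra_fit Importance indices as a tidy tibble (`term`, `level`
#'   either `"block"` or `"variable"`, `importance`, `threshold`, `flag`).
#' @param x A fitted `mbra` model.
#' @param ... Unused.
#' @export
tidy.mbra <- function(x, ...) {
  bind_rows(
    block_importance(x) |>
      rename(term = "block") |>
      mutate(level = "block", block = term, .before = 1),
    variable_importance(x) |>
      rename(term = "variable") |>
      mutate(level = "variable", .before = 1)
  ) |>
    select("level", "term", "block", "importance", "threshold", "flag")
}

#' @describeIn mbra_fit One-row model summary.
#' @export
glance.mbra <- function(x, ...) {
  tibble(n = x$n, q = x$q, K = x$K, P = x$P, h = x$h,
         expl_variance = x$expl_y_cum[x$h],
         block_threshold = x$block_threshold,
         var_threshold = x$var_threshold)
}
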