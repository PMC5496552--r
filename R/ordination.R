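# Constrained-ordination primitives: redundancy analysis, adjusted R2,
# permutation tests, forward selection with the double-stopping rule, and
# NIPALS partial least squares. These are the building blocks of the
# multiblock model and of variation partitioning, so they are implemented on
# shared least-squares projections; vegan serves as an independent
# cross-check in the test suite.

prepare_xy <- function(Y, X, check_cols = TRUE) {
  Ym <- df_to_matrix(Y, "response")
  Xm <- df_to_matrix(X, "predictors")
  check_aligned(Ym, Xm, "response and predictors")
  if (check_cols && ncol(Xm) > 0) {
    cst <- apply(Xm, 2, function(v) stats::sd(v) < 1e-12)
    if (any(cst)) {
      abort(sprintf("constant predictor column(s): %s",
                    paste(colnames(Xm)[cst] %||% which(cst), collapse = ", ")))
    }
    if (ncol(Xm) > 1) {
      dup <- duplicated(t(Xm))
      if (any(dup)) {
        abort(sprintf("duplicate predictor column(s): %s",
                      paste(colnames(Xm)[dup] %||% which(dup), collapse = ", ")))
      }
    }
  }
  Yc <- scale_matrix(Ym, scale = FALSE)
  Xc <- scale_matrix(Xm, scale = FALSE)
  list(Y = Yc, X = Xc, n = nrow(Ym))
}

#' Redundancy analysis (RDA)
#'
#' Fits the constrained ordination `Y ~ X`: the multivariate response is
#' projected onto the span of the predictors and the explained proportion of
#' total response variance is `R2 = SS(fitted) / SS(total)`. Ordination axes
#' are the principal axes of the fitted values.
#'
#' @param Y Response table (sites x species); data frame with an optional
#'   leading id column, or a numeric matrix. Centred internally.
#' @param X Predictor table over the same sites.
#' @return An object of class `rda_fit`: list with `r2`, `r2_adj`, `n`, `m`
#'   (predictor rank), `eig` (eigenvalues of the fitted-value crossproduct,
#'   nonincreasing), `eig_prop` (the same as proportions of total response
#'   variance), and `pseudo_f`.
#' @export
rda_fit <- function(Y, X) {
  d <- prepare_xy(Y, X)
  if (ss_total(d$Y) < 1e-12) abort("response has zero variance")
  Q <- span_basis(d$X)
  m <- ncol(Q)
  if (m == 0) abort("predictors have empty column span")
  fitted <- Q %*% crossprod(Q, d$Y)
  ss_tot <- ss_total(d$Y)
  ss_exp <- ss_total(fitted)
  r2 <- ss_exp / ss_tot
  n <- d$n
  eig <- sort(eigen(crossprod(fitted), symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  eig <- pmax(eig, 0)
  df_res <- n - m - 1
  pseudo_f <- if (df_res > 0) (ss_exp / m) / ((ss_tot - ss_exp) / df_res) else NA_real_
  structure(
    list(r2 = r2,
         r2_adj = if (df_res >= 1) adjusted_r2(r2, n, m) else NA_real_,
         n = n, m = m,
         eig = eig, eig_prop = eig / ss_tot,
         pseudo_f = pseudo_f, perm_p = NA_real_),
    class = "rda_fit")
}

#' Adjusted R-squared (Ezekiel correction)
#'
#' `1 - (1 - r2) * (n - 1) / (n - m - 1)`; penalises the number of predictors
#' and makes explained-variance fractions additive in variation partitioning.
#' May be negative.
#'
#' @param r2 Unadjusted proportion of variance explained.
#' @param n Number of sites.
#' @param m Number of (independent) predictor variables.
#' @return The adjusted proportion.
#' @export
#' @examples
#' adjusted_r2(0.5, 68, 16)
adjusted_r2 <- function(r2, n, m) {
  if (n - m - 1 < 1) abort("adjusted R2 needs n - m - 1 >= 1")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Permutation test for an RDA model
#'
#' Tests the global significance of `Y ~ X` by permuting the rows of the
#' response: `p = (1 + #(F_perm >= F_obs)) / (n_perm + 1)`.
#'
#' @inheritParams rda_fit
#' @param n_perm Number of random permutations (>= 1).
#' @param seed Optional integer seed for the permutation stream.
#' @return A tibble with one row: `pseudo_f`, `perm_p`, `r2`, `n_perm`.
#' @export
rda_permutation_test <- function(Y, X, n_perm = 999, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  d <- prepare_xy(Y, X)
  if (ss_total(d$Y) < 1e-12) abort("response has zero variance")
  Q <- span_basis(d$X)
  m <- ncol(Q)
  n <- d$n
  stat <- function(Ymat) {
    ss_exp <- ss_total(crossprod(Q, Ymat))
    ss_tot <- ss_total(Ymat)
    (ss_exp / m) / ((ss_tot - ss_exp) / (n - m - 1))
  }
  f_obs <- stat(d$Y)
  perm_fun <- function() {
    f_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      f_perm[b] <- stat(d$Y[sample.int(n), , drop = FALSE])
    }
    f_perm
  }
  f_perm <- if (is.null(seed)) perm_fun() else withr::with_seed(seed, perm_fun())
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  tibble(pseudo_f = f_obs, perm_p = p,
         r2 = ss_total(Q %*% crossprod(Q, d$Y)) / ss_total(d$Y),
         n_perm = n_perm)
}

#' Partial redundancy analysis (pRDA)
#'
#' RDA of `Y` on `X` after removing the effect of conditioning variables `Z`
#' from both response and predictors. The semipartial `r2` is reported on the
#' total variance of the original (centred) response, and `r2_adj` as the
#' difference `adjR2(X+Z) - adjR2(Z)`. When `n_perm > 0` the unique
#' contribution of `X` is tested by permuting the reduced-model (Z-only)
#' residuals of the response.
#'
#' @inheritParams rda_fit
#' @param Z Conditioning table (may be `NULL` or have zero columns, in which
#'   case the fit is identical to [rda_fit()]).
#' @param n_perm Number of permutations for the partial test (0 = no test).
#' @param seed Optional integer seed.
#' @return An `rda_fit` object (with `perm_p` filled in when tested).
#' @export
partial_rda <- function(Y, X, Z = NULL, n_perm = 0, seed = NULL) {
  if (is.null(Z) || NCOL(Z) == 0) {
    fit <- rda_fit(Y, X)
    if (n_perm > 0) {
      fit$perm_p <- rda_permutation_test(Y, X, n_perm, seed)$perm_p
    }
    return(fit)
  }
  Ym <- scale_matrix(df_to_matrix(Y, "response"), scale = FALSE)
  Xm <- scale_matrix(df_to_matrix(X, "predictors"), scale = FALSE)
  Zm <- scale_matrix(df_to_matrix(Z, "conditioning"), scale = FALSE)
  check_aligned(Ym, Xm, "response and predictors")
  check_aligned(Ym, Zm, "response and conditioning variables")
  Qz <- span_basis(Zm)
  Xr <- Xm - Qz %*% crossprod(Qz, Xm)
  # columns numerically inside span(Z) carry no information
  keep <- sqrt(colSums(Xr^2)) > 1e-8 * pmax(sqrt(colSums(Xm^2)), 1e-300)
  Xr <- Xr[, keep, drop = FALSE]
  Qx <- span_basis(Xr)
  if (ncol(Qx) == 0) {
    abort("predictors carry no information beyond the conditioning variables")
  }
  Yr <- Ym - Qz %*% crossprod(Qz, Ym)
  fitted <- Qx %*% crossprod(Qx, Yr)
  ss_tot <- ss_total(Ym)
  ss_exp <- ss_total(fitted)
  n <- nrow(Ym)
  m <- ncol(Qx)
  mz <- ncol(Qz)
  r2 <- ss_exp / ss_tot
  # adjusted semipartial: adjR2(full) - adjR2(conditioning)
  r2_full <- (ss_exp + ss_total(crossprod(Qz, Ym))) / ss_tot
  r2_z <- ss_total(crossprod(Qz, Ym)) / ss_tot
  r2_adj <- adjusted_r2(r2_full, n, m + mz) - adjusted_r2(r2_z, n, mz)
  eig <- sort(eigen(crossprod(fitted), symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  df_res <- n - m - mz - 1
  ss_res <- ss_total(Yr) - ss_exp
  f_obs <- (ss_exp / m) / (ss_res / df_res)
  perm_p <- NA_real_
  if (n_perm > 0) {
    stat <- function(Ymat) {
      # Ymat: residualized response under reduced model
      e <- ss_total(crossprod(Qx, Ymat))
      (e / m) / ((ss_total(Ymat) - ss_total(crossprod(Qz, Ymat)) - e) / df_res)
    }
    perm_fun <- function() {
      f_perm <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        f_perm[b] <- stat(Yr[sample.int(n), , drop = FALSE])
      }
      f_perm
    }
    f_perm <- if (is.null(seed)) perm_fun() else withr::with_seed(seed, perm_fun())
    perm_p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  }
  structure(
    list(r2 = r2, r2_adj = r2_adj, n = n, m = m,
         eig = pmax(eig, 0), eig_prop = pmax(eig, 0) / ss_tot,
         pseudo_f = f_obs, perm_p = perm_p),
    class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis fit\n")
  cat(sprintf("  n = %d sites, m = %d predictors\n", x$n, x$m))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f\n", x$r2, x$r2_adj))
  if (!is.na(x$perm_p)) cat(sprintf("  pseudo-F = %.3f, P = %.4g\n",
                                    x$pseudo_f, x$perm_p))
  invisible(x)
}

#' Forward selection of predictors with the double-stopping rule
#'
#' Classical forward selection inflates Type I error and explained variance;
#' the double-stopping rule guards it twice. First, the model with all
#' candidates must itself be significant at `alpha`, otherwise nothing is
#' selected (`stop_reason = "global_ns"`). Then variables are added greedily
#' (largest added fit first) and selection stops when the best remaining
#' candidate's permutation p-value exceeds `alpha` or when the cumulative
#' adjusted R2 would exceed the adjusted R2 of the all-candidate model.
#'
#' @inheritParams rda_fit
#' @param candidates Candidate predictor table.
#' @param alpha Significance level for each step (default 0.05).
#' @param n_perm Permutations per step test (default 9999).
#' @param seed Optional integer seed.
#' @return An object of class `forward_selection`: tibble `steps` (variable,
#'   added r2, cumulative adjusted R2, permutation p), `selected`,
#'   `global_r2_adj`, `global_p`, `stop_reason` in `"alpha"`,
#'   `"r2adj_ceiling"`, `"exhausted"`, `"global_ns"`.
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, n_perm = 9999,
                           seed = NULL) {
  Xm <- df_to_matrix(candidates, "candidates")
  if (ncol(Xm) == 0) abort("no candidate predictors supplied")
  if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
  keep <- apply(Xm, 2, function(v) stats::sd(v) > 1e-12)
  if (!all(keep)) {
    warn(sprintf("dropping constant candidate(s): %s",
                 paste(colnames(Xm)[!keep], collapse = ", ")))
    Xm <- Xm[, keep, drop = FALSE]
    if (ncol(Xm) == 0) abort("no candidate predictors supplied")
  }
  Ym <- scale_matrix(df_to_matrix(Y, "response"), scale = FALSE)
  check_aligned(Ym, Xm, "response and candidates")
  Xc <- scale_matrix(Xm, scale = FALSE)
  n <- nrow(Ym)
  ss_tot <- ss_total(Ym)
  seed <- seed %||% sample.int(.Machine$integer.max, 1)

  # double-stop guard 1: global model significance and adjusted-R2 ceiling
  Qg <- span_basis(Xc)
  global_r2 <- ss_total(crossprod(Qg, Ym)) / ss_tot
  global_r2_adj <- adjusted_r2(global_r2, n, ncol(Qg))
  # test on the orthonormal span so duplicate candidates are harmless
  global_p <- rda_permutation_test(Ym, Qg, n_perm = n_perm,
                                   seed = derive_seed(seed, "global"))$perm_p
  empty_steps <- tibble(variable = character(0), r2_added = numeric(0),
                        r2_adj_cum = numeric(0), perm_p = numeric(0))
  result <- function(steps, reason) {
    structure(list(steps = steps, selected = steps$variable,
                   global_r2_adj = global_r2_adj, global_p = global_p,
                   alpha = alpha, n_perm = n_perm, stop_reason = reason),
              class = "forward_selection")
  }
  if (global_p > alpha) return(result(empty_steps, "global_ns"))

  remaining <- colnames(Xc)
  selected <- character(0)
  steps <- empty_steps
  Qs <- matrix(0, n, 0)            # orthonormal basis of selected set
  E <- Ym                          # residual response on selected set
  step_i <- 0
  reason <- "exhausted"
  while (length(remaining) > 0) {
    step_i <- step_i + 1
    # residual of each remaining candidate on the selected span
    Xr <- Xc[, remaining, drop = FALSE]
    if (ncol(Qs) > 0) Xr <- Xr - Qs %*% crossprod(Qs, Xr)
    norms <- sqrt(colSums(Xr^2))
    viable <- norms > 1e-8 * sqrt(n)
    if (!any(viable)) { reason <- "exhausted"; break }
    ss_add <- vapply(seq_along(remaining), function(j) {
      if (!viable[j]) return(0)
      q <- Xr[, j] / norms[j]
      sum(as.vector(crossprod(q, E))^2)
    }, numeric(1))
    best <- which.max(ss_add)
    if (ss_add[best] <= 1e-12) { reason <- "exhausted"; break }
    q_best <- Xr[, best] / norms[best]
    s <- ncol(Qs)
    df_res <- n - s - 1 - 1
    if (df_res < 1) { reason <- "exhausted"; break }
    ss_res_sel <- ss_total(E)
    f_obs <- ss_add[best] / ((ss_res_sel - ss_add[best]) / df_res)
    # permutation of reduced-model residuals
    f_perm <- withr::with_seed(derive_seed(seed, paste0("step", step_i)), {
      fp <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        Ep <- E[sample.int(n), , drop = FALSE]
        sa <- sum(as.vector(crossprod(q_best, Ep))^2)
        fp[b] <- sa / ((ss_total(Ep) - sa) / df_res)
      }
      fp
    })
    p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
    if (p > alpha) { reason <- "alpha"; break }
    new_sel <- c(selected, remaining[best])
    Q_new <- cbind(Qs, q_best)
    r2_cum <- ss_total(crossprod(Q_new, Ym)) / ss_tot
    r2_adj_cum <- adjusted_r2(r2_cum, n, ncol(Q_new))
    if (r2_adj_cum > global_r2_adj + 1e-12) { reason <- "r2adj_ceiling"; break }
    steps <- bind_rows(steps, tibble(variable = remaining[best],
                                     r2_added = ss_add[best] / ss_tot,
                                     r2_adj_cum = r2_adj_cum,
                                     perm_p = p))
    selected <- new_sel
    Qs <- Q_new
    E <- Ym - Qs %*% crossprod(Qs, Ym)
    remaining <- remaining[-best]
    if (length(remaining) == 0) reason <- "exhausted"
  }
  result(steps, reason)
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("Forward selection (double-stopping): %d selected, stop = %s\n",
              length(x$selected), x$stop_reason))
  cat(sprintf("  global adjusted R2 = %.4f (P = %.4g)\n",
              x$global_r2_adj, x$global_p))
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

#' @export
tidy.forward_selection <- function(x, ...) {
  x$steps
}

#' @export
glance.forward_selection <- function(x, ...) {
  tibble(n_selected = length(x$selected), global_r2_adj = x$global_r2_adj,
         global_p = x$global_p, stop_reason = x$stop_reason,
         alpha = x$alpha, n_perm = x$n_perm)
}

#' Partial least-squares regression components (NIPALS)
#'
#' Extracts `h` covariance-maximising PLS2 components of `X` with respect to
#' the multivariate response `Y`, with deflation of both matrices. The
#' component scores are the low-dimensional summary used as the "biotic"
#' predictor block representing the other trophic level.
#'
#' @inheritParams rda_fit
#' @param X Predictor table (the other community).
#' @param h Number of components.
#' @param scale_x,scale_y Unit-variance scaling of predictors / responses
#'   (defaults: predictors scaled, responses centred only).
#' @return An object of class `pls_components`: `scores` (sites x h),
#'   `x_weights`, `y_weights`, `expl_var` (% of response variance explained
#'   per component) and `cum_expl_var`.
#' @export
plsr_fit <- function(Y, X, h = 2, scale_x = TRUE, scale_y = FALSE) {
  Ym <- df_to_matrix(Y, "response")
  Xm <- df_to_matrix(X, "predictors")
  check_aligned(Ym, Xm, "response and predictors")
  Yc <- scale_matrix(Ym, scale = scale_y)
  Xc <- scale_matrix(Xm, scale = scale_x)
  rk <- qr(Xc)$rank
  if (h > rk) abort(sprintf("h = %d exceeds predictor rank %d", h, rk))
  n <- nrow(Xc)
  ss_tot <- ss_total(Yc)
  Xd <- Xc; Yd <- Yc
  Tm <- matrix(0, n, h)
  W <- matrix(0, ncol(Xc), h, dimnames = list(colnames(Xc), NULL))
  C <- matrix(0, ncol(Yc), h, dimnames = list(colnames(Yc), NULL))
  for (a in seq_len(h)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    w <- rep(0, ncol(Xd))
    for (it in seq_len(500)) {
      w_new <- crossprod(Xd, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      t_sc <- Xd %*% w_new
      c_vec <- crossprod(Yd, t_sc) / sum(t_sc^2)
      u_new <- Yd %*% c_vec / sum(c_vec^2)
      if (sqrt(sum((w_new - w)^2)) < 1e-12) { w <- w_new; u <- u_new; break }
      w <- w_new; u <- u_new
    }
    t_sc <- Xd %*% w
    p_vec <- crossprod(Xd, t_sc) / sum(t_sc^2)
    c_vec <- crossprod(Yd, t_sc) / sum(t_sc^2)
    Xd <- Xd - t_sc %*% t(p_vec)
    Yd <- Yd - t_sc %*% t(c_vec)
    Tm[, a] <- t_sc
    W[, a] <- w
    C[, a] <- c_vec
  }
  # explained response variance from regression of original Y on the scores
  expl <- numeric(h)
  for (a in seq_len(h)) {
    Qa <- span_basis(Tm[, seq_len(a), drop = FALSE])
    expl[a] <- ss_total(crossprod(Qa, Yc)) / ss_tot
  }
  expl_var <- diff(c(0, expl)) * 100
  rownames(Tm) <- rownames(Xm)
  colnames(Tm) <- paste0("comp", seq_len(h))
  structure(
    list(scores = Tm, x_weights = W, y_weights = C,
         expl_var = expl_var, cum_expl_var = cumsum(expl_var), h = h),
    class = "pls_components")
}

#' @export
print.pls_components <- function(x, ...) {
  cat(sprintf("PLS regression components (h = %d)\n", x$h))
  cat("  % response variance explained:",
      paste(sprintf("%.1f", x$expl_var), collapse = ", "), "\n")
  invisible(x)
}
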