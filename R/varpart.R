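# Variation partitioning of a community matrix between two predictor sets
# (abiotic and biotic) using differences of adjusted R2 from (partial) RDA.

#' Partition community variation between abiotic and biotic predictor sets
#'
#' The total variation of the response is split into four additive fractions
#' of adjusted R2: pure abiotic `[a]`, pure biotic `[b]`, their shared part
#' `[c]` and the unexplained remainder `[d]`:
#' `[a] = adjR2(ab) - adjR2(b)`, `[b] = adjR2(ab) - adjR2(a)`,
#' `[c] = adjR2(a) + adjR2(b) - adjR2(ab)`, `[d] = 1 - adjR2(ab)`.
#' The testable fractions `[a]` and `[b]` get permutation p-values from
#' partial RDA (conditioning on the other set); the shared fraction has no
#' permutation test. Negative adjusted fractions are reported as computed,
#' never truncated, so the additive identities hold exactly.
#'
#' @inheritParams rda_fit
#' @param x_abiotic Abiotic predictor table.
#' @param x_biotic Biotic predictor table.
#' @param n_perm Permutations for the tests of `[a]`, `[b]` and the full
#'   model (default 999; 0 skips testing).
#' @param seed Optional integer seed.
#' @return An object of class `varpart2`: tibble `fractions` (fraction,
#'   r2_adj, perm_p), plus `r2adj_abiotic`, `r2adj_biotic`, `r2adj_full`,
#'   `n_perm`.
#' @export
varpart2 <- function(Y, x_abiotic, x_biotic, n_perm = 999, seed = NULL) {
  Ym <- df_to_matrix(Y, "response")
  Xa <- df_to_matrix(x_abiotic, "abiotic predictors")
  Xb <- df_to_matrix(x_biotic, "biotic predictors")
  if (ncol(Xa) == 0 || ncol(Xb) == 0) abort("both predictor sets must be nonempty")
  check_aligned(Ym, Xa, "response and abiotic predictors")
  check_aligned(Ym, Xb, "response and biotic predictors")
  n <- nrow(Ym)
  r2a_fit <- rda_r2_rank(Ym, Xa)
  r2b_fit <- rda_r2_rank(Ym, Xb)
  r2ab_fit <- rda_r2_rank(Ym, cbind(Xa, Xb))
  if (r2ab_fit$m >= n - 1) abort("combined predictors leave no residual degrees of freedom")
  r2adj_a <- adjusted_r2(r2a_fit$r2, n, r2a_fit$m)
  r2adj_b <- adjusted_r2(r2b_fit$r2, n, r2b_fit$m)
  r2adj_ab <- adjusted_r2(r2ab_fit$r2, n, r2ab_fit$m)
  fa <- r2adj_ab - r2adj_b
  fb <- r2adj_ab - r2adj_a
  fc <- r2adj_a + r2adj_b - r2adj_ab
  fd <- 1 - r2adj_ab
  p_a <- p_b <- p_full <- NA_real_
  if (n_perm > 0) {
    seed <- seed %||% sample.int(.Machine$integer.max, 1)
    # a fraction is untestable when its set adds no span beyond the other
    p_a <- if (r2ab_fit$m == r2b_fit$m) NA_real_ else
      partial_rda(Ym, Xa, Xb, n_perm = n_perm,
                  seed = derive_seed(seed, "fraction-a"))$perm_p
    p_b <- if (r2ab_fit$m == r2a_fit$m) NA_real_ else
      partial_rda(Ym, Xb, Xa, n_perm = n_perm,
                  seed = derive_seed(seed, "fraction-b"))$perm_p
    # test on the span basis so overlapping sets are harmless
    Qfull <- span_basis(scale_matrix(cbind(Xa, Xb), scale = FALSE))
    rownames(Qfull) <- rownames(Ym)
    p_full <- rda_permutation_test(Ym, Qfull, n_perm = n_perm,
                                   seed = derive_seed(seed, "full"))$perm_p
  }
  structure(
    list(fractions = tibble(
      fraction = c("a", "b", "c", "d"),
      label = c("pure abiotic", "pure biotic", "shared", "unexplained"),
      r2_adj = c(fa, fb, fc, fd),
      perm_p = c(p_a, p_b, NA_real_, NA_real_)),
      r2adj_abiotic = r2adj_a, r2adj_biotic = r2adj_b, r2adj_full = r2adj_ab,
      p_full = p_full, n = n, n_perm = n_perm),
    class = "varpart2")
}

# r2 and predictor rank without the strict column checks of rda_fit (varpart
# routinely feeds overlapping sets whose union is rank deficient).
rda_r2_rank <- function(Ym, Xm) {
  Yc <- scale_matrix(Ym, scale = FALSE)
  Xc <- scale_matrix(Xm, scale = FALSE)
  Q <- span_basis(Xc)
  list(r2 = ss_total(crossprod(Q, Yc)) / ss_total(Yc), m = ncol(Q))
}

#' @export
print.varpart2 <- function(x, ...) {
  cat("Variation partitioning (adjusted R2 fractions)\n")
  print(x$fractions)
  if (!is.na(x$p_full)) cat(sprintf("  full model P = %.4g (%d permutations)\n",
                                    x$p_full, x$n_perm))
  invisible(x)
}

#' @describeIn varpart2 Fractions as a tibble.
#' @param x A `varpart2` object.
#' @param ... Unused.
#' @export
tidy.varpart2 <- function(x, ...) {
  x$fractions
}

#' @describeIn varpart2 One-row summary with the three adjusted R2 values.
#' @export
glance.varpart2 <- function(x, ...) {
  tibble(r2adj_abiotic = x$r2adj_abiotic, r2adj_biotic = x$r2adj_biotic,
         r2adj_full = x$r2adj_full, p_full = x$p_full, n = x$n,
         n_perm = x$n_perm)
}

#' Narrative summary of a variation partitioning result
#'
#' Validates the additive identity, formats the fractions as percentages to
#' one decimal and states the ordering among the pure abiotic, pure biotic
#' and shared fractions. A negative shared fraction is reported with a
#' warning, never clamped.
#'
#' @param r A [varpart2()] result.
#' @return A list with `fractions` (tibble with `percent` formatting),
#'   `ordering` (text statement) and `statement`.
#' @export
summarize_varpart <- function(r) {
  stopifnot(inherits(r, "varpart2"))
  fr <- r$fractions$r2_adj
  names(fr) <- r$fractions$fraction
  if (abs(sum(fr) - 1) > 1e-10) {
    abort("fractions do not sum to 1; corrupted result")
  }
  if (fr[["c"]] < 0) {
    warn(sprintf("negative shared fraction [c] = %.4f (reported as computed)",
                 fr[["c"]]))
  }
  ord <- order(-fr[c("a", "b", "c")])
  lab <- c(a = "pure abiotic", b = "pure biotic", c = "shared")[
    names(fr[c("a", "b", "c")])[ord]]
  ordering <- paste(lab, collapse = " > ")
  fractions <- r$fractions |>
    mutate(percent = sprintf("%.1f%%", 100 * .data$r2_adj))
  statement <- sprintf(
    "Explained variation: %s (%s); ordering among fractions: %s.",
    sprintf("%.1f%%", 100 * r$r2adj_full),
    paste(sprintf("[%s] %s", fractions$fraction, fractions$percent),
          collapse = ", "),
    ordering)
  list(fractions = fractions, ordering = ordering, statement = statement)
}
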