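# C-score co-occurrence analysis under the fixed-fixed (FF) swap null model:
# matrix-level segregation tests and pairwise screening with the
# confidence-limit (CL) and empirical mean-Bayes criteria. The null matrices
# come from a sequential checkerboard-swap Markov chain that preserves both
# row (species) and column (site) totals exactly; the chain is symmetric, so
# its stationary distribution is uniform over the fixed-margin class.

#' C-score of a species pair
#'
#' For two presence/absence vectors with row totals `R_a`, `R_b` and `S`
#' shared sites, the checkerboard score is `(R_a - S) * (R_b - S)`. Large
#' values indicate segregation, zero indicates complete overlap.
#'
#' @param occ_a,occ_b Binary site vectors of equal length.
#' @return A single nonnegative number.
#' @export
#' @examples
#' c_score_pair(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 1))
c_score_pair <- function(occ_a, occ_b) {
  if (length(occ_a) != length(occ_b)) {
    abort("occurrence vectors must have equal length")
  }
  if (!all(c(occ_a, occ_b) %in% c(0, 1))) abort("occurrence vectors must be binary")
  s <- sum(occ_a * occ_b)
  (sum(occ_a) - s) * (sum(occ_b) - s)
}

#' Matrix-level C-score
#'
#' Arithmetic mean of [c_score_pair()] over all unique species pairs of a
#' species-by-site occurrence table.
#'
#' @param m Species-by-site occurrence table (first column `species_id`) or
#'   binary matrix.
#' @return A single number.
#' @export
c_score_matrix <- function(m) {
  occ <- occurrence_to_matrix(m)
  r <- nrow(occ)
  if (r < 2) abort("need at least two species")
  mean(pair_c_scores(occ))
}

# Vector of C-scores for all unique pairs (upper triangle order).
pair_c_scores <- function(occ) {
  S <- tcrossprod(occ)
  R <- rowSums(occ)
  D <- (R - S) * t(R - S)   # (R_i - S_ij)(R_j - S_ij)
  D[upper.tri(D)]
}

#' Fixed-fixed swap null ensemble
#'
#' Randomizes a binary species-by-site matrix while preserving every row and
#' column total exactly, by the sequential swap algorithm: repeatedly pick a
#' random 2x2 submatrix and, when it is a checkerboard, swap its diagonal.
#' Matrices are sampled after `burn_in` attempts and every `thin` attempts
#' thereafter. Because the proposal (a uniformly chosen 2x2 submatrix) is
#' symmetric, the chain's stationary distribution is uniform over the
#' fixed-margin class; it is driven by [vegan::nullmodel()]'s compiled
#' `"tswap"` (trial swap) sampler, which counts unswappable proposals as
#' attempts. Matrices without any swappable checkerboard (e.g. fully nested
#' ones) yield an ensemble of copies, with a warning.
#'
#' @param m Species-by-site occurrence table or binary matrix.
#' @param n_null Number of null matrices (default 1000).
#' @param burn_in Swap attempts discarded before the first sample (default
#'   30000).
#' @param thin Swap attempts between samples (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `null_ensemble`: 3-d array `matrices`
#'   (species x sites x n_null), source margins, chain parameters, and a
#'   fingerprint of the source matrix.
#' @export
ff_swap_null <- function(m, n_null = 1000, burn_in = 30000, thin = 1000,
                         seed = NULL) {
  if (n_null < 1) abort("n_null must be >= 1")
  occ <- occurrence_to_matrix(m)
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  if (!has_checkerboard(occ)) {
    warn("matrix has no swappable 2x2 checkerboard; ensemble is copies of the input")
    arr <- array(occ, dim = c(nrow(occ), ncol(occ), n_null))
  } else {
    nm <- vegan::nullmodel(occ, "tswap")
    sim <- stats::simulate(nm, nsim = n_null, burnin = burn_in, thin = thin,
                           seed = seed)
    arr <- array(as.integer(sim), dim = dim(sim)[1:3])
  }
  dimnames(arr) <- list(rownames(occ), colnames(occ), NULL)
  structure(
    list(matrices = arr, n_null = n_null, burn_in = burn_in, thin = thin,
         seed = seed,
         row_totals = rowSums(occ), col_totals = colSums(occ),
         fingerprint = rlang::hash(occ)),
    class = "null_ensemble")
}

# any pair of rows with both (1,0) and (0,1) column patterns?
has_checkerboard <- function(occ) {
  r <- nrow(occ)
  if (r < 2 || ncol(occ) < 2) return(FALSE)
  for (i in seq_len(r - 1)) {
    xi <- occ[i, ]
    for (j in seq((i + 1), r)) {
      xj <- occ[j, ]
      if (any(xi == 1 & xj == 0) && any(xi == 0 & xj == 1)) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("FF null ensemble: %d matrices (%d species x %d sites), burn-in %d, thin %d\n",
              x$n_null, dim(x$matrices)[1], dim(x$matrices)[2],
              x$burn_in, x$thin))
  invisible(x)
}

check_ensemble <- function(m, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  occ <- occurrence_to_matrix(m)
  if (!identical(rlang::hash(occ), ensemble$fingerprint)) {
    abort("ensemble was not built from this matrix")
  }
  occ
}

#' Matrix-level co-occurrence test
#'
#' Compares the observed matrix-level C-score with its distribution over an
#' FF null ensemble. `p_upper` (`p_lower`) is the proportion of null scores
#' at least (at most) as extreme as the observed one, with the add-one
#' correction `(1 + #) / (n_null + 1)`. A null distribution with zero spread
#' is flagged degenerate (p = 1, SES undefined).
#'
#' @param m The occurrence table the ensemble was built from.
#' @param ensemble A [ff_swap_null()] ensemble of `m`.
#' @return A one-row tibble: `observed`, `null_mean`, `null_sd`, `ses`,
#'   `p_upper`, `p_lower`, `degenerate`.
#' @export
matrix_level_test <- function(m, ensemble) {
  occ <- check_ensemble(m, ensemble)
  obs <- c_score_matrix(occ)
  nulls <- apply(ensemble$matrices, 3, function(x) mean(pair_c_scores(x)))
  mu <- mean(nulls); s <- stats::sd(nulls)
  degenerate <- !is.finite(s) || s < 1e-12
  tibble(
    observed = obs, null_mean = mu, null_sd = s,
    ses = if (degenerate) NA_real_ else (obs - mu) / s,
    p_upper = if (degenerate) 1 else
      (1 + sum(nulls >= obs)) / (ensemble$n_null + 1),
    p_lower = if (degenerate) 1 else
      (1 + sum(nulls <= obs)) / (ensemble$n_null + 1),
    degenerate = degenerate, n_null = ensemble$n_null)
}

#' Pairwise co-occurrence screening (CL criterion)
#'
#' Computes every unique species pair's observed C-score and its null
#' distribution across the ensemble. A pair is flagged under the
#' confidence-limit (CL) criterion when its observed score falls outside the
#' central `level` mass of its null distribution, i.e. when the tail
#' proportion `P(null >= c_obs)` or `P(null <= c_obs)` is at most
#' `(1 - level) / 2`; counting ties into the tail keeps the criterion
#' conservative for the heavily tied discrete C-score distributions.
#' Flagged pairs are classified `"segregated"` when the observed score
#' exceeds the null mean and `"aggregated"` when it falls below. Pairs whose
#' null distribution has zero spread are classified `"random"` and flagged
#' degenerate, never significant.
#'
#' @inheritParams matrix_level_test
#' @param level Two-tailed confidence level (default 0.95).
#' @return A tibble with one row per pair: `species_a`, `species_b`, `r_a`,
#'   `r_b`, `shared`, `c_obs`, `null_mean`, `null_sd`, `null_lo`, `null_hi`,
#'   `ses`, `cl_flag`, `bayesm_flag` (initialised `FALSE`, see
#'   [bayes_m_filter()]), `classification`, `degenerate`.
#' @export
pairwise_test <- function(m, ensemble, level = 0.95) {
  occ <- check_ensemble(m, ensemble)
  r <- nrow(occ)
  if (r < 2) abort("need at least two species")
  ids <- rownames(occ) %||% paste0("sp", seq_len(r))
  up <- upper.tri(matrix(0, r, r))
  ia <- row(up)[up]; ib <- col(up)[up]
  S <- tcrossprod(occ)
  R <- rowSums(occ)
  c_obs <- pair_c_scores(occ)
  n_null <- ensemble$n_null
  nullC <- matrix(0, length(c_obs), n_null)
  for (b in seq_len(n_null)) {
    nullC[, b] <- pair_c_scores(ensemble$matrices[, , b])
  }
  mu <- rowMeans(nullC)
  sdv <- sqrt(pmax(rowMeans(nullC^2) - mu^2, 0) * n_null / max(n_null - 1, 1))
  lo_p <- (1 - level) / 2
  sorted <- t(apply(nullC, 1, sort.int, method = "quick"))
  # confidence limits (empirical quantiles), reported for reference
  idx_lo <- max(1L, ceiling(lo_p * n_null))
  idx_hi <- min(n_null, ceiling((1 - lo_p) * n_null))
  null_lo <- sorted[, idx_lo]
  null_hi <- sorted[, idx_hi]
  # tail proportions with ties counted into the tail
  tail_up <- rowMeans(nullC >= c_obs)
  tail_dn <- rowMeans(nullC <= c_obs)
  degenerate <- sdv < 1e-12
  cl_flag <- !degenerate & (tail_up <= lo_p | tail_dn <= lo_p)
  classification <- rep("random", length(c_obs))
  classification[cl_flag & c_obs > mu] <- "segregated"
  classification[cl_flag & c_obs < mu] <- "aggregated"
  cl_flag <- cl_flag & classification != "random"
  out <- tibble(
    species_a = ids[ia], species_b = ids[ib],
    r_a = R[ia], r_b = R[ib], shared = S[up],
    c_obs = c_obs, null_mean = mu, null_sd = sdv,
    null_lo = null_lo, null_hi = null_hi,
    ses = ifelse(degenerate, NA_real_, (c_obs - mu) / sdv),
    cl_flag = cl_flag, bayesm_flag = FALSE,
    classification = classification, degenerate = degenerate)
  attr(out, "level") <- level
  attr(out, "fingerprint") <- ensemble$fingerprint
  attr(out, "null_scores") <- nullC
  class(out) <- c("pair_screen", class(out))
  out
}

#' Empirical mean-Bayes screening of CL-flagged pairs
#'
#' The CL criterion is prone to Type I errors when thousands of pairs are
#' screened. The mean-Bayes filter retains only the excess of observed pairs
#' over the null expectation: the pooled null pair scores define `n_bins`
#' equal-width bins (top bin closed); the expected count per bin is the mean
#' number of pairs falling in it across null matrices; for every bin whose
#' observed count exceeds that expectation, the excess (rounded) most-extreme
#' CL-flagged pairs, ranked by `|SES|`, receive `bayesm_flag`. The mean-Bayes
#' set is a subset of the CL set by construction.
#'
#' @param pairs A [pairwise_test()] result.
#' @param ensemble The ensemble the pairs were screened against.
#' @param n_bins Number of score bins (default 20).
#' @return The `pairs` tibble with `bayesm_flag` updated.
#' @export
bayes_m_filter <- function(pairs, ensemble, n_bins = 20) {
  stopifnot(inherits(pairs, "pair_screen"))
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (!identical(attr(pairs, "fingerprint"), ensemble$fingerprint)) {
    abort("pairs were not screened against this ensemble")
  }
  nullC <- attr(pairs, "null_scores")
  rng <- range(c(nullC, pairs$c_obs))
  if (diff(rng) == 0) {
    pairs$bayesm_flag <- FALSE
    return(pairs)
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_of <- function(x) pmin(findInterval(x, edges, rightmost.closed = TRUE),
                             n_bins)
  obs_bin <- bin_of(pairs$c_obs)
  obs_count <- tabulate(obs_bin, n_bins)
  null_bin <- bin_of(as.vector(nullC))
  exp_count <- tabulate(null_bin, n_bins) / ncol(nullC)
  pairs$bayesm_flag <- FALSE
  for (bin in seq_len(n_bins)) {
    excess <- round(obs_count[bin] - exp_count[bin])
    if (excess < 1) next
    cand <- which(obs_bin == bin & pairs$cl_flag)
    if (!length(cand)) next
    take <- cand[order(-abs(pairs$ses[cand]))][seq_len(min(excess, length(cand)))]
    pairs$bayesm_flag[take] <- TRUE
  }
  pairs
}

#' Cross-tabulate flagged pairs by trophic category and classification
#'
#' Labels every flagged pair `p-p`, `l-l` or `p-l` from the species metadata
#' and counts them by aggregated/segregated classification.
#'
#' @param pairs A [pairwise_test()] (optionally [bayes_m_filter()]-ed)
#'   result.
#' @param meta Species metadata with `species_id` and `trophic_group`
#'   (`"plant"` / `"leafhopper"`).
#' @param criterion `"cl"` or `"bayesm"`: which flag defines the counted set.
#' @return A list with `table` (tibble pair_category x classification with
#'   counts) and `pairs` (the flagged subset with `pair_category` added).
#' @export
classify_pairs <- function(pairs, meta, criterion = c("cl", "bayesm")) {
  criterion <- match.arg(criterion)
  meta <- as_tibble(meta)
  grp <- function(ids) {
    g <- meta$trophic_group[match(ids, meta$species_id)]
    if (anyNA(g)) {
      abort(sprintf("species missing from metadata: %s",
                    paste(unique(ids[is.na(g)]), collapse = ", ")))
    }
    g
  }
  ga <- grp(pairs$species_a)
  gb <- grp(pairs$species_b)
  short <- c(plant = "p", leafhopper = "l")
  cat2 <- function(a, b) {
    x <- paste0(short[a], "-", short[b])
    x[x == "l-p"] <- "p-l"
    x
  }
  flagged <- if (criterion == "cl") pairs$cl_flag else pairs$bayesm_flag
  sub <- pairs[flagged, , drop = FALSE]
  sub$pair_category <- cat2(ga[flagged], gb[flagged])
  tab <- tidyr::expand_grid(pair_category = c("p-p", "l-l", "p-l"),
                            classification = c("segregated", "aggregated")) |>
    left_join(sub |> count(.data$pair_category, .data$classification),
              by = c("pair_category", "classification")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  list(table = tab, pairs = as_tibble(sub))
}
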