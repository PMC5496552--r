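test_that("pair C-score follows the checkerboard formula", {
  expect_identical(c_score_pair(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 1)), 2)
  expect_identical(c_score_pair(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_identical(c_score_pair(c(1, 1, 0, 0), c(0, 0, 1, 1)), 4)
  expect_error(c_score_pair(c(1, 0), c(1, 0, 1)), "length")
})

test_that("matrix C-score equals the exhaustive pair-loop oracle", {
  expect_identical(c_score_matrix(rbind(sp1 = c(1, 0), sp2 = c(0, 1))), 1)
  expect_identical(c_score_matrix(matrix(1, 3, 4,
                                         dimnames = list(paste0("s", 1:3),
                                                         NULL))), 0)
  for (s in 1:50) {
    m <- random_binary(10, 12, fill = 0.4, seed = 300 + s)
    expect_equal(c_score_matrix(m), oracle_c_score_matrix(m),
                 tolerance = 1e-12)
  }
  expect_error(c_score_matrix(random_binary(1, 5)), "two species")
})

test_that("FF ensemble preserves margins exactly and is seeded", {
  m <- random_binary(10, 10, fill = 0.4, seed = 17)
  ens <- ff_swap_null(m, n_null = 50, burn_in = 2000, thin = 100, seed = 4)
  for (b in seq_len(50)) {
    expect_identical(unname(rowSums(ens$matrices[, , b])), unname(rowSums(m)))
    expect_identical(unname(colSums(ens$matrices[, , b])), unname(colSums(m)))
  }
  ens2 <- ff_swap_null(m, n_null = 50, burn_in = 2000, thin = 100, seed = 4)
  expect_identical(ens$matrices, ens2$matrices)
  # nested matrix: no checkerboard anywhere, ensemble is copies
  nested <- rbind(sp1 = c(1, 1), sp2 = c(1, 0))
  expect_warning(ens3 <- ff_swap_null(nested, n_null = 5, seed = 1),
                 "checkerboard")
  for (b in 1:5) expect_identical(unname(ens3$matrices[, , b]),
                                  unname(nested))
})

test_that("swap chain samples the enumerable FF class uniformly", {
  # 3x3 permutation-like matrix: the class is small enough to enumerate
  m <- rbind(sp1 = c(1, 1, 0), sp2 = c(1, 0, 1), sp3 = c(0, 1, 1))
  states <- enumerate_ff_class(m)
  key <- function(x) paste(x, collapse = "")
  ens <- ff_swap_null(m, n_null = 5000, burn_in = 500, thin = 4, seed = 8)
  seen <- apply(ens$matrices, 3, key)
  tab <- table(factor(seen, levels = vapply(states, key, character(1))))
  expect_identical(length(states), 6L)
  expect_true(all(tab > 0))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("matrix-level test flags planted segregation and handles degeneracy", {
  planted <- list(list(a = 1, b = 2, class = "segregated"),
                  list(a = 3, b = 4, class = "segregated"),
                  list(a = 5, b = 6, class = "segregated"),
                  list(a = 7, b = 8, class = "segregated"),
                  list(a = 9, b = 10, class = "segregated"))
  m <- generate_binary_cooccurrence(12, 30, planted, fill = 0.45, seed = 3)
  ens <- ff_swap_null(m, n_null = 300, burn_in = 5000, thin = 100, seed = 5)
  res <- matrix_level_test(m, ens)
  expect_lte(res$p_upper, 0.01)
  expect_gt(res$ses, 0)
  # degenerate singleton class
  nested <- rbind(sp1 = c(1, 1), sp2 = c(1, 0))
  suppressWarnings(ens_d <- ff_swap_null(nested, n_null = 20, seed = 1))
  res_d <- matrix_level_test(nested, ens_d)
  expect_true(res_d$degenerate)
  expect_identical(res_d$p_upper, 1)
  # provenance check
  other <- random_binary(12, 30, seed = 99)
  expect_error(matrix_level_test(other, ens), "not built")
})

test_that("pairwise screening recovers planted pairs with correct classes", {
  planted <- list(list(a = 1, b = 2, class = "segregated"),
                  list(a = 3, b = 4, class = "aggregated"))
  m <- generate_binary_cooccurrence(14, 68, planted, fill = 0.4, seed = 21)
  ens <- ff_swap_null(m, n_null = 400, burn_in = 10000, thin = 200, seed = 22)
  pr <- pairwise_test(m, ens)
  seg <- pr[pr$species_a == "sp01" & pr$species_b == "sp02", ]
  agg <- pr[pr$species_a == "sp03" & pr$species_b == "sp04", ]
  expect_identical(seg$classification, "segregated")
  expect_true(seg$cl_flag)
  expect_identical(seg$shared, 0)
  expect_identical(agg$classification, "aggregated")
  expect_identical(agg$c_obs, 0)
  # PairResult invariants
  expect_true(all(pr$c_obs >= 0))
  expect_true(all(pr$shared <= pmin(pr$r_a, pr$r_b)))
  expect_true(all(pr$classification[pr$cl_flag & pr$c_obs > pr$null_mean] ==
                    "segregated"))
  expect_true(all(!pr$cl_flag[pr$degenerate]))
})

test_that("pairwise type-I rate is near nominal on random matrices", {
  rates <- numeric(30)
  for (s in seq_len(30)) {
    m <- random_binary(12, 25, fill = 0.4, seed = 700 + s)
    ens <- ff_swap_null(m, n_null = 300, burn_in = 5000, thin = 100,
                        seed = 800 + s)
    pr <- pairwise_test(m, ens)
    rates[s] <- mean(pr$cl_flag)
  }
  expect_lte(abs(mean(rates) - 0.05), 0.03)
})

test_that("mean-Bayes filter is a strict subset screen", {
  planted <- list(list(a = 1, b = 2, class = "segregated"),
                  list(a = 3, b = 4, class = "aggregated"))
  m <- generate_binary_cooccurrence(14, 68, planted, fill = 0.4, seed = 31)
  ens <- ff_swap_null(m, n_null = 300, burn_in = 10000, thin = 200, seed = 32)
  pr <- pairwise_test(m, ens)
  pr2 <- bayes_m_filter(pr, ens, n_bins = 20)
  expect_true(all(!pr2$bayesm_flag | pr2$cl_flag))
  # strong planted pairs survive the filter
  expect_true(pr2$bayesm_flag[pr2$species_a == "sp01" & pr2$species_b == "sp02"])
  # empty CL set stays empty
  pr_none <- pr
  pr_none$cl_flag[] <- FALSE
  expect_true(all(!bayes_m_filter(pr_none, ens, 20)$bayesm_flag))
  expect_error(bayes_m_filter(pr, ens, n_bins = 1), "n_bins")
})

test_that("classification cross-tabulates by trophic category", {
  sites <- 40
  planted <- list(list(a = 1, b = 5, class = "segregated"),
                  list(a = 2, b = 6, class = "aggregated"))
  m <- generate_binary_cooccurrence(8, sites, planted, fill = 0.45, seed = 41)
  ens <- ff_swap_null(m, n_null = 300, burn_in = 5000, thin = 100, seed = 42)
  pr <- pairwise_test(m, ens)
  meta <- tibble::tibble(
    species_id = sprintf("sp%02d", 1:8),
    trophic_group = rep(c("plant", "leafhopper"), each = 4))
  cl <- classify_pairs(pr, meta, "cl")
  expect_identical(sum(cl$table$n), sum(pr$cl_flag))
  expect_setequal(unique(cl$table$pair_category), c("p-p", "l-l", "p-l"))
  # planted p-l pairs appear with their classes
  expect_true(any(cl$pairs$pair_category == "p-l" &
                    cl$pairs$classification == "segregated"))
  expect_error(classify_pairs(pr, meta[1:3, ], "cl"), "missing")
  expect_s3_class(autoplot(pr), "ggplot")
})
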