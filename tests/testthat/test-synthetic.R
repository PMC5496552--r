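test_that("environmental blocks have the requested shape and seeded determinism", {
  specs <- vineyard_block_specs()
  env <- generate_env_blocks(68, specs, seed = 1)
  expect_identical(names(env$blocks),
                   c("Man", "Top", "Soil", "Struc", "Land200", "Land500"))
  widths <- vapply(env$blocks, function(b) ncol(b) - 1L, integer(1))
  expect_identical(unname(widths), c(5L, 5L, 9L, 5L, 6L, 6L))
  expect_true(all(vapply(env$blocks, nrow, integer(1)) == 68L))
  env2 <- generate_env_blocks(68, specs, seed = 1)
  expect_identical(env$blocks, env2$blocks)
  expect_identical(env$truth$latent_gradients, env2$truth$latent_gradients)
  # noise-free single-variable blocks are exactly proportional to gradients
  s0 <- list(block_spec("A", 1, latent_loading = 2, noise_sd = 0),
             block_spec("B", 1, noise_sd = 0))
  e0 <- generate_env_blocks(20, s0, seed = 3)
  expect_equal(unname(cor(e0$blocks$A$A_v1,
                          e0$truth$latent_gradients[, "A"])), 1)
  # validation errors
  expect_error(generate_env_blocks(2, specs), "n_sites")
  expect_error(block_spec("A", 0), "n_vars")
  expect_error(generate_env_blocks(10, list(block_spec("A", 2),
                                            block_spec("A", 2))), "unique")
  expect_error(generate_env_blocks(10, list(block_spec("A", 2)),
                                   block_effect_shares = c(1)), NA)
  expect_error(generate_env_blocks(10, list(block_spec("A", 2)),
                                   block_effect_shares = c(0.5, 0.5)),
               "K nonnegative")
})

test_that("plant community responds to the composite gradient and is reproducible", {
  env <- generate_env_blocks(50, vineyard_block_specs(), seed = 7)
  p1 <- generate_plant_community(env, 30, seed = 9)
  p2 <- generate_plant_community(env, 30, seed = 9)
  expect_identical(p1, p2)
  m <- as.matrix(p1[-1])
  expect_true(all(m >= 0 & m <= 100))
  expect_error(generate_plant_community(env, 30, niche_breadth = 0),
               "niche_breadth")
  # noise off: deterministic Gaussian response, species at opposite extremes
  # occupy (almost) disjoint site sets
  p0 <- generate_plant_community(env, 10, niche_breadth = 0.4, noise_sd = 0,
                                 seed = 1)
  m0 <- as.matrix(p0[-1])
  first <- m0[, 1] > 0; last <- m0[, 10] > 0
  expect_lte(sum(first & last), 1)
})

test_that("bottom-up coupling switches producer dependence on and off", {
  env <- generate_env_blocks(2000, list(block_spec("A", 3)), seed = 11)
  plants <- generate_plant_community(env, 12, seed = 12)
  guilds <- make_guild_table(10, setdiff(names(plants), "site_id"), 4)
  # coupling 0: consumer community independent of the producers
  h0 <- generate_leafhopper_community(env, plants, guilds, coupling = 0,
                                      seed = 13)
  cors <- cor(as.matrix(plants[-1]), as.matrix(h0[-1]))
  expect_lt(mean(abs(cors)), 0.05)
  # counts are nonnegative integers
  hm <- as.matrix(h0[-1])
  expect_true(all(hm >= 0 & hm == round(hm)))
  # coupling 1, noise off: specialist presence equals its host presence
  h1 <- generate_leafhopper_community(env, plants, guilds, coupling = 1,
                                      noise = FALSE, seed = 14)
  host <- guilds$host_species[1]
  expect_identical(unname(as.matrix(h1[-1])[, 1] > 0),
                   unname(as.matrix(plants[-1])[, host] > 0))
  # unknown host is an error
  bad <- guilds; bad$host_species[1] <- "Nonexistent_sp"
  expect_error(generate_leafhopper_community(env, plants, bad, seed = 1),
               "absent")
})

test_that("binary generator plants exact aggregation and segregation", {
  planted <- list(list(a = 1, b = 2, class = "segregated"),
                  list(a = "sp03", b = "sp04", class = "aggregated"))
  m <- generate_binary_cooccurrence(10, 24, planted, fill = 0.3, seed = 5)
  mm <- as.matrix(m[-1])
  expect_true(all(mm %in% 0:1))
  expect_identical(sum(mm[1, ] * mm[2, ]), 0L)   # zero shared sites
  expect_identical(mm[3, ], mm[4, ])             # identical occupancy
  expect_identical(c_score_pair(mm[3, ], mm[4, ]), 0L)
  m2 <- generate_binary_cooccurrence(10, 24, planted, fill = 0.3, seed = 5)
  expect_identical(m, m2)
  expect_error(generate_binary_cooccurrence(4, 10, list(
    list(a = 9, b = 1, class = "segregated"))), "unknown species")
  expect_error(generate_binary_cooccurrence(4, 10, fill = 1), "fill")
})

test_that("all-equal niche optima give near-null pairwise structure", {
  # all species share one optimum: occurrence differences are pure noise, so
  # the CL criterion should flag about the nominal share of pairs
  env <- generate_env_blocks(40, list(block_spec("A", 2)), seed = 21)
  env$truth$composite[] <- 0  # flat gradient: identical optima everywhere
  p <- generate_plant_community(env$truth, 10, niche_breadth = 1,
                                noise_sd = 1, detection_floor = 20, seed = 22)
  occ <- to_presence_absence(p)
  keep <- rowSums(as.matrix(occ[-1])) > 0
  occ <- occ[keep, ]
  ens <- ff_swap_null(occ, n_null = 300, burn_in = 5000, thin = 100, seed = 23)
  pr <- pairwise_test(occ, ens)
  expect_lte(mean(pr$cl_flag), 0.1)
})

test_that("the vineyard profile writes a complete, reloadable file set", {
  dir <- withr::local_tempdir()
  sim <- simulate_vineyard(seed = 2, n_sites = 20, n_plants = 15,
                           n_hoppers = 10, n_specialists = 4, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "plants.tsv", "leafhoppers.tsv", "blockmap.tsv", "species_meta.tsv",
    "hosts.tsv", "truth.json")))))
  blocks <- read_blocks(file.path(dir, "blocks"), file.path(dir, "blockmap.tsv"))
  expect_identical(length(blocks), 6L)
  expect_identical(sum(vapply(blocks, ncol, integer(1))), 36L)
  plants <- read_community(file.path(dir, "plants.tsv"),
                           file.path(dir, "species_meta.tsv"))
  expect_equal(as.matrix(plants[-1]), as.matrix(sim$plants[-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$coupling_strength, 0.7)
})

test_that("strong coupling routes abiotic structure into the shared fraction", {
  # with bottom-up coupling >= 0.7 and a strong abiotic signal, the variance
  # the plant-derived biotic block explains in the consumers overlaps the
  # abiotic variance: shared [c] should beat pure biotic [b] in most runs
  n_rep <- 50
  wins <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    sim <- simulate_vineyard(seed = 560000 + s, n_sites = 68, n_plants = 20,
                             n_hoppers = 15, n_specialists = 5,
                             coupling = 0.8)
    Y <- hellinger_transform(sim$hoppers)
    abiotic <- do.call(cbind, lapply(sim$blocks, function(b)
      as.matrix(b[-1])))
    biotic <- plsr_fit(Y, hellinger_transform(log_transform_cover(sim$plants)),
                       h = 2)$scores
    vp <- varpart2(Y, abiotic, biotic, n_perm = 0)
    fr <- setNames(vp$fractions$r2_adj, vp$fractions$fraction)
    wins[s] <- fr[["c"]] > fr[["b"]]
  }
  expect_gte(mean(wins), 0.8)
})
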