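# Synthetic two-trophic-level communities with known ground truth. The
# generator emulates the structure of a vineyard survey: sites described by
# thematic blocks of abiotic variables driven by latent gradients, a producer
# (plant) community responding to the gradients through Gaussian niches, and
# a consumer (leafhopper) community coupled bottom-up to the producers with
# specialist/generalist guild structure, plus planted aggregated/segregated
# pairs for co-occurrence oracles.

#' Specify one synthetic predictor block
#'
#' @param name Block label.
#' @param n_vars Number of variables (>= 1).
#' @param latent_loading Per-variable coefficient on the block's latent
#'   gradient; recycled to `n_vars`.
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @return A `block_spec` list.
#' @export
block_spec <- function(name, n_vars, latent_loading = 1, noise_sd = 0.5) {
  if (n_vars < 1) abort(sprintf("block '%s': n_vars must be >= 1", name))
  if (any(noise_sd < 0)) abort(sprintf("block '%s': noise_sd must be >= 0", name))
  structure(list(name = name, n_vars = as.integer(n_vars),
                 latent_loading = rep_len(latent_loading, n_vars),
                 noise_sd = noise_sd),
            class = "block_spec")
}

#' Generate blocked environmental predictors with known latent structure
#'
#' Each block gets its own standard-normal latent gradient over sites; block
#' variables are `latent_loading * gradient + N(0, noise_sd)`. The returned
#' ground truth records the gradients, the per-block effect shares used by
#' the community generators, and the seed.
#'
#' @param n_sites Number of sites (>= 3).
#' @param specs List of [block_spec()]s with unique names.
#' @param block_effect_shares Nonnegative per-block weights, summing to 1,
#'   giving each block's share of the community-driving composite gradient
#'   (default: equal shares).
#' @param seed Integer seed.
#' @return A list with `blocks` (named list of site-by-variable tibbles) and
#'   `truth` (class `ground_truth`: `latent_gradients` sites x K,
#'   `block_effect_shares`, `composite` gradient, `seed`).
#' @export
generate_env_blocks <- function(n_sites, specs, block_effect_shares = NULL,
                                seed = 1) {
  if (n_sites < 3) abort("n_sites must be >= 3")
  if (!length(specs)) abort("at least one block spec is required")
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "block_spec")) abort("specs must be block_spec objects")
    s
  })
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("block names must be unique")
  K <- length(specs)
  shares <- block_effect_shares %||% rep(1 / K, K)
  if (length(shares) != K || any(shares < 0)) {
    abort("block_effect_shares must be K nonnegative weights")
  }
  if (abs(sum(shares) - 1) > 1e-12) abort("block_effect_shares must sum to 1")
  site_ids <- sprintf("site_%02d", seq_len(n_sites))
  withr::with_seed(seed, {
    G <- matrix(rnorm(n_sites * K), n_sites, K,
                dimnames = list(site_ids, nm))
    blocks <- lapply(seq_len(K), function(k) {
      s <- specs[[k]]
      vals <- outer(G[, k], s$latent_loading) +
        matrix(rnorm(n_sites * s$n_vars, sd = s$noise_sd),
               n_sites, s$n_vars)
      colnames(vals) <- sprintf("%s_v%d", s$name, seq_len(s$n_vars))
      rownames(vals) <- site_ids
      matrix_to_df(vals, id_col = "site_id")
    })
    names(blocks) <- nm
    composite <- as.vector(G %*% sqrt(shares))
  })
  truth <- structure(
    list(latent_gradients = G, block_effect_shares = stats::setNames(shares, nm),
         composite = composite, coupling_strength = NA_real_,
         planted_pairs = list(), seed = seed),
    class = "ground_truth")
  list(blocks = blocks, truth = truth)
}

#' Generate a producer (plant) community along the latent gradients
#'
#' Species optima are spread uniformly over the range of the composite
#' gradient (the share-weighted combination of the block gradients); the
#' expected percent cover of a species at a site is a Gaussian function of
#' the gradient distance to its optimum, with multiplicative log-normal noise
#' and a cap at 100. Values below a small threshold are truncated to zero so
#' that species have realistic occupancies.
#'
#' @param env The `blocks`+`truth` list from [generate_env_blocks()], or a
#'   `ground_truth` object.
#' @param n_species Number of species (>= 2).
#' @param niche_breadth Gaussian niche standard deviation on the gradient
#'   scale (> 0).
#' @param max_cover Expected cover at the optimum, percent.
#' @param noise_sd Log-normal noise sd on the log scale (0 = deterministic).
#' @param detection_floor Covers below this value are recorded as absent.
#' @param seed Integer seed.
#' @return A site-by-species tibble of percent covers in `[0, 100]`.
#' @export
generate_plant_community <- function(env, n_species, niche_breadth = 1,
                                     max_cover = 60, noise_sd = 0.6,
                                     detection_floor = 1, seed = 1) {
  truth <- if (inherits(env, "ground_truth")) env else env$truth
  if (!inherits(truth, "ground_truth")) abort("env must carry a ground_truth")
  if (n_species < 2) abort("n_species must be >= 2")
  if (niche_breadth <= 0) abort("niche_breadth must be > 0")
  g <- truth$composite
  n <- length(g)
  rng <- range(g)
  optima <- seq(rng[1], rng[2], length.out = n_species)
  mu <- max_cover * exp(-outer(g, optima, "-")^2 / (2 * niche_breadth^2))
  withr::with_seed(seed, {
    vals <- if (noise_sd > 0) {
      mu * matrix(rlnorm(n * n_species, meanlog = -noise_sd^2 / 2,
                         sdlog = noise_sd), n, n_species)
    } else {
      mu
    }
  })
  vals <- pmin(vals, 100)
  vals[vals < detection_floor] <- 0
  dimnames(vals) <- list(rownames(truth$latent_gradients),
                         sprintf("Plantgen%02d_sp%02d",
                                 ((seq_len(n_species) - 1) %% 12) + 1,
                                 seq_len(n_species)))
  matrix_to_df(vals, id_col = "site_id")
}

#' Build a guild table for a synthetic consumer community
#'
#' Assigns the first `n_specialists` consumers one host plant species each
#' (cycled over the producer list) and the rest the generalist guild.
#'
#' @param n_species Number of consumer species.
#' @param plant_ids Producer species identifiers.
#' @param n_specialists Number of specialist consumers.
#' @return A tibble with `species_id`, `guild`, `host_species`, `host_genus`.
#' @export
make_guild_table <- function(n_species, plant_ids, n_specialists) {
  stopifnot(n_specialists <= n_species)
  ids <- sprintf("Hoppergen%02d_sp%02d",
                 ((seq_len(n_species) - 1) %% 9) + 1, seq_len(n_species))
  host <- rep(NA_character_, n_species)
  if (n_specialists > 0) {
    host[seq_len(n_specialists)] <- rep_len(plant_ids, n_specialists)
  }
  tibble(species_id = ids,
         guild = c(rep("specialist", n_specialists),
                   rep("generalist", n_species - n_specialists)),
         host_species = host,
         host_genus = ifelse(is.na(host), NA_character_, genus_of(host)))
}

#' Generate a consumer (leafhopper) community coupled to the producers
#'
#' Specialist expected abundance is proportional to the abundance of the
#' assigned host plant; generalist expected abundance to a random-weighted
#' composite of all plants. Both are mixed with an abiotic Gaussian-niche
#' term weighted `1 - coupling`, so `coupling = 1` gives purely bottom-up
#' assemblages and `coupling = 0` assemblages independent of the producers.
#' The abiotic term runs on a consumer-specific latent axis (not the shared
#' composite gradient), so the coupling parameter cleanly switches the
#' bottom-up dependence on and off. Counts are Poisson draws around the
#' expectation (or the rounded expectation when `noise = FALSE`).
#'
#' @inheritParams generate_plant_community
#' @param plants Producer community tibble from [generate_plant_community()].
#' @param guilds Guild table from [make_guild_table()] (columns `species_id`,
#'   `guild`, `host_species`).
#' @param coupling Bottom-up coupling strength in `[0, 1]`.
#' @param mean_abundance Expected count scale at full signal.
#' @param noise Draw Poisson counts (`TRUE`) or return rounded expectations.
#' @return A site-by-species tibble of nonnegative integer counts.
#' @export
generate_leafhopper_community <- function(env, plants, guilds, coupling = 0.7,
                                          niche_breadth = 1,
                                          mean_abundance = 20, noise = TRUE,
                                          seed = 1) {
  truth <- if (inherits(env, "ground_truth")) env else env$truth
  if (!inherits(truth, "ground_truth")) abort("env must carry a ground_truth")
  if (coupling < 0 || coupling > 1) abort("coupling must be in [0, 1]")
  pm <- check_community(plants, "producer community")
  if (nrow(pm) != length(truth$composite)) {
    abort("plants and environment describe different site sets")
  }
  guilds <- as_tibble(guilds)
  n_sp <- nrow(guilds)
  if (n_sp < 1) abort("guild table is empty")
  unknown <- guilds$host_species[guilds$guild == "specialist" &
                                   !is.na(guilds$host_species) &
                                   !(guilds$host_species %in% colnames(pm))]
  if (length(unknown)) {
    abort(sprintf("specialist host(s) absent from the producer community: %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  n <- length(truth$composite)
  # normalise each biotic driver to mean 1 over sites so coupling compares
  # like with like
  unit_mean <- function(v) if (mean(v) > 0) v / mean(v) else v
  withr::with_seed(seed, {
    g <- rnorm(n)  # consumer-specific abiotic axis
    rng <- range(g)
    optima <- seq(rng[1], rng[2], length.out = n_sp)
    wts <- matrix(runif(ncol(pm) * n_sp), ncol(pm), n_sp)
    mu <- matrix(0, n, n_sp)
    for (s in seq_len(n_sp)) {
      biotic <- if (guilds$guild[s] == "specialist" &&
                    !is.na(guilds$host_species[s])) {
        pm[, guilds$host_species[s]]
      } else {
        as.vector(pm %*% wts[, s])
      }
      abiotic <- exp(-(g - optima[s])^2 / (2 * niche_breadth^2))
      mu[, s] <- mean_abundance * (coupling * unit_mean(biotic) +
                                     (1 - coupling) * unit_mean(abiotic))
    }
    counts <- if (noise) {
      matrix(rpois(n * n_sp, lambda = mu), n, n_sp)
    } else {
      round(mu)
    }
  })
  dimnames(counts) <- list(rownames(pm), guilds$species_id)
  matrix_to_df(counts, id_col = "site_id")
}

#' Generate a binary occurrence matrix with planted co-occurrence pairs
#'
#' Background cells are i.i.d. Bernoulli(`fill`); planted segregated pairs
#' are overwritten so that the two species share zero sites (complementary
#' occupancy over a random subset), planted aggregated pairs so that their
#' occupancy is identical.
#'
#' @param n_species,n_sites Matrix dimensions (both >= 2).
#' @param planted_pairs List of `list(a =, b =, class = "segregated" |
#'   "aggregated")` with species indices or ids.
#' @param fill Background occupancy probability, strictly in (0, 1).
#' @param seed Integer seed.
#' @return A species-by-site tibble of 0/1 values with a `planted_pairs`
#'   attribute naming the planted pairs.
#' @export
generate_binary_cooccurrence <- function(n_species, n_sites,
                                         planted_pairs = list(), fill = 0.3,
                                         seed = 1) {
  if (n_species < 2 || n_sites < 2) abort("need at least 2 species and 2 sites")
  if (fill <= 0 || fill >= 1) abort("fill must be strictly between 0 and 1")
  ids <- sprintf("sp%02d", seq_len(n_species))
  resolve <- function(x) {
    if (is.character(x)) x <- match(x, ids)
    if (is.na(x) || x < 1 || x > n_species) abort("planted pair references unknown species")
    as.integer(x)
  }
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_species * n_sites, 1, fill), n_species, n_sites)
    planted <- list()
    for (pp in planted_pairs) {
      a <- resolve(pp$a); b <- resolve(pp$b)
      cls <- match.arg(pp$class, c("segregated", "aggregated"))
      if (cls == "segregated") {
        occ_a <- rbinom(n_sites, 1, 0.5)
        m[a, ] <- occ_a
        m[b, ] <- 1L - occ_a
      } else {
        occ <- rbinom(n_sites, 1, 0.5)
        m[a, ] <- occ
        m[b, ] <- occ
      }
      planted <- c(planted, list(list(a = ids[a], b = ids[b], class = cls)))
    }
  })
  dimnames(m) <- list(ids, sprintf("site_%02d", seq_len(n_sites)))
  out <- matrix_to_df(m, id_col = "species_id")
  attr(out, "planted_pairs") <- planted
  out
}

#' Default block specification of the vineyard emulation profile
#'
#' Six abiotic blocks with the variable counts of a vineyard survey
#' (management 5, topography 5, soil 9, vegetation structure 5, landscape
#' composition at 200 m and 500 m, 6 each).
#'
#' @param noise_sd Within-block noise sd passed to every [block_spec()].
#' @return A list of six `block_spec`s.
#' @export
vineyard_block_specs <- function(noise_sd = 0.5) {
  widths <- c(Man = 5, Top = 5, Soil = 9, Struc = 5, Land200 = 6, Land500 = 6)
  lapply(names(widths), function(nm) {
    block_spec(nm, widths[[nm]], latent_loading = 1, noise_sd = noise_sd)
  })
}

#' Simulate the full vineyard emulation profile
#'
#' Generates the default study-shaped dataset: 68 sites, six abiotic blocks
#' (5/5/9/5/6/6 variables), 120 producer and 80 consumer species (30
#' specialists), bottom-up coupling 0.7, topography-dominant effect shares.
#' Optionally writes the tables as UTF-8 TSV files (`plants.tsv`,
#' `leafhoppers.tsv`, `blocks/*.tsv`, `blockmap.tsv`, `species_meta.tsv`)
#' plus `truth.json` into `out_dir`.
#'
#' @param seed Master seed.
#' @param n_sites,n_plants,n_hoppers,n_specialists Profile sizes.
#' @param coupling Bottom-up coupling strength.
#' @param block_effect_shares Per-block effect shares (default: dominant
#'   topography block, remainder spread equally).
#' @param out_dir Optional output directory.
#' @return A list with `plants`, `hoppers`, `blocks`, `meta`, `hosts`,
#'   `truth` (invisibly if written to disk).
#' @export
simulate_vineyard <- function(seed = 1, n_sites = 68, n_plants = 120,
                              n_hoppers = 80, n_specialists = 30,
                              coupling = 0.7, block_effect_shares = NULL,
                              out_dir = NULL) {
  specs <- vineyard_block_specs()
  shares <- block_effect_shares %||% {
    s <- rep(0.3 / 5, 6); s[2] <- 0.7; s
  }
  env <- generate_env_blocks(n_sites, specs, block_effect_shares = shares,
                             seed = derive_seed(seed, "env"))
  plants <- generate_plant_community(env, n_plants,
                                     seed = derive_seed(seed, "plants"))
  guilds <- make_guild_table(n_hoppers, colnames(df_to_matrix(plants)),
                             n_specialists)
  hoppers <- generate_leafhopper_community(env, plants, guilds,
                                           coupling = coupling,
                                           seed = derive_seed(seed, "hoppers"))
  meta <- bind_rows(
    tibble(species_id = colnames(df_to_matrix(plants)),
           trophic_group = "plant", guild = "none",
           host_genera = NA_character_),
    tibble(species_id = guilds$species_id, trophic_group = "leafhopper",
           guild = guilds$guild, host_genera = guilds$host_genus))
  hosts <- guilds |>
    filter(.data$guild == "specialist") |>
    select(leafhopper_id = "species_id", host_genus = "host_genus",
           host_species = "host_species")
  truth <- env$truth
  truth$coupling_strength <- coupling
  result <- list(plants = plants, hoppers = hoppers, blocks = env$blocks,
                 meta = meta, hosts = hosts, truth = truth, seed = seed)
  if (is.null(out_dir)) return(result)
  dir.create(file.path(out_dir, "blocks"), recursive = TRUE,
             showWarnings = FALSE)
  write_tsv_ <- function(x, path) readr::write_tsv(x, path, progress = FALSE)
  write_tsv_(plants, file.path(out_dir, "plants.tsv"))
  write_tsv_(hoppers, file.path(out_dir, "leafhoppers.tsv"))
  blockmap <- imap(env$blocks, function(b, nm) {
    tibble(variable = setdiff(names(b), "site_id"), block = nm)
  }) |> bind_rows()
  write_tsv_(blockmap, file.path(out_dir, "blockmap.tsv"))
  for (nm in names(env$blocks)) {
    write_tsv_(env$blocks[[nm]], file.path(out_dir, "blocks",
                                           paste0(nm, ".tsv")))
  }
  write_tsv_(meta, file.path(out_dir, "species_meta.tsv"))
  write_tsv_(hosts, file.path(out_dir, "hosts.tsv"))
  jsonlite::write_json(
    list(block_effect_shares = as.list(truth$block_effect_shares),
         coupling_strength = coupling, seed = seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(result)
}
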