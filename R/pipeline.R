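# End-to-end orchestration of the three analysis steps: preprocessing and
# per-block forward selection, multiblock models in both directions with the
# other community entering as a two-component PLS block, variation
# partitioning, and co-occurrence screening on the generalist-common and
# specialist-host submatrices.

#' Read a community table with species metadata
#'
#' Expects a UTF-8, tab-separated file with site rows: first column the site
#' identifier, remaining columns numeric species abundances with unique
#' labels. Metadata (if given) must cover every species column.
#'
#' @param path Community TSV path.
#' @param meta_path Optional species metadata TSV (columns `species_id`,
#'   `trophic_group`, `guild`, ...).
#' @return A tibble; metadata, when supplied, is attached as the
#'   `species_meta` attribute.
#' @export
read_community <- function(path, meta_path = NULL) {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          name_repair = "minimal")
  if (anyDuplicated(names(data))) {
    abort(sprintf("duplicate species column(s) in %s: %s", path,
                  paste(unique(names(data)[duplicated(names(data))]),
                        collapse = ", ")))
  }
  if (nrow(data) == 0 || ncol(data) < 2) abort(sprintf("empty community table: %s", path))
  m <- check_community(data, sprintf("community table %s", path))
  out <- matrix_to_df(m, id_col = names(data)[1])
  if (!is.null(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(colnames(m), meta$species_id)
    if (length(missing)) {
      abort(sprintf("species missing from metadata: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    attr(out, "species_meta") <- meta[match(colnames(m), meta$species_id), ]
  }
  out
}

#' Read predictor blocks from a directory and a block map
#'
#' The block map (TSV with columns `variable`, `block`) assigns every
#' variable to exactly one named block; variables present in the data but
#' absent from the map, or listed twice, are an error. Each block is read
#' from `dir/<block>.tsv`; blocks that end up with zero variables are dropped
#' with a warning. All blocks must share the same ordered site set.
#'
#' @param dir Directory holding one TSV per block.
#' @param blockmap_path Path to the block map TSV.
#' @return A [block_collection()].
#' @export
read_blocks <- function(dir, blockmap_path) {
  map <- readr::read_tsv(blockmap_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("variable", "block") %in% names(map))) {
    abort("block map needs columns 'variable' and 'block'")
  }
  if (anyDuplicated(map$variable)) {
    abort(sprintf("variable(s) mapped twice: %s",
                  paste(unique(map$variable[duplicated(map$variable)]),
                        collapse = ", ")))
  }
  block_names <- unique(map$block)
  blocks <- list()
  for (nm in block_names) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) abort(sprintf("missing block file: %s", path))
    b <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- df_to_matrix(b, sprintf("block '%s'", nm))
    extra <- setdiff(colnames(m), map$variable)
    if (length(extra)) {
      abort(sprintf("variable(s) not in the block map: %s",
                    paste(extra, collapse = ", ")))
    }
    keep <- intersect(colnames(m), map$variable[map$block == nm])
    if (!length(keep)) {
      warn(sprintf("block '%s' has no mapped variables; dropped", nm))
      next
    }
    blocks[[nm]] <- m[, keep, drop = FALSE]
  }
  if (!length(blocks)) abort("no blocks left after mapping")
  block_collection(blocks)
}

#' Assemble a pipeline configuration
#'
#' Collects the tunable parameters of the three-step analysis with the
#' defaults used throughout the package. Smaller permutation / null /
#' bootstrap counts are useful for smoke tests.
#'
#' @param seed Master seed; every stochastic step derives a child seed from
#'   it (see [derive_seed()]).
#' @param min_sites Occupancy filter cutoff.
#' @param alpha,n_perm_select Forward-selection level and permutations.
#' @param h Number of model dimensions, or `"auto"` for cross-validated
#'   choice up to `h_max`.
#' @param h_max,cv_repeats Cross-validation search range and repeats.
#' @param bootstrap_b,level Bootstrap replicates and interval level (0 skips
#'   the bootstrap).
#' @param n_perm_varpart Permutations for the variation partitioning tests.
#' @param n_null,burn_in,thin,n_bins Co-occurrence chain and binning
#'   parameters.
#' @param n_common Number of common producers in the G-C submatrix.
#' @return A list of class `trophlink_config`.
#' @export
trophlink_config <- function(seed = 1, min_sites = 5, alpha = 0.05,
                             n_perm_select = 9999, h = "auto", h_max = 5,
                             cv_repeats = 20, bootstrap_b = 200,
                             level = 0.95, n_perm_varpart = 999,
                             n_null = 1000, burn_in = 30000, thin = 1000,
                             n_bins = 20, n_common = 88) {
  cfg <- as.list(environment())
  structure(cfg, class = "trophlink_config")
}

#' Step 1: forward selection, PLS biotic blocks and the two multiblock models
#'
#' For each response community, candidate abiotic variables are screened by
#' per-block forward selection (double-stopping, `alpha`,
#' `n_perm_select` permutations); blocks emptied by selection are dropped
#' with a warning (shrinking `K` and the `1/K` threshold). The other
#' community is summarised by its first two PLS components, which enter the
#' multiblock model as the biotic block. Dimensionality is chosen by
#' repeated twofold cross-validation when `h = "auto"`, and bootstrap
#' tolerance intervals are attached when `bootstrap_b > 1`.
#'
#' @param plants Producer community table (already transformed/filtered).
#' @param hoppers Consumer community table (already transformed/filtered).
#' @param blocks Abiotic [block_collection()].
#' @param config A [trophlink_config()].
#' @return A list with per-response entries `plants` and `leafhoppers`, each
#'   holding `selection` (per-block forward selections), `pls`
#'   (the other community's components), `model` (the [mbra_fit()]),
#'   `cv` (when `h = "auto"`) and `boot` (when bootstrapped).
#' @export
run_step1 <- function(plants, hoppers, blocks, config = trophlink_config()) {
  blocks <- block_collection(blocks)
  one_direction <- function(Y, other, label) {
    sseed <- derive_seed(config$seed, paste0("step1-", label))
    selection <- imap(blocks, function(b, nm) {
      forward_select(Y, b, alpha = config$alpha,
                     n_perm = config$n_perm_select,
                     seed = derive_seed(sseed, paste0("select-", nm)))
    })
    kept <- list()
    for (nm in names(blocks)) {
      sel <- selection[[nm]]$selected
      if (!length(sel)) {
        warn(sprintf("[%s] block '%s' empty after forward selection; dropped",
                     label, nm))
        next
      }
      kept[[nm]] <- blocks[[nm]][, sel, drop = FALSE]
    }
    pls <- plsr_fit(Y, other, h = 2)
    biotic <- pls$scores
    colnames(biotic) <- paste0("Biotic_", c("pls1", "pls2"))
    kept$Biotic <- biotic
    h_use <- config$h
    cv <- NULL
    if (identical(h_use, "auto")) {
      cv <- select_ncomp_cv(Y, kept, h_max = config$h_max,
                            repeats = config$cv_repeats,
                            seed = derive_seed(sseed, "cv"))
      h_use <- cv$h_opt
    }
    model <- mbra_fit(Y, kept, h = h_use)
    boot <- NULL
    if (config$bootstrap_b > 1) {
      boot <- mbra_bootstrap(Y, kept, h = h_use, B = config$bootstrap_b,
                             level = config$level,
                             seed = derive_seed(sseed, "boot"))
    }
    list(selection = selection, pls = pls, blocks = kept, model = model,
         cv = cv, boot = boot)
  }
  list(plants = one_direction(plants, hoppers, "plants"),
       leafhoppers = one_direction(hoppers, plants, "leafhoppers"))
}

#' Run the full three-step analysis
#'
#' Orchestrates the pipeline end to end on already-transformed community
#' tables: Step 1 ([run_step1()]), Step 2 ([varpart2()] with all selected
#' abiotic variables against the two-component biotic matrix, per response),
#' and Step 3 (matrix-level tests on both communities plus pairwise
#' screening of the generalist-common and specialist-host submatrices).
#'
#' @inheritParams run_step1
#' @param meta Species metadata (`species_id`, `trophic_group`, `guild`).
#' @param hosts Host association table for specialists.
#' @return A list of class `trophlink_report` with entries `step1`, `step2`,
#'   `step3`, `config`.
#' @export
run_all <- function(plants, hoppers, blocks, meta, hosts,
                    config = trophlink_config()) {
  blocks <- block_collection(blocks)
  step1 <- run_step1(plants, hoppers, blocks, config)

  step2 <- lapply(c(plants = "plants", leafhoppers = "leafhoppers"),
                  function(resp) {
    dir <- step1[[resp]]
    Y <- if (resp == "plants") plants else hoppers
    abiotic <- do.call(cbind, dir$blocks[setdiff(names(dir$blocks), "Biotic")])
    if (is.null(abiotic) || ncol(abiotic) == 0) {
      # selection is a parsimony device; when it retains nothing the
      # abiotic/biotic partition still needs an abiotic matrix
      warn(sprintf(
        "step2 (%s): no abiotic variables survived selection; using all",
        resp))
      abiotic <- do.call(cbind, lapply(blocks, identity))
    }
    vp <- varpart2(Y, abiotic, dir$blocks$Biotic,
                   n_perm = config$n_perm_varpart,
                   seed = derive_seed(config$seed, paste0("varpart-", resp)))
    list(varpart = vp, summary = summarize_varpart(vp))
  })

  occ_p <- to_presence_absence(plants)
  occ_h <- to_presence_absence(hoppers)
  mat_test <- function(occ, label) {
    ens <- ff_swap_null(occ, n_null = config$n_null, burn_in = config$burn_in,
                        thin = config$thin,
                        seed = derive_seed(config$seed, paste0("ff-", label)))
    matrix_level_test(occ, ens)
  }
  pair_run <- function(occ, label) {
    ens <- ff_swap_null(occ, n_null = config$n_null, burn_in = config$burn_in,
                        thin = config$thin,
                        seed = derive_seed(config$seed, paste0("ffpairs-", label)))
    pr <- pairwise_test(occ, ens, level = config$level)
    pr <- bayes_m_filter(pr, ens, n_bins = config$n_bins)
    list(pairs = pr,
         cl = classify_pairs(pr, meta, "cl"),
         bayesm = classify_pairs(pr, meta, "bayesm"))
  }
  sub <- build_pair_matrices(occ_p, occ_h, meta, hosts,
                             n_common = config$n_common)
  step3 <- list(
    matrix_level = list(plants = mat_test(occ_p, "plants"),
                        leafhoppers = mat_test(occ_h, "leafhoppers")),
    gc = pair_run(sub$gc, "gc"),
    sh = pair_run(sub$sh, "sh"),
    unmatched = sub$unmatched)

  structure(list(step1 = step1, step2 = step2, step3 = step3,
                 config = config),
            class = "trophlink_report")
}

#' @export
print.trophlink_report <- function(x, ...) {
  cat("Three-step assemblage analysis\n")
  for (resp in c("plants", "leafhoppers")) {
    m <- x$step1[[resp]]$model
    cat(sprintf("\n[%s] multiblock model: h = %d, explained variance %.1f%%\n",
                resp, m$h, 100 * m$expl_y_cum[m$h]))
    cat("  ", x$step2[[resp]]$summary$statement, "\n")
  }
  ml <- x$step3$matrix_level
  cat(sprintf("\nMatrix-level C-score: plants SES %.2f (p_upper %.4g); leafhoppers SES %.2f (p_upper %.4g)\n",
              ml$plants$ses, ml$plants$p_upper,
              ml$leafhoppers$ses, ml$leafhoppers$p_upper))
  for (nm in c("gc", "sh")) {
    pr <- x$step3[[nm]]$pairs
    cat(sprintf("%s pairs: %d CL-flagged, %d mean-Bayes-flagged of %d\n",
                toupper(nm), sum(pr$cl_flag), sum(pr$bayesm_flag), nrow(pr)))
  }
  invisible(x)
}
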