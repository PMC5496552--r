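# Response-matrix preparation: transforms, rarity filtering, presence-absence
# conversion and assembly of the two pairwise screening submatrices.

check_community <- function(data, what = "community table") {
  m <- df_to_matrix(data, what)
  if (ncol(m) == 0 || nrow(m) == 0) abort(sprintf("empty %s", what))
  if (any(m < 0)) abort(sprintf("negative abundance in %s", what))
  m
}

#' Log-transform a cover/abundance table
#'
#' Applies `x -> log(1 + x)` cell-wise (natural log by default), the usual way
#' of damping the influence of highly abundant species in percent-cover data.
#' Zeros map to zero and ordering is preserved.
#'
#' @param data Site-by-species table: a data frame whose first column is the
#'   site identifier, remaining columns nonnegative species abundances.
#' @param base Logarithm base, default `exp(1)`.
#' @return A tibble of the same shape with transformed values.
#' @export
log_transform_cover <- function(data, base = exp(1)) {
  m <- check_community(data)
  matrix_to_df(log1p(m) / log(base), id_col = first_colname(data))
}

#' Hellinger-transform an abundance table
#'
#' Each cell becomes the square root of the species' relative abundance in its
#' site: `y_ij -> sqrt(y_ij / sum_j y_ij)`. The transform reduces the weight
#' of both very abundant species and double absences, and makes Euclidean
#' ordination distances ecologically meaningful. Sites with zero total keep
#' all-zero rows.
#'
#' @inheritParams log_transform_cover
#' @return A tibble of the same shape with transformed values.
#' @export
hellinger_transform <- function(data) {
  m <- check_community(data)
  rs <- rowSums(m)
  rs[rs == 0] <- 1  # all-zero rows stay all-zero
  matrix_to_df(sqrt(m / rs), id_col = first_colname(data))
}

#' Drop species occurring in fewer than `min_sites` sites
#'
#' The rarity filter removes species whose occupancy (number of sites with
#' abundance > 0) is below a cutoff, guarding the downstream analyses against
#' vagrant and accidental records. The site set is unchanged and surviving
#' species keep their order.
#'
#' @inheritParams log_transform_cover
#' @param min_sites Minimum occupancy required to retain a species.
#' @return A tibble with the retained species columns.
#' @export
occupancy_filter <- function(data, min_sites = 5) {
  stopifnot(min_sites >= 0)
  m <- check_community(data)
  keep <- colSums(m > 0) >= min_sites
  if (!any(keep)) warn("occupancy filter removed every species")
  matrix_to_df(m[, keep, drop = FALSE], id_col = first_colname(data))
}

#' Convert an abundance table to a presence-absence occurrence table
#'
#' Cells become 1 where abundance is strictly positive. The result is
#' transposed to the species-by-site orientation used by the co-occurrence
#' null models: first column `species_id`, remaining columns one per site.
#'
#' @inheritParams log_transform_cover
#' @return A species-by-site tibble of 0/1 values.
#' @export
to_presence_absence <- function(data) {
  m <- check_community(data)
  occ <- t((m > 0) * 1L)
  matrix_to_df(occ, id_col = "species_id")
}

first_colname <- function(data) {
  if (is.data.frame(data) && ncol(data) >= 1 && !is.numeric(data[[1]])) {
    names(data)[1]
  } else {
    "site_id"
  }
}

occurrence_to_matrix <- function(occ) {
  m <- df_to_matrix(occ, "occurrence table")
  if (!all(m %in% c(0, 1))) abort("occurrence table must be binary 0/1")
  m
}

#' Assemble the generalist-common and specialist-host pairwise submatrices
#'
#' Builds the two species-by-site occurrence submatrices screened for pairwise
#' co-occurrence: `gc` stacks all generalist consumers with the most
#' widespread and abundant producers ("common" producers, ranked by occupancy
#' with ties broken by total abundance), and `sh` stacks all specialist
#' consumers with the union of their matched host producers. Host matching
#' tries the exact host species first and otherwise accepts any congeneric
#' producer present in the data; specialists with no match at species or genus
#' level are reported in `unmatched` and excluded from `sh`.
#'
#' @param plants Producer occurrence table (species-by-site, as returned by
#'   [to_presence_absence()]).
#' @param hoppers Consumer occurrence table (species-by-site).
#' @param meta Species metadata: columns `species_id`, `trophic_group`
#'   (`"plant"`/`"leafhopper"`), `guild` (`"generalist"`, `"specialist"` or
#'   `"none"`).
#' @param hosts Host association table for specialists: columns
#'   `leafhopper_id`, `host_genus`, optionally `host_species`.
#' @param n_common Number of common producers retained in `gc`.
#' @return A list with species-by-site tibbles `gc` and `sh` (with a
#'   `provenance` attribute tibble giving trophic group and guild per row) and
#'   a tibble `unmatched` of specialists without any matchable host.
#' @export
build_pair_matrices <- function(plants, hoppers, meta, hosts, n_common = 88) {
  pm <- occurrence_to_matrix(plants)
  hm <- occurrence_to_matrix(hoppers)
  if (!identical(colnames(pm), colnames(hm))) {
    abort("producer and consumer occurrence tables must share the same sites")
  }
  meta <- as_tibble(meta)
  need <- c("species_id", "trophic_group", "guild")
  if (!all(need %in% names(meta))) {
    abort("meta must have columns species_id, trophic_group, guild")
  }
  guild_of <- function(ids) {
    meta$guild[match(ids, meta$species_id)]
  }

  # G-C: generalist consumers + top-N common producers
  gen_ids <- rownames(hm)[guild_of(rownames(hm)) == "generalist"]
  occ <- rowSums(pm > 0)
  abun <- rowSums(pm)
  ord <- order(-occ, -abun, seq_along(occ))
  common_ids <- rownames(pm)[ord][seq_len(min(n_common, nrow(pm)))]
  gc <- rbind(hm[gen_ids, , drop = FALSE], pm[common_ids, , drop = FALSE])

  # S-H: specialist consumers + matched hosts (exact species, else congenus)
  spec_ids <- rownames(hm)[guild_of(rownames(hm)) == "specialist"]
  hosts <- as_tibble(hosts)
  if (!all(c("leafhopper_id", "host_genus") %in% names(hosts))) {
    abort("hosts must have columns leafhopper_id, host_genus")
  }
  plant_genus <- genus_of(rownames(pm))
  matched_hosts <- character(0)
  unmatched <- character(0)
  kept_spec <- character(0)
  for (sp in spec_ids) {
    asc <- hosts[hosts$leafhopper_id == sp, , drop = FALSE]
    found <- character(0)
    if (nrow(asc)) {
      if ("host_species" %in% names(asc)) {
        exact <- asc$host_species[!is.na(asc$host_species) &
                                    asc$host_species %in% rownames(pm)]
        found <- c(found, exact)
      }
      if (!length(found)) {
        cong <- rownames(pm)[plant_genus %in% asc$host_genus]
        found <- c(found, cong)
      }
    }
    if (length(found)) {
      kept_spec <- c(kept_spec, sp)
      matched_hosts <- union(matched_hosts, found)
    } else {
      unmatched <- c(unmatched, sp)
    }
  }
  # keep host rows in producer-table order
  matched_hosts <- rownames(pm)[rownames(pm) %in% matched_hosts]
  sh <- rbind(hm[kept_spec, , drop = FALSE], pm[matched_hosts, , drop = FALSE])

  prov <- function(ids) {
    tibble(species_id = ids,
           trophic_group = meta$trophic_group[match(ids, meta$species_id)],
           guild = meta$guild[match(ids, meta$species_id)])
  }
  gc_df <- matrix_to_df(gc, id_col = "species_id")
  sh_df <- matrix_to_df(sh, id_col = "species_id")
  attr(gc_df, "provenance") <- prov(rownames(gc))
  attr(sh_df, "provenance") <- prov(rownames(sh))
  list(gc = gc_df, sh = sh_df,
       unmatched = tibble(species_id = unmatched))
}

# "Genus_species" or "Genus species" naming; genus = first token.
genus_of <- function(ids) {
  sub("[_ ].*$", "", ids)
}
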