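# Internal representation helpers. User-facing tables are tibbles whose first
# column is an identifier (site_id for site x variable tables, species_id for
# species x site occurrence tables); numerical work happens on plain matrices
# with ids kept in dimnames.

#' Derive a child seed from a master seed and a label
#'
#' Every stochastic step of the pipeline draws its own seed deterministically
#' from the master seed and a step label, so that reruns are reproducible
#' end-to-end and steps can be re-executed in isolation.
#'
#' @param master Integer master seed.
#' @param label Character label naming the consuming step.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "step1-plants")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  h <- (as.double(master) %% 2147483647) + 1
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Convert a community / predictor table to a numeric matrix. If the first
# column is non-numeric it is treated as the id column and moved to rownames.
df_to_matrix <- function(data, what = "table") {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  if (!is.data.frame(data)) {
    abort(sprintf("%s must be a data frame or matrix", what))
  }
  df <- as.data.frame(data)
  ids <- NULL
  if (ncol(df) >= 1 && !is.numeric(df[[1]])) {
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      abort(sprintf("duplicate identifiers in %s: %s", what,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    df <- df[, -1, drop = FALSE]
  }
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric column(s) in %s: %s", what,
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(names(df))) {
    abort(sprintf("duplicate column labels in %s", what))
  }
  m <- as.matrix(df)
  if (!is.null(ids)) rownames(m) <- ids
  m
}

# Back to a tibble with an explicit id column.
matrix_to_df <- function(m, id_col = "site_id") {
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  out <- tibble(!!id_col := ids, !!!out)
  out
}

# Column-centre (and optionally unit-scale) a matrix; constant columns get
# scale 1 so they stay finite.
scale_matrix <- function(m, scale = TRUE) {
  ctr <- colMeans(m)
  x <- sweep(m, 2, ctr, "-")
  scl <- rep(1, ncol(m))
  if (scale) {
    scl <- apply(x, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    x <- sweep(x, 2, scl, "/")
  }
  attr(x, "center") <- ctr
  attr(x, "scale") <- scl
  x
}

# Orthonormal basis of the column span of X (columns with negligible residual
# norm dropped). Returns a matrix with 0 columns when X has no span.
span_basis <- function(x, tol = 1e-10) {
  if (is.null(dim(x)) || ncol(x) == 0) {
    return(matrix(0, nrow = NROW(x), ncol = 0))
  }
  qr_x <- qr(x, tol = tol)
  r <- qr_x$rank
  if (r == 0) return(matrix(0, nrow = nrow(x), ncol = 0))
  qr.Q(qr_x)[, seq_len(r), drop = FALSE]
}

# Sum of squares of a (centred) matrix.
ss_total <- function(m) sum(m^2)

check_aligned <- function(a, b, what = "inputs") {
  if (nrow(a) != nrow(b)) {
    abort(sprintf("%s must have the same number of rows (%d vs %d)",
                  what, nrow(a), nrow(b)))
  }
  ra <- rownames(a); rb <- rownames(b)
  if (!is.null(ra) && !is.null(rb) && !identical(ra, rb)) {
    abort(sprintf("%s are not aligned on the same sites", what))
  }
  invisible(TRUE)
}
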