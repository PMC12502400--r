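#' Shannon diversity index (natural log)
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the sum-normalized abundance vector;
#' zero entries contribute nothing. Natural log is used throughout the
#' package, so a community of n equally abundant members has \eqn{H = \ln n}.
#'
#' @param abundances non-negative numeric vector with at least one positive
#'   entry.
#' @return Shannon index in nats.
#' @export
shannon <- function(abundances) {
  if (any(abundances < 0, na.rm = TRUE)) abort("negative abundances")
  if (anyNA(abundances) || sum(abundances) <= 0) {
    abort("Shannon index undefined for an all-zero abundance vector")
  }
  as.numeric(vegan::diversity(abundances, index = "shannon"))
}

#' Per-sample Shannon diversity of an omics table
#'
#' @param t an `omics_table`.
#' @return tibble with columns `sample`, `layer`, `shannon`.
#' @export
sample_shannon <- function(t) {
  stopifnot(inherits(t, "omics_table"))
  tibble::tibble(
    sample = colnames(t$values),
    layer = t$layer,
    shannon = as.numeric(apply(t$values, 2, shannon))
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} for every sample
#' pair of the table. Values lie in \[0, 1\]; identical columns give 0 and
#' disjoint supports give 1. A table containing an all-zero sample is
#' rejected (the distance to it is undefined).
#'
#' @param t an `omics_table` (raw or normalized).
#' @return symmetric numeric matrix of class `distance_matrix` with sample
#'   dimnames and zero diagonal.
#' @export
bray_curtis <- function(t) {
  stopifnot(inherits(t, "omics_table"))
  if (ncol(t$values) < 2) abort("need >=2 samples for a distance matrix")
  zero <- colSums(t$values) == 0
  if (any(zero)) {
    abort(paste0("Bray-Curtis undefined for all-zero sample(s): ",
                 toString(head(colnames(t$values)[zero], 5))))
  }
  d <- as.matrix(vegan::vegdist(Matrix_t(t$values), method = "bray"))
  diag(d) <- 0
  class(d) <- c("distance_matrix", class(d))
  d
}

# samples-in-rows view used by vegan
Matrix_t <- function(values) t(values)

# Validate an externally supplied distance matrix.
as_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (is.null(rownames(d))) abort("distance matrix must carry sample names")
  if (max(abs(d - t(d))) > 1e-12) abort("distance matrix must be symmetric")
  if (any(diag(d) != 0)) abort("distance matrix diagonal must be 0")
  if (any(d < 0)) abort("distance matrix entries must be non-negative")
  class(d) <- c("distance_matrix", "matrix", "array")
  d
}
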