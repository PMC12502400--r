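#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix. For a categorical grouping the
#' pseudo-F comes from the classical decomposition of the squared
#' dissimilarities,
#' \deqn{F = \frac{SS_B / (k - 1)}{SS_W / (n - k)},}
#' with \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g} and
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n}; \eqn{R^2 = SS_B / SS_T}. For a
#' numeric factor (e.g. age) the equivalent Gower-matrix regression form is
#' used: the doubly centred matrix \eqn{G = -\frac12 C D^{(2)} C} is
#' projected on the centred covariate and \eqn{F = SS_{model} /
#' (SS_{res}/(n-2))}.
#'
#' The permutation p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{F^\pi \ge F\}) / (1 + n_{perm})}, so p is never 0 and is
#' bounded below by \eqn{1/(n_{perm}+1)}. When the grouping has two levels
#' and the number of distinct label assignments is at most `n_perm`, the
#' permutation distribution is enumerated exhaustively instead of sampled
#' and \eqn{p} is the exact fraction of assignments (the observed one
#' included) with \eqn{F^\pi \ge F}.
#'
#' Samples with a missing factor value are dropped before testing.
#' Permutations are free (no strata).
#'
#' @param d symmetric distance matrix with sample dimnames (e.g. from
#'   [bray_curtis()]).
#' @param labels grouping factor (character/factor, >=2 groups of >=2
#'   samples) or numeric covariate, aligned with the rows of `d`.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream; the global RNG state
#'   is left untouched.
#' @param factor_name label recorded in the result.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; `NULL` (default) enumerates automatically when feasible.
#' @return an object of class `permanova` with fields `factor`, `pseudo_F`,
#'   `R2`, `p`, `n_perm`, `n`, `method`, `exhaustive`.
#' @export
permanova <- function(d, labels, n_perm = 1000, seed = NULL,
                      factor_name = "group", exhaustive = NULL) {
  d <- as_distance_matrix(d)
  if (length(labels) != nrow(d)) abort("`labels` must align with the distance matrix")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  keep <- !is.na(labels)
  d <- d[keep, keep, drop = FALSE]
  labels <- labels[keep]
  n <- nrow(d)
  d2 <- d^2
  sst <- sum(d2) / (2 * n)
  if (sst <= .Machine$double.eps * n^2) {
    abort("constant distance matrix: zero total sum of squares")
  }

  if (is.numeric(labels)) {
    res <- permanova_continuous(d2, labels, n_perm, seed, sst)
    method <- "continuous"
    exh <- FALSE
  } else {
    if (!is.factor(labels)) {
      labels <- factor(as.character(labels),
                       levels = sort(unique(as.character(labels)), method = "radix"))
    }
    labels <- droplevels(labels)
    sizes <- table(labels)
    if (length(sizes) < 2) abort("need >=2 groups")
    if (any(sizes < 2)) {
      abort(paste0("group(s) with <2 samples: ",
                   toString(names(sizes)[sizes < 2])))
    }
    n_assign <- choose(n, sizes[1])
    exh <- if (is.null(exhaustive)) {
      length(sizes) == 2 && n_assign <= n_perm
    } else {
      isTRUE(exhaustive)
    }
    if (exh && length(sizes) != 2) abort("exhaustive enumeration supports two groups only")
    res <- permanova_categorical(d2, labels, n_perm, seed, sst, exh)
    method <- "categorical"
  }

  structure(
    list(factor = factor_name, pseudo_F = res$F_obs, R2 = res$R2, p = res$p,
         n_perm = res$n_perm, n = n, method = method, exhaustive = exh),
    class = "permanova"
  )
}

# SS_within for one label assignment, from the squared-distance matrix.
ss_within <- function(d2, labels) {
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
}

permanova_categorical <- function(d2, labels, n_perm, seed, sst, exh) {
  n <- length(labels)
  k <- nlevels(labels)
  ssw <- ss_within(d2, labels)
  ssb <- sst - ssw
  F_obs <- (ssb / (k - 1)) / (ssw / (n - k))
  R2 <- ssb / sst

  if (exh) {
    g1 <- levels(labels)[1]
    m <- sum(labels == g1)
    sets <- combn(n, m)
    F_all <- apply(sets, 2, function(idx) {
      lab <- factor(ifelse(seq_len(n) %in% idx, g1, "other"))
      ssw_p <- ss_within(d2, lab)
      ((sst - ssw_p) / (k - 1)) / (ssw_p / (n - k))
    })
    p <- mean(F_all >= F_obs - 1e-12)
    return(list(F_obs = F_obs, R2 = R2, p = p, n_perm = ncol(sets)))
  }

  perms <- draw_permutations(n, n_perm, seed)
  # vectorized within-group quadratic forms over all permutations
  ssw_perm <- numeric(n_perm)
  for (g in levels(labels)) {
    sel <- labels == g
    ind <- matrix(0, n, n_perm)
    ind[cbind(as.vector(perms[sel, ]), rep(seq_len(n_perm), each = sum(sel)))] <- 1
    ssw_perm <- ssw_perm + colSums(ind * (d2 %*% ind)) / (2 * sum(sel))
  }
  F_perm <- ((sst - ssw_perm) / (k - 1)) / (ssw_perm / (n - k))
  p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)
  list(F_obs = F_obs, R2 = R2, p = p, n_perm = n_perm)
}

permanova_continuous <- function(d2, x, n_perm, seed, sst) {
  n <- length(x)
  if (sd(x) == 0) abort("constant covariate")
  G <- gower_center(d2)
  xc <- x - mean(x)
  ssm <- drop(crossprod(xc, G %*% xc)) / sum(xc^2)
  F_obs <- ssm / ((sst - ssm) / (n - 2))
  R2 <- ssm / sst
  perms <- draw_permutations(n, n_perm, seed)
  X <- matrix(xc[perms], n, n_perm)
  ssm_perm <- colSums(X * (G %*% X)) / colSums(X^2)
  F_perm <- ssm_perm / ((sst - ssm_perm) / (n - 2))
  p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)
  list(F_obs = F_obs, R2 = R2, p = p, n_perm = n_perm)
}

gower_center <- function(d2) {
  A <- -0.5 * d2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) + mean(A)
}

draw_permutations <- function(n, n_perm, seed) {
  draw <- function() vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA [%s]: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%s%d permutations, n = %d)\n",
              x$factor, x$pseudo_F, x$R2, x$p,
              if (x$exhaustive) "exhaustive " else "", x$n_perm, x$n))
  invisible(x)
}

#' @rdname permanova
#' @param x a `permanova` object.
#' @param ... unused.
#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(factor = x$factor, pseudo_F = x$pseudo_F, R2 = x$R2,
                 p = x$p, n_perm = x$n_perm, n = x$n, method = x$method)
}

#' @rdname permanova
#' @export
glance.permanova <- function(x, ...) tidy(x)

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] on the sub-matrix of every unordered pair of groups and
#' adjusts the permutation p-values across the pairs with Benjamini-Hochberg.
#'
#' @inheritParams permanova
#' @return tibble with one row per group pair: `comparison`, `pseudo_F`,
#'   `R2`, `p`, `q`, `n_perm`, `n`.
#' @export
pairwise_permanova <- function(d, labels, n_perm = 1000, seed = NULL) {
  d <- as_distance_matrix(d)
  # locale-independent pair order: factor level order when given, C order otherwise
  lev <- if (is.factor(labels)) levels(droplevels(labels)) else
    sort(unique(as.character(labels)), method = "radix")
  labels <- factor(as.character(labels), levels = lev)
  if (length(lev) < 2) abort("need >=2 groups")
  pairs <- combn(lev, 2, simplify = FALSE)
  rows <- purrr::imap(pairs, function(pr, i) {
    keep <- labels %in% pr
    fit <- permanova(d[keep, keep, drop = FALSE], droplevels(labels[keep]),
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else sub_seed(seed, i),
                     factor_name = comparison_label(pr[1], pr[2]),
                     exhaustive = FALSE)
    dplyr::rename(tidy(fit), comparison = "factor")[, c("comparison", "pseudo_F", "R2", "p", "n_perm", "n")]
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, q = p.adjust(.data$p, method = "BH"), .after = "p")
}
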