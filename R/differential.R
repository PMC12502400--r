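#' Kruskal-Wallis omnibus test with Dunn post hoc, per feature
#'
#' For every feature of the table, runs a tie-corrected Kruskal-Wallis test
#' across the three diagnosis groups followed by Dunn's pairwise post hoc
#' comparisons on the joint ranks:
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with average ranks for ties and two-sided normal p-values.
#' Benjamini-Hochberg adjustment is applied across features separately
#' within the omnibus family and within each pairwise-comparison family
#' (mirroring per-panel correction).
#'
#' A feature constant across all samples is not an error: its p and q are
#' set to 1 and the row is flagged.
#'
#' @param t an `omics_table`.
#' @param meta a `cohort_metadata` tibble; all three groups must be present
#'   with at least two samples each.
#' @return a differential table (tibble) with columns `feature`,
#'   `comparison` (`"omnibus"` or `"<g1>_vs_<g2>"`), `test`, `statistic`,
#'   `p`, `q`, `direction` (sign of the first-group minus second-group mean),
#'   `effect` (log2 fold change of group means with a scale-adaptive
#'   pseudocount), `flag`.
#' @export
kruskal_dunn <- function(t, meta) {
  stopifnot(inherits(t, "omics_table"))
  m <- align_metadata(meta, t)
  g <- droplevels(m$group)
  sizes <- table(g)
  if (length(sizes) < 3) abort("all three groups must be present")
  if (any(sizes < 2)) abort("each group needs >=2 samples")
  eps <- if (any(t$values > 0)) half_min_positive(t$values) else 0
  lev <- levels(g)
  pairs <- combn(lev, 2, simplify = FALSE)
  vals <- t$values
  feats <- rownames(vals)
  N <- ncol(vals)
  k <- length(lev)

  # vectorized across features: joint ranks, tie terms, group rank sums
  ind <- vapply(lev, function(l) as.numeric(g == l), numeric(N))
  nvec <- colSums(ind)
  ranks <- t(apply(vals, 1, rank))
  ties <- apply(ranks, 1, tie_term)
  const <- apply(vals, 1, function(x) max(x) == min(x))
  rsum <- ranks %*% ind
  # tie-corrected Kruskal-Wallis H (identical to stats::kruskal.test)
  H0 <- 12 / (N * (N + 1)) * rowSums(sweep(rsum^2, 2, nvec, "/")) - 3 * (N + 1)
  tie_corr <- 1 - ties / (N^3 - N)
  H <- ifelse(tie_corr > 0, H0 / tie_corr, NA_real_)
  p_omni <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  H[const] <- NA_real_
  p_omni[const] <- 1

  omni <- tibble::tibble(
    feature = feats, comparison = "omnibus", test = "kruskal",
    statistic = as.numeric(H), p = as.numeric(p_omni),
    direction = NA_real_, effect = NA_real_,
    flag = ifelse(const, "constant", NA_character_))

  mu <- sweep(vals %*% ind, 2, nvec, "/")
  rbar <- sweep(rsum, 2, nvec, "/")
  sigma2_base <- N * (N + 1) / 12 - ties / (12 * (N - 1))
  pair_rows <- purrr::map(pairs, function(pr) {
    ni <- nvec[pr[1]]; nj <- nvec[pr[2]]
    z <- (rbar[, pr[1]] - rbar[, pr[2]]) / sqrt(sigma2_base * (1 / ni + 1 / nj))
    out <- tibble::tibble(
      feature = feats, comparison = comparison_label(pr[1], pr[2]),
      test = "dunn", statistic = as.numeric(z),
      p = as.numeric(2 * pnorm(-abs(z))),
      direction = as.numeric(sign(mu[, pr[1]] - mu[, pr[2]])),
      effect = log2_fc(as.numeric(mu[, pr[1]]), as.numeric(mu[, pr[2]]), eps),
      flag = ifelse(const, "constant", NA_character_))
    out$statistic[const] <- NA_real_
    out$p[const] <- 1
    out$direction[const] <- 0
    out$effect[const] <- 0
    out
  })

  dplyr::bind_rows(c(list(omni), pair_rows)) |>
    dplyr::group_by(.data$comparison) |>
    dplyr::mutate(q = p.adjust(.data$p, method = "BH"), .after = "p") |>
    dplyr::ungroup()
}

#' Pairwise Mann-Whitney test per feature
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of one group pair for
#' every feature, with Benjamini-Hochberg adjustment across features. Small
#' untied samples are tested exactly; otherwise the normal approximation
#' with tie correction is used (the standard [stats::wilcox.test()]
#' behaviour). The statistic is the U of the first group against the second,
#' so \eqn{U(x, y) + U(y, x) = n_1 n_2}.
#'
#' @param t an `omics_table`.
#' @param meta a `cohort_metadata` tibble.
#' @param pair character vector of two group labels, e.g. `c("HC", "PD")`.
#' @return differential tibble with the same columns as [kruskal_dunn()].
#' @export
pairwise_mannwhitney <- function(t, meta, pair) {
  stopifnot(inherits(t, "omics_table"), length(pair) == 2)
  m <- align_metadata(meta, t)
  i1 <- which(m$group == pair[1]); i2 <- which(m$group == pair[2])
  if (length(i1) == 0 || length(i2) == 0) {
    abort(paste0("empty group in pair ", comparison_label(pair[1], pair[2])))
  }
  eps <- if (any(t$values > 0)) half_min_positive(t$values) else 0
  cmp <- comparison_label(pair[1], pair[2])

  rows <- purrr::map_dfr(rownames(t$values), function(f) {
    x <- t$values[f, i1]; y <- t$values[f, i2]
    if (length(unique(c(x, y))) == 1L) {
      return(tibble::tibble(feature = f, comparison = cmp, test = "mannwhitney",
                            statistic = length(x) * length(y) / 2, p = 1,
                            direction = 0, effect = 0, flag = "constant"))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble::tibble(feature = f, comparison = cmp, test = "mannwhitney",
                   statistic = as.numeric(wt$statistic), p = wt$p.value,
                   direction = sign(mean(x) - mean(y)),
                   effect = log2_fc(mean(x), mean(y), eps),
                   flag = NA_character_)
  })
  dplyr::mutate(rows, q = p.adjust(.data$p, method = "BH"), .after = "p")
}

#' Variance explained by a clinical factor, per feature
#'
#' Quantifies how much of each feature's variance a clinical factor accounts
#' for via the one-way ANOVA decomposition
#' \eqn{explained = 1 - SS_W / SS_T}, where \eqn{SS_W} pools the
#' within-level sums of squares and \eqn{SS_T} is the total sum of squares
#' around the grand mean. The fraction is unitless, lies in \[0, 1\], and is
#' invariant under affine rescaling of the feature. Samples with a missing
#' factor value are dropped for this factor. Per-level sample variances are
#' returned alongside so alternative summaries can be reconstructed.
#'
#' A feature with zero total variance gets `explained = 0` with a flag.
#'
#' @param t an `omics_table`.
#' @param meta a `cohort_metadata` tibble.
#' @param factor_name metadata column to decompose on (e.g. `"group"`,
#'   `"sex"`, `"constipation"`).
#' @return tibble with columns `feature`, `factor`, `explained`,
#'   `var_total`, `n_used`, `flag`, and a nested `levels` list-column of
#'   per-level `n` and `var`.
#' @export
variance_explained <- function(t, meta, factor_name) {
  stopifnot(inherits(t, "omics_table"))
  if (!factor_name %in% names(meta)) {
    abort(paste0("factor '", factor_name, "' not in metadata"))
  }
  m <- align_metadata(meta, t)
  fac <- m[[factor_name]]
  keep <- !is.na(fac)
  fac <- factor(as.character(fac[keep]))
  if (nlevels(fac) < 2) abort("factor must have >=2 levels after dropping missing values")
  vals <- t$values[, keep, drop = FALSE]

  purrr::map_dfr(rownames(vals), function(f) {
    x <- vals[f, ]
    grand <- mean(x)
    sst <- sum((x - grand)^2)
    level_tbl <- tibble::tibble(
      level = levels(fac),
      n = as.integer(table(fac)),
      var = as.numeric(tapply(x, fac, var))
    )
    if (sst <= 0) {
      return(tibble::tibble(feature = f, factor = factor_name, explained = 0,
                            var_total = 0, n_used = length(x),
                            flag = "zero_variance", levels = list(level_tbl)))
    }
    ssw <- sum(tapply(x, fac, function(v) sum((v - mean(v))^2)))
    expl <- min(max(1 - ssw / sst, 0), 1)
    tibble::tibble(feature = f, factor = factor_name, explained = expl,
                   var_total = var(x), n_used = length(x),
                   flag = NA_character_, levels = list(level_tbl))
  })
}

#' Extract significant compounds from a differential table
#'
#' Filters the omnibus rows of a [kruskal_dunn()] result at `q <
#' q_threshold` and annotates each retained compound with the pairwise
#' contrasts that also pass the threshold. Unidentified compounds should be
#' removed from the table before testing (they cannot be linked to microbial
#' genes); the synthetic generator marks them in the feature annotation.
#'
#' @param diff differential tibble from [kruskal_dunn()].
#' @param q_threshold FDR threshold (default 0.05).
#' @return tibble with columns `feature`, `q`, `direction_hint` (consensus
#'   sign over significant contrasts), `contrasts` (comma-separated
#'   significant pairwise contrasts).
#' @export
significant_compounds <- function(diff, q_threshold = 0.05) {
  check_fraction(q_threshold, "q_threshold", hi_open = TRUE)
  if (nrow(diff) == 0) {
    return(tibble::tibble(feature = character(), q = numeric(),
                          direction_hint = numeric(), contrasts = character()))
  }
  omni <- dplyr::filter(diff, .data$comparison == "omnibus", .data$q < q_threshold)
  if (nrow(omni) == 0) {
    return(tibble::tibble(feature = character(), q = numeric(),
                          direction_hint = numeric(), contrasts = character()))
  }
  pairs_sig <- diff |>
    dplyr::filter(.data$comparison != "omnibus", .data$q < q_threshold,
                  .data$feature %in% omni$feature) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(direction_hint = sign(sum(.data$direction, na.rm = TRUE)),
                     contrasts = paste(.data$comparison, collapse = ","))
  omni |>
    dplyr::select("feature", "q") |>
    dplyr::left_join(pairs_sig, by = "feature") |>
    dplyr::mutate(contrasts = dplyr::coalesce(.data$contrasts, ""),
                  direction_hint = dplyr::coalesce(.data$direction_hint, 0)) |>
    dplyr::arrange(.data$q)
}

#' Write a differential table to TSV
#' @param diff differential tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(diff, path) {
  out <- dplyr::select(diff, !dplyr::any_of("levels"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
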