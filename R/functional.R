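#' Paired gene-abundance vs transcript differential analysis over a KO set
#'
#' For each KO of interest, tests the group pair separately in the
#' functional metagenome (gene abundance, funMG) and the functional
#' metatranscriptome (expression, funMT) with a two-sided Mann-Whitney test,
#' adjusting Benjamini-Hochberg within each (layer, pair) family. Rows are
#' tagged by layer so gene-vs-transcript dissociation -- a KO whose
#' transcripts shift while its gene abundance does not -- is directly
#' queryable. The log2 fold change uses a pseudocount of half the smallest
#' positive value of the corresponding layer (recorded in the `eps`
#' attribute).
#'
#' KOs absent from a layer are not an error: their rows carry missing values
#' and a flag.
#'
#' @param funMG,funMT sum-normalized `omics_table`s of the two functional
#'   layers.
#' @param meta a `cohort_metadata` tibble.
#' @param kos character vector of KO ids to test.
#' @param pair two group labels, e.g. `c("HC", "PD")`.
#' @return differential tibble with columns `feature`, `layer`,
#'   `comparison`, `test`, `statistic`, `p`, `q`, `direction`, `effect`,
#'   `flag`.
#' @export
differential_ko <- function(funMG, funMT, meta, kos, pair = c("HC", "PD")) {
  stopifnot(inherits(funMG, "omics_table"), inherits(funMT, "omics_table"))
  if (!funMG$normalized || !funMT$normalized) {
    abort("funMG and funMT must be sum-normalized (see sum_normalize())")
  }
  if (length(kos) < 1) abort("need >=1 KO")
  layers <- list(funMG = funMG, funMT = funMT)
  out <- purrr::imap_dfr(layers, function(t, layer_name) {
    present <- intersect(kos, rownames(t$values))
    absent <- setdiff(kos, present)
    res <- if (length(present) > 0) {
      sub <- omics_table(t$values[present, , drop = FALSE], layer = t$layer,
                         normalized = FALSE)
      pairwise_mannwhitney(sub, meta, pair)
    } else {
      tibble::tibble()
    }
    if (length(absent) > 0) {
      res <- dplyr::bind_rows(res, tibble::tibble(
        feature = absent, comparison = comparison_label(pair[1], pair[2]),
        test = "mannwhitney", statistic = NA_real_, p = NA_real_,
        q = NA_real_, direction = NA_real_, effect = NA_real_,
        flag = "ko_absent"))
    }
    dplyr::mutate(res, layer = layer_name, .after = "feature")
  })
  attr(out, "eps") <- vapply(layers, function(t) {
    if (any(t$values > 0)) half_min_positive(t$values) else 0
  }, numeric(1))
  out
}

#' Spearman correlation between metabolites and features of another layer
#'
#' Spearman rho (average-rank ties) between every metabolite of `mm` and
#' every feature of `other` over the shared sample set, with two-sided
#' p-values from the t approximation (exact permutation available via
#' `exact = TRUE` for small n) and Benjamini-Hochberg adjustment across all
#' (metabolite, feature) pairs. Constant vectors leave rho undefined; such
#' rows are flagged.
#'
#' @param mm an `omics_table` (typically the significant metabolites).
#' @param other an `omics_table` sharing the sample set (e.g. species-level
#'   taxMT).
#' @param mm_features,other_features optional subsets of features to
#'   correlate (defaults: all).
#' @param exact use the exact permutation null (only sensible for n <= 10).
#' @return tibble with columns `metabolite`, `feature`, `rho`, `p`, `q`,
#'   `flag`.
#' @export
metabolite_feature_correlation <- function(mm, other, mm_features = NULL,
                                           other_features = NULL, exact = FALSE) {
  stopifnot(inherits(mm, "omics_table"), inherits(other, "omics_table"))
  shared <- intersect(colnames(mm$values), colnames(other$values))
  if (length(shared) < 3) abort("need >=3 shared samples")
  mm_features <- mm_features %||% rownames(mm$values)
  other_features <- other_features %||% rownames(other$values)
  A <- mm$values[mm_features, shared, drop = FALSE]
  B <- other$values[other_features, shared, drop = FALSE]

  grid <- tidyr::expand_grid(metabolite = mm_features, feature = other_features)
  rows <- purrr::pmap_dfr(grid, function(metabolite, feature) {
    x <- A[metabolite, ]; y <- B[feature, ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(metabolite = metabolite, feature = feature,
                            rho = NA_real_, p = NA_real_, flag = "constant"))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
    tibble::tibble(metabolite = metabolite, feature = feature,
                   rho = as.numeric(ct$estimate), p = ct$p.value,
                   flag = NA_character_)
  })
  dplyr::mutate(rows, q = p.adjust(.data$p, method = "BH"), .after = "p")
}

#' Pathway panel: expression and functional-diversity fold changes
#'
#' For a configured pathway KO list (e.g. chemotaxis or flagellar assembly),
#' combines the gene-vs-transcript differential rows of [differential_ko()]
#' with the log2 fold change of the mean per-KO taxonomic Shannon diversity
#' between the two groups, and tallies how many pathway members are down,
#' up, or unchanged in the transcriptome at `q < q_threshold`. Shannon
#' diversity is computed per sample and then averaged within group (not
#' pooled per group first); this choice is recorded in the result.
#'
#' @param funMG,funMT sum-normalized `omics_table`s.
#' @param tensor a `taxon_tensor` (TPM or counts) providing the
#'   genus-resolved expression of the pathway KOs.
#' @param meta a `cohort_metadata` tibble.
#' @param kos non-empty pathway KO list.
#' @param pair two group labels.
#' @param q_threshold FDR threshold for the tally (default 0.05).
#' @return object of class `pathway_panel`: list with `table` (differential
#'   rows joined to `shannon_log2fc`), `tally` (per layer, pathway members
#'   decreased (`down`) or increased (`up`) in the second group of the pair
#'   at `q < q_threshold`, plus `unchanged`; down/up/unchanged counts per
#'   layer; down + up + unchanged = pathway size), and `shannon`
#'   (per-sample Shannon values).
#' @export
pathway_panel <- function(funMG, funMT, tensor, meta, kos, pair = c("HC", "PD"),
                          q_threshold = 0.05) {
  if (length(kos) < 1) abort("empty pathway KO list")
  diff <- differential_ko(funMG, funMT, meta, kos, pair)

  tensor_kos <- intersect(kos, dimnames(tensor$values)[[2]])
  shannon_tbl <- purrr::map_dfr(tensor_kos, function(k) ko_taxon_shannon(tensor, k))
  sh_fc <- if (nrow(shannon_tbl) > 0) {
    m <- meta[match(shannon_tbl$sample, meta$sample), ]
    shannon_tbl |>
      dplyr::mutate(group = m$group) |>
      dplyr::filter(.data$group %in% pair, !is.na(.data$shannon)) |>
      dplyr::group_by(.data$ko, .data$group) |>
      dplyr::summarise(mean_h = mean(.data$shannon), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "group", values_from = "mean_h") |>
      dplyr::mutate(shannon_log2fc = log2_fc(.data[[pair[1]]], .data[[pair[2]]],
                                             eps = 1e-6)) |>
      dplyr::select(feature = "ko", "shannon_log2fc")
  } else {
    tibble::tibble(feature = character(), shannon_log2fc = numeric())
  }
  table <- dplyr::left_join(diff, sh_fc, by = "feature")

  # direction is sign(mean(pair[1]) - mean(pair[2])), so a member that is
  # lower in the second group (e.g. decreased in PD for HC vs PD) counts as
  # "down"
  tally <- table |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      down = sum(.data$q < q_threshold & .data$direction > 0, na.rm = TRUE),
      up = sum(.data$q < q_threshold & .data$direction < 0, na.rm = TRUE),
      unchanged = dplyr::n() - .data$down - .data$up
    )
  structure(list(table = table, tally = tally, pair = pair,
                 q_threshold = q_threshold, shannon = shannon_tbl,
                 shannon_convention = "per-sample Shannon, averaged within group"),
            class = "pathway_panel")
}

#' @export
print.pathway_panel <- function(x, ...) {
  cat(sprintf("<pathway_panel> %s: %d KOs\n",
              paste(x$pair, collapse = " vs "),
              dplyr::n_distinct(x$table$feature)))
  print(x$tally)
  invisible(x)
}

#' @rdname pathway_panel
#' @param x a `pathway_panel`.
#' @param ... unused.
#' @export
tidy.pathway_panel <- function(x, ...) x$table

#' @rdname pathway_panel
#' @export
glance.pathway_panel <- function(x, ...) {
  tidyr::pivot_wider(x$tally, names_from = "layer",
                     values_from = c("down", "up", "unchanged"))
}
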