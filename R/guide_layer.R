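#' Select the guide omics layer
#'
#' A guide layer is an omics layer that separates the diagnosis groups while
#' being unassociated with the measured confounders, so that downstream
#' feature-level analysis driven by it is unlikely to chase confounder
#' structure. For every supplied layer this runs a Bray-Curtis PERMANOVA
#' against the diagnosis group and against each confounder; a layer is
#' eligible when its group p-value is below `alpha` and every confounder
#' p-value is at or above `alpha`. Eligible layers are ranked by group
#' \eqn{R^2} (descending) and the top layer is flagged as the winner. When no
#' layer is eligible the report carries an empty winner and an explicit flag
#' rather than an error.
#'
#' Raw layers are sum-normalized before computing distances; a merged
#' meta-metabolome table (per-block normalization recorded by
#' [merge_mm_blocks()]) is used as supplied. Samples with a missing
#' confounder value are dropped for that factor only.
#'
#' @param layers named list of `omics_table`s.
#' @param meta a `cohort_metadata` tibble covering all samples.
#' @param confounders metadata column names to screen against
#'   (default `c("sex", "age", "constipation")`).
#' @param alpha significance threshold (default 0.05, the study-wide
#'   convention).
#' @param n_perm permutations per test (default 1000).
#' @param seed integer seed; each (layer, factor) test draws from its own
#'   derived substream.
#' @return an object of class `guide_selection`: list with `report` (tibble
#'   of layer x factor PERMANOVA results), `eligible` (ranked character
#'   vector), `winner` (layer name or `NA`), `alpha`, `n_perm`.
#' @export
select_guide_layer <- function(layers, meta, confounders = c("sex", "age", "constipation"),
                               alpha = 0.05, n_perm = 1000, seed = NULL) {
  if (length(layers) < 1) abort("need >=1 layer")
  if (is.null(names(layers)) || any(names(layers) == "")) {
    abort("`layers` must be a named list")
  }
  bad <- setdiff(confounders, names(meta))
  if (length(bad) > 0) {
    abort(paste0("confounder(s) not in metadata: ", toString(bad)))
  }
  check_fraction(alpha, "alpha", hi_open = TRUE)

  rows <- purrr::imap(layers, function(t, layer_name) {
    m <- align_metadata(meta, t)
    tt <- if (t$normalized || isTRUE(attr(t, "blocks_normalized"))) t else sum_normalize(t)
    d <- bray_curtis(tt)
    i <- match(layer_name, names(layers))
    factors <- c("group", confounders)
    purrr::imap_dfr(setNames(factors, factors), function(f, fname) {
      vals <- if (fname == "group") m$group else m[[fname]]
      if (is.logical(vals)) vals <- ifelse(vals, "yes", "no")
      fit <- permanova(d, vals, n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else sub_seed(seed, i * 17 + match(fname, factors)),
                       factor_name = fname, exhaustive = FALSE)
      dplyr::mutate(tidy(fit), layer = layer_name, .before = 1)
    })
  })
  report <- dplyr::bind_rows(rows)

  verdict <- report |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      group_p = .data$p[.data$factor == "group"],
      group_R2 = .data$R2[.data$factor == "group"],
      confounded = any(.data$p[.data$factor != "group"] < alpha),
      eligible = .data$group_p < alpha & !.data$confounded
    ) |>
    dplyr::arrange(dplyr::desc(.data$group_R2))
  eligible <- verdict$layer[verdict$eligible]
  winner <- if (length(eligible) > 0) eligible[1] else NA_character_

  structure(
    list(report = report, verdict = verdict, eligible = eligible,
         winner = winner, alpha = alpha, n_perm = n_perm),
    class = "guide_selection"
  )
}

#' @export
print.guide_selection <- function(x, ...) {
  cat("<guide_selection>\n")
  if (is.na(x$winner)) {
    cat("  no eligible guide layer at alpha =", x$alpha, "\n")
  } else {
    cat("  guide layer:", x$winner,
        if (length(x$eligible) > 1) paste0("(also eligible: ", toString(x$eligible[-1]), ")") else "",
        "\n")
  }
  print(x$verdict)
  invisible(x)
}

#' @rdname select_guide_layer
#' @param x a `guide_selection`.
#' @param ... unused.
#' @export
tidy.guide_selection <- function(x, ...) x$report

#' @rdname select_guide_layer
#' @export
glance.guide_selection <- function(x, ...) {
  tibble::tibble(winner = x$winner, n_eligible = length(x$eligible),
                 n_layers = dplyr::n_distinct(x$report$layer),
                 alpha = x$alpha, n_perm = x$n_perm)
}

#' Tile plot of the guide-layer PERMANOVA screen
#'
#' One tile per layer x factor, filled by \eqn{R^2} and sized by
#' \eqn{-\log_{10} p} -- the conventional rendering of a confounder screen.
#'
#' @param object a `guide_selection`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.guide_selection <- function(object, ...) {
  df <- dplyr::mutate(object$report, neglog_p = -log10(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$layer)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$neglog_p, colour = .data$R2), shape = 15) +
    ggplot2::scale_size_continuous(name = expression(-log[10](p))) +
    ggplot2::scale_colour_viridis_c(name = expression(R^2)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "PERMANOVA screen: diagnosis vs confounders") +
    ggplot2::theme_minimal()
}
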