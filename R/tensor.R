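#' Genus x KO x sample expression tensor
#'
#' Taxon-resolved functional expression: a non-negative 3-d array indexed by
#' genus, KO and sample, either raw counts or transcripts-per-million (TPM).
#' Summing over genera reproduces (up to normalization) the functional
#' metatranscriptome table restricted to the tensor's KOs. Per-genus family
#' annotation can be attached for display.
#'
#' @param values non-negative numeric 3-d array with dimnames
#'   `(genus, ko, sample)`.
#' @param tpm logical; `TRUE` once sample slices are scaled to 1e6.
#' @param genus_info optional tibble with columns `genus`, `family`.
#' @return a `taxon_tensor` object.
#' @export
taxon_tensor <- function(values, tpm = FALSE, genus_info = NULL) {
  if (!is.array(values) || length(dim(values)) != 3) {
    abort("`values` must be a 3-d array (genus x ko x sample)")
  }
  if (is.null(dimnames(values)) || any(vapply(dimnames(values), is.null, logical(1)))) {
    abort("`values` must carry genus, ko and sample dimnames")
  }
  if (anyNA(values) || any(values < 0)) abort("tensor entries must be non-negative")
  structure(list(values = values, tpm = isTRUE(tpm), genus_info = genus_info),
            class = "taxon_tensor")
}

#' @export
print.taxon_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<taxon_tensor> %d genera x %d KOs x %d samples (%s)\n",
              d[1], d[2], d[3], if (x$tpm) "TPM" else "counts"))
  invisible(x)
}

#' @rdname taxon_tensor
#' @param x a `taxon_tensor`.
#' @param ... unused.
#' @export
tidy.taxon_tensor <- function(x, ...) {
  dn <- dimnames(x$values)
  out <- tidyr::expand_grid(sample = dn[[3]], ko = dn[[2]], genus = dn[[1]])
  # expand_grid varies the last column fastest, matching column-major array order
  out$value <- as.vector(x$values)
  dplyr::select(out, "genus", "ko", "sample", "value")
}

#' Read / write a tensor as long-format TSV
#'
#' Columns `genus`, `ko`, `sample`, `value`; missing combinations are taken
#' as zero on read.
#'
#' @param path TSV path.
#' @param tpm whether the stored values are TPM.
#' @return [load_taxon_tensor()] returns a `taxon_tensor`;
#'   [write_taxon_tensor()] returns `path` invisibly.
#' @export
load_taxon_tensor <- function(path, tpm = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    genus = readr::col_character(), ko = readr::col_character(),
    sample = readr::col_character(), value = readr::col_double()
  ), progress = FALSE)
  genera <- sort(unique(df$genus)); kos <- sort(unique(df$ko))
  samples <- sort(unique(df$sample))
  arr <- array(0, dim = c(length(genera), length(kos), length(samples)),
               dimnames = list(genera, kos, samples))
  arr[cbind(match(df$genus, genera), match(df$ko, kos), match(df$sample, samples))] <- df$value
  taxon_tensor(arr, tpm = tpm)
}

#' @rdname load_taxon_tensor
#' @param tensor a `taxon_tensor`.
#' @export
write_taxon_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "taxon_tensor"))
  df <- dplyr::filter(tidy(tensor), .data$value != 0)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Collapse a tensor over genera to a functional table
#'
#' @param tensor a `taxon_tensor`.
#' @param layer layer tag for the resulting table (default `"funMT"`).
#' @return an `omics_table` (KO x sample).
#' @export
collapse_tensor <- function(tensor, layer = "funMT") {
  stopifnot(inherits(tensor, "taxon_tensor"))
  vals <- apply(tensor$values, c(2, 3), sum)
  omics_table(vals, layer = layer, normalized = FALSE)
}

#' TPM normalization of a count tensor
#'
#' Scales every sample slice so its (genus, KO) cells sum to 1e6. No
#' gene-length term is applied: synthetic features are length-free, and
#' real-data users are expected to supply pre-length-normalized counts.
#' Invariant under scaling all counts of a sample by a positive constant.
#'
#' @param counts a `taxon_tensor` of raw counts.
#' @return a `taxon_tensor` with `tpm = TRUE`.
#' @export
tpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "taxon_tensor"))
  totals <- apply(counts$values, 3, sum)
  if (any(totals <= 0)) {
    abort(paste0("zero-total sample(s): ",
                 toString(head(dimnames(counts$values)[[3]][totals <= 0], 5))))
  }
  vals <- sweep(counts$values, 3, totals / 1e6, "/")
  taxon_tensor(vals, tpm = TRUE, genus_info = counts$genus_info)
}

#' Per-sample Shannon diversity of the taxa expressing one KO
#'
#' For each sample, the Shannon index (nats) over the genus-level expression
#' vector of the KO: how many, and how evenly, genera carry out the
#' function. Samples with zero total expression of the KO yield `NA`, not 0
#' (an unexpressed function has no diversity, rather than minimal
#' diversity).
#'
#' @param tensor a `taxon_tensor`.
#' @param ko a KO id present in the tensor.
#' @return tibble with columns `ko`, `sample`, `shannon`.
#' @export
ko_taxon_shannon <- function(tensor, ko) {
  stopifnot(inherits(tensor, "taxon_tensor"))
  if (!ko %in% dimnames(tensor$values)[[2]]) {
    abort(paste0("KO not in tensor: ", ko))
  }
  slice <- tensor$values[, ko, , drop = TRUE]
  if (is.null(dim(slice))) slice <- matrix(slice, ncol = length(slice),
                                           dimnames = list(NULL, dimnames(tensor$values)[[3]]))
  h <- apply(slice, 2, function(v) if (sum(v) <= 0) NA_real_ else shannon(v))
  tibble::tibble(ko = ko, sample = names(h), shannon = as.numeric(h))
}

#' Group-mean TPM profiles per genus and KO
#'
#' Means of TPM values per diagnosis group for every (genus, KO) cell, plus
#' per-genus per-group totals. The square-root transform conventionally used
#' to display the totals is included as a column; the untransformed sums are
#' kept alongside.
#'
#' @param tensor a `taxon_tensor` in TPM units.
#' @param meta a `cohort_metadata` tibble.
#' @return list of class `genus_profiles` with tibbles `cells`
#'   (genus, ko, group, mean_tpm) and `genus_totals`
#'   (genus, group, total, sqrt_total).
#' @export
genus_group_profiles <- function(tensor, meta) {
  stopifnot(inherits(tensor, "taxon_tensor"))
  dn <- dimnames(tensor$values)
  m <- meta[match(dn[[3]], meta$sample), ]
  if (anyNA(m$sample)) abort("tensor samples missing from metadata")
  g <- droplevels(m$group)
  if (any(table(g) == 0)) abort("group with zero samples")
  cells <- purrr::map_dfr(levels(g), function(grp) {
    sub <- tensor$values[, , g == grp, drop = FALSE]
    mu <- apply(sub, c(1, 2), mean)
    tibble::as_tibble(mu, rownames = "genus") |>
      tidyr::pivot_longer(-"genus", names_to = "ko", values_to = "mean_tpm") |>
      dplyr::mutate(group = grp)
  })
  totals <- cells |>
    dplyr::group_by(.data$genus, .data$group) |>
    dplyr::summarise(total = sum(.data$mean_tpm), .groups = "drop") |>
    dplyr::mutate(sqrt_total = sqrt(.data$total))
  structure(list(cells = cells, genus_totals = totals,
                 groups = levels(g), genus_info = tensor$genus_info),
            class = "genus_profiles")
}

#' Canberra distance between rows of a matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / (|x_i| + |y_i|)}, with zero-denominator
#' terms contributing 0 (no missing-value rescaling).
#'
#' @param m numeric matrix; distances between rows.
#' @return a `dist` object.
#' @export
canberra_distance <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      num <- abs(xi - m[j, ])
      den <- abs(xi) + abs(m[j, ])
      term <- ifelse(den > 0, num / den, 0)
      out[i, j] <- out[j, i] <- sum(term)
    }
  }
  as.dist(out)
}

#' Cluster genera by their gene-level fold-change profiles
#'
#' Computes the log2 fold change of group-mean TPM between the two groups of
#' `pair` for every (genus, KO) cell (scale-adaptive pseudocount), then
#' clusters genera by agglomerative hierarchical clustering with Canberra
#' distance and Ward.D2 linkage, cut at `k` clusters. The procedure is fully
#' deterministic: identical input yields an identical assignment and
#' dendrogram order.
#'
#' @param profiles a `genus_profiles` object.
#' @param pair two group labels, fold change is first over second.
#' @param k number of clusters (the conventional display uses 4).
#' @return tibble `(genus, cluster, dendro_order)` with the `hclust` object
#'   and the log2FC matrix attached as attributes `hclust` and `log2fc`.
#' @export
cluster_genera <- function(profiles, pair = c("HC", "PD"), k = 4) {
  stopifnot(inherits(profiles, "genus_profiles"), length(pair) == 2)
  wide <- profiles$cells |>
    dplyr::filter(.data$group %in% pair) |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_tpm")
  if (!all(pair %in% names(wide))) abort("pair groups absent from profiles")
  eps <- half_min_positive(c(wide[[pair[1]]], wide[[pair[2]]]))
  wide$log2fc <- log2_fc(wide[[pair[1]]], wide[[pair[2]]], eps)
  fc <- wide |>
    dplyr::select("genus", "ko", "log2fc") |>
    tidyr::pivot_wider(names_from = "ko", values_from = "log2fc")
  m <- as.matrix(fc[, -1]); rownames(m) <- fc$genus
  if (nrow(m) < 2) abort("need >=2 genera to cluster")
  if (k > nrow(m)) abort("k exceeds the number of genera")
  hc <- hclust(canberra_distance(m), method = "ward.D2")
  assignment <- cutree(hc, k = k)
  out <- tibble::tibble(genus = names(assignment),
                        cluster = as.integer(assignment)) |>
    dplyr::mutate(dendro_order = match(.data$genus, hc$labels[hc$order]))
  attr(out, "hclust") <- hc
  attr(out, "log2fc") <- m
  out
}

#' Differential expression of extracellular flagellar genes per genus
#'
#' Kruskal-Wallis plus Dunn comparisons across the three diagnosis groups of
#' the TPM expression of each (genus, gene) pair, for the genes encoding the
#' extracellular parts of the flagellum. The default panel covers flagellin
#' (fliC), the filament cap (fliD, fliS) and the hook-filament junction
#' (flgK, flgL), mapped to their KO ids.
#'
#' @param tensor a `taxon_tensor` in TPM units.
#' @param meta a `cohort_metadata` tibble.
#' @param genes named character vector of KO ids (names are gene symbols);
#'   default [flagellar_gene_panel()].
#' @param genera character vector of genus ids to report on.
#' @return differential tibble with `genus` and `gene` columns ahead of the
#'   [kruskal_dunn()] columns; genes absent from the tensor yield flagged
#'   rows.
#' @export
extracellular_flagellar_report <- function(tensor, meta, genes = flagellar_gene_panel(),
                                           genera) {
  stopifnot(inherits(tensor, "taxon_tensor"))
  if (length(genera) < 1) abort("need >=1 genus")
  dn <- dimnames(tensor$values)
  bad_gen <- setdiff(genera, dn[[1]])
  if (length(bad_gen) > 0) {
    abort(paste0("genus not in tensor: ", toString(bad_gen)))
  }
  if (is.null(names(genes))) names(genes) <- genes
  rows <- purrr::imap_dfr(genes, function(ko, sym) {
    if (!ko %in% dn[[2]]) {
      return(tibble::tibble(genus = genera, gene = sym, ko = ko,
                            comparison = "omnibus", test = "kruskal",
                            statistic = NA_real_, p = NA_real_, q = NA_real_,
                            direction = NA_real_, effect = NA_real_,
                            flag = "gene_absent"))
    }
    mat <- tensor$values[genera, ko, , drop = FALSE]
    vals <- matrix(mat, nrow = length(genera),
                   dimnames = list(paste0(genera, "|", sym), dn[[3]]))
    tab <- omics_table(vals, layer = "funMT", normalized = FALSE)
    kruskal_dunn(tab, meta) |>
      tidyr::separate_wider_delim("feature", "|", names = c("genus", "gene")) |>
      dplyr::mutate(ko = ko, .after = "gene")
  })
  rows
}

#' Default extracellular flagellar gene panel
#'
#' KO ids of flagellin (fliC), filament cap (fliD, fliS) and hook-filament
#' junction (flgK, flgL) genes.
#'
#' @return named character vector of KO ids.
#' @export
flagellar_gene_panel <- function() {
  c(fliC = "K02406", fliD = "K02407", fliS = "K02422",
    flgK = "K02396", flgL = "K02397")
}
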