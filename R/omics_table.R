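#' Omics abundance tables
#'
#' An `omics_table` holds one feature-by-sample abundance matrix together with
#' its layer identity (`taxMG`, `taxMT`, `taxMP`, `funMG`, `funMT`, `funMP` or
#' `MM`), a `normalized` flag distinguishing raw counts from sum-normalized
#' fractions, and optional per-feature annotation (block of origin for merged
#' metabolome tables, identified/unidentified status for compounds).
#'
#' Values must be non-negative; feature and sample identifiers must be unique;
#' a normalized table must have every sample column summing to 1.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   row and column names.
#' @param layer one of `"taxMG"`, `"taxMT"`, `"taxMP"`, `"funMG"`, `"funMT"`,
#'   `"funMP"`, `"MM"`.
#' @param normalized logical; `TRUE` if sample columns are fractions summing
#'   to 1.
#' @param feature_info optional tibble of per-feature annotation with a
#'   `feature` column matching `rownames(values)`.
#' @return an `omics_table` object.
#' @export
omics_table <- function(values, layer, normalized = FALSE, feature_info = NULL) {
  layer <- match.arg(layer, omics_layers())
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("duplicate feature identifiers: ", toString(head(dup, 5))))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    abort(paste0("duplicate sample identifiers: ", toString(head(dup, 5))))
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric or missing value at feature '%s', sample '%s'",
                  rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative value %g at feature '%s', sample '%s'",
                  values[idx[1], idx[2]],
                  rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (isTRUE(normalized)) {
    cs <- colSums(values)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad) > 0) {
      abort(paste0("normalized table has sample columns not summing to 1: ",
                   toString(head(colnames(values)[bad], 5))))
    }
  }
  if (!is.null(feature_info)) {
    feature_info <- tibble::as_tibble(feature_info)
    if (!"feature" %in% names(feature_info) ||
        !setequal(feature_info$feature, rownames(values))) {
      abort("`feature_info` must have a `feature` column matching the rownames")
    }
    feature_info <- feature_info[match(rownames(values), feature_info$feature), ]
  }
  structure(
    list(values = values, layer = layer, normalized = isTRUE(normalized),
         feature_info = feature_info),
    class = "omics_table"
  )
}

omics_layers <- function() c("taxMG", "taxMT", "taxMP", "funMG", "funMT", "funMP", "MM")

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("<omics_table> layer=%s  %d features x %d samples  (%s)\n",
              x$layer, nrow(x$values), ncol(x$values),
              if (x$normalized) "sum-normalized" else "raw"))
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

#' @rdname omics_table
#' @param x an `omics_table`.
#' @param ... unused.
#' @export
tidy.omics_table <- function(x, ...) {
  out <- tibble::as_tibble(x$values, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "sample", values_to = "value") |>
    dplyr::mutate(layer = x$layer, .before = 1)
  if (!is.null(x$feature_info)) {
    out <- dplyr::left_join(out, x$feature_info, by = "feature")
  }
  out
}

#' Read an omics abundance table from TSV
#'
#' The expected layout is the ubiquitous feature-table convention: a header
#' row of sample identifiers (first header cell ignored), one feature per
#' row with its identifier in the first column, tab-separated, `.` decimal,
#' UTF-8, no quoting. The table is validated (no negative or non-numeric
#' cells, unique identifiers) and returned raw (`normalized = FALSE`) with
#' row and column order preserved.
#'
#' @param path path to a TSV file.
#' @param layer omics layer tag for the table.
#' @return an `omics_table`.
#' @export
load_omics_table <- function(path, layer) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) abort("expected a feature id column plus >=1 sample column")
  features <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- apply(body, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body), dimnames = dimnames(body))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell '%s' at feature '%s', sample '%s' in %s",
                  body[bad[1, 1], bad[1, 2]], features[bad[1, 1]],
                  colnames(body)[bad[1, 2]], path))
  }
  rownames(num) <- features
  omics_table(num, layer = layer, normalized = FALSE)
}

#' Write an omics table to TSV
#'
#' Inverse of [load_omics_table()]: first column `feature`, one column per
#' sample. Values are written in full precision so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param t an `omics_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(t, path) {
  stopifnot(inherits(t, "omics_table"))
  df <- tibble::as_tibble(t$values, rownames = "feature")
  # readr writes doubles in shortest round-trippable form, so write -> read
  # reproduces the matrix bit-exactly
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Sum-normalize an omics table
#'
#' Divides every sample column by its sum so columns become relative
#' abundances summing to 1. Idempotent. Columns of all zeros are rejected
#' (the sample is named in the error).
#'
#' @param t an `omics_table`.
#' @return an `omics_table` with `normalized = TRUE`.
#' @export
sum_normalize <- function(t) {
  stopifnot(inherits(t, "omics_table"))
  cs <- colSums(t$values)
  if (any(cs <= 0)) {
    abort(paste0("cannot sum-normalize: all-zero sample column(s): ",
                 toString(head(colnames(t$values)[cs <= 0], 5))))
  }
  vals <- sweep(t$values, 2, cs, "/")
  omics_table(vals, layer = t$layer, normalized = TRUE, feature_info = t$feature_info)
}

#' Merge the three meta-metabolome blocks
#'
#' The meta-metabolome is measured in three blocks (untargeted, targeted
#' short-chain fatty acids, targeted bile acids). Each block is sum-normalized
#' first and the normalized blocks are then concatenated, so every block's
#' sub-columns sum to 1 while the merged columns sum to 3. The block of
#' origin is recorded per feature. All three blocks must cover the identical
#' sample set; feature identifiers must not collide across blocks.
#'
#' @param untargeted,scfa,bile_acids `omics_table`s sharing one sample set.
#' @return a merged `omics_table` with layer `"MM"`.
#' @export
merge_mm_blocks <- function(untargeted, scfa, bile_acids) {
  blocks <- list(untargeted = untargeted, scfa = scfa, bile_acids = bile_acids)
  for (b in blocks) stopifnot(inherits(b, "omics_table"))
  ref <- colnames(untargeted$values)
  for (nm in names(blocks)) {
    smp <- colnames(blocks[[nm]]$values)
    if (!setequal(smp, ref)) {
      diff <- c(setdiff(ref, smp), setdiff(smp, ref))
      abort(paste0("sample sets differ (block '", nm, "'): ", toString(diff)))
    }
  }
  # normalize per block, then concatenate
  blocks <- lapply(blocks, function(b) {
    b <- if (b$normalized) b else sum_normalize(b)
    b$values <- b$values[, ref, drop = FALSE]
    b
  })
  feats <- unlist(lapply(blocks, function(b) rownames(b$values)), use.names = FALSE)
  if (anyDuplicated(feats)) {
    dup <- unique(feats[duplicated(feats)])
    abort(paste0("duplicate feature identifiers across blocks: ", toString(head(dup, 5))))
  }
  vals <- do.call(rbind, lapply(blocks, function(b) b$values))
  rownames(vals) <- feats
  info <- dplyr::bind_rows(lapply(names(blocks), function(nm) {
    fi <- blocks[[nm]]$feature_info
    base <- tibble::tibble(feature = rownames(blocks[[nm]]$values), block = nm)
    if (!is.null(fi)) base <- dplyr::left_join(base, fi, by = "feature")
    base
  }))
  # merged columns sum to (number of blocks), so the table itself is raw;
  # per-block normalization is recorded in the annotation
  out <- omics_table(vals, layer = "MM", normalized = FALSE, feature_info = info)
  attr(out, "blocks_normalized") <- TRUE
  out
}
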