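#' Cohort metadata
#'
#' Per-sample clinical metadata driving every group comparison: diagnosis
#' group (`HC`, `iRBD`, `PD`), the confounders sex, age and constipation, and
#' a free-text recruitment cohort label. Group labels must be complete and
#' drawn from the three-level set; confounders may contain missing values
#' (they are dropped per factor at analysis time), group may not.
#'
#' @param df data frame with columns `sample`, `group`, `sex`, `age`,
#'   `constipation`, `cohort`.
#' @return a validated tibble of class `cohort_metadata`.
#' @export
cohort_metadata <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("sample", "group", "sex", "age", "constipation", "cohort")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata missing column(s): ", toString(missing_cols)))
  }
  if (anyDuplicated(df$sample)) abort("duplicate sample identifiers in metadata")
  if (anyNA(df$group)) abort("`group` may not contain missing values")
  bad <- setdiff(unique(as.character(df$group)), c("HC", "iRBD", "PD"))
  if (length(bad) > 0) {
    abort(paste0("`group` labels outside {HC, iRBD, PD}: ", toString(bad)))
  }
  df$group <- factor(as.character(df$group), levels = c("HC", "iRBD", "PD"))
  bad_sex <- setdiff(unique(as.character(df$sex[!is.na(df$sex)])), c("M", "F"))
  if (length(bad_sex) > 0) {
    abort(paste0("`sex` labels outside {M, F}: ", toString(bad_sex)))
  }
  df$sex <- as.character(df$sex)
  df$age <- as.numeric(df$age)
  df$constipation <- as.logical(df$constipation)
  df$cohort <- as.character(df$cohort)
  class(df) <- c("cohort_metadata", class(df))
  df
}

#' Read cohort metadata from TSV
#'
#' @param path TSV file with columns `sample`, `group`, `sex`, `age`,
#'   `constipation`, `cohort`.
#' @return a `cohort_metadata` tibble.
#' @export
load_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    group = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_double(),
    constipation = readr::col_logical(),
    cohort = readr::col_character()
  ), progress = FALSE)
  cohort_metadata(df)
}

#' Write cohort metadata to TSV
#' @param meta a `cohort_metadata` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- dplyr::mutate(meta, group = as.character(.data$group))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Align metadata rows to the sample columns of an omics table; every sample
# must have a metadata row.
align_metadata <- function(meta, t) {
  samples <- colnames(t$values)
  missing <- setdiff(samples, meta$sample)
  if (length(missing) > 0) {
    abort(paste0("samples without metadata: ", toString(head(missing, 5))))
  }
  meta[match(samples, meta$sample), ]
}
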