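#' Read a CpG beta-value matrix
#'
#' Reads a delimited file with one row per CpG: a first column of CpG
#' identifiers and one column per sample of beta values (fraction methylated,
#' in \[0, 1\]). The delimiter is sniffed from the extension (`.csv` = comma,
#' anything else = tab). Missing values are encoded by `missing_sentinel` and
#' stored as `NA` (an explicit mask, never a numeric placeholder).
#'
#' @param path Path to a TSV/CSV file.
#' @param missing_sentinel Token marking a missing value. Default `"NA"`.
#' @return A tibble with first column `cpg_id` and one numeric column per
#'   sample.
#' @seealso [write_beta_matrix()], [read_sample_sheet()]
#' @export
read_beta_matrix <- function(path, missing_sentinel = "NA") {
  raw <- read_table_auto(path)
  if (ncol(raw) < 2) abort("Beta matrix needs a CpG-id column plus sample columns.")
  names(raw)[1] <- "cpg_id"
  raw$cpg_id <- as.character(raw$cpg_id)
  if (anyDuplicated(raw$cpg_id)) {
    dups <- unique(raw$cpg_id[duplicated(raw$cpg_id)])
    abort(paste0("Duplicate CpG id(s): ", paste(head(dups, 5), collapse = ", ")))
  }
  if (anyDuplicated(names(raw))) abort("Duplicate sample ids in header.")
  for (col in names(raw)[-1]) {
    v <- raw[[col]]
    v[v == missing_sentinel] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "Cannot parse value '%s' at CpG '%s', sample '%s'.",
        v[bad[1]], raw$cpg_id[bad[1]], col
      ))
    }
    out_of_range <- which(!is.na(num) & (num < 0 | num > 1))
    if (length(out_of_range) > 0) {
      abort(sprintf(
        "Beta value %s outside [0, 1] at CpG '%s', sample '%s'.",
        format(num[out_of_range[1]]), raw$cpg_id[out_of_range[1]], col
      ))
    }
    raw[[col]] <- num
  }
  as_tibble(raw)
}

#' Write a CpG beta-value matrix
#'
#' @param beta Beta tibble as returned by [read_beta_matrix()] or
#'   [generate_cohort()].
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @param missing_sentinel Token used for missing values.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, missing_sentinel = "NA") {
  check_beta_tbl(beta)
  write_table_auto(beta, path, na = missing_sentinel)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet carries the classification target and covariates:
#' columns `sample_id`, `status` (1 = case, 0 = control), `age` (years),
#' `sex` (0/1 code), `smoker` (0/1).
#'
#' @param path Path to a CSV/TSV file.
#' @param beta Optional beta tibble; when supplied, sample ids are checked
#'   against the matrix columns and the sheet is returned in matrix column
#'   order.
#' @return A tibble with the five required columns.
#' @export
read_sample_sheet <- function(path, beta = NULL) {
  sheet <- read_table_auto(path)
  if (nrow(sheet) == 0) abort("Sample sheet is empty.")
  for (col in intersect(names(sheet), c("status", "age", "sex", "smoker"))) {
    sheet[[col]] <- as.numeric(sheet[[col]])
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  check_sample_sheet(sheet)
  if (!is.null(beta)) sheet <- align_sheet(beta, sheet)
  as_tibble(sheet)
}

#' Write a sample sheet
#'
#' @inheritParams read_sample_sheet
#' @param sheet Sample-sheet tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  check_sample_sheet(sheet)
  write_table_auto(sheet, path)
  invisible(path)
}

#' Write a CpG selection list
#'
#' One row per selected CpG with its prefilter p-value and Shannon entropy,
#' ordered by descending entropy with ties broken lexicographically by CpG id
#' so the file is deterministic.
#'
#' @param selection A selection tibble (see [select_top_fraction()]); columns
#'   other than `cpg_id`, `p_value`, `entropy` are dropped, absent ones are
#'   written as NA.
#' @param path Output TSV path.
#' @return `path`, invisibly. Warns and writes a header-only file when the
#'   selection is empty.
#' @export
write_selection <- function(selection, path) {
  if (!is.data.frame(selection) || !"cpg_id" %in% names(selection)) {
    abort("`selection` must be a data frame with a `cpg_id` column.")
  }
  out <- tibble(
    cpg_id = as.character(selection$cpg_id),
    p_value = if ("p_value" %in% names(selection)) selection$p_value else NA_real_,
    entropy = if ("entropy" %in% names(selection)) selection$entropy else NA_real_
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$entropy), .data$cpg_id)
  if (nrow(out) == 0) warn("Empty selection: writing header-only file.")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a CpG selection list written by [write_selection()]
#'
#' @param path Path to the selection TSV.
#' @return A tibble with columns `cpg_id`, `p_value`, `entropy`.
#' @export
read_selection <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cpg_id = readr::col_character(),
    p_value = readr::col_double(),
    entropy = readr::col_double()
  ))
}

#' Write a metrics report as JSON
#'
#' @param metrics A one-row metrics tibble from [classification_metrics()], or
#'   any list of scalars.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(as.list(metrics), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

# ---- internal dialect helpers ------------------------------------------------

read_table_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  if (nrow(out) == 0 && ncol(out) == 0) abort(paste0("Empty file: ", path))
  out
}

write_table_auto <- function(x, path, na = "NA") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path, na = na)
  } else {
    readr::write_tsv(x, path, na = na)
  }
}
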