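#' Round half away from zero
#'
#' Base `round()` rounds half to even; discretization of beta values uses the
#' conventional half-away-from-zero rule so bin boundaries are predictable.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), digits = 0)
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# size of a top-fraction selection from a pool of size l, with an epsilon
# guard because fractions like 0.15 are not exactly representable and
# fraction * l can overshoot the intended integer by one ulp
top_fraction_size <- function(fraction, l) {
  as.integer(ceiling(fraction * l - sqrt(.Machine$double.eps)))
}

# Deterministic child seeds (< 2^31) from a base seed plus a stage tag, so
# every stage/replicate has its own reproducible RNG stream.
derive_seeds <- function(base_seed, n, tag = "") {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1, n >= 1)
  offset <- if (nzchar(tag)) sum(utf8ToInt(tag)) * 131L else 0L
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((as.integer(base_seed) + offset) %% (.Machine$integer.max - 1L))
  sample.int(.Machine$integer.max - 1L, n)
}

# ---- beta-matrix tibble conventions ------------------------------------------
# A beta table is a tibble whose first column `cpg_id` holds unique CpG
# identifiers and whose remaining columns are samples, values in [0,1] or NA.

beta_sample_ids <- function(beta) setdiff(names(beta), "cpg_id")

beta_values <- function(beta, cpgs = NULL, samples = NULL) {
  x <- as.matrix(beta[, beta_sample_ids(beta), drop = FALSE])
  rownames(x) <- beta$cpg_id
  if (!is.null(cpgs)) {
    missing <- setdiff(cpgs, rownames(x))
    if (length(missing) > 0) {
      abort(paste0(
        "Unknown CpG id(s): ", paste(head(missing, 5), collapse = ", "),
        if (length(missing) > 5) ", ..."
      ))
    }
    x <- x[cpgs, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(x))
    if (length(missing) > 0) {
      abort(paste0(
        "Unknown sample id(s): ", paste(head(missing, 5), collapse = ", ")
      ))
    }
    x <- x[, samples, drop = FALSE]
  }
  x
}

check_beta_tbl <- function(beta, call = rlang::caller_env()) {
  if (!is.data.frame(beta) || !identical(names(beta)[1], "cpg_id")) {
    abort("`beta` must be a data frame with first column `cpg_id`.", call = call)
  }
  if (anyDuplicated(beta$cpg_id)) {
    abort("Duplicate CpG ids in beta table.", call = call)
  }
  if (ncol(beta) < 2) {
    abort("Beta table has no sample columns.", call = call)
  }
  invisible(beta)
}

check_sample_sheet <- function(sheet, call = rlang::caller_env()) {
  required <- c("sample_id", "status", "age", "sex", "smoker")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    abort(paste0("Sample sheet lacks column(s): ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  if (nrow(sheet) == 0) abort("Sample sheet is empty.", call = call)
  if (anyDuplicated(sheet$sample_id)) {
    abort("Duplicate sample ids in sample sheet.", call = call)
  }
  if (!all(sheet$status %in% c(0, 1))) {
    abort("`status` must be 0 (control) or 1 (case).", call = call)
  }
  invisible(sheet)
}

# Align the sheet to the beta table's sample columns; error on mismatch.
align_sheet <- function(beta, sheet, call = rlang::caller_env()) {
  ids <- beta_sample_ids(beta)
  unknown <- setdiff(sheet$sample_id, ids)
  if (length(unknown) > 0) {
    abort(paste0(
      "Sample id(s) absent from beta matrix: ",
      paste(head(unknown, 5), collapse = ", ")
    ), call = call)
  }
  absent <- setdiff(ids, sheet$sample_id)
  if (length(absent) > 0) {
    abort(paste0(
      "Beta matrix sample(s) absent from sheet: ",
      paste(head(absent, 5), collapse = ", ")
    ), call = call)
  }
  sheet[match(ids, sheet$sample_id), , drop = FALSE]
}
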