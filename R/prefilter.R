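#' Drop CpGs with missing values
#'
#' Quality-control step: removes every CpG row containing at least one missing
#' beta value, keeping only completely observed CpGs.
#'
#' @param beta Beta tibble (first column `cpg_id`).
#' @return The beta tibble restricted to fully observed CpGs, with an
#'   attribute `n_dropped` giving the number removed. Errors if nothing
#'   survives.
#' @export
qc_drop_missing <- function(beta) {
  check_beta_tbl(beta)
  x <- beta_values(beta)
  keep <- rowSums(is.na(x)) == 0
  n_dropped <- sum(!keep)
  if (!any(keep)) abort("All CpGs have missing values; nothing survives QC.")
  inform(sprintf("QC: dropped %d of %d CpGs with missing data.", n_dropped, nrow(x)))
  out <- beta[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-CpG linear p-value prefilter
#'
#' Stage 1 of CpG selection: each CpG's beta values are individually linearly
#' modeled against the binary target, and the two-sided p-value of the slope
#' is recorded. For a binary regressor this p-value is algebraically identical
#' to the pooled-variance two-sample t-test p-value, and the implementation
#' computes it in that closed form (vectorized over CpGs). CpGs with
#' `p_value < alpha` (strict) are retained.
#'
#' Zero-variance CpGs carry no information about the target; their p-value is
#' defined as 1 so they are never retained.
#'
#' @param beta Beta tibble with no missing values (run [qc_drop_missing()]
#'   first).
#' @param samples Sample sheet tibble (`status` is the target), or a bare
#'   0/1 vector aligned with the matrix columns.
#' @param alpha Significance threshold; the conventional operating point is
#'   0.05 ("p-value below 5%").
#' @param sample_scope Optional character vector of sample ids to filter on.
#'   The default (NULL) uses all samples, matching the reference procedure of
#'   prefiltering on the full dataset; passing only training-sample ids gives
#'   a leakage-free strict mode.
#' @param adjust Multiple-testing adjustment for the retention rule: `"none"`
#'   (default, raw p-values) or `"BH"` (Benjamini-Hochberg FDR).
#' @return A tibble of class `cpg_pvalues` with columns `cpg_id`, `p_value`,
#'   `retained`, and attributes `alpha` and `n_samples`.
#' @export
pvalue_filter <- function(beta, samples, alpha = 0.05, sample_scope = NULL,
                          adjust = c("none", "BH")) {
  check_beta_tbl(beta)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    abort("`alpha` must be in [0, 1].")
  }
  if (is.data.frame(samples)) {
    check_sample_sheet(samples)
    samples <- align_sheet(beta, samples)
    target <- samples$status
    names(target) <- samples$sample_id
  } else {
    target <- samples
    if (length(target) != length(beta_sample_ids(beta))) {
      abort("Target length must match the number of sample columns.")
    }
    names(target) <- beta_sample_ids(beta)
  }
  if (!all(target %in% c(0, 1))) abort("Target must be binary {0, 1}.")
  scope <- sample_scope %||% names(target)
  x <- beta_values(beta, samples = scope)
  y <- target[scope]
  if (anyNA(x)) abort("Missing beta values; run qc_drop_missing() first.")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("Both target classes must be present.")

  m1 <- rowMeans(x[, y == 1, drop = FALSE])
  m0 <- rowMeans(x[, y == 0, drop = FALSE])
  ss1 <- rowSums((x[, y == 1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((x[, y == 0, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2
  sp2 <- (ss1 + ss0) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tstat <- (m1 - m0) / se
  p <- 2 * pt(-abs(tstat), df)
  # zero within-group variance: perfectly separated groups -> p = 0;
  # globally constant CpG -> no association, p = 1
  degenerate <- se == 0
  p[degenerate & (m1 != m0)] <- 0
  constant <- degenerate & (m1 == m0)
  p[constant] <- 1
  if (any(constant)) {
    inform(sprintf("%d zero-variance CpG(s) assigned p = 1.", sum(constant)))
  }
  p_rule <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  out <- tibble(
    cpg_id = rownames(x),
    p_value = unname(p),
    retained = unname(p_rule < alpha)
  )
  out <- structure(out, class = c("cpg_pvalues", class(out)))
  attr(out, "alpha") <- alpha
  attr(out, "n_samples") <- length(y)
  attr(out, "adjust") <- adjust
  out
}

#' Ids retained by a prefilter profile
#'
#' @param pvalues A `cpg_pvalues` tibble from [pvalue_filter()].
#' @return Character vector of retained CpG ids (the set of size l).
#' @export
retained_ids <- function(pvalues) {
  if (!all(c("cpg_id", "retained") %in% names(pvalues))) {
    abort("`pvalues` must have columns `cpg_id` and `retained`.")
  }
  pvalues$cpg_id[pvalues$retained]
}
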