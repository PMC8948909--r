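#' Discretize beta values into assay-precision bins
#'
#' Maps each beta value (fraction in \[0, 1\]) to a percentage rounded to
#' `decimals` decimal places, using half-away-from-zero rounding, and counts
#' how many values fall in each distinct bin. Two decimals of precision in
#' percentage terms (the default) yields bins 0.01 percentage points wide.
#'
#' @param values Numeric vector of beta values in \[0, 1\].
#' @param decimals Binning precision in decimal places of the percentage.
#' @return A tibble with columns `bin` (percentage value of the bin) and
#'   `count`, ordered by bin.
#' @examples
#' discretize_beta(c(0.2113, 0.21131, 0.2114))
#' @export
discretize_beta <- function(values, decimals = 2) {
  if (length(values) == 0) abort("Cannot discretize an empty vector.")
  if (anyNA(values)) abort("Missing values cannot be discretized.")
  if (any(values < 0 | values > 1)) abort("Beta values must lie in [0, 1].")
  keys <- beta_bin_keys(values, decimals)
  tab <- table(keys)
  tibble(
    bin = as.numeric(names(tab)) / 10^decimals,
    count = as.integer(tab)
  )
}

# integer bin keys: value * 100 rounded half-away-from-zero to `decimals`,
# scaled to integers so floating-point keys never collide spuriously
beta_bin_keys <- function(values, decimals) {
  floor(values * 100 * 10^decimals + 0.5)
}

#' Shannon entropy of a category-count vector
#'
#' Computes `H = -sum(p_i * log2(p_i))` in bits, with probabilities estimated
#' as plain relative frequencies and the convention `0 * log2(0) = 0`. The
#' absolute value is returned (identical, since H is non-negative).
#'
#' @param counts Non-negative counts per category; either a numeric vector or
#'   a tibble with a `count` column as produced by [discretize_beta()].
#' @return Entropy in bits (a single non-negative number).
#' @examples
#' shannon_entropy(c(1, 1, 1, 1)) # log2(4) = 2 bits
#' shannon_entropy(discretize_beta(c(0.1, 0.1, 0.9, 0.9)))
#' @export
shannon_entropy <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  if (length(counts) == 0) abort("`counts` is empty.")
  if (anyNA(counts) || any(counts < 0)) abort("Counts must be non-negative.")
  total <- sum(counts)
  if (total < 1) abort("Total count must be at least 1.")
  p <- counts[counts > 0] / total
  abs(-sum(p * log2(p)))
}

#' Per-CpG Shannon entropy profile
#'
#' Stage 2 of CpG selection: discretizes each CpG's beta values (restricted to
#' the given samples — the training set, in the standard workflow) and
#' computes its Shannon entropy in bits. Entropy here measures how spread out
#' a CpG's methylation values are across individuals at the assay's precision;
#' a constant CpG has 0 bits, a CpG whose values are all distinct has
#' `log2(n)` bits.
#'
#' @param beta Beta tibble with no missing values.
#' @param samples Character vector of sample ids over which entropy is
#'   estimated (typically the training samples only). NULL uses all samples.
#' @param cpgs Character vector of CpG ids to profile. Defaults to the CpGs
#'   retained by `pvalues` when given, otherwise all CpGs.
#' @param decimals Binning precision passed to [discretize_beta()].
#' @param pvalues Optional `cpg_pvalues` tibble from [pvalue_filter()]; its
#'   retained set supplies `cpgs` and its p-values are carried through into
#'   the profile.
#' @return A tibble of class `cpg_entropy` with columns `cpg_id`,
#'   (optionally `p_value`) and `entropy`, plus attributes `decimals` and
#'   `n_train`.
#' @export
cpg_entropy <- function(beta, samples = NULL, cpgs = NULL, decimals = 2,
                        pvalues = NULL) {
  check_beta_tbl(beta)
  if (is.null(cpgs) && !is.null(pvalues)) cpgs <- retained_ids(pvalues)
  if (!is.null(cpgs) && length(cpgs) == 0) {
    abort("Empty CpG set: nothing to profile (no CpGs survived filtering?).")
  }
  if (!is.null(samples) && length(samples) == 0) {
    abort("`samples` must name at least one sample.")
  }
  x <- beta_values(beta, cpgs = cpgs, samples = samples)
  if (anyNA(x)) abort("Missing beta values; run qc_drop_missing() first.")
  if (any(x < 0 | x > 1)) abort("Beta values must lie in [0, 1].")
  keys <- beta_bin_keys(x, decimals)
  h <- apply(keys, 1, function(k) {
    counts <- rle(sort(k))$lengths
    p <- counts / length(k)
    abs(-sum(p * log2(p)))
  })
  out <- tibble(cpg_id = rownames(x), entropy = unname(h))
  if (!is.null(pvalues)) {
    out <- dplyr::left_join(out, pvalues[, c("cpg_id", "p_value")], by = "cpg_id")
    out <- out[, c("cpg_id", "p_value", "entropy")]
  }
  out <- structure(out, class = c("cpg_entropy", class(tibble())))
  attr(out, "decimals") <- decimals
  attr(out, "n_train") <- ncol(x)
  out
}

#' Select the top fraction of a score profile
#'
#' Keeps the `ceiling(fraction * l)` highest-scoring CpGs from a profile of
#' size l. The score column is `entropy` when present (the standard entropy
#' selection, default fraction 10%), otherwise `sd` (volatility selection).
#' Ties at the cut are broken by lexicographic CpG id, a stable documented
#' rule, so selections at nested fractions are themselves nested.
#'
#' @param profile A `cpg_entropy` or `cpg_volatility` tibble (any tibble with
#'   `cpg_id` and a score column).
#' @param fraction Fraction of the profile to keep, in (0, 1\].
#' @return A tibble of class `cpg_selection` with the profile columns of the
#'   selected CpGs and attributes `rule` (list with mode, fraction, score) and
#'   `pool_size`.
#' @export
select_top_fraction <- function(profile, fraction = 0.10) {
  score <- selection_score(profile)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
    fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1].")
  }
  l <- nrow(profile)
  if (l == 0) abort("Cannot select from an empty profile.")
  q <- top_fraction_size(fraction, l)
  ord <- order(-profile[[score]], profile$cpg_id)
  out <- profile[ord[seq_len(q)], , drop = FALSE]
  new_selection(out,
    rule = list(mode = "top_fraction", fraction = fraction, score = score),
    pool_size = l
  )
}

#' Select CpGs whose entropy exceeds a threshold
#'
#' Fixed-threshold selection rule: keeps every CpG with score strictly greater
#' than `threshold` (in bits for entropy profiles).
#'
#' @inheritParams select_top_fraction
#' @param threshold Strict lower bound on the score.
#' @return A `cpg_selection` tibble (may be empty), ordered by descending
#'   score then CpG id.
#' @export
select_above <- function(profile, threshold) {
  score <- selection_score(profile)
  if (!is.numeric(threshold) || length(threshold) != 1) {
    abort("`threshold` must be a single number.")
  }
  keep <- profile[[score]] > threshold
  out <- profile[keep, , drop = FALSE]
  ord <- order(-out[[score]], out$cpg_id)
  new_selection(out[ord, , drop = FALSE],
    rule = list(mode = "threshold", threshold = threshold, score = score),
    pool_size = nrow(profile)
  )
}

selection_score <- function(profile, call = rlang::caller_env()) {
  if (!is.data.frame(profile) || !"cpg_id" %in% names(profile)) {
    abort("`profile` must be a data frame with a `cpg_id` column.", call = call)
  }
  if ("entropy" %in% names(profile)) return("entropy")
  if ("sd" %in% names(profile)) return("sd")
  abort("`profile` must have an `entropy` or `sd` score column.", call = call)
}

new_selection <- function(x, rule, pool_size) {
  out <- structure(as_tibble(x), class = c("cpg_selection", class(tibble())))
  attr(out, "rule") <- rule
  attr(out, "pool_size") <- pool_size
  out
}
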