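#' Per-CpG volatility (standard deviation) profile
#'
#' Computes each CpG's sample standard deviation of beta values (denominator
#' n - 1) over the chosen samples. "Volatility" is this field's shorthand for
#' per-CpG dispersion; it underlies the baseline selectors used to benchmark
#' the entropy selection.
#'
#' @param beta Beta tibble with no missing values.
#' @param samples Character vector of sample ids to use (typically training
#'   samples, for symmetry with the entropy stage). NULL uses all samples.
#' @param cpgs Character vector of CpG ids to profile; NULL profiles all.
#' @return A tibble of class `cpg_volatility` with columns `cpg_id`, `sd`.
#' @export
cpg_sd <- function(beta, samples = NULL, cpgs = NULL) {
  check_beta_tbl(beta)
  x <- beta_values(beta, cpgs = cpgs, samples = samples)
  if (anyNA(x)) abort("Missing beta values; run qc_drop_missing() first.")
  n <- ncol(x)
  if (n < 2) abort("Need at least two samples to compute a standard deviation.")
  m <- rowMeans(x)
  sds <- sqrt(rowSums((x - m)^2) / (n - 1))
  out <- tibble(cpg_id = rownames(x), sd = unname(sds))
  structure(out, class = c("cpg_volatility", class(tibble())))
}

#' Raw top-volatility baseline selection
#'
#' Baseline selector: ranks all CpGs (no p-value prefilter) by standard
#' deviation and keeps the top `fraction` (default 2%, chosen to give a
#' dimensionality comparable to the entropy pipeline's output).
#'
#' @inheritParams cpg_sd
#' @param fraction Fraction of all CpGs to keep, in (0, 1\].
#' @return A `cpg_selection` tibble with columns `cpg_id`, `sd`.
#' @export
select_top_volatile <- function(beta, fraction = 0.02, samples = NULL) {
  profile <- cpg_sd(beta, samples = samples)
  select_top_fraction(profile, fraction)
}

#' Size-matched top-volatility selection from the prefiltered pool
#'
#' Baseline selector: within the p-value-prefiltered CpG pool, keeps the
#' `size` CpGs with the largest standard deviation — `size` is matched exactly
#' to the entropy selection's size so the two approaches feed the classifier
#' the same dimensionality.
#'
#' @inheritParams cpg_sd
#' @param pvalues A `cpg_pvalues` tibble from [pvalue_filter()].
#' @param size Number of CpGs to select (q).
#' @return A `cpg_selection` tibble of exactly `size` rows.
#' @export
select_matched_volatile <- function(beta, pvalues, size, samples = NULL) {
  pool <- retained_ids(pvalues)
  if (length(pool) == 0) abort("Prefiltered pool is empty.")
  if (!is.numeric(size) || size < 1 || size > length(pool)) {
    abort("`size` must be between 1 and the prefiltered pool size.")
  }
  profile <- cpg_sd(beta, samples = samples, cpgs = pool)
  ord <- order(-profile$sd, profile$cpg_id)
  out <- profile[ord[seq_len(size)], , drop = FALSE]
  new_selection(out,
    rule = list(mode = "matched_size", size = size, score = "sd"),
    pool_size = length(pool)
  )
}

#' Standard-deviation sensitivity buckets over a selection pool
#'
#' Sensitivity sweep: from a pool of already-selected CpGs (normally the
#' entropy selection), takes the top 5%, 10%, ..., 50% most volatile subsets.
#' Bucket sizes use `ceiling(fraction * pool size)`; with the stable tie rule
#' the buckets are nested.
#'
#' @inheritParams cpg_sd
#' @param pool A `cpg_selection` tibble or character vector of CpG ids.
#' @param fractions Fractions to sweep, default `seq(0.05, 0.50, by = 0.05)`.
#' @return A tibble with columns `fraction`, `n_selected` and a list-column
#'   `selection` of `cpg_selection` tibbles.
#' @export
sd_sensitivity_buckets <- function(beta, pool,
                                   fractions = seq(0.05, 0.50, by = 0.05),
                                   samples = NULL) {
  ids <- if (is.data.frame(pool)) pool$cpg_id else as.character(pool)
  if (length(ids) == 0) abort("Selection pool is empty.")
  if (any(fractions <= 0 | fractions > 1)) {
    abort("All `fractions` must be in (0, 1].")
  }
  profile <- cpg_sd(beta, samples = samples, cpgs = ids)
  sels <- purrr::map(fractions, function(f) select_top_fraction(profile, f))
  tibble(
    fraction = fractions,
    n_selected = purrr::map_int(sels, nrow),
    selection = sels
  )
}
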