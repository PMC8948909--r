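#' Plan a replicated selection-versus-baseline experiment
#'
#' Describes which experimental arms to run, the replication scheme and every
#' tunable stage parameter. Available arms:
#' \describe{
#'   \item{`direct_all_pfiltered`}{all p-value-prefiltered CpGs, no entropy
#'     selection (the "direct approach").}
#'   \item{`entropy_top10`}{top-`entropy_fraction` Shannon-entropy selection
#'     from the prefiltered pool (computed on training samples only).}
#'   \item{`random_sets`}{`n_random_sets` random size-matched subsets of the
#'     prefiltered pool, `reps_per_set` training runs each — the control for
#'     pure dimensionality reduction.}
#'   \item{`sd_raw2pct`}{top 2% most volatile CpGs with no prefilter.}
#'   \item{`sd_matched`}{size-matched top-volatility subset of the
#'     prefiltered pool.}
#'   \item{`sd_buckets`}{top 5%..50% (5% steps) most volatile subsets of the
#'     entropy-selected pool.}
#' }
#' Every arm trains on CpG features plus the age/sex/smoking covariates,
#' re-splitting train/test per replicate and recomputing train-dependent
#' selections on that replicate's training samples.
#'
#' @param arms Character vector of arm names (see above).
#' @param n_replicates Replicates per non-random arm.
#' @param n_random_sets,reps_per_set Random-control design: number of random
#'   CpG sets and training replicates per set.
#' @param test_fraction,stratified Split parameters, see [make_split()].
#' @param alpha Prefilter significance threshold.
#' @param entropy_fraction Top fraction kept by the entropy selection.
#' @param decimals Entropy binning precision.
#' @param sd_fractions Fractions for the `sd_buckets` sweep.
#' @param raw_sd_fraction Fraction for the raw volatility baseline.
#' @param net A [net_config()] used by every arm (its seed is re-derived per
#'   replicate).
#' @param base_seed Master seed; all replicate, split, selection and training
#'   seeds derive deterministically from it.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(arms = c("direct_all_pfiltered", "entropy_top10",
                                     "random_sets"),
                            n_replicates = 10, n_random_sets = 10,
                            reps_per_set = 10, test_fraction = 0.15,
                            stratified = TRUE, alpha = 0.05,
                            entropy_fraction = 0.10, decimals = 2,
                            sd_fractions = seq(0.05, 0.50, by = 0.05),
                            raw_sd_fraction = 0.02,
                            net = net_config(), base_seed = 1) {
  known <- c(
    "direct_all_pfiltered", "entropy_top10", "random_sets",
    "sd_raw2pct", "sd_matched", "sd_buckets"
  )
  bad <- setdiff(arms, known)
  if (length(bad) > 0) {
    abort(paste0("Unknown arm(s): ", paste(bad, collapse = ", ")))
  }
  if (n_replicates < 1 || n_random_sets < 1 || reps_per_set < 1) {
    abort("Replication counts must be positive.")
  }
  structure(
    list(
      arms = arms, n_replicates = as.integer(n_replicates),
      n_random_sets = as.integer(n_random_sets),
      reps_per_set = as.integer(reps_per_set),
      test_fraction = test_fraction, stratified = stratified, alpha = alpha,
      entropy_fraction = entropy_fraction, decimals = decimals,
      sd_fractions = sd_fractions, raw_sd_fraction = raw_sd_fraction,
      net = net, base_seed = as.integer(base_seed)
    ),
    class = "experiment_plan"
  )
}

# one train/evaluate run for a given selection and split
run_single <- function(beta, samples, selection, split, net, net_seed) {
  if ((is.data.frame(selection) && nrow(selection) == 0) ||
    (!is.data.frame(selection) && length(selection) == 0)) {
    abort("Selection is empty: arm cannot train a classifier.")
  }
  features <- build_features(beta, selection, samples, split)
  cfg <- net
  cfg$seed <- as.integer(net_seed)
  model <- train_network(features, cfg)
  metrics <- evaluate_model(model, features)
  n_sel <- if (is.data.frame(selection)) nrow(selection) else length(selection)
  dplyr::mutate(metrics, n_selected = n_sel, .before = 1)
}

#' Run one experimental arm
#'
#' Executes `n_replicates` independent replicates of the given arm on a
#' cohort: fresh train/test split, arm-specific CpG selection (recomputed on
#' that replicate's training samples where the selection is train-dependent),
#' covariate features, network training and test-set evaluation.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or a list
#'   with elements `beta` and `samples`.
#' @param arm Arm name, see [experiment_plan()].
#' @param plan An [experiment_plan()].
#' @param pvalues Optional precomputed [pvalue_filter()] result (it is
#'   split-independent, so callers running several arms can share it).
#' @return A tibble with one row per replicate (for `sd_buckets`, one row per
#'   replicate and fraction): `arm`, `replicate`, `n_selected`, `error_rate`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, `n_test`.
#' @export
run_arm <- function(cohort, arm, plan = experiment_plan(), pvalues = NULL) {
  if (arm == "random_sets") {
    return(run_random_control(cohort, plan = plan, pvalues = pvalues))
  }
  beta <- cohort$beta
  samples <- cohort$samples
  if (is.null(pvalues)) pvalues <- pvalue_filter(beta, samples, plan$alpha)
  pool <- retained_ids(pvalues)
  if (length(pool) == 0 && arm != "sd_raw2pct") {
    abort(sprintf("Arm '%s': prefiltered pool is empty.", arm))
  }
  split_seeds <- derive_seeds(plan$base_seed, plan$n_replicates, "split")
  net_seeds <- derive_seeds(plan$base_seed, plan$n_replicates, "net")
  q <- top_fraction_size(plan$entropy_fraction, length(pool))

  purrr::map_dfr(seq_len(plan$n_replicates), function(r) {
    split <- make_split(samples, plan$test_fraction, split_seeds[r], plan$stratified)
    train <- split_ids(split, "train")
    selection <- switch(arm,
      direct_all_pfiltered = pool,
      entropy_top10 = {
        profile <- cpg_entropy(beta,
          samples = train, pvalues = pvalues, decimals = plan$decimals
        )
        select_top_fraction(profile, plan$entropy_fraction)
      },
      sd_raw2pct = select_top_volatile(beta, plan$raw_sd_fraction, samples = train),
      sd_matched = select_matched_volatile(beta, pvalues, q, samples = train),
      sd_buckets = NULL,
      abort(paste0("Unknown arm: ", arm))
    )
    if (arm == "sd_buckets") {
      profile <- cpg_entropy(beta,
        samples = train, pvalues = pvalues, decimals = plan$decimals
      )
      epool <- select_top_fraction(profile, plan$entropy_fraction)
      buckets <- sd_sensitivity_buckets(beta, epool,
        fractions = plan$sd_fractions, samples = train
      )
      purrr::map_dfr(seq_len(nrow(buckets)), function(i) {
        res <- run_single(
          beta, samples, buckets$selection[[i]], split, plan$net, net_seeds[r]
        )
        dplyr::mutate(res,
          arm = sprintf("sd_bucket_%02d", round(100 * buckets$fraction[i])),
          replicate = r, .before = 1
        )
      })
    } else {
      res <- run_single(beta, samples, selection, split, plan$net, net_seeds[r])
      dplyr::mutate(res, arm = arm, replicate = r, .before = 1)
    }
  })
}

#' Run the random-selection control
#'
#' Dimensionality control: samples `n_random_sets` CpG sets uniformly without
#' replacement from the p-value-prefiltered pool, each of exactly size `q`
#' (matched to the entropy selection's size), and trains `reps_per_set`
#' replicates per set with fresh splits. All seeds derive from the plan's
#' base seed.
#'
#' @inheritParams run_arm
#' @param q Matched selection size; defaults to
#'   `ceiling(entropy_fraction * pool size)`.
#' @return A tibble with one row per (set, rep): columns as in [run_arm()]
#'   plus `set`.
#' @export
run_random_control <- function(cohort, q = NULL, plan = experiment_plan(),
                               pvalues = NULL) {
  beta <- cohort$beta
  samples <- cohort$samples
  if (is.null(pvalues)) pvalues <- pvalue_filter(beta, samples, plan$alpha)
  pool <- retained_ids(pvalues)
  if (length(pool) == 0) abort("Random control: prefiltered pool is empty.")
  q <- q %||% top_fraction_size(plan$entropy_fraction, length(pool))
  if (q > length(pool)) abort("`q` exceeds the prefiltered pool size.")

  n_runs <- plan$n_random_sets * plan$reps_per_set
  set_seeds <- derive_seeds(plan$base_seed, plan$n_random_sets, "randomset")
  split_seeds <- derive_seeds(plan$base_seed, n_runs, "randomsplit")
  net_seeds <- derive_seeds(plan$base_seed, n_runs, "randomnet")

  purrr::map_dfr(seq_len(plan$n_random_sets), function(s) {
    set.seed(set_seeds[s])
    ids <- sort(sample(pool, q))
    purrr::map_dfr(seq_len(plan$reps_per_set), function(j) {
      run <- (s - 1) * plan$reps_per_set + j
      split <- make_split(
        samples, plan$test_fraction, split_seeds[run], plan$stratified
      )
      res <- run_single(beta, samples, ids, split, plan$net, net_seeds[run])
      dplyr::mutate(res,
        arm = "random_sets", replicate = run, set = s, .before = 1
      )
    })
  })
}

#' Compare replicate error rates between two arms
#'
#' Dual test of the difference in mean replicate error rates: a Welch
#' two-sample t-test and a distribution-free permutation test of the mean
#' difference. The permutation test enumerates all reassignments when
#' feasible, otherwise uses Monte-Carlo permutations with an add-one
#' correction; it is the authoritative one of the pair.
#'
#' @param errors_a,errors_b Numeric vectors of replicate error rates.
#' @param n_perm Monte-Carlo permutation count (used when exhaustive
#'   enumeration exceeds `exhaustive_limit` reassignments).
#' @param seed Seed for Monte-Carlo permutations.
#' @param exhaustive_limit Maximum number of reassignments enumerated
#'   exhaustively.
#' @return A tibble with rows `welch` and `permutation`: `method`,
#'   `estimate` (mean a - mean b), `p_value`, `n_a`, `n_b`.
#' @export
compare_arms <- function(errors_a, errors_b, n_perm = 10000, seed = 1,
                         exhaustive_limit = 20000) {
  a <- as.numeric(errors_a)
  b <- as.numeric(errors_b)
  if (length(a) < 1 || length(b) < 1) abort("Both arms need replicates.")
  obs <- mean(a) - mean(b)
  welch_p <- tryCatch(
    t.test(a, b)$p.value,
    error = function(e) NA_real_ # constant data: Welch undefined
  )
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  tol <- 1e-12
  if (choose(n, na) <= exhaustive_limit) {
    combos <- utils::combn(n, na)
    diffs <- apply(combos, 2, function(idx) {
      mean(pooled[idx]) - mean(pooled[-idx])
    })
    perm_p <- mean(abs(diffs) >= abs(obs) - tol)
  } else {
    set.seed(seed)
    count <- sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= abs(obs) - tol
    }, logical(1)))
    perm_p <- (count + 1) / (n_perm + 1)
  }
  tibble(
    method = c("welch", "permutation"),
    estimate = obs,
    p_value = c(welch_p, perm_p),
    n_a = na, n_b = length(b)
  )
}

#' t-distribution confidence interval on a mean
#'
#' Interval for the mean of replicate error rates. Constant replicates give a
#' zero-width interval at the value; a single replicate gives a flagged
#' degenerate interval with `NA` bounds.
#'
#' @param replicates Numeric vector of replicate values.
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble: `mean`, `lo`, `hi`, `level`, `n_replicates`.
#' @export
confidence_interval <- function(replicates, level = 0.95) {
  x <- as.numeric(replicates)
  if (length(x) == 0) abort("No replicates.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  m <- mean(x)
  if (length(x) == 1) {
    warn("Single replicate: confidence interval is degenerate.")
    return(tibble(mean = m, lo = NA_real_, hi = NA_real_,
      level = level, n_replicates = 1L))
  }
  half <- qt(1 - (1 - level) / 2, df = length(x) - 1) * sd(x) / sqrt(length(x))
  tibble(
    mean = m, lo = m - half, hi = m + half,
    level = level, n_replicates = length(x)
  )
}

#' Run a full multi-arm experiment
#'
#' Orchestrates the complete comparison: shared p-value prefilter, then every
#' arm in the plan with its replication scheme, per-arm mean error rates with
#' t confidence intervals, pairwise arm comparisons (Welch + permutation),
#' and the achieved dimensionality-reduction fraction of the entropy
#' selection relative to the full CpG panel.
#'
#' @inheritParams run_arm
#' @return An object of class `ms_experiment`: list with `replicates` (all
#'   per-replicate rows), `summary` (per arm: mean error, CI, mean
#'   sensitivity/specificity/AUC, mean selection size), `comparisons`
#'   (entropy arm versus each other arm), `sizes` (list: `m`, `m_qc`, `l`,
#'   `q`, `reduction`), and `plan`.
#' @export
run_experiment <- function(cohort, plan = experiment_plan()) {
  beta <- cohort$beta
  m_total <- nrow(beta)
  beta <- qc_drop_missing(beta)
  cohort <- list(beta = beta, samples = cohort$samples)
  pvalues <- pvalue_filter(beta, cohort$samples, plan$alpha)
  l <- length(retained_ids(pvalues))
  if (l == 0) abort("Prefilter retained no CpGs; experiment aborted.")
  q <- top_fraction_size(plan$entropy_fraction, l)

  replicates <- purrr::map_dfr(
    plan$arms,
    function(arm) run_arm(cohort, arm, plan, pvalues = pvalues)
  )

  summary <- replicates |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_error = mean(.data$error_rate),
      ci_lo = suppressWarnings(confidence_interval(.data$error_rate)$lo),
      ci_hi = suppressWarnings(confidence_interval(.data$error_rate)$hi),
      mean_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      mean_specificity = mean(.data$specificity, na.rm = TRUE),
      mean_auc = mean(.data$auc, na.rm = TRUE),
      mean_n_selected = mean(.data$n_selected),
      .groups = "drop"
    )

  comparisons <- NULL
  arms_present <- unique(replicates$arm)
  if ("entropy_top10" %in% arms_present) {
    ent <- replicates$error_rate[replicates$arm == "entropy_top10"]
    others <- setdiff(arms_present, "entropy_top10")
    cmp_seeds <- derive_seeds(plan$base_seed, max(1L, length(others)), "compare")
    comparisons <- purrr::map_dfr(seq_along(others), function(i) {
      other <- others[i]
      res <- compare_arms(
        ent, replicates$error_rate[replicates$arm == other],
        seed = cmp_seeds[i]
      )
      dplyr::mutate(res, comparison = paste0("entropy_top10_vs_", other),
        .before = 1)
    })
  }

  structure(
    list(
      replicates = replicates, summary = summary, comparisons = comparisons,
      sizes = list(
        m = m_total, m_qc = nrow(beta), l = l, q = q,
        reduction = 1 - q / m_total
      ),
      plan = plan
    ),
    class = "ms_experiment"
  )
}

#' @export
print.ms_experiment <- function(x, ...) {
  cat(sprintf(
    "<ms_experiment> m = %d CpGs -> %d post-QC -> l = %d prefiltered -> q = %d selected (%.1f%% reduction)\n",
    x$sizes$m, x$sizes$m_qc, x$sizes$l, x$sizes$q, 100 * x$sizes$reduction
  ))
  print(x$summary)
  if (!is.null(x$comparisons)) {
    cat("comparisons (replicate error rates):\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' @export
tidy.ms_experiment <- function(x, ...) x$summary

#' @export
glance.ms_experiment <- function(x, ...) {
  ent <- x$summary[x$summary$arm == "entropy_top10", ]
  tibble(
    n_arms = nrow(x$summary),
    m = x$sizes$m, l = x$sizes$l, q = x$sizes$q,
    reduction = x$sizes$reduction,
    entropy_mean_error = if (nrow(ent)) ent$mean_error else NA_real_
  )
}

#' Enrichment of planted CpGs in a selection
#'
#' Hypergeometric over-representation test: given the ground-truth set of
#' informative CpGs, tests whether a selection drawn from a pool contains
#' more of them than a uniformly random same-size draw would
#' (`phyper`, upper tail).
#'
#' @param selection A `cpg_selection` or character vector of selected ids.
#' @param truth Character vector of informative (planted) CpG ids.
#' @param pool Character vector of ids the selection was drawn from.
#' @return A one-row tibble: `n_selected`, `n_truth_in_pool`, `n_hits`,
#'   `expected_hits`, `p_value`.
#' @export
truth_enrichment <- function(selection, truth, pool) {
  ids <- if (is.data.frame(selection)) selection$cpg_id else as.character(selection)
  if (!all(ids %in% pool)) abort("Selection must be a subset of the pool.")
  k <- length(ids)
  white <- sum(pool %in% truth)
  hits <- sum(ids %in% truth)
  p <- stats::phyper(hits - 1, white, length(pool) - white, k, lower.tail = FALSE)
  tibble(
    n_selected = k, n_truth_in_pool = white, n_hits = hits,
    expected_hits = k * white / length(pool), p_value = p
  )
}
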