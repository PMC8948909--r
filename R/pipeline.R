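#' Run the full selection-and-classification pipeline
#'
#' Single entry point wiring the stages: cohort input (simulated or read from
#' disk), missing-data QC, per-CpG p-value prefilter, training-set Shannon
#' entropy selection, network training, test-set evaluation, and (optionally)
#' the replicated multi-arm experiment. Each stage logs its input/output
#' dimensions (m CpGs, post-QC, l prefiltered, q selected) and writes its
#' artifact under `out_dir`.
#'
#' @param config A named list or path to a YAML file. Recognized keys:
#'   \describe{
#'     \item{`cohort`}{either a list of [cohort_spec()] arguments (simulate)
#'       or `list(beta = <path>, samples = <path>)` (read from disk).}
#'     \item{`alpha`}{prefilter threshold (default 0.05).}
#'     \item{`entropy`}{list: `fraction` (default 0.10), `decimals` (2).}
#'     \item{`net`}{list of [net_config()] arguments.}
#'     \item{`split`}{list: `test_fraction` (0.15), `stratified` (TRUE).}
#'     \item{`experiment`}{optional list of [experiment_plan()] arguments;
#'       when present the multi-arm experiment also runs.}
#'     \item{`seed`}{master seed (default 1).}
#'   }
#'   Unknown keys are rejected.
#' @param out_dir Directory for artifacts (created if needed).
#' @return The report list (also written to `report.json`), invisibly:
#'   package version, config hash, stage dimensions, selection size, test
#'   metrics and, when requested, the experiment summary.
#' @export
run_pipeline <- function(config, out_dir = tempfile("msrun")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  known <- c("cohort", "alpha", "entropy", "net", "split", "experiment", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05
  entropy_cfg <- modifyList(list(fraction = 0.10, decimals = 2),
    config$entropy %||% list())
  split_cfg <- modifyList(list(test_fraction = 0.15, stratified = TRUE),
    config$split %||% list())
  net <- do.call(net_config, config$net %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  config_hash <- hash_config(config)

  # ---- stage: cohort ---------------------------------------------------------
  cohort_cfg <- config$cohort %||% list()
  truth <- NULL
  if (!is.null(cohort_cfg$beta)) {
    beta <- read_beta_matrix(cohort_cfg$beta)
    samples <- read_sample_sheet(cohort_cfg$samples, beta = beta)
  } else {
    spec_args <- cohort_cfg
    if (is.null(spec_args$seed)) spec_args$seed <- seed
    cohort <- generate_cohort(do.call(cohort_spec, spec_args))
    beta <- cohort$beta
    samples <- cohort$samples
    truth <- cohort$truth
    write_beta_matrix(beta, file.path(out_dir, "beta.tsv"))
    write_sample_sheet(samples, file.path(out_dir, "samples.csv"))
    readr::write_tsv(tibble(cpg_id = truth), file.path(out_dir, "truth.tsv"))
  }
  m <- nrow(beta)
  inform(sprintf("[cohort] m = %d CpGs x %d samples", m, nrow(samples)))

  # ---- stage: QC + prefilter -------------------------------------------------
  beta <- qc_drop_missing(beta)
  inform(sprintf("[qc] %d CpGs survive missing-data QC", nrow(beta)))
  pvalues <- pvalue_filter(beta, samples, alpha)
  l <- length(retained_ids(pvalues))
  inform(sprintf("[prefilter] l = %d CpGs at p < %g", l, alpha))
  readr::write_tsv(as_tibble(pvalues), file.path(out_dir, "pvalues.tsv"))
  if (l == 0) {
    abort(sprintf(
      "[entropy] aborting: prefilter at alpha = %g retained no CpGs.", alpha
    ))
  }

  # ---- stage: split + entropy selection --------------------------------------
  split <- make_split(samples, split_cfg$test_fraction, seed, split_cfg$stratified)
  profile <- cpg_entropy(beta,
    samples = split_ids(split, "train"),
    pvalues = pvalues, decimals = entropy_cfg$decimals
  )
  selection <- select_top_fraction(profile, entropy_cfg$fraction)
  q <- nrow(selection)
  inform(sprintf("[entropy] q = %d CpGs selected (top %g%%)",
    q, 100 * entropy_cfg$fraction))
  write_selection(selection, file.path(out_dir, "selection.tsv"))

  # ---- stage: train + evaluate -----------------------------------------------
  features <- build_features(beta, selection, samples, split)
  net$seed <- as.integer(seed)
  model <- train_network(features, net)
  write_model(model, file.path(out_dir, "model.json"))
  metrics <- evaluate_model(model, features)
  write_metrics_json(metrics, file.path(out_dir, "metrics.json"))
  inform(sprintf("[evaluate] test error %.3f (n = %d)",
    metrics$error_rate, metrics$n_test))

  # ---- stage: experiment (optional) ------------------------------------------
  experiment_summary <- NULL
  if (!is.null(config$experiment)) {
    plan_args <- config$experiment
    if (is.null(plan_args$base_seed)) plan_args$base_seed <- seed
    plan_args$net <- do.call(net_config, plan_args$net %||% (config$net %||% list()))
    plan <- do.call(experiment_plan, plan_args)
    experiment <- run_experiment(list(beta = beta, samples = samples), plan)
    readr::write_tsv(experiment$replicates, file.path(out_dir, "replicates.tsv"))
    experiment_summary <- list(
      summary = experiment$summary,
      comparisons = experiment$comparisons,
      sizes = experiment$sizes
    )
  }

  report <- list(
    package = "methylentropy",
    version = as.character(utils::packageVersion("methylentropy")),
    config_hash = config_hash,
    seed = seed,
    dimensions = list(m = m, m_qc = nrow(beta), l = l, q = q),
    reduction = 1 - q / m,
    metrics = as.list(metrics),
    experiment = experiment_summary
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null", force = TRUE
  )
  invisible(report)
}

# md5 of the canonical JSON encoding of the config, for provenance
hash_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
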