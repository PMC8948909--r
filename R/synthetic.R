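#' Specify a synthetic methylation cohort
#'
#' Describes a case/control blood-methylation cohort with a planted subset of
#' differentially methylated CpGs, a block of exactly-constant ("flat") CpGs,
#' and uninformative noisy CpGs. Defaults mirror the reference study design:
#' 140 cases / 139 controls, ages uniform on 16--66 years, 77/279 male,
#' 138/279 smokers.
#'
#' The generative model is a moment-corrected logit-normal: each CpG has a
#' baseline mean beta, cases are shifted by `effect_size` at informative CpGs,
#' and per-sample values are drawn on the logit scale with a dispersion chosen
#' so the beta-scale within-group standard deviation is approximately
#' `noise_sd`, then mapped back through the logistic link (values stay strictly
#' inside (0, 1)) and rounded to the assay's measurement precision
#' (`value_decimals` decimals of the beta fraction).
#'
#' @param n_cases,n_controls Sample counts per class.
#' @param n_cpgs Total number of CpGs (m).
#' @param n_informative Number of planted differentially methylated CpGs.
#' @param effect_size Mean beta shift in cases at informative CpGs, in
#'   \[0, 0.5\].
#' @param base_beta_shape Length-2 shape parameters of the Beta distribution
#'   from which baseline per-CpG mean betas are drawn (squeezed into
#'   \[0.05, 0.95\]).
#' @param noise_sd Within-group beta-scale dispersion.
#' @param n_flat Number of CpGs with exactly zero sample variance.
#' @param covariate_effects Named list of beta shifts per unit of covariate
#'   (`age` per scaled-age unit, `sex`, `smoker`); all zero by default so
#'   covariates are pure nuisance inputs.
#' @param liability_sd Spread of the per-sample disease-liability factor.
#'   All informative CpGs respond to a single latent liability
#'   `status + liability_sd * N(0, 1)` (cases shifted by one unit), emulating
#'   a shared driver such as immune-cell composition or inflammatory state.
#'   Because every disease-associated CpG tracks the same overlapping
#'   liability, no classifier can exceed the liability's own class
#'   separation — methylation classifiers on real blood data plateau well
#'   short of perfect accuracy for exactly this reason. 0 makes informative
#'   CpGs independent carriers of a clean status signal.
#' @param value_decimals Measurement precision: emitted betas are rounded to
#'   this many decimals of the beta fraction (default 3, i.e. 0.1 percentage
#'   points).
#' @param age_range Integer age bounds (years), inclusive.
#' @param male_rate,smoker_rate Bernoulli rates for the sex and smoking
#'   covariates.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [default_paper_spec()]
#' @export
cohort_spec <- function(n_cases = 140, n_controls = 139, n_cpgs = 2000,
                        n_informative = 100, effect_size = 0.15,
                        base_beta_shape = c(0.8, 0.8), noise_sd = 0.15,
                        n_flat = 20,
                        covariate_effects = list(age = 0, sex = 0, smoker = 0),
                        liability_sd = 0.4, value_decimals = 3,
                        age_range = c(16, 66),
                        male_rate = 77 / 279, smoker_rate = 138 / 279,
                        seed = 1) {
  spec <- list(
    n_cases = n_cases, n_controls = n_controls, n_cpgs = n_cpgs,
    n_informative = n_informative, effect_size = effect_size,
    base_beta_shape = base_beta_shape, noise_sd = noise_sd, n_flat = n_flat,
    covariate_effects = modifyList(
      list(age = 0, sex = 0, smoker = 0), as.list(covariate_effects)
    ),
    liability_sd = liability_sd, value_decimals = value_decimals,
    age_range = age_range, male_rate = male_rate, smoker_rate = smoker_rate,
    seed = seed
  )
  counts <- c(n_cases, n_controls, n_cpgs, n_informative, n_flat)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("Counts must be non-negative integers.")
  }
  if (n_cases < 1 || n_controls < 1) abort("Need at least one case and one control.")
  if (n_cpgs < 1) abort("`n_cpgs` must be positive.")
  if (n_informative + n_flat > n_cpgs) {
    abort("`n_informative` + `n_flat` must not exceed `n_cpgs`.")
  }
  if (effect_size < 0 || effect_size > 0.5) abort("`effect_size` must be in [0, 0.5].")
  if (noise_sd <= 0 || noise_sd >= 0.5) abort("`noise_sd` must be in (0, 0.5).")
  if (liability_sd < 0) abort("`liability_sd` must be non-negative.")
  if (length(base_beta_shape) != 2 || any(base_beta_shape <= 0)) {
    abort("`base_beta_shape` must be two positive shape parameters.")
  }
  if (length(age_range) != 2 || age_range[1] > age_range[2]) {
    abort("`age_range` must be increasing bounds.")
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d cases / %d controls, %d CpGs (%d informative, %d flat)\n",
    x$n_cases, x$n_controls, x$n_cpgs, x$n_informative, x$n_flat
  ))
  cat(sprintf(
    "  effect_size = %.3f, noise_sd = %.3f, liability_sd = %.2f, seed = %d\n",
    x$effect_size, x$noise_sd, x$liability_sd, x$seed
  ))
  invisible(x)
}

#' Cohort spec mirroring the reference study at reduced CpG count
#'
#' Returns a [cohort_spec()] with the study's sample composition (140 cases,
#' 139 controls) and a CpG count scaled down from the 450K array's 485,512
#' probes by `scale`.
#'
#' @param scale Fraction of 485,512 CpGs to simulate, in (0, 1\].
#' @param ... Further arguments passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_paper_spec <- function(scale = 0.01, ...) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1) {
    abort("`scale` must be in (0, 1].")
  }
  n_cpgs <- floor(485512 * scale)
  cohort_spec(
    n_cases = 140, n_controls = 139, n_cpgs = n_cpgs,
    n_informative = max(1L, round(0.05 * n_cpgs)),
    n_flat = round(0.01 * n_cpgs),
    ...
  )
}

#' Generate a synthetic methylation cohort
#'
#' Draws a CpG-by-sample beta matrix, a sample sheet with disease status and
#' covariates, and records the ground truth (which CpGs carry the planted
#' case/control signal and which are flat).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `beta` (tibble, first column `cpg_id`), `samples` (sample sheet tibble),
#'   `truth` (character vector of informative CpG ids), `flat_ids`
#'   (character vector of zero-variance CpG ids) and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_cases = 20, n_controls = 20,
#'   n_cpgs = 50, n_informative = 5, n_flat = 2, seed = 7))
#' dim(cohort$beta)
#' table(cohort$samples$status)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    spec <- do.call(cohort_spec, as.list(spec))
  }
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  m <- spec$n_cpgs

  sample_id <- sprintf("S%04d", seq_len(n))
  status <- c(rep(1L, spec$n_cases), rep(0L, spec$n_controls))
  age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  sex <- rbinom(n, 1, spec$male_rate)
  smoker <- rbinom(n, 1, spec$smoker_rate)
  samples <- tibble(
    sample_id = sample_id, status = status, age = age,
    sex = sex, smoker = smoker
  )

  cpg_id <- sprintf("cg%08d", seq_len(m))
  informative <- sort(sample(m, spec$n_informative))
  flat <- sort(sample(setdiff(seq_len(m), informative), spec$n_flat))

  # baseline mean betas: bimodal-ish Beta draw squeezed away from 0/1;
  # informative CpGs take mid-range baselines so the case shift stays in range
  mu <- 0.05 + 0.90 * rbeta(m, spec$base_beta_shape[1], spec$base_beta_shape[2])
  if (spec$n_informative > 0) {
    hi <- min(0.80, 0.95 - spec$effect_size)
    mu[informative] <- runif(spec$n_informative, 0.20, hi)
  }

  age_scaled <- (age - spec$age_range[1]) /
    max(1, diff(spec$age_range))
  cov_shift <- spec$covariate_effects$age * age_scaled +
    spec$covariate_effects$sex * sex +
    spec$covariate_effects$smoker * smoker

  # per-sample disease liability: cases shifted by one unit, overlapping with
  # controls; every informative CpG responds to it, so the liability's own
  # class separation bounds achievable classification accuracy
  liability <- status + spec$liability_sd * rnorm(n)

  values <- matrix(NA_real_, nrow = m, ncol = n,
    dimnames = list(cpg_id, sample_id)
  )
  dec <- spec$value_decimals
  eps <- 10^(-dec)
  is_flat <- seq_len(m) %in% flat
  is_inf <- seq_len(m) %in% informative

  for (i in seq_len(m)) {
    if (is_flat[i]) {
      values[i, ] <- rep(round_half_up(mu[i], dec), n)
      next
    }
    target_mean <- mu[i] + cov_shift +
      if (is_inf[i]) spec$effect_size * liability else 0
    target_mean <- pmin(pmax(target_mean, 0.05), 0.95)
    s_lat <- spec$noise_sd / (target_mean * (1 - target_mean))
    # second-order moment correction so E[beta] matches target_mean despite
    # the nonlinear logistic link
    bias <- 0.5 * spec$noise_sd^2 * (1 - 2 * target_mean) /
      (target_mean * (1 - target_mean))
    xi <- qlogis(pmin(pmax(target_mean - bias, 0.02), 0.98))
    b <- plogis(xi + s_lat * rnorm(n))
    values[i, ] <- pmin(pmax(round_half_up(b, dec), eps), 1 - eps)
  }

  beta <- dplyr::bind_cols(
    tibble(cpg_id = cpg_id),
    as_tibble(values)
  )
  structure(
    list(
      beta = beta, samples = samples,
      truth = cpg_id[informative], flat_ids = cpg_id[flat],
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d CpGs x %d samples (%d cases / %d controls)\n",
    nrow(x$beta), nrow(x$samples),
    sum(x$samples$status == 1), sum(x$samples$status == 0)
  ))
  cat(sprintf(
    "  planted informative: %d, flat: %d, seed: %d\n",
    length(x$truth), length(x$flat_ids), x$spec$seed
  ))
  invisible(x)
}
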