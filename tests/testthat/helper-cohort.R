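# Small cohorts and network configs shared across tests. Everything is
# generated in code at test time; seeds are fixed so the suite is
# deterministic.

tiny_cohort <- function(n_cases = 30, n_controls = 30, n_cpgs = 200,
                        n_informative = 20, effect_size = 0.2, n_flat = 10,
                        seed = 42, ...) {
  generate_cohort(cohort_spec(
    n_cases = n_cases, n_controls = n_controls, n_cpgs = n_cpgs,
    n_informative = n_informative, effect_size = effect_size,
    n_flat = n_flat, seed = seed, ...
  ))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

small_net <- function(seed = 1, ...) {
  net_config(hidden_units = 8, max_epochs = 150, seed = seed, ...)
}

# a tiny beta tibble built by hand
manual_beta <- function(values, cpg_ids = NULL, sample_ids = NULL) {
  m <- nrow(values)
  n <- ncol(values)
  cpg_ids <- cpg_ids %||% sprintf("cg%03d", seq_len(m))
  sample_ids <- sample_ids %||% sprintf("S%02d", seq_len(n))
  out <- tibble::as_tibble(as.data.frame(values))
  names(out) <- sample_ids
  dplyr::bind_cols(tibble::tibble(cpg_id = cpg_ids), out)
}

manual_sheet <- function(status, age = NULL, sex = NULL, smoker = NULL,
                         sample_ids = NULL) {
  n <- length(status)
  tibble::tibble(
    sample_id = sample_ids %||% sprintf("S%02d", seq_len(n)),
    status = status,
    age = age %||% rep(40, n),
    sex = sex %||% rep(0, n),
    smoker = smoker %||% rep(0, n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
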