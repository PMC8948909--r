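test_that("identical replicate vectors give permutation p = 1 and zero effect", {
  res <- compare_arms(rep(0.2, 6), rep(0.2, 6))
  perm <- res[res$method == "permutation", ]
  expect_equal(perm$p_value, 1)
  expect_equal(perm$estimate, 0)
})

test_that("disjoint supports reach the exhaustive permutation minimum", {
  a <- rep(0.1, 6)
  b <- rep(0.5, 6)
  res <- compare_arms(a, b) # C(12,6) = 924, enumerated exhaustively
  perm <- res[res$method == "permutation", ]
  expect_equal(perm$p_value, 2 / 924, tolerance = 1e-12)
  expect_equal(perm$estimate, -0.4)
})

test_that("swapping arms flips the effect sign but not the p-value", {
  set.seed(31)
  a <- runif(8, 0.1, 0.3)
  b <- runif(8, 0.2, 0.4)
  r1 <- compare_arms(a, b)
  r2 <- compare_arms(b, a)
  expect_equal(r1$estimate, -r2$estimate)
  expect_equal(
    r1$p_value[r1$method == "permutation"],
    r2$p_value[r2$method == "permutation"]
  )
})

test_that("Monte-Carlo permutation kicks in above the exhaustive limit", {
  set.seed(32)
  a <- rnorm(15, 0.2, 0.05)
  b <- rnorm(15, 0.2, 0.05) # C(30,15) >> limit
  res <- compare_arms(a, b, n_perm = 2000, seed = 5)
  perm_p <- res$p_value[res$method == "permutation"]
  expect_gte(perm_p, 1 / 2001)
  expect_lte(perm_p, 1)
  # same seed, same answer
  res2 <- compare_arms(a, b, n_perm = 2000, seed = 5)
  expect_identical(res$p_value, res2$p_value)
})

test_that("confidence intervals: degenerate, symmetric and shrinking cases", {
  # constant replicates: zero width at the value
  ci <- confidence_interval(rep(0.25, 5))
  expect_equal(ci$lo, 0.25)
  expect_equal(ci$hi, 0.25)

  # two replicates {0, 1}: symmetric about 0.5
  ci2 <- confidence_interval(c(0, 1))
  expect_equal(ci2$mean, 0.5)
  expect_equal(ci2$hi - 0.5, 0.5 - ci2$lo)

  # single replicate: flagged degenerate
  expect_warning(ci1 <- confidence_interval(0.3), "degenerate")
  expect_true(is.na(ci1$lo))

  # width shrinks like 1/sqrt(k)
  set.seed(33)
  width_at <- function(k) {
    mean(replicate(60, {
      ci <- confidence_interval(rnorm(k, 0.5, 0.1))
      ci$hi - ci$lo
    }))
  }
  w10 <- width_at(10)
  w40 <- width_at(40)
  expect_equal(w40 / w10, 0.5, tolerance = 0.15)
})

test_that("run_arm produces one metrics row per replicate and honors q", {
  cohort <- tiny_cohort(n_cases = 40, n_controls = 40, n_cpgs = 300,
    n_informative = 30, n_flat = 10, seed = 51)
  plan <- experiment_plan(
    arms = c("direct_all_pfiltered", "entropy_top10"),
    n_replicates = 2, net = small_net(), base_seed = 61
  )
  pf <- quiet(pvalue_filter(cohort$beta, cohort$samples))
  l <- length(retained_ids(pf))
  res <- quiet(run_arm(cohort, "entropy_top10", plan, pvalues = pf))
  expect_equal(nrow(res), 2)
  expect_true(all(res$n_selected == ceiling(0.10 * l)))
  expect_true(all(res$error_rate >= 0 & res$error_rate <= 1))

  direct <- quiet(run_arm(cohort, "direct_all_pfiltered", plan, pvalues = pf))
  expect_true(all(direct$n_selected == l))
})

test_that("random control sets are exact-size subsets of the prefiltered pool", {
  cohort <- tiny_cohort(n_cases = 40, n_controls = 40, n_cpgs = 300,
    n_informative = 30, n_flat = 10, seed = 51)
  plan <- experiment_plan(
    n_random_sets = 3, reps_per_set = 2, net = small_net(), base_seed = 62
  )
  pf <- quiet(pvalue_filter(cohort$beta, cohort$samples))
  pool <- retained_ids(pf)
  res <- quiet(run_random_control(cohort, q = 7, plan = plan, pvalues = pf))
  expect_equal(nrow(res), 6)
  expect_true(all(res$n_selected == 7))
  expect_equal(unique(res$set), 1:3)

  # q = pool size means every random set is the pool itself
  res_all <- quiet(run_random_control(cohort,
    q = length(pool),
    plan = experiment_plan(n_random_sets = 2, reps_per_set = 1,
      net = small_net(), base_seed = 63),
    pvalues = pf
  ))
  expect_true(all(res_all$n_selected == length(pool)))
})

test_that("experiments are bit-reproducible from the base seed", {
  cohort <- tiny_cohort(n_cases = 30, n_controls = 30, n_cpgs = 200,
    n_informative = 20, n_flat = 5, seed = 52)
  plan <- experiment_plan(
    arms = c("entropy_top10", "sd_matched"),
    n_replicates = 2, net = small_net(), base_seed = 64
  )
  e1 <- quiet(run_experiment(cohort, plan))
  e2 <- quiet(run_experiment(cohort, plan))
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$summary, e2$summary)
})

test_that("sd_buckets arm reports one row per replicate and fraction", {
  cohort <- tiny_cohort(n_cases = 30, n_controls = 30, n_cpgs = 200,
    n_informative = 20, n_flat = 5, seed = 53)
  plan <- experiment_plan(
    arms = "sd_buckets", n_replicates = 1,
    sd_fractions = c(0.25, 0.5), net = small_net(), base_seed = 65
  )
  res <- quiet(run_arm(cohort, "sd_buckets", plan))
  expect_equal(nrow(res), 2)
  expect_equal(sort(unique(res$arm)), c("sd_bucket_25", "sd_bucket_50"))
  expect_true(res$n_selected[res$arm == "sd_bucket_25"] <=
    res$n_selected[res$arm == "sd_bucket_50"])
})

test_that("a single-replicate plan yields a flagged degenerate CI", {
  cohort <- tiny_cohort(n_cases = 30, n_controls = 30, n_cpgs = 150,
    n_informative = 15, n_flat = 5, seed = 54)
  plan <- experiment_plan(
    arms = "entropy_top10", n_replicates = 1,
    net = small_net(), base_seed = 66
  )
  exp <- quiet(run_experiment(cohort, plan))
  expect_equal(exp$summary$n_replicates, 1L)
  expect_true(is.na(exp$summary$ci_lo))
})

test_that("selection-size reduction is reported from the run, not assumed", {
  cohort <- tiny_cohort(n_cases = 30, n_controls = 30, n_cpgs = 200,
    n_informative = 20, n_flat = 5, seed = 55)
  plan <- experiment_plan(arms = "entropy_top10", n_replicates = 1,
    net = small_net(), base_seed = 67)
  exp <- quiet(run_experiment(cohort, plan))
  expect_equal(exp$sizes$reduction, 1 - exp$sizes$q / exp$sizes$m)
  expect_true(exp$sizes$m >= exp$sizes$m_qc)
  expect_true(exp$sizes$m_qc >= exp$sizes$l)
  expect_true(exp$sizes$l >= exp$sizes$q)
})

test_that("hypergeometric enrichment matches phyper and flags subsets", {
  pool <- sprintf("cg%03d", 1:50)
  truth <- pool[1:10]
  sel <- pool[c(1:6, 40:44)] # 6 hits of 11 selected
  enr <- truth_enrichment(sel, truth, pool)
  expect_equal(enr$n_hits, 6)
  expect_equal(enr$p_value, phyper(5, 10, 40, 11, lower.tail = FALSE))
  expect_error(truth_enrichment(c("cg999"), truth, pool), "subset")
})

test_that("experiment plan validates arm names and replication counts", {
  expect_error(experiment_plan(arms = "bogus_arm"), "Unknown arm")
  expect_error(experiment_plan(n_replicates = 0), "positive")
})
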