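test_that("discretization bins betas at two percent-decimals with half-up rounding", {
  bins <- discretize_beta(c(0.2113, 0.21131, 0.2114), decimals = 2)
  expect_equal(bins$bin, c(21.13, 21.14))
  expect_equal(bins$count, c(2L, 1L))

  # constant vector: one bin holding everything
  bins2 <- discretize_beta(rep(0.5, 7))
  expect_equal(nrow(bins2), 1)
  expect_equal(bins2$count, 7L)

  # half-away-from-zero at the bin edge: 0.21135 * 100 = 21.135 -> 21.14
  bins3 <- discretize_beta(0.21135, decimals = 2)
  expect_equal(bins3$bin, 21.14)

  # coarser precision can only merge bins
  set.seed(4)
  v <- runif(50)
  expect_lte(nrow(discretize_beta(v, decimals = 0)),
    nrow(discretize_beta(v, decimals = 2)))

  expect_error(discretize_beta(numeric(0)), "empty")
  expect_error(discretize_beta(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("shannon_entropy matches closed forms and a brute-force oracle", {
  expect_equal(shannon_entropy(5), 0) # single category
  expect_equal(shannon_entropy(c(3, 3)), 1) # two equal categories
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2)
  for (k in c(3, 8, 16)) {
    expect_equal(shannon_entropy(rep(2, k)), log2(k), tolerance = 1e-12)
  }
  # independent summation oracle
  brute <- function(counts) {
    total <- sum(counts)
    h <- 0
    for (c_i in counts) {
      if (c_i > 0) {
        p_i <- c_i / total
        h <- h - p_i * log2(p_i)
      }
    }
    abs(h)
  }
  expect_equal(shannon_entropy(c(3, 1)), brute(c(3, 1)), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:25) {
    counts <- sample(0:20, sample(2:12, 1), replace = TRUE)
    if (sum(counts) == 0) counts <- counts + 1
    expect_equal(shannon_entropy(counts), brute(counts), tolerance = 1e-12)
  }
  expect_error(shannon_entropy(c(2, -1)), "non-negative")
  # accepts the discretizer's tibble output directly
  expect_equal(shannon_entropy(discretize_beta(c(0.1, 0.1, 0.9, 0.9))), 1)
})

test_that("entropy profile uses only the training samples", {
  cohort <- tiny_cohort()
  samples <- cohort$samples$sample_id
  train <- samples[1:40]
  prof <- cpg_entropy(cohort$beta, samples = train)

  # perturb only test-sample values: profile must not change
  beta2 <- cohort$beta
  test_cols <- setdiff(samples, train)
  for (cn in test_cols) beta2[[cn]] <- rev(beta2[[cn]])
  prof2 <- cpg_entropy(beta2, samples = train)
  expect_identical(prof$entropy, prof2$entropy)
})

test_that("entropy bounds: 0 for flat CpGs, log2(n) for all-distinct values", {
  cohort <- tiny_cohort()
  train <- cohort$samples$sample_id[1:32]
  prof <- cpg_entropy(cohort$beta, samples = train)
  expect_true(all(prof$entropy >= 0))
  expect_true(all(prof$entropy <= log2(32) + 1e-12))
  flat <- prof$entropy[prof$cpg_id %in% cohort$flat_ids]
  expect_true(all(flat == 0))

  # a CpG with all-distinct binned values reaches the log2(n) ceiling
  distinct <- manual_beta(matrix(seq(0.1, 0.9, length.out = 16), 1))
  p <- cpg_entropy(distinct)
  expect_equal(p$entropy, log2(16), tolerance = 1e-12)
})

test_that("entropy is invariant under sample permutation", {
  cohort <- tiny_cohort(n_cpgs = 50, n_informative = 5, n_flat = 5)
  ids <- cohort$samples$sample_id
  prof <- cpg_entropy(cohort$beta, samples = ids)
  set.seed(6)
  prof_perm <- cpg_entropy(cohort$beta, samples = sample(ids))
  expect_equal(prof$entropy, prof_perm$entropy)
})

test_that("coarsening the bins never increases entropy", {
  cohort <- tiny_cohort(n_cpgs = 80, n_informative = 10, n_flat = 5)
  fine <- cpg_entropy(cohort$beta, decimals = 2)
  coarse <- cpg_entropy(cohort$beta, decimals = 0)
  expect_true(all(coarse$entropy <= fine$entropy + 1e-12))
})

test_that("top-fraction selection sizes, ordering and tie rule", {
  prof <- tibble::tibble(
    cpg_id = sprintf("cg%03d", 1:100),
    entropy = seq(0.01, 1, length.out = 100)
  )
  sel <- select_top_fraction(prof, 0.10)
  expect_equal(nrow(sel), 10)
  expect_true(min(sel$entropy) >= max(prof$entropy[!prof$cpg_id %in% sel$cpg_id]))

  # f = 1 selects everything
  expect_equal(nrow(select_top_fraction(prof, 1)), 100)

  # all-equal entropies: lexicographically first ids win
  ties <- tibble::tibble(cpg_id = sprintf("cg%02d", 10:1), entropy = rep(1, 10))
  sel_t <- select_top_fraction(ties, 0.3)
  expect_equal(sort(sel_t$cpg_id), c("cg01", "cg02", "cg03"))

  expect_error(select_top_fraction(prof, 0), "fraction")
  expect_error(select_top_fraction(prof, 1.2), "fraction")
})

test_that("nested fractions give nested selections", {
  cohort <- tiny_cohort()
  prof <- cpg_entropy(cohort$beta)
  fracs <- c(0.05, 0.1, 0.25, 0.5, 1)
  sels <- lapply(fracs, function(f) select_top_fraction(prof, f)$cpg_id)
  for (i in seq_len(length(fracs) - 1)) {
    expect_true(all(sels[[i]] %in% sels[[i + 1]]))
  }
})

test_that("threshold selection is strict and matches a brute-force count", {
  cohort <- tiny_cohort()
  train <- cohort$samples$sample_id[1:40]
  prof <- cpg_entropy(cohort$beta, samples = train)

  # threshold 0 keeps exactly the non-constant CpGs
  sel0 <- select_above(prof, 0)
  expect_setequal(sel0$cpg_id, prof$cpg_id[prof$entropy > 0])

  # threshold at the ceiling keeps nothing
  expect_equal(nrow(select_above(prof, log2(length(train)))), 0)

  # median threshold: brute-force count
  med <- median(prof$entropy)
  sel_m <- select_above(prof, med)
  expect_equal(nrow(sel_m), sum(prof$entropy > med))
})

test_that("profiling an empty retained set is an error", {
  cohort <- tiny_cohort(n_cpgs = 30, n_informative = 0, effect_size = 0,
    n_flat = 0)
  pf <- quiet(pvalue_filter(cohort$beta, cohort$samples, alpha = 1e-12))
  expect_error(cpg_entropy(cohort$beta, pvalues = pf), "Empty CpG set")
})
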