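test_that("split sizes, reproducibility and stratification", {
  cohort <- tiny_cohort(n_cases = 140, n_controls = 139, n_cpgs = 10,
    n_informative = 0, effect_size = 0, n_flat = 0)
  sp <- make_split(cohort$samples, test_fraction = 0.15, seed = 1)
  n_test <- sum(sp$split == "test")
  expect_true(n_test %in% c(41, 42))
  expect_setequal(sp$sample_id, cohort$samples$sample_id)

  # same seed: identical plan
  sp2 <- make_split(cohort$samples, test_fraction = 0.15, seed = 1)
  expect_identical(as.data.frame(sp), as.data.frame(sp2))

  # stratified: class ratio in the test set within one sample of global
  status <- cohort$samples$status[match(sp$sample_id, cohort$samples$sample_id)]
  n_case_test <- sum(status == 1 & sp$split == "test")
  expect_lte(abs(n_case_test - 0.15 * 140), 1)

  expect_error(make_split(cohort$samples, test_fraction = 0.999), "class|split")
  expect_error(make_split(cohort$samples, test_fraction = 0), "test_fraction")
  expect_error(make_split(cohort$samples, test_fraction = 1), "test_fraction")
})

test_that("feature block: dimension q + 3, train-based age scaling, clipping", {
  cohort <- tiny_cohort(n_cpgs = 40, n_informative = 5, n_flat = 0)
  sp <- make_split(cohort$samples, seed = 2)
  ids <- cohort$beta$cpg_id[1:7]
  fb <- build_features(cohort$beta, ids, cohort$samples, sp)
  expect_equal(ncol(fb$x_train), 10) # 7 CpGs + age + sex + smoker
  expect_equal(nrow(fb$x_train) + nrow(fb$x_test), nrow(cohort$samples))
  expect_true(all(fb$x_train[, "age_scaled"] >= 0 &
    fb$x_train[, "age_scaled"] <= 1))
  expect_true(all(fb$x_test[, "age_scaled"] >= 0 &
    fb$x_test[, "age_scaled"] <= 1))

  # all-identical ages: constant zero feature
  flat_age <- cohort$samples
  flat_age$age <- 50
  fb2 <- build_features(cohort$beta, ids, flat_age, sp)
  expect_true(all(fb2$x_train[, "age_scaled"] == 0))

  # test-set age outside the training range gets clipped, with a message
  stretched <- cohort$samples
  test_id <- split_ids(sp, "test")[1]
  stretched$age[stretched$sample_id == test_id] <- 120
  expect_message(
    fb3 <- build_features(cohort$beta, ids, stretched, sp),
    "clipped"
  )
  expect_equal(unname(fb3$x_test[test_id, "age_scaled"]), 1)

  expect_error(build_features(cohort$beta, "cg_missing", cohort$samples, sp),
    "Unknown CpG")
  expect_error(build_features(cohort$beta, character(), cohort$samples, sp),
    "empty")
})

test_that("forward pass matches the closed-form composition to 1e-12", {
  # hand-set 1-feature network: logistic(tanh(w x + b) v + c)
  model <- structure(
    list(
      W1 = matrix(1.7, 1, 1), b1 = -0.3, w2 = 2.1, b2 = 0.4,
      feature_names = "x",
      config = net_config(hidden_units = 1),
      history = tibble::tibble(), n_epochs = 0L, converged = FALSE,
      final_loss = NA_real_
    ),
    class = "ms_net"
  )
  x <- matrix(seq(-2, 2, by = 0.25), ncol = 1)
  pred <- predict(model, x)
  oracle <- plogis(tanh(1.7 * x[, 1] - 0.3) * 2.1 + 0.4)
  expect_equal(pred$.prob, oracle, tolerance = 1e-12)

  # a wider random net against an independently coded loop
  set.seed(5)
  W1 <- matrix(rnorm(12), 3, 4)
  b1 <- rnorm(3)
  w2 <- rnorm(3)
  b2 <- rnorm(1)
  model2 <- structure(
    list(
      W1 = W1, b1 = b1, w2 = w2, b2 = b2,
      feature_names = paste0("f", 1:4),
      config = net_config(hidden_units = 3),
      history = tibble::tibble(), n_epochs = 0L, converged = FALSE,
      final_loss = NA_real_
    ),
    class = "ms_net"
  )
  xs <- matrix(rnorm(20), 5, 4)
  got <- predict(model2, xs)$.prob
  for (i in 1:5) {
    hidden <- numeric(3)
    for (h in 1:3) hidden[h] <- tanh(sum(W1[h, ] * xs[i, ]) + b1[h])
    expect_equal(got[i], plogis(sum(hidden * w2) + b2), tolerance = 1e-12)
  }
})

test_that("probability 0.5 classifies as case and predictions stay in (0, 1)", {
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  model <- train_network(x, small_net(), targets = y)
  pred <- predict(model, x)
  # logistic output: probabilities bounded (saturation to the boundary at
  # double precision is possible once the net memorizes)
  expect_true(all(pred$.prob >= 0 & pred$.prob <= 1))
  expect_equal(pred$.label, as.integer(pred$.prob >= 0.5))

  # untrained model (max_epochs = 0) still yields valid probabilities
  raw <- train_network(x, net_config(hidden_units = 4, max_epochs = 0),
    targets = y)
  expect_equal(raw$n_epochs, 0L)
  p0 <- predict(raw, x)
  expect_true(all(p0$.prob > 0 & p0$.prob < 1))
})

test_that("SCG separates two well-separated Gaussian blobs", {
  set.seed(3)
  n <- 30
  x <- rbind(
    matrix(rnorm(2 * n, mean = -2, sd = 0.4), n, 2),
    matrix(rnorm(2 * n, mean = 2, sd = 0.4), n, 2)
  )
  y <- rep(c(0, 1), each = n)
  model <- train_network(x, net_config(hidden_units = 8, max_epochs = 300),
    targets = y)
  pred <- predict(model, x)
  expect_lte(sum(pred$.label != y), 1)
  # training loss history is non-increasing over accepted steps
  expect_true(all(diff(model$history$loss) <= 1e-12))
})

test_that("training is bit-reproducible from the seed", {
  set.seed(14)
  x <- matrix(runif(200), 50, 4)
  y <- rep(c(0, 1), 25)
  m1 <- train_network(x, small_net(seed = 7), targets = y)
  m2 <- train_network(x, small_net(seed = 7), targets = y)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$history, m2$history)
  m3 <- train_network(x, small_net(seed = 8), targets = y)
  expect_false(identical(m1$W1, m3$W1))
})

test_that("duplicating every sample leaves the loss surface and fit unchanged", {
  set.seed(15)
  x <- matrix(runif(120), 30, 4)
  y <- rep(c(0, 1), 15)

  # exact invariance of the loss and gradient under uniform reweighting
  theta <- rnorm(4 * 6 + 6 + 6 + 1, sd = 0.3)
  f1 <- methylentropy:::net_loss_grad(theta, x, y, 4, 6)
  f2 <- methylentropy:::net_loss_grad(theta, rbind(x, x), c(y, y), 4, 6)
  expect_equal(f1$loss, f2$loss, tolerance = 1e-12)
  expect_equal(f1$grad, f2$grad, tolerance = 1e-10)

  # short training runs stay on the same trajectory (long runs diverge only
  # through floating-point summation order)
  cfg <- net_config(hidden_units = 6, max_epochs = 20, seed = 2)
  m1 <- train_network(x, cfg, targets = y)
  m2 <- train_network(rbind(x, x), cfg, targets = c(y, y))
  grid <- matrix(runif(40), 10, 4)
  expect_equal(predict(m1, grid)$.prob, predict(m2, grid)$.prob,
    tolerance = 1e-6
  )
})

test_that("gradient-descent trainer satisfies the same contract", {
  set.seed(16)
  n <- 25
  x <- rbind(
    matrix(rnorm(2 * n, -1.5, 0.4), n, 2),
    matrix(rnorm(2 * n, 1.5, 0.4), n, 2)
  )
  y <- rep(c(0, 1), each = n)
  model <- train_network(
    x,
    net_config(hidden_units = 6, trainer = "gradient_descent",
      max_epochs = 500, patience = 25),
    targets = y
  )
  expect_lte(mean(predict(model, x)$.label != y), 0.1)
  expect_true(all(diff(model$history$loss) <= 1e-12))
})

test_that("models survive a JSON round-trip exactly", {
  set.seed(17)
  x <- matrix(runif(80), 20, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c(0, 1), 10)
  model <- train_network(x, small_net(seed = 3), targets = y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$W1, model$W1)
  expect_equal(back$w2, model$w2)
  expect_equal(back$feature_names, model$feature_names)
  expect_equal(predict(back, x)$.prob, predict(model, x)$.prob)
})

test_that("training rejects degenerate inputs", {
  x <- matrix(runif(20), 10, 2)
  expect_error(train_network(x, small_net(), targets = rep(1, 10)), "class")
  expect_error(train_network(x, small_net(), targets = rep(c(0.5, 1), 5)),
    "binary")
  x[1, 1] <- NA
  expect_error(train_network(x, small_net(), targets = rep(c(0, 1), 5)),
    "Non-finite")
})
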