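#' Neural-network configuration
#'
#' Configuration for the case/control classifier: a feedforward network with
#' one hidden layer of symmetric-sigmoid (tanh) units and a single
#' positive-sigmoid (logistic) output unit, all with biases, trained to
#' minimize mean squared error on the 0/1 target.
#'
#' @param hidden_units Number of hidden neurons (default 50).
#' @param trainer Training algorithm: `"scg"` (scaled conjugate gradient, the
#'   default) or `"gradient_descent"`. Both satisfy the same trained-model
#'   contract, so further trainers can be plugged in.
#' @param max_epochs Maximum training iterations; 0 returns the initial
#'   (random) weights untouched.
#' @param patience Early stopping: stop after this many consecutive
#'   iterations whose loss improvement is below `min_delta`.
#' @param min_delta Minimum loss improvement counted as progress.
#' @param learning_rate Initial step size for the gradient-descent trainer
#'   (ignored by SCG).
#' @param seed Seed for weight initialization; training is deterministic
#'   given the seed.
#' @return An object of class `net_config`.
#' @export
net_config <- function(hidden_units = 50, trainer = c("scg", "gradient_descent"),
                       max_epochs = 1000, patience = 6, min_delta = 1e-6,
                       learning_rate = 0.01, seed = 1) {
  trainer <- match.arg(trainer)
  if (hidden_units < 1) abort("`hidden_units` must be at least 1.")
  if (max_epochs < 0) abort("`max_epochs` must be non-negative.")
  structure(
    list(
      hidden_units = as.integer(hidden_units), trainer = trainer,
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      min_delta = min_delta, learning_rate = learning_rate,
      seed = as.integer(seed)
    ),
    class = "net_config"
  )
}

#' Split samples into training and testing sets
#'
#' Reproducible train/test split with the test set holding approximately
#' `test_fraction` of the samples (default 15%). With stratification (the
#' default) the split is drawn within each class, so the test-set class ratio
#' is within one sample of the cohort ratio; per-class test counts use
#' `round(test_fraction * n_class)`.
#'
#' @param samples Sample sheet tibble with `sample_id` and `status`.
#' @param test_fraction Fraction of samples held out for testing, in (0, 1).
#' @param seed Integer seed.
#' @param stratified Draw the split within each class?
#' @return A tibble of class `split_plan` with columns `sample_id`, `split`
#'   (`"train"`/`"test"`).
#' @export
make_split <- function(samples, test_fraction = 0.15, seed = 1,
                       stratified = TRUE) {
  check_sample_sheet(samples)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1).")
  }
  set.seed(seed)
  test_ids <- character()
  if (stratified) {
    for (cls in unique(samples$status)) {
      ids <- samples$sample_id[samples$status == cls]
      n_test <- round(test_fraction * length(ids))
      if (n_test >= length(ids)) {
        abort("`test_fraction` leaves no training samples in a class.")
      }
      test_ids <- c(test_ids, sample(ids, n_test))
    }
  } else {
    n_test <- round(test_fraction * nrow(samples))
    if (n_test >= nrow(samples) || n_test == 0) {
      abort("`test_fraction` gives a degenerate split.")
    }
    test_ids <- sample(samples$sample_id, n_test)
  }
  plan <- tibble(
    sample_id = samples$sample_id,
    split = ifelse(samples$sample_id %in% test_ids, "test", "train")
  )
  train_status <- samples$status[plan$split == "train"]
  if (length(unique(train_status)) < 2) {
    abort("Training set must contain both classes.")
  }
  if (!any(plan$split == "test")) abort("Test set is empty.")
  out <- structure(plan, class = c("split_plan", class(tibble())))
  attr(out, "test_fraction") <- test_fraction
  attr(out, "seed") <- seed
  attr(out, "stratified") <- stratified
  out
}

#' Ids on one side of a split plan
#'
#' @param split A `split_plan` tibble from [make_split()].
#' @param which `"train"` or `"test"`.
#' @return Character vector of sample ids.
#' @export
split_ids <- function(split, which = c("train", "test")) {
  which <- match.arg(which)
  split$sample_id[split$split == which]
}

#' Assemble the classifier's feature block
#'
#' Builds per-sample feature vectors: the selected CpGs' beta values (already
#' in \[0, 1\], passed through unchanged) followed by scaled age, sex and
#' smoking status. Age is min-max scaled using the training samples only;
#' test-set ages outside the training range are clipped to \[0, 1\].
#'
#' @param beta Beta tibble with no missing values.
#' @param selection A `cpg_selection` tibble or character vector of CpG ids.
#' @param samples Sample sheet tibble.
#' @param split A `split_plan` from [make_split()].
#' @return An object of class `feature_block`: list with `x_train`, `y_train`,
#'   `x_test`, `y_test`, `feature_names`, `age_range`, `train_ids`,
#'   `test_ids`.
#' @export
build_features <- function(beta, selection, samples, split) {
  check_beta_tbl(beta)
  check_sample_sheet(samples)
  ids <- if (is.data.frame(selection)) selection$cpg_id else as.character(selection)
  if (length(ids) == 0) abort("Selection is empty: no CpG features to build.")
  samples <- align_sheet(beta, samples)
  x <- t(beta_values(beta, cpgs = ids))
  if (anyNA(x) || any(!is.finite(x))) abort("Non-finite feature values.")

  train_ids <- split_ids(split, "train")
  test_ids <- split_ids(split, "test")
  meta <- samples[match(rownames(x), samples$sample_id), ]

  age_train <- meta$age[meta$sample_id %in% train_ids]
  rng <- range(age_train)
  if (rng[1] == rng[2]) {
    age_scaled <- rep(0, nrow(meta))
  } else {
    age_scaled <- (meta$age - rng[1]) / (rng[2] - rng[1])
    clipped <- age_scaled < 0 | age_scaled > 1
    if (any(clipped)) {
      inform(sprintf(
        "%d test-set age(s) outside the training range were clipped.",
        sum(clipped)
      ))
      age_scaled <- pmin(pmax(age_scaled, 0), 1)
    }
  }
  features <- cbind(x, age_scaled = age_scaled, sex = meta$sex, smoker = meta$smoker)
  y <- meta$status

  tr <- rownames(features) %in% train_ids
  te <- rownames(features) %in% test_ids
  structure(
    list(
      x_train = features[tr, , drop = FALSE], y_train = y[tr],
      x_test = features[te, , drop = FALSE], y_test = y[te],
      feature_names = colnames(features), age_range = rng,
      train_ids = rownames(features)[tr], test_ids = rownames(features)[te]
    ),
    class = "feature_block"
  )
}

# ---- network internals -------------------------------------------------------

net_init <- function(n_in, n_hidden, seed) {
  set.seed(seed)
  list(
    W1 = matrix(runif(n_hidden * n_in, -1, 1) / sqrt(n_in + 1), n_hidden, n_in),
    b1 = runif(n_hidden, -1, 1) / sqrt(n_in + 1),
    w2 = runif(n_hidden, -1, 1) / sqrt(n_hidden + 1),
    b2 = runif(1, -1, 1) / sqrt(n_hidden + 1)
  )
}

net_pack <- function(w) c(as.numeric(w$W1), w$b1, w$w2, w$b2)

net_unpack <- function(theta, n_in, n_hidden) {
  i <- n_hidden * n_in
  list(
    W1 = matrix(theta[seq_len(i)], n_hidden, n_in),
    b1 = theta[i + seq_len(n_hidden)],
    w2 = theta[i + n_hidden + seq_len(n_hidden)],
    b2 = theta[i + 2 * n_hidden + 1]
  )
}

# forward pass: logistic(tanh(X W1' + b1) w2 + b2)
net_forward <- function(w, x) {
  a1 <- tanh(sweep(x %*% t(w$W1), 2, w$b1, `+`))
  drop(plogis(a1 %*% w$w2 + w$b2))
}

net_loss_grad <- function(theta, x, y, n_in, n_hidden) {
  w <- net_unpack(theta, n_in, n_hidden)
  n <- nrow(x)
  z1 <- sweep(x %*% t(w$W1), 2, w$b1, `+`)
  a1 <- tanh(z1)
  z2 <- drop(a1 %*% w$w2 + w$b2)
  phat <- plogis(z2)
  err <- phat - y
  loss <- mean(err^2)
  d2 <- 2 * err * phat * (1 - phat) / n
  gw2 <- drop(crossprod(a1, d2))
  gb2 <- sum(d2)
  d1 <- (d2 %o% w$w2) * (1 - a1^2)
  gW1 <- crossprod(d1, x)
  gb1 <- colSums(d1)
  list(loss = loss, grad = c(as.numeric(gW1), gb1, gw2, gb2))
}

# Scaled conjugate gradient (Moller 1993) on a generic loss/gradient pair.
# fn(theta) must return list(loss, grad). Returns list(theta, history,
# epochs, converged).
scg_optimize <- function(theta, fn, max_epochs, patience, min_delta) {
  n_par <- length(theta)
  sigma0 <- 1e-5
  lambda <- 1e-6
  lambda_bar <- 0
  cur <- fn(theta)
  r <- -cur$grad
  p <- r
  success <- TRUE
  history <- numeric(0)
  stall <- 0L
  delta <- 0
  k <- 0L
  while (k < max_epochs) {
    k <- k + 1L
    p2 <- sum(p^2)
    if (p2 == 0) break
    if (success) {
      sigma_k <- sigma0 / sqrt(p2)
      g_shift <- fn(theta + sigma_k * p)$grad
      s <- (g_shift - cur$grad) / sigma_k
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    cand_theta <- theta + alpha * p
    cand <- fn(cand_theta)
    Delta <- 2 * delta * (cur$loss - cand$loss) / mu^2
    if (Delta >= 0) {
      improve <- cur$loss - cand$loss
      theta <- cand_theta
      r_new <- -cand$grad
      lambda_bar <- 0
      success <- TRUE
      if (k %% n_par == 0) {
        p <- r_new
      } else {
        beta_k <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta_k * p
      }
      r <- r_new
      cur <- cand
      if (Delta >= 0.75) lambda <- max(lambda / 4, 1e-15)
      # plateau detection counts accepted steps only: rejected steps are the
      # algorithm's normal trust-region calibration, not lack of progress
      stall <- if (improve < min_delta) stall + 1L else 0L
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (lambda > 1e15) break
    history <- c(history, cur$loss)
    if (stall >= patience) break
    if (sqrt(sum(r^2)) < 1e-10) break
  }
  list(theta = theta, history = history, epochs = k, converged = stall >= patience)
}

# adaptive-step gradient descent ("bold driver"): accept and grow the step on
# improvement, reject and shrink on failure
gd_optimize <- function(theta, fn, max_epochs, patience, min_delta, lr) {
  cur <- fn(theta)
  history <- numeric(0)
  stall <- 0L
  k <- 0L
  while (k < max_epochs) {
    k <- k + 1L
    cand_theta <- theta - lr * cur$grad
    cand <- fn(cand_theta)
    if (cand$loss <= cur$loss) {
      improve <- cur$loss - cand$loss
      theta <- cand_theta
      cur <- cand
      lr <- lr * 1.05
      stall <- if (improve < min_delta) stall + 1L else 0L
    } else {
      lr <- lr / 2
      stall <- stall + 1L
    }
    history <- c(history, cur$loss)
    if (stall >= patience || lr < 1e-14) break
  }
  list(theta = theta, history = history, epochs = k, converged = stall >= patience)
}

#' Train the case/control neural network
#'
#' Fits the one-hidden-layer network (tanh hidden units, logistic output,
#' biases throughout) by full-batch minimization of the mean squared error on
#' the 0/1 target. The default trainer is scaled conjugate gradient (Moller's
#' algorithm); training stops at `max_epochs`, on a gradient-norm floor, or
#' when the loss plateaus for `patience` iterations.
#'
#' @param features A `feature_block` from [build_features()] (its training
#'   half is used), or a numeric matrix of features (samples x variables).
#' @param config A [net_config()].
#' @param targets 0/1 vector; required when `features` is a bare matrix.
#' @return An object of class `ms_net`: weights (`W1`, `b1`, `w2`, `b2`),
#'   `feature_names`, `config`, `history` (per-iteration training loss),
#'   `n_epochs`, `converged`, `final_loss`.
#' @export
train_network <- function(features, config = net_config(), targets = NULL) {
  if (inherits(features, "feature_block")) {
    x <- features$x_train
    y <- features$y_train
  } else {
    x <- as.matrix(features)
    y <- targets
  }
  if (is.null(y)) abort("`targets` required when `features` is a matrix.")
  if (!all(y %in% c(0, 1))) abort("Targets must be binary {0, 1}.")
  if (length(unique(y)) < 2) abort("Need at least one sample of each class.")
  if (anyNA(x) || any(!is.finite(x))) abort("Non-finite feature values.")
  if (nrow(x) != length(y)) abort("Feature rows must match target length.")

  n_in <- ncol(x)
  nh <- config$hidden_units
  w0 <- net_init(n_in, nh, config$seed)
  theta <- net_pack(w0)
  fn <- function(th) net_loss_grad(th, x, y, n_in, nh)

  if (config$max_epochs == 0) {
    fit <- list(theta = theta, history = numeric(0), epochs = 0L, converged = FALSE)
  } else if (config$trainer == "scg") {
    fit <- scg_optimize(theta, fn, config$max_epochs, config$patience, config$min_delta)
  } else {
    fit <- gd_optimize(
      theta, fn, config$max_epochs, config$patience,
      config$min_delta, config$learning_rate
    )
  }
  w <- net_unpack(fit$theta, n_in, nh)
  structure(
    list(
      W1 = w$W1, b1 = w$b1, w2 = w$w2, b2 = w$b2,
      feature_names = colnames(x), config = config,
      history = tibble(epoch = seq_along(fit$history), loss = fit$history),
      n_epochs = fit$epochs, converged = fit$converged,
      final_loss = if (length(fit$history)) fit$history[length(fit$history)] else fn(theta)$loss
    ),
    class = "ms_net"
  )
}

#' Predict case/control status
#'
#' Forward pass of a trained network. The predicted probability is the output
#' unit's logistic activation; the label is 1 (case) when the probability is
#' at least 0.5 (ties classify as case, a documented rule).
#'
#' @param object An `ms_net` from [train_network()].
#' @param newdata A numeric feature matrix (samples x variables) or a
#'   `feature_block` (its test half is used).
#' @param ... Unused.
#' @return A tibble with columns `.prob` and `.label`.
#' @export
predict.ms_net <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_block")) newdata <- newdata$x_test
  x <- as.matrix(newdata)
  if (ncol(x) != ncol(object$W1)) {
    abort(sprintf(
      "Feature dimension mismatch: model expects %d, got %d.",
      ncol(object$W1), ncol(x)
    ))
  }
  prob <- net_forward(object, x)
  tibble(.prob = prob, .label = as.integer(prob >= 0.5))
}

#' @export
print.ms_net <- function(x, ...) {
  cat(sprintf(
    "<ms_net> %d -> %d tanh -> 1 logistic; trainer %s, %d epochs, final MSE %.6g\n",
    ncol(x$W1), length(x$b1), x$config$trainer, x$n_epochs, x$final_loss
  ))
  invisible(x)
}

#' Serialize a trained network to JSON
#'
#' Writes the architecture, weight arrays, feature names and training summary
#' so a model can be stored and reloaded exactly.
#'
#' @param model An `ms_net`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    hidden_units = length(model$b1),
    W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    feature_names = model$feature_names,
    trainer = model$config$trainer, seed = model$config$seed,
    n_epochs = model$n_epochs, final_loss = model$final_loss
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network serialized by [write_model()]
#'
#' @param path Path to the model JSON.
#' @return An `ms_net` (history is not stored on disk and comes back empty).
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      W1 = matrix(unlist(p$W1), nrow = p$hidden_units),
      b1 = as.numeric(p$b1), w2 = as.numeric(p$w2), b2 = as.numeric(p$b2),
      feature_names = p$feature_names,
      config = net_config(
        hidden_units = p$hidden_units, trainer = p$trainer, seed = p$seed
      ),
      history = tibble(epoch = integer(0), loss = numeric(0)),
      n_epochs = p$n_epochs, converged = NA, final_loss = p$final_loss
    ),
    class = "ms_net"
  )
}
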