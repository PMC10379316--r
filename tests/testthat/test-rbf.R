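test_that("hidden activation follows the half-activation-at-spread convention", {
  net <- rbf_network(centers = matrix(c(0, 0), nrow = 1), spread = 0.7,
                     output_weights = matrix(1, 1, 1), output_biases = 0)
  expect_equal(hidden_activations(net, c(0, 0)), 1)
  # at distance exactly one spread, activation is exp(-0.8326^2) ~ 0.5
  act <- hidden_activations(net, c(0.7, 0))
  expect_equal(act, exp(-0.8326^2))
  expect_lt(abs(act - 0.5), 1e-4)
  # very wide kernels saturate toward 1
  wide <- rbf_network(matrix(c(0, 0), 1), spread = 1e6,
                      output_weights = matrix(1, 1, 1), output_biases = 0)
  expect_gt(hidden_activations(wide, c(3, -2)), 1 - 1e-9)
  expect_error(hidden_activations(net, c(1, 2, 3)), "dimension error")
})

test_that("prediction matches an independent re-evaluation of the formulas", {
  fit <- random_trained_net()
  net <- fit$network
  set.seed(31)
  probe <- cbind(runif(40, -1.5, 1.5), runif(40, -1.5, 1.5))
  expect_lt(max(abs(predict(net, probe) - brute_force_predict(net, probe))),
            1e-10)
})

test_that("degenerate networks predict as their structure dictates", {
  bias_only <- rbf_network(matrix(numeric(0), 0, 2), spread = 1,
                           output_weights = matrix(0, 2, 0),
                           output_biases = c(3.5, -1))
  pred <- predict(bias_only, cbind(runif(5), runif(5)))
  expect_equal(unname(pred), cbind(rep(3.5, 5), rep(-1, 5)))

  one <- rbf_network(matrix(c(0.2, -0.3), 1), spread = 1,
                     output_weights = matrix(1, 1, 1), output_biases = 0)
  expect_equal(as.numeric(predict(one, matrix(c(0.2, -0.3), 1))), 1)
})

test_that("output-weight solving is exact least squares and rank tolerant", {
  set.seed(5)
  X <- cbind(runif(9, -1, 1), runif(9, -1, 1))
  Y <- cbind(X[, 1]^2, X[, 1] - X[, 2])
  # interpolation regime: Gaussian kernel on distinct points is nonsingular
  sol <- solve_output_weights(X, spread = 0.8, X, Y)
  expect_lt(sol$mse, 1e-8)

  const <- matrix(4.2, 9, 1)
  solc <- solve_output_weights(X[1:3, , drop = FALSE], 1, X, const)
  expect_equal(as.numeric(solc$output_biases), 4.2, tolerance = 1e-8)
  expect_lt(max(abs(solc$output_weights)), 1e-6)

  # duplicated center: rank-deficient but the optimum residual is unchanged
  dup <- rbind(X[1:4, ], X[1, ])
  sol4 <- solve_output_weights(X[1:4, ], 0.8, X, Y)
  sol5 <- solve_output_weights(dup, 0.8, X, Y)
  expect_equal(sol5$mse, sol4$mse, tolerance = 1e-10)
})

test_that("greedy incremental training is monotone, exact at saturation, deterministic", {
  x1 <- matrix(c(0.3, -0.2), 1)
  y1 <- matrix(c(1, 2), 1)
  fit1 <- train_incremental(x1, y1, spread = 1, max_neurons = 1)
  expect_lt(min(fit1$trace$mse), 1e-20)

  set.seed(13)
  for (rep in 1:5) {
    X <- cbind(runif(8, -1, 1), runif(8, -1, 1))
    Y <- cbind(sin(2 * X[, 1]), X[, 2]^3)
    fit <- train_incremental(X, Y, spread = 0.9, max_neurons = 8)
    expect_true(all(diff(fit$trace$mse) <= 1e-12))
    expect_lt(fit$trace$mse[nrow(fit$trace)], 1e-8)  # full interpolation
  }

  X5 <- cbind(seq(-1, 1, length.out = 5), c(0.1, -0.4, 0.2, 0.9, -0.8))
  Y5 <- cbind(X5[, 1] + X5[, 2])
  fit5 <- train_incremental(X5, Y5, spread = 1.1, max_neurons = 5)
  expect_lt(fit5$trace$mse[6], 1e-8)

  expect_error(train_incremental(X5, Y5, spread = 1, max_neurons = 6),
               "config error")
})

test_that("training is invariant to row permutation on generic data", {
  set.seed(77)
  X <- cbind(runif(10, -1, 1), runif(10, -1, 1))
  Y <- cbind(exp(X[, 1]), X[, 1] * X[, 2])
  fit_a <- train_incremental(X, Y, spread = 1, max_neurons = 4)
  perm <- sample(10)
  fit_b <- train_incremental(X[perm, ], Y[perm, , drop = FALSE],
                             spread = 1, max_neurons = 4)
  # same centers as a set, same predictions
  ka <- fit_a$network$centers[order(fit_a$network$centers[, 1]), ]
  kb <- fit_b$network$centers[order(fit_b$network$centers[, 1]), ]
  expect_equal(ka, kb, tolerance = 1e-12)
  probe <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  expect_equal(predict(fit_a$network, probe), predict(fit_b$network, probe),
               tolerance = 1e-8)
})

test_that("splitting is disjoint, exhaustive, rounded and seeded", {
  s <- split_dataset(20, c(0.70, 0.15, 0.15), seed = 3)
  expect_equal(lengths(s), c(train = 14, assess = 3, test = 3))
  all_idx <- sort(c(s$train, s$assess, s$test))
  expect_equal(all_idx, 1:20)
  expect_identical(split_dataset(20, seed = 3), s)
  expect_false(identical(split_dataset(20, seed = 4), s))
  expect_error(split_dataset(2, seed = 1), "insufficient-data")
})

test_that("hyperparameter scan covers the grid and selects the argmin", {
  ds <- simulate_dataset(noise_free_config(6))
  design <- assemble_design(delta_transform(ds, "require_t0"))
  split <- split_dataset(nrow(design$X), seed = 6)
  ni <- fit_minmax(design$X[split$train, ])
  no <- fit_minmax(design$Y[split$train, ])
  Xn <- normalize_minmax(ni, design$X)
  Yn <- normalize_minmax(no, design$Y)

  scan <- scan_hyperparameters(Xn, Yn, neuron_counts = seq(0, 28, 2),
                               spreads = c(0.05, 0.10, 0.50, 1.00, 1.50,
                                           2.00, 2.50, 3.00),
                               split = split)
  expect_equal(nrow(scan$table), 15 * 8)
  expect_true(all(scan$table$effective_neurons <=
                  sum(!duplicated(Xn[split$train, ]))))
  # selection is the argmin of assessment MSE
  expect_equal(scan$best$mse_assess, min(scan$table$mse_assess))
  # training MSE is non-increasing in neuron count at fixed spread (up to
  # round-off in the ill-conditioned near-interpolation regime)
  for (sp in unique(scan$table$spread)) {
    sub <- scan$table[scan$table$spread == sp, ]
    sub <- sub[order(sub$neurons), ]
    expect_true(all(diff(sub$mse_train) <= 1e-10))
  }

  single <- scan_hyperparameters(Xn, Yn, neuron_counts = 4, spreads = 1,
                                 split = split)
  expect_equal(single$best$neurons, 4)
  expect_equal(single$best$spread, 1)
})

test_that("model save/load round trip preserves predictions exactly", {
  fit <- random_trained_net()
  net <- fit$network
  net$metadata <- list(note = "round-trip check")
  path <- withr::local_tempfile(fileext = ".json")
  save_rbf_model(net, path)
  back <- load_rbf_model(path)
  probe <- cbind(runif(15, -1, 1), runif(15, -1, 1))
  expect_equal(predict(back, probe), predict(net, probe), tolerance = 1e-15)
  expect_identical(back$metadata$format_version, "rbf-model-1")

  # a file missing a required field is rejected with the field name
  obj <- jsonlite::read_json(path)
  obj$spread <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_rbf_model(path2), "spread")
})
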