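# Shared builders for the test suite.

# A minimal valid measurement table.
tiny_measurements <- function() {
  data.frame(
    temperature_K = c(253, 253, 253, 253),
    time_weeks = c(0, 1, 0, 1),
    indicator = c("FFA", "FFA", "SSP", "SSP"),
    replicate = 1L,
    value = c(3.08, 5.34, 69.74, 59.02),
    stringsAsFactors = FALSE
  )
}

# Noise-free copy of the calibrated carp configuration.
noise_free_config <- function(seed = 1, time_grid = NULL) {
  cfg <- default_carp_config(seed)
  cfg$kinetics <- lapply(cfg$kinetics, function(p) {
    p$noise_sd[] <- 0
    p
  })
  if (!is.null(time_grid)) cfg$time_grid <- time_grid
  cfg
}

# Independent re-evaluation of the network formulas: explicit per-neuron loop
# over Gaussian activations and the linear output sum, sharing no code with
# predict().
brute_force_predict <- function(net, X) {
  X <- as.matrix(X)
  out <- matrix(NA_real_, nrow(X), length(net$output_biases))
  for (i in seq_len(nrow(X))) {
    n_hidden <- nrow(net$centers)
    Yj <- numeric(n_hidden)
    for (j in seq_len(n_hidden)) {
      dist2 <- sum((net$centers[j, ] - X[i, ])^2)
      Yj[j] <- exp(-(net$bandwidth_constant / net$spread)^2 * dist2)
    }
    for (k in seq_along(net$output_biases)) {
      acc <- net$output_biases[k]
      for (j in seq_len(n_hidden)) {
        acc <- acc + net$output_weights[k, j] * Yj[j]
      }
      out[i, k] <- acc
    }
  }
  out
}

# A small trained network on random smooth data, for round-trip and oracle
# checks.
random_trained_net <- function(seed = 7, n = 12, neurons = 5, spread = 1.2) {
  set.seed(seed)
  X <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  Y <- cbind(sin(X[, 1]) + X[, 2], X[, 1] * X[, 2], cos(X[, 2]))
  colnames(X) <- c("a", "b")
  colnames(Y) <- c("y1", "y2", "y3")
  train_incremental(X, Y, spread = spread, max_neurons = neurons)
}
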