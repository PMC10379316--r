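# Gaussian radial basis function network with greedy incremental center
# selection and exact least-squares output weights.
#
# Hidden unit j has activation Y_j = exp(-(b * ||x - c_j||)^2) with bandwidth
# b = 0.8326 / spread, so that activation is exactly one-half when the input
# lies one spread away from the center (exp(-0.8326^2) = 0.4999...). The
# output layer is linear with bias: Y_k = sum_j w_kj Y_j + w_k0.

RBF_BANDWIDTH_CONSTANT <- 0.8326

# Hidden-activation matrix: rows of X against rows of centers.
.rbf_phi <- function(X, centers, spread) {
  X <- as.matrix(X)
  centers <- as.matrix(centers)
  stopifnot(ncol(X) == ncol(centers), spread > 0)
  b2 <- (RBF_BANDWIDTH_CONSTANT / spread)^2
  # squared Euclidean distances via the expansion ||x||^2 - 2 x.c + ||c||^2
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) -
    2 * tcrossprod(X, centers)
  exp(-b2 * pmax(d2, 0))
}

# Minimum-norm least squares: argmin ||A B - Y||_F, rank-tolerant via SVD.
.lstsq_minnorm <- function(A, Y) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) {
    return(matrix(0, ncol(A), ncol(Y)))
  }
  sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], Y) / sv$d[pos])
}

#' Construct an RBF network object
#'
#' @param centers Matrix of hidden-unit centers (rows) in the normalized
#'   input space; zero rows for a bias-only network.
#' @param spread Positive bandwidth hyperparameter: activation is 0.5 at
#'   distance = spread from a center.
#' @param output_weights Outputs x hidden matrix of linear output weights.
#' @param output_biases Numeric vector of output biases.
#' @param normalization Optional list with elements \code{input} and
#'   \code{output}, each a \code{minmax_params}, enabling prediction on the
#'   original scale.
#' @param input_names,output_names Variable names.
#' @param metadata Free-form provenance list.
#' @return Object of class \code{rbf_network}.
#' @export
rbf_network <- function(centers, spread, output_weights, output_biases,
                        normalization = NULL,
                        input_names = NULL, output_names = NULL,
                        metadata = list()) {
  centers <- as.matrix(centers)
  output_weights <- as.matrix(output_weights)
  stopifnot(spread > 0,
            ncol(output_weights) == nrow(centers),
            length(output_biases) == nrow(output_weights))
  structure(list(centers = centers, spread = spread,
                 bandwidth_constant = RBF_BANDWIDTH_CONSTANT,
                 output_weights = output_weights,
                 output_biases = as.numeric(output_biases),
                 normalization = normalization,
                 input_names = input_names, output_names = output_names,
                 metadata = metadata),
            class = "rbf_network")
}

#' @export
print.rbf_network <- function(x, ...) {
  cat("<rbf_network> ", nrow(x$centers), " hidden neurons, spread ", x$spread,
      ", ", nrow(x$output_weights), " outputs\n", sep = "")
  invisible(x)
}

#' Hidden-layer activations for one input point
#'
#' @param net An \code{rbf_network}.
#' @param x Numeric vector on the normalized input scale, of the network's
#'   input arity.
#' @return Numeric vector of hidden activations in (0, 1], one per neuron.
#' @export
hidden_activations <- function(net, x) {
  stopifnot(inherits(net, "rbf_network"))
  if (length(x) != ncol(net$centers)) {
    stop("dimension error: input has length ", length(x),
         ", network expects ", ncol(net$centers), call. = FALSE)
  }
  if (nrow(net$centers) == 0) return(numeric(0))
  drop(.rbf_phi(matrix(x, nrow = 1), net$centers, net$spread))
}

#' Predict with an RBF network
#'
#' @param object An \code{rbf_network}.
#' @param X Input matrix (one row per point). On scale \code{"normalized"}
#'   the rows are already in the [-1, 1] model space; on \code{"original"}
#'   they are raw (temperature, time) values which are normalized with the
#'   stored parameters, and the outputs are mapped back to raw delta units.
#' @param scale \code{"normalized"} or \code{"original"}.
#' @param ... Unused.
#' @return Matrix of predictions (rows = input points, columns = outputs).
#' @export
predict.rbf_network <- function(object, X, scale = c("normalized", "original"),
                                ...) {
  scale <- match.arg(scale)
  if (is.null(object$output_weights)) {
    stop("state error: network has no trained output weights", call. = FALSE)
  }
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != ncol(object$centers) && nrow(object$centers) > 0) {
    stop("dimension error: input arity mismatch", call. = FALSE)
  }
  if (scale == "original") {
    if (is.null(object$normalization)) {
      stop("state error: network carries no normalization parameters",
           call. = FALSE)
    }
    X <- normalize_minmax(object$normalization$input, X)
  }
  n_out <- length(object$output_biases)
  if (nrow(object$centers) == 0) {
    pred <- matrix(rep(object$output_biases, each = nrow(X)), nrow = nrow(X))
  } else {
    phi <- .rbf_phi(X, object$centers, object$spread)
    pred <- phi %*% t(object$output_weights) +
      matrix(rep(object$output_biases, each = nrow(X)), nrow = nrow(X))
  }
  colnames(pred) <- object$output_names
  if (scale == "original") {
    pred <- denormalize_minmax(object$normalization$output, pred)
    colnames(pred) <- object$output_names
  }
  pred
}

#' Exact least-squares output weights for fixed centers
#'
#' Minimizes the Frobenius residual of the linear output layer (with bias)
#' over the training rows; rank deficiency (e.g. duplicated centers) is
#' handled by the minimum-norm solution.
#'
#' @param centers Center matrix (possibly zero rows).
#' @param spread Bandwidth hyperparameter.
#' @param X Training inputs (normalized), one row per point.
#' @param Y Training targets (normalized), one row per point.
#' @return List with \code{output_weights} (outputs x hidden),
#'   \code{output_biases}, and \code{mse} (mean squared residual over all
#'   rows and outputs).
#' @export
solve_output_weights <- function(centers, spread, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  centers <- as.matrix(centers)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1)
  if (nrow(centers) == 0) {
    biases <- colMeans(Y)
    resid <- sweep(Y, 2, biases)
    return(list(output_weights = matrix(0, ncol(Y), 0),
                output_biases = as.numeric(biases),
                mse = mean(resid^2)))
  }
  phi <- .rbf_phi(X, centers, spread)
  A <- cbind(1, phi)
  B <- .lstsq_minnorm(A, Y)
  resid <- Y - A %*% B
  list(output_weights = t(B[-1, , drop = FALSE]),
       output_biases = as.numeric(B[1, ]),
       mse = mean(resid^2))
}

#' Greedy incremental RBF training
#'
#' Starts from a bias-only network (zero hidden neurons) and repeatedly adds
#' as the next center the training input, not already a center, that gives
#' the lowest training MSE after re-solving the output weights by least
#' squares. Stops at \code{max_neurons} or once the MSE goal is reached.
#' Ties are broken by lowest row index, so training is fully deterministic.
#'
#' @param X,Y Normalized training inputs and targets (equal row counts).
#' @param spread Bandwidth hyperparameter.
#' @param max_neurons Maximum hidden-layer size; must not exceed the number
#'   of distinct training inputs.
#' @param mse_goal Stop early once training MSE is at or below this value.
#' @param normalization Optional normalization parameters to embed in the
#'   returned network.
#' @param output_names,metadata Passed to the network object.
#' @return List with \code{network} (the trained \code{rbf_network}),
#'   \code{trace} (data frame of \code{neurons}, \code{mse} after each
#'   addition, starting at 0 neurons) and \code{center_order} (row indices of
#'   the chosen centers, in selection order).
#' @export
train_incremental <- function(X, Y, spread, max_neurons, mse_goal = 0,
                              normalization = NULL, output_names = NULL,
                              metadata = list()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1, max_neurons >= 0, spread > 0)
  n <- nrow(X)
  n_distinct <- sum(!duplicated(X))
  if (max_neurons > n_distinct) {
    stop("config error: max_neurons (", max_neurons,
         ") exceeds distinct training inputs (", n_distinct, ")",
         call. = FALSE)
  }
  phi_all <- .rbf_phi(X, X, spread)  # column j = activations of center at row j

  fit_for <- function(chosen) {
    if (length(chosen) == 0) {
      biases <- colMeans(Y)
      resid <- sweep(Y, 2, biases)
      return(list(B = matrix(biases, nrow = 1), mse = mean(resid^2)))
    }
    A <- cbind(1, phi_all[, chosen, drop = FALSE])
    B <- .lstsq_minnorm(A, Y)
    list(B = B, mse = mean((Y - A %*% B)^2))
  }

  chosen <- integer(0)
  fit <- fit_for(chosen)
  trace <- data.frame(neurons = 0L, mse = fit$mse)
  # candidate pool: lowest-index representative of each distinct input row
  pool <- which(!duplicated(X))

  while (length(chosen) < max_neurons && fit$mse > mse_goal) {
    candidates <- setdiff(pool, chosen)
    best_mse <- Inf; best_cand <- NA_integer_; best_fit <- NULL
    for (cand in candidates) {  # ascending index => ties keep lowest index
      f <- fit_for(c(chosen, cand))
      if (f$mse < best_mse - 0) {
        best_mse <- f$mse; best_cand <- cand; best_fit <- f
      }
    }
    chosen <- c(chosen, best_cand)
    fit <- best_fit
    trace <- rbind(trace, data.frame(neurons = length(chosen), mse = fit$mse))
  }

  B <- fit$B
  net <- rbf_network(
    centers = X[chosen, , drop = FALSE],
    spread = spread,
    output_weights = if (length(chosen) == 0) matrix(0, ncol(Y), 0)
                     else t(B[-1, , drop = FALSE]),
    output_biases = as.numeric(B[1, ]),
    normalization = normalization,
    input_names = colnames(X), output_names = output_names %||% colnames(Y),
    metadata = metadata
  )
  list(network = net, trace = trace, center_order = chosen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random train/assessment/test split
#'
#' @param n_rows Number of design rows (>= 3).
#' @param fractions Length-3 positive fractions summing to 1; the training
#'   and assessment sizes are rounded, the test set takes the remainder.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List of disjoint, exhaustive index vectors \code{train},
#'   \code{assess}, \code{test}.
#' @export
split_dataset <- function(n_rows, fractions = c(0.70, 0.15, 0.15), seed) {
  if (n_rows < 3) {
    stop("insufficient-data error: need at least 3 rows, got ", n_rows,
         call. = FALSE)
  }
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9)
  n_train <- round(fractions[1] * n_rows)
  n_assess <- round(fractions[2] * n_rows)
  n_test <- n_rows - n_train - n_assess
  stopifnot(n_train >= 1, n_assess >= 0, n_test >= 0)
  perm <- .with_seed(seed, sample.int(n_rows))
  list(train = sort(perm[seq_len(n_train)]),
       assess = sort(perm[n_train + seq_len(n_assess)]),
       test = sort(perm[n_train + n_assess + seq_len(n_test)]))
}

#' Hyperparameter scan over hidden-layer size and spread
#'
#' For each spread, runs one greedy incremental training to the largest
#' requested neuron count on the training split (the greedy path is nested,
#' so every smaller count is an exact prefix), re-solves the output weights
#' at each requested count, and records the training-split and
#' assessment-split MSE (normalized scale, averaged over all outputs).
#' Requested counts above the number of distinct training inputs are clamped
#' to it (both counts are recorded). The selected pair minimizes the
#' assessment MSE; ties prefer fewer neurons, then smaller spread.
#'
#' @param X,Y Normalized design matrices (all rows).
#' @param neuron_counts Integer vector of hidden-layer sizes to scan.
#' @param spreads Numeric vector of spreads to scan.
#' @param split List of index vectors \code{train}/\code{assess}/\code{test}
#'   (as from \code{split_dataset}); if \code{NULL}, computed from
#'   \code{split_fractions} and \code{seed}.
#' @param split_fractions,seed Used only when \code{split} is \code{NULL}.
#' @return List of class \code{rbf_scan}: \code{table} (data frame with
#'   columns \code{neurons}, \code{effective_neurons}, \code{spread},
#'   \code{mse_train}, \code{mse_assess}), \code{best} (selected
#'   \code{neurons}, \code{effective_neurons}, \code{spread},
#'   \code{mse_assess}), and the \code{split} used.
#' @export
scan_hyperparameters <- function(X, Y, neuron_counts, spreads, split = NULL,
                                 split_fractions = c(0.70, 0.15, 0.15),
                                 seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(length(neuron_counts) >= 1, length(spreads) >= 1,
            all(neuron_counts >= 0), all(spreads > 0))
  if (is.null(split)) {
    stopifnot(!is.null(seed))
    split <- split_dataset(nrow(X), split_fractions, seed)
  }
  Xtr <- X[split$train, , drop = FALSE]; Ytr <- Y[split$train, , drop = FALSE]
  Xas <- X[split$assess, , drop = FALSE]; Yas <- Y[split$assess, , drop = FALSE]
  n_distinct <- sum(!duplicated(Xtr))
  counts <- sort(unique(as.integer(neuron_counts)))
  eff <- pmin(counts, n_distinct)

  rows <- list()
  for (sp in sort(spreads)) {
    path <- train_incremental(Xtr, Ytr, spread = sp,
                              max_neurons = max(eff), mse_goal = 0)
    for (i in seq_along(counts)) {
      m <- eff[i]
      chosen <- path$center_order[seq_len(m)]
      sol <- solve_output_weights(Xtr[chosen, , drop = FALSE], sp, Xtr, Ytr)
      net <- rbf_network(Xtr[chosen, , drop = FALSE], sp,
                         sol$output_weights, sol$output_biases)
      pred_as <- predict(net, Xas, scale = "normalized")
      rows[[length(rows) + 1]] <- data.frame(
        neurons = counts[i], effective_neurons = m, spread = sp,
        mse_train = sol$mse, mse_assess = mean((Yas - pred_as)^2))
    }
  }
  table <- do.call(rbind, rows)
  ord <- order(table$mse_assess, table$neurons, table$spread)
  best <- table[ord[1], ]
  structure(list(table = table,
                 best = list(neurons = best$neurons,
                             effective_neurons = best$effective_neurons,
                             spread = best$spread,
                             mse_assess = best$mse_assess),
                 split = split),
            class = "rbf_scan")
}

#' @export
print.rbf_scan <- function(x, ...) {
  cat("<rbf_scan> ", nrow(x$table), " grid points; best: ",
      x$best$neurons, " neurons (effective ", x$best$effective_neurons,
      "), spread ", x$best$spread,
      ", assessment MSE ", format(x$best$mse_assess, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Save / load an RBF network as JSON
#'
#' Lossless, human-readable round trip of centers, spread, output weights and
#' biases, normalization parameters and metadata, with a format version tag.
#'
#' @param net An \code{rbf_network}.
#' @param path File path.
#' @return \code{save_rbf_model}: invisibly, \code{path};
#'   \code{load_rbf_model}: the restored \code{rbf_network}.
#' @export
save_rbf_model <- function(net, path) {
  stopifnot(inherits(net, "rbf_network"))
  norm <- if (is.null(net$normalization)) NULL else {
    lapply(net$normalization, function(p) {
      list(variables = names(p$min), min = unname(p$min), max = unname(p$max))
    })
  }
  obj <- list(
    version = "rbf-model-1",
    spread = net$spread,
    bandwidth_constant = net$bandwidth_constant,
    input_names = net$input_names,
    output_names = net$output_names,
    centers = net$centers,
    output_weights = net$output_weights,
    output_biases = net$output_biases,
    normalization = norm,
    metadata = net$metadata[setdiff(names(net$metadata), "config")]
  )
  # digits = I(17): serialize doubles at full precision so the round trip is
  # bit exact
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_rbf_model
#' @export
load_rbf_model <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("parse error: ", conditionMessage(e), call. = FALSE)
                  })
  for (field in c("version", "spread", "centers", "output_weights",
                  "output_biases")) {
    if (is.null(obj[[field]])) {
      stop("parse error: missing field '", field, "'", call. = FALSE)
    }
  }
  centers <- obj$centers
  if (is.null(dim(centers))) {
    centers <- matrix(as.numeric(centers),
                      nrow = length(centers) %/% max(1, length(obj$input_names)),
                      byrow = TRUE)
  }
  ow <- obj$output_weights
  if (is.null(dim(ow))) {
    ow <- matrix(as.numeric(ow), nrow = length(obj$output_biases))
  }
  if (length(centers) == 0) {
    centers <- matrix(numeric(0), nrow = 0, ncol = length(obj$input_names))
    ow <- matrix(0, nrow = length(obj$output_biases), ncol = 0)
  }
  colnames(centers) <- obj$input_names
  norm <- if (is.null(obj$normalization)) NULL else {
    lapply(obj$normalization, function(p) {
      structure(list(min = stats::setNames(as.numeric(p$min), p$variables),
                     max = stats::setNames(as.numeric(p$max), p$variables)),
                class = "minmax_params")
    })
  }
  net <- rbf_network(centers = centers, spread = obj$spread,
                     output_weights = ow, output_biases = obj$output_biases,
                     normalization = norm,
                     input_names = obj$input_names,
                     output_names = obj$output_names,
                     metadata = as.list(obj$metadata))
  net$metadata$format_version <- obj$version
  net
}
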