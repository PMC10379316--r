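# Delta-from-baseline transform and min-max scaling. The network predicts the
# change of each indicator from its own time-0 value at the same storage
# temperature, delta C = C_t - C_0, computed on replicate means.

#' Delta-from-baseline transform
#'
#' For every (temperature, indicator), subtracts the baseline replicate-mean
#' value from the replicate mean at each time. Under \code{"require_t0"} the
#' baseline is the week-0 record (an error if absent); under
#' \code{"first_observed"} it is the earliest available week for that
#' (temperature, indicator).
#'
#' @param dataset A \code{quality_dataset}.
#' @param baseline_policy \code{"require_t0"} or \code{"first_observed"}.
#' @return Data frame of class \code{delta_dataset} with columns
#'   \code{temperature_K}, \code{time_weeks}, \code{indicator}, \code{delta},
#'   and attributes \code{baselines} (the per-(temperature, indicator)
#'   baseline value and week) and \code{baseline_policy}.
#' @export
delta_transform <- function(dataset,
                            baseline_policy = c("require_t0", "first_observed")) {
  baseline_policy <- match.arg(baseline_policy)
  means <- replicate_means(dataset)
  if (nrow(means) == 0) stop("empty dataset", call. = FALSE)

  key <- interaction(means$temperature_K, means$indicator, drop = TRUE)
  base_rows <- lapply(split(seq_len(nrow(means)), key), function(idx) {
    sub <- means[idx, , drop = FALSE]
    if (baseline_policy == "require_t0") {
      hit <- which(sub$time_weeks == 0)
      if (length(hit) == 0) {
        stop("baseline-missing error: no week-0 record for (",
             sub$temperature_K[1], " K, ", sub$indicator[1], ")",
             call. = FALSE)
      }
    } else {
      hit <- which.min(sub$time_weeks)
    }
    sub[hit[1], c("temperature_K", "indicator", "time_weeks", "value")]
  })
  baselines <- do.call(rbind, base_rows)
  names(baselines)[names(baselines) == "time_weeks"] <- "baseline_week"
  names(baselines)[names(baselines) == "value"] <- "baseline_value"
  rownames(baselines) <- NULL

  merged <- merge(means, baselines, by = c("temperature_K", "indicator"))
  out <- data.frame(temperature_K = merged$temperature_K,
                    time_weeks = merged$time_weeks,
                    indicator = merged$indicator,
                    delta = merged$value - merged$baseline_value,
                    stringsAsFactors = FALSE)
  out <- out[order(out$temperature_K, out$time_weeks, out$indicator), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, baselines = baselines, baseline_policy = baseline_policy,
            class = c("delta_dataset", "data.frame"))
}

#' Assemble network design matrices from a delta dataset
#'
#' One row per (temperature, time) that has deltas for all five indicators;
#' incomplete rows are dropped and reported. Inputs are (temperature, time);
#' outputs are the five indicator deltas in canonical order.
#'
#' @param delta A \code{delta_dataset}.
#' @return List with \code{X} (n x 2 matrix: temperature_K, time_weeks),
#'   \code{Y} (n x 5 matrix of deltas), \code{rows} (data frame of the
#'   retained (temperature, time) pairs) and \code{dropped} (data frame of
#'   dropped pairs with their missing indicators).
#' @export
assemble_design <- function(delta) {
  inds <- indicator_names()
  wide <- stats::reshape(as.data.frame(delta), direction = "wide",
                         idvar = c("temperature_K", "time_weeks"),
                         timevar = "indicator", v.names = "delta")
  delta_cols <- paste0("delta.", inds)
  for (col in setdiff(delta_cols, names(wide))) wide[[col]] <- NA_real_
  wide <- wide[order(wide$temperature_K, wide$time_weeks), , drop = FALSE]
  complete <- stats::complete.cases(wide[delta_cols])
  dropped <- wide[!complete, , drop = FALSE]
  if (nrow(dropped) > 0) {
    dropped$missing <- apply(dropped[delta_cols], 1, function(r) {
      paste(inds[is.na(r)], collapse = ",")
    })
  }
  kept <- wide[complete, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("no-complete-rows error: no (temperature, time) has all five indicators",
         call. = FALSE)
  }
  X <- as.matrix(kept[c("temperature_K", "time_weeks")])
  Y <- as.matrix(kept[delta_cols])
  colnames(Y) <- inds
  rownames(X) <- rownames(Y) <- NULL
  list(X = X, Y = Y,
       rows = data.frame(temperature_K = kept$temperature_K,
                         time_weeks = kept$time_weeks),
       dropped = if (nrow(dropped) > 0)
         data.frame(temperature_K = dropped$temperature_K,
                    time_weeks = dropped$time_weeks,
                    missing = dropped$missing,
                    stringsAsFactors = FALSE)
       else
         data.frame(temperature_K = numeric(0), time_weeks = numeric(0),
                    missing = character(0)))
}

#' Fit per-column min-max normalization parameters
#'
#' @param m Numeric matrix (columns = variables).
#' @return List of class \code{minmax_params} with named numeric vectors
#'   \code{min} and \code{max}.
#' @export
fit_minmax <- function(m) {
  m <- as.matrix(m)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  degenerate <- maxs <= mins
  if (any(degenerate)) {
    stop("degenerate-variable error: constant column(s): ",
         paste(colnames(m)[degenerate], collapse = ", "), call. = FALSE)
  }
  structure(list(min = mins, max = maxs), class = "minmax_params")
}

#' Min-max normalization to [-1, 1] and its exact inverse
#'
#' \code{normalize_minmax} maps the fitted minimum to -1 and maximum to +1;
#' out-of-range values extrapolate linearly (no clipping), so applying the
#' training-split parameters to validation data is well defined.
#'
#' @param params A \code{minmax_params}.
#' @param m Numeric matrix (or vector for a single variable) with as many
#'   columns as \code{params} has variables.
#' @return Matrix of the same shape on the transformed scale.
#' @export
normalize_minmax <- function(params, m) {
  stopifnot(inherits(params, "minmax_params"))
  m <- if (is.null(dim(m))) matrix(m, nrow = 1) else as.matrix(m)
  stopifnot(ncol(m) == length(params$min))
  sweep(sweep(m, 2, params$min), 2, params$max - params$min, "/") * 2 - 1
}

#' @rdname normalize_minmax
#' @param s Matrix on the normalized scale.
#' @export
denormalize_minmax <- function(params, s) {
  stopifnot(inherits(params, "minmax_params"))
  s <- if (is.null(dim(s))) matrix(s, nrow = 1) else as.matrix(s)
  stopifnot(ncol(s) == length(params$min))
  sweep(sweep((s + 1) / 2, 2, params$max - params$min, "*"), 2, params$min, "+")
}
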