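# Validation metrics: per-point relative errors against the published +/-10%
# acceptance band, MSE and coefficient of determination per indicator, the
# Pearson correlation matrix across indicators, and the summary fractions
# used to describe end-of-storage degradation.

#' Percent relative error between experimental and predicted values
#'
#' \code{((C_exp - C_pre) / C_exp) * 100}. The signed mode matches the
#' reported validation tables (positive when the prediction undershoots the
#' experimental value); the absolute mode feeds the +/-10% acceptance band.
#'
#' @param experimental,predicted Numeric vectors (experimental must be
#'   nonzero).
#' @param mode \code{"signed"} or \code{"absolute"}.
#' @return Percent relative error(s).
#' @export
relative_error <- function(experimental, predicted,
                           mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (any(experimental == 0)) {
    stop("undefined-denominator error: experimental value is zero",
         call. = FALSE)
  }
  re <- (experimental - predicted) / experimental * 100
  if (mode == "absolute") abs(re) else re
}

#' Mean squared error
#' @param y,yhat Numeric vectors of equal, nonzero length.
#' @return Mean of squared differences.
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0) {
    stop("dimension error: y and yhat must have equal nonzero length",
         call. = FALSE)
  }
  mean((y - yhat)^2)
}

#' Coefficient of determination
#'
#' \code{R^2 = 1 - SS_res / SS_tot}; equals 1 only for a perfect fit, and can
#' be negative for fits worse than the mean.
#'
#' @param y,yhat Numeric vectors of equal, nonzero length; \code{y} must not
#'   be constant.
#' @return The coefficient of determination.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0) {
    stop("dimension error: y and yhat must have equal nonzero length",
         call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("r_squared undefined: zero variance in y", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Percent decrease from an initial value
#' @param C0 Initial value (> 0).
#' @param Ct Later value.
#' @return \code{(C0 - Ct) / C0 * 100}.
#' @export
percent_decrease <- function(C0, Ct) {
  if (any(C0 <= 0)) stop("domain error: C0 must be positive", call. = FALSE)
  (C0 - Ct) / C0 * 100
}

#' Residual fraction of an initial value
#'
#' Complements \code{percent_decrease} to 100.
#'
#' @param C0 Initial value (> 0).
#' @param Ct Later value.
#' @return \code{Ct / C0 * 100}.
#' @export
residual_fraction <- function(C0, Ct) {
  if (any(C0 <= 0)) stop("domain error: C0 must be positive", call. = FALSE)
  Ct / C0 * 100
}

#' Pearson correlation matrix across the five indicators
#'
#' Computed on replicate means of the complete (temperature, time) rows —
#' rows where all five indicators were measured — pooled across temperatures
#' by default. The pooling scheme and row count are recorded as attributes,
#' along with a two-tailed t-test significance flag at the 0.01 level.
#'
#' @param dataset A \code{quality_dataset}.
#' @param pooling \code{"all"} (one pooled matrix) or
#'   \code{"per_temperature"} (a named list of matrices).
#' @return For \code{"all"}: a 5 x 5 correlation matrix with attributes
#'   \code{pooling}, \code{n_rows}, \code{temperatures} and
#'   \code{significant_01}. For \code{"per_temperature"}: a named list of
#'   such matrices.
#' @export
pearson_matrix <- function(dataset, pooling = c("all", "per_temperature")) {
  pooling <- match.arg(pooling)
  means <- replicate_means(dataset)
  if (pooling == "per_temperature") {
    temps <- sort(unique(means$temperature_K))
    out <- lapply(temps, function(tp) {
      sub <- dataset
      sub$measurements <-
        sub$measurements[sub$measurements$temperature_K == tp, , drop = FALSE]
      pearson_matrix(sub, pooling = "all")
    })
    names(out) <- as.character(temps)
    return(out)
  }
  inds <- indicator_names()
  wide <- stats::reshape(means[c("temperature_K", "time_weeks", "indicator",
                                 "value")],
                         direction = "wide",
                         idvar = c("temperature_K", "time_weeks"),
                         timevar = "indicator", v.names = "value")
  value_cols <- paste0("value.", inds)
  for (col in setdiff(value_cols, names(wide))) wide[[col]] <- NA_real_
  complete <- stats::complete.cases(wide[value_cols])
  kept <- wide[complete, value_cols, drop = FALSE]
  n <- nrow(kept)
  if (n < 3) {
    stop("insufficient-data error: need >= 3 complete rows, got ", n,
         call. = FALSE)
  }
  r <- stats::cor(as.matrix(kept))
  dimnames(r) <- list(inds, inds)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- pval < 0.01
  diag(sig) <- NA
  structure(r, pooling = pooling, n_rows = n,
            temperatures = sort(unique(wide$temperature_K[complete])),
            significant_01 = sig)
}

#' Validation report against one temperature's measurement series
#'
#' Predicts each indicator's delta at every observed week (> 0) of the target
#' temperature, converts to absolute values by adding that (temperature,
#' indicator)'s baseline, and reports the signed percent relative error per
#' week, MSE and coefficient of determination per indicator on the original
#' scale, and the global maximum absolute relative error with the +/-10%
#' acceptance flag. Cells with an experimental value of zero are excluded
#' from the relative-error summary with a warning.
#'
#' @param net A trained \code{rbf_network} carrying normalization parameters.
#' @param dataset A \code{quality_dataset} containing the target temperature.
#' @param temperature Validation temperature in kelvin.
#' @param baseline_policy Baseline rule for the delta transform (must match
#'   the one used for training).
#' @return Object of class \code{validation_report}: list with \code{table}
#'   (indicator, week, experimental, predicted, relative_error),
#'   \code{per_indicator} (mse, r_squared), \code{max_abs_relative_error},
#'   \code{pass} (TRUE iff every defined |relative error| <= 10),
#'   \code{excluded}, \code{temperature}, \code{baseline_policy}.
#' @export
validation_report <- function(net, dataset, temperature,
                              baseline_policy = c("require_t0",
                                                  "first_observed")) {
  baseline_policy <- match.arg(baseline_policy)
  stopifnot(inherits(net, "rbf_network"))
  if (is.null(net$normalization)) {
    stop("state error: network carries no normalization parameters",
         call. = FALSE)
  }
  sub <- dataset
  sub$measurements <-
    sub$measurements[sub$measurements$temperature_K == temperature, ,
                     drop = FALSE]
  if (nrow(sub$measurements) == 0) {
    stop("data error: dataset has no measurements at ", temperature, " K",
         call. = FALSE)
  }
  delta <- delta_transform(sub, baseline_policy)
  baselines <- attr(delta, "baselines")
  means <- replicate_means(sub)
  means <- means[means$time_weeks > 0, , drop = FALSE]

  weeks <- sort(unique(means$time_weeks))
  Xval <- cbind(temperature_K = temperature, time_weeks = weeks)
  pred_delta <- predict(net, Xval, scale = "original")

  rows <- list()
  for (ind in indicator_names()) {
    base <- baselines$baseline_value[baselines$indicator == ind]
    if (length(base) == 0) next
    sub_means <- means[means$indicator == ind, , drop = FALSE]
    for (j in seq_len(nrow(sub_means))) {
      wk <- sub_means$time_weeks[j]
      pd <- pred_delta[match(wk, weeks), ind]
      rows[[length(rows) + 1]] <- data.frame(
        indicator = ind, time_weeks = wk,
        experimental = sub_means$value[j],
        predicted = base + pd, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(match(tab$indicator, indicator_names()), tab$time_weeks), ]
  rownames(tab) <- NULL

  defined <- tab$experimental != 0
  tab$relative_error <- NA_real_
  tab$relative_error[defined] <- relative_error(tab$experimental[defined],
                                                tab$predicted[defined],
                                                mode = "signed")
  excluded <- tab[!defined, c("indicator", "time_weeks"), drop = FALSE]
  if (nrow(excluded) > 0) {
    warning("relative error undefined (experimental value 0) for ",
            nrow(excluded), " cell(s); excluded from the acceptance band",
            call. = FALSE)
  }

  per_ind <- do.call(rbind, lapply(split(tab, tab$indicator), function(s) {
    data.frame(indicator = s$indicator[1],
               mse = mse(s$experimental, s$predicted),
               r_squared = r_squared(s$experimental, s$predicted),
               stringsAsFactors = FALSE)
  }))
  per_ind <- per_ind[match(intersect(indicator_names(), per_ind$indicator),
                           per_ind$indicator), ]
  rownames(per_ind) <- NULL

  max_abs <- max(abs(tab$relative_error), na.rm = TRUE)
  structure(list(table = tab, per_indicator = per_ind,
                 max_abs_relative_error = max_abs,
                 pass = max_abs <= 10,
                 excluded = excluded,
                 temperature = temperature,
                 baseline_policy = baseline_policy),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation at ", x$temperature, " K (baseline: ", x$baseline_policy,
      ")\n", sep = "")
  weeks <- sort(unique(x$table$time_weeks))
  hdr <- sprintf("%-12s %-14s %s", "Indicator", "",
                 paste(sprintf("%8g", weeks), collapse = " "))
  cat(hdr, "\n")
  for (ind in unique(x$table$indicator)) {
    s <- x$table[x$table$indicator == ind, ]
    line <- function(label, vals) {
      v <- vals[match(weeks, s$time_weeks)]
      cat(sprintf("%-12s %-14s %s\n", ind, label,
                  paste(sprintf("%8.2f", v), collapse = " ")))
    }
    line("predicted", s$predicted)
    line("experimental", s$experimental)
    line("rel. err (%)", s$relative_error)
  }
  cat(sprintf("max |relative error| = %.2f%% -> %s (+/-10%% band)\n",
              x$max_abs_relative_error, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Write a validation report as JSON
#' @param report A \code{validation_report}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(
    list(temperature_K = report$temperature,
         baseline_policy = report$baseline_policy,
         max_abs_relative_error = report$max_abs_relative_error,
         pass = report$pass,
         per_indicator = report$per_indicator,
         table = report$table,
         excluded = report$excluded),
    path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}
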