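test_that("relative error reproduces the printed week-17 validation entries", {
  # published week-17 pairs where 2-dp rounding is benign
  expect_equal(round(relative_error(16.81, 16.82), 2), -0.06)
  expect_equal(round(relative_error(43.14, 43.17), 2), -0.07)
  expect_equal(relative_error(5, 5), 0)
  # sign convention: positive when the prediction undershoots
  expect_gt(relative_error(10, 9), 0)
  expect_equal(relative_error(10, 11, mode = "absolute"), 10)
  expect_error(relative_error(0, 1), "undefined-denominator")
})

test_that("mse and r_squared behave as the standard definitions", {
  y <- c(1, 2, 3)
  expect_equal(mse(y, y), 0)
  expect_equal(r_squared(y, y), 1)
  expect_equal(mse(y, c(1, 2, 4)), 1 / 3)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_error(mse(y, c(1, 2)), "dimension error")
  expect_error(r_squared(c(2, 2, 2), y), "zero variance")
})

test_that("percent decrease and residual fraction match the printed summaries", {
  expect_equal(round(percent_decrease(63.84, 22.46), 2), 64.82)
  expect_equal(round(percent_decrease(69.74, 43.14), 2), 38.14)
  expect_equal(round(percent_decrease(66.74, 59.24), 2), 11.24)
  expect_equal(round(residual_fraction(0.27, 0.05), 2), 18.52)
  expect_equal(percent_decrease(7, 7), 0)
  expect_equal(residual_fraction(7, 7), 100)
  expect_error(percent_decrease(0, 1), "domain error")
  # complement identity
  set.seed(8)
  C0 <- runif(50, 0.1, 100); Ct <- runif(50, 0, 100)
  expect_equal(percent_decrease(C0, Ct) + residual_fraction(C0, Ct),
               rep(100, 50))
})

test_that("pearson matrix is a valid pooled correlation with recorded scheme", {
  ds <- carp_253K_fixture()
  r <- pearson_matrix(ds)
  expect_equal(dim(r), c(5, 5))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(unname(r), unname(t(r)))
  expect_true(all(r >= -1 & r <= 1))
  expect_equal(attr(r, "n_rows"), 10)

  # textbook covariance-formula oracle on the ten printed Ca-ATPase/SH pairs
  means <- replicate_means(ds)
  wk <- means$time_weeks > 0
  ca <- means$value[means$indicator == "CA_ATPASE" & wk]
  sh <- means$value[means$indicator == "SH" & wk]
  oracle <- sum((ca - mean(ca)) * (sh - mean(sh))) /
    sqrt(sum((ca - mean(ca))^2) * sum((sh - mean(sh))^2))
  expect_equal(r["CA_ATPASE", "SH"], oracle, tolerance = 1e-12)
  expect_gt(r["CA_ATPASE", "SH"], 0.9)  # strongly positive, as published

  # affine rescaling of an indicator leaves correlations unchanged
  scaled <- ds
  idx <- scaled$measurements$indicator == "SH"
  scaled$measurements$value[idx] <- scaled$measurements$value[idx] * 3 + 2
  expect_equal(unname(pearson_matrix(scaled)), unname(r), tolerance = 1e-12)

  tiny <- ds
  tiny$measurements <- tiny$measurements[tiny$measurements$time_weeks <= 2, ]
  expect_error(pearson_matrix(tiny), "insufficient-data")
})

test_that("perfect linear and anti-linear indicators give r = +/-1", {
  t <- c(0, 1, 2, 3, 5)
  mk <- function(ind, v) data.frame(temperature_K = 253, time_weeks = t,
                                    indicator = ind, replicate = 1L, value = v)
  ds <- quality_dataset(rbind(mk("TBARS", 0.2 + 0.1 * t),
                              mk("FFA", 1 + 0.5 * t),
                              mk("SSP", 70 - 2 * t),
                              mk("CA_ATPASE", 0.3 - 0.01 * t),
                              mk("SH", 7 - 0.2 * t)))
  r <- pearson_matrix(ds)
  expect_equal(r["TBARS", "FFA"], 1)
  expect_equal(r["TBARS", "SSP"], -1)
})

test_that("validation in the interpolation regime passes the 10% band", {
  ds <- simulate_dataset(noise_free_config(9))
  design <- assemble_design(delta_transform(ds, "require_t0"))
  ni <- fit_minmax(design$X); no <- fit_minmax(design$Y)
  fit <- train_incremental(normalize_minmax(ni, design$X),
                           normalize_minmax(no, design$Y),
                           spread = 1, max_neurons = nrow(design$X),
                           normalization = list(input = ni, output = no),
                           output_names = colnames(design$Y))
  rep_ <- validation_report(fit$network, ds, 253, "require_t0")
  expect_lt(rep_$max_abs_relative_error, 0.5)
  expect_true(rep_$pass)
  expect_equal(nrow(rep_$table), 50)  # 5 indicators x 10 post-baseline weeks
  expect_named(rep_$per_indicator, c("indicator", "mse", "r_squared"))
  expect_true(all(rep_$per_indicator$r_squared > 0.999))
})

test_that("zero experimental values are excluded from the band with a warning", {
  ds <- simulate_dataset(noise_free_config(10))
  m <- ds$measurements
  pick <- which(m$temperature_K == 253 & m$time_weeks == 17 &
                m$indicator == "CA_ATPASE")
  m$value[pick] <- 0
  ds2 <- quality_dataset(m)
  design <- assemble_design(delta_transform(ds2, "require_t0"))
  ni <- fit_minmax(design$X); no <- fit_minmax(design$Y)
  fit <- train_incremental(normalize_minmax(ni, design$X),
                           normalize_minmax(no, design$Y),
                           spread = 1, max_neurons = 20,
                           normalization = list(input = ni, output = no),
                           output_names = colnames(design$Y))
  expect_warning(rep_ <- validation_report(fit$network, ds2, 253, "require_t0"),
                 "undefined")
  expect_equal(rep_$excluded$indicator, "CA_ATPASE")
  expect_equal(rep_$excluded$time_weeks, 17)
  expect_false(any(is.na(rep_$table$relative_error[
    !(rep_$table$indicator == "CA_ATPASE" & rep_$table$time_weeks == 17)])))
})
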