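test_that("indicator catalogue has the five indicators with correct directions", {
  tab <- indicator_table()
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$indicator, c("TBARS", "FFA", "SSP", "CA_ATPASE", "SH"))
  expect_equal(indicator_direction(c("TBARS", "FFA")),
               c("increasing", "increasing"))
  expect_equal(indicator_direction(c("SSP", "CA_ATPASE", "SH")),
               rep("decreasing", 3))
  expect_error(indicator_direction("PH"), "unknown indicator")
})

test_that("dataset construction validates schema, keys and ranges", {
  ds <- quality_dataset(tiny_measurements())
  expect_s3_class(ds, "quality_dataset")
  expect_equal(nrow(ds$measurements), 4)

  expect_error(quality_dataset(tiny_measurements()[, -5]), "missing column")
  bad <- rbind(tiny_measurements(), tiny_measurements()[1, ])
  expect_error(quality_dataset(bad), "uniqueness error")
  neg <- tiny_measurements(); neg$value[2] <- -1
  expect_error(quality_dataset(neg), "validation error")
  unk <- tiny_measurements(); unk$indicator[1] <- "PH"
  expect_error(quality_dataset(unk), "unknown indicator")
})

test_that("CSV reader parses valid rows and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature_K,time_weeks,indicator,replicate,value",
               "253,1,TBARS,1,0.34"), path)
  ds <- read_quality_csv(path)
  expect_equal(nrow(ds$measurements), 1)
  expect_equal(ds$measurements$value, 0.34)

  writeLines("temperature_K,time_weeks,indicator,replicate,value", path)
  expect_equal(nrow(read_quality_csv(path)$measurements), 0)

  writeLines(c("temperature_K,time_weeks,indicator,value", "253,1,TBARS,0.34"),
             path)
  expect_error(read_quality_csv(path), "missing column.*replicate")

  writeLines(c("temperature_K,time_weeks,indicator,replicate,value",
               "253,1,TBARS,1,0.34", "253,1,TBARS,1,0.35"), path)
  expect_error(read_quality_csv(path), "uniqueness error")

  expect_error(read_quality_csv(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("CSV round trip is the identity at full precision", {
  ds <- carp_253K_fixture()
  # stress full-precision doubles too
  odd <- quality_dataset(data.frame(
    temperature_K = 245, time_weeks = c(0, 1 / 3), indicator = "SH",
    replicate = 1L, value = c(7.31, pi), stringsAsFactors = FALSE))
  for (d in list(ds, odd)) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_quality_csv(d, path)
    back <- read_quality_csv(path)
    expect_identical(back$measurements$value, d$measurements$value)
    expect_identical(back$measurements[1:4], d$measurements[1:4])
  }

  empty <- quality_dataset(tiny_measurements()[0, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_quality_csv(empty, path)
  expect_identical(readLines(path),
                   "temperature_K,time_weeks,indicator,replicate,value")
})

test_that("published 253 K fixture holds the printed series and anchors", {
  ds <- carp_253K_fixture()
  m <- ds$measurements
  expect_equal(nrow(m), 54)  # 5 indicators x 10 weeks + 4 week-0 anchors
  lookup <- function(t, ind) m$value[m$time_weeks == t & m$indicator == ind]
  expect_equal(lookup(17, "FFA"), 16.81)
  expect_equal(lookup(0, "SSP"), 69.74)
  expect_length(lookup(0, "TBARS"), 0)  # never printed, never fabricated
  expect_equal(lookup(1, "TBARS"), 0.34)
  expect_equal(lookup(17, "CA_ATPASE"), 0.05)
  # replicate sds travel in metadata, one per stored mean
  expect_equal(nrow(ds$metadata$replicate_sd), 54)
})

test_that("anchor table holds printed cells only and respects direction", {
  a <- anchor_table()
  row <- function(ind, tp) a[a$indicator == ind & a$temperature_K == tp, ]
  expect_equal(row("SSP", 261)$initial, 63.84)
  expect_equal(row("SSP", 261)$final, 22.46)
  expect_equal(row("FFA", 261)$final, 39.46)
  expect_true(is.na(row("TBARS", 261)$initial))
  expect_true(is.na(row("FFA", 245)$final))  # only the ratio is printed
  both <- !is.na(a$initial) & !is.na(a$final)
  dir <- indicator_direction(a$indicator)
  expect_true(all(ifelse(dir[both] == "increasing",
                         a$final[both] >= a$initial[both],
                         a$final[both] <= a$initial[both])))
})

test_that("replicate means average replicates per (temperature, time, indicator)", {
  m <- tiny_measurements()
  m2 <- m; m2$replicate <- 2L; m2$value <- m2$value + 1
  ds <- quality_dataset(rbind(m, m2))
  rm_ <- replicate_means(ds)
  expect_equal(nrow(rm_), 4)
  expect_true(all(rm_$n_replicates == 2))
  expect_equal(rm_$value[rm_$indicator == "FFA" & rm_$time_weeks == 0], 3.58)
})
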