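test_that("long and wide time-series dialects parse to the same wells", {
  long <- data.frame(plate_id = "p1",
                     well = rep(c("a1", "B2"), each = 3),
                     time_min = rep(c(0, 10, 20), 2),
                     od_raw = c(0.1, 0.2, 0.3, 0.15, 0.25, 0.35))
  f_long <- tempfile(fileext = ".csv")
  write.csv(long, f_long, row.names = FALSE)
  ts <- read_plate_timeseries(f_long, "long")
  expect_length(ts, 2)
  expect_equal(ts[["p1:A1"]]$od_raw, c(0.1, 0.2, 0.3))
  expect_equal(ts[["p1:B2"]]$well, "B2")  # case normalized

  wide <- data.frame(time_min = c(0, 10, 20), A1 = c(0.1, 0.2, 0.3),
                     A2 = c(0.2, 0.3, 0.4), A3 = c(0.3, 0.4, 0.5))
  f_wide <- tempfile(fileext = ".csv")
  write.csv(wide, f_wide, row.names = FALSE)
  tw <- read_plate_timeseries(f_wide, "wide", plate_id = "p1")
  expect_length(tw, 3)
  expect_equal(tw[["p1:A2"]]$od_raw, c(0.2, 0.3, 0.4))
})

test_that("time-series round trip write -> read is the identity", {
  ts <- list(well_timeseries("p1", "A1", c(0, 10, 20), c(0.1, 0.22, 0.31)),
             well_timeseries("p1", "H12", c(0, 10, 20), c(0.3, 0.2, 0.1)))
  f <- tempfile(fileext = ".csv")
  write_plate_timeseries(ts, f)
  back <- read_plate_timeseries(f, "long")
  expect_equal(back[["p1:A1"]]$od_raw, ts[[1]]$od_raw)
  expect_equal(back[["p1:H12"]]$times, ts[[2]]$times)
})

test_that("parsing is order-independent and rejects malformed input", {
  long <- data.frame(plate_id = "p1", well = rep("A1", 3),
                     time_min = c(20, 0, 10), od_raw = c(0.3, 0.1, 0.2))
  f <- tempfile(fileext = ".csv")
  write.csv(long, f, row.names = FALSE)
  ts <- read_plate_timeseries(f, "long")
  expect_equal(ts[["p1:A1"]]$times, c(0, 10, 20))
  expect_equal(ts[["p1:A1"]]$od_raw, c(0.1, 0.2, 0.3))

  dup <- rbind(long, data.frame(plate_id = "p1", well = "A1",
                                time_min = 10, od_raw = 0.5))
  write.csv(dup, f, row.names = FALSE)
  expect_error(read_plate_timeseries(f, "long"), "duplicate time")

  bad <- long; names(bad)[4] <- "od"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_plate_timeseries(f, "long"), "od_raw")

  nn <- long; nn$od_raw <- c("0.3", "x", "0.2")
  write.csv(nn, f, row.names = FALSE)
  expect_error(read_plate_timeseries(f, "long"), "non-numeric")
})

test_that("plate map validates roles, genotypes and reference flags", {
  base <- data.frame(well = c("A1", "A2", "H12"),
                     genotype = c("empty", "pip", ""),
                     vector = c("empty", "pip", ""),
                     treatment = c("H2O2", "H2O2", ""),
                     concentration = c(0, 1, NA),
                     conc_unit = c("mM", "mM", ""),
                     replicate = c(1, 1, 1),
                     role = c("sample", "sample", "blank"),
                     is_reference_condition = c(1, 0, 0),
                     is_empty_vector = c("true", "false", "false"))
  f <- tempfile(fileext = ".csv")
  write.csv(base, f, row.names = FALSE)
  pm <- read_plate_map(f)
  expect_s3_class(pm, "plate_map")
  expect_equal(sum(pm$role == "sample"), 2)
  expect_true(pm$is_empty_vector[1])

  # blanks need no genotype; samples do
  bad <- base; bad$genotype[2] <- ""
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_plate_map(f), "without genotype")

  # no blanks is a recorded warning, not fatal
  noblank <- base[base$role == "sample", ]
  write.csv(noblank, f, row.names = FALSE)
  pm2 <- read_plate_map(f)
  expect_match(attr(pm2, "warnings"), "no blank")

  # two reference concentrations in one genotype x treatment series
  conflict <- base
  conflict$genotype <- c("pip", "pip", "")
  conflict$well <- c("A1", "A2", "H12")
  conflict$is_reference_condition <- c(1, 1, 0)
  write.csv(conflict, f, row.names = FALSE)
  expect_error(read_plate_map(f), "more than one concentration")
})

test_that("results table round trip preserves values to 6 significant digits", {
  tab <- data.frame(genotype = "pip", treatment = "H2O2",
                    concentration = 0.5, replicate = 1L,
                    lambda = 312.3456789, mu = 0.01234567,
                    kappa = 2.3456789, phi_used = 755.5,
                    auc = 1234.56789, delta_auc_vs_control = NA,
                    rel_auc_vs_empty = 0.87654321,
                    flags = "missing_control")
  f <- tempfile(fileext = ".csv")
  write_results(tab, f)
  back <- read_results(f)
  expect_equal(nrow(back), 1)
  expect_equal(back$lambda, tab$lambda, tolerance = 1e-5)
  expect_equal(back$auc, tab$auc, tolerance = 1e-5)
  expect_true(is.na(back$delta_auc_vs_control))
  expect_equal(back$flags, "missing_control")
})
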