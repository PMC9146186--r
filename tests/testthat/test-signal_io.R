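test_that("CSV records round-trip bit-faithfully and infer fs from a time column", {
  d <- withr::local_tempdir()
  # minimal all-zero record
  p0 <- file.path(d, "zeros.csv")
  utils::write.csv(data.frame(a = c(0, 0, 0), b = c(0, 0, 0)), p0,
                   row.names = FALSE)
  rec0 <- read_ecg_csv(p0, fs = 1000)
  expect_equal(n_channels(rec0), 2L)
  expect_equal(n_samples(rec0), 3L)
  # fs inferred from a time column with 1 ms steps
  pt <- file.path(d, "timed.csv")
  utils::write.csv(data.frame(time = c(0, 0.001, 0.002), v = c(1, 2, 3)), pt,
                   row.names = FALSE)
  expect_equal(read_ecg_csv(pt)$fs, 1000)
  # random record round trip: channel count, order and values preserved
  set.seed(11)
  rec <- ecg_record(matrix(rnorm(500), ncol = 5,
                           dimnames = list(NULL, paste0("lead", 5:1))),
                    fs = 250)
  pr <- file.path(d, "rt.csv")
  write_ecg_csv(rec, pr)
  back <- read_ecg_csv(pr, fs = 250)
  expect_equal(back$channel_names, rec$channel_names)
  expect_lt(max(abs(back$data - rec$data)), 1e-9)
})

test_that("CSV reader reports parse and usage errors precisely", {
  d <- withr::local_tempdir()
  pb <- file.path(d, "bad.csv")
  writeLines(c("a,b", "1,2", "1,oops"), pb)
  err <- tryCatch(read_ecg_csv(pb, fs = 100), error = function(e) e)
  expect_s3_class(err, "fecg_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_error(suppressWarnings(read_ecg_csv(file.path(d, "zeros2.csv"))))
  ok <- file.path(d, "ok.csv")
  utils::write.csv(data.frame(a = 1:3), ok, row.names = FALSE)
  expect_error(read_ecg_csv(ok), class = "fecg_value_error")
})

test_that("WFDB format-16 records round-trip with annotations", {
  d <- withr::local_tempdir()
  rec <- ecg_record(matrix(seq(-1, 1, length.out = 20), ncol = 2), fs = 360,
                    ref_fetal_r = c(4L, 8L), ref_maternal_r = c(3L, 9L))
  write_wfdb(rec, file.path(d, "rt"))
  back <- read_wfdb(file.path(d, "rt"))
  expect_equal(n_channels(back), 2L)
  expect_equal(n_samples(back), 10L)
  expect_equal(back$fs, 360)
  expect_lt(max(abs(back$data - rec$data)), 1e-3)  # 1/gain quantization
  expect_identical(back$ref_fetal_r, c(4L, 8L))
  expect_identical(back$ref_maternal_r, c(3L, 9L))
})

test_that("WFDB format-212 packing is decoded correctly", {
  d <- withr::local_tempdir()
  # hand-packed pairs: (100, -200) and (5, 7)
  writeBin(as.raw(c(100, 240, 56, 5, 0, 7)), file.path(d, "p.dat"))
  writeLines(c("p 2 1000 2",
               "p.dat 212 200(0)/mV 12 0 0 0 0 chA",
               "p.dat 212 200(0)/mV 12 0 0 0 0 chB"),
             file.path(d, "p.hea"))
  rec <- read_wfdb(file.path(d, "p.hea"))
  expect_equal(rec$data * 200, cbind(chA = c(100, 5), chB = c(-200, 7)),
               ignore_attr = TRUE)
  expect_equal(rec$channel_names, c("chA", "chB"))
})

test_that("WFDB reader rejects missing and unsupported inputs", {
  d <- withr::local_tempdir()
  expect_error(read_wfdb(file.path(d, "nope")), class = "fecg_format_error")
  writeLines(c("u 1 500 4", "u.dat 80 200/mV"), file.path(d, "u.hea"))
  writeBin(raw(4), file.path(d, "u.dat"))
  expect_error(read_wfdb(file.path(d, "u.hea")),
               class = "fecg_unsupported_format")
})

test_that("annotation files survive long gaps via SKIP words", {
  d <- withr::local_tempdir()
  p <- file.path(d, "big.qrs")
  samples <- c(5L, 200000L, 200300L)  # second interval needs a SKIP
  fecgtools:::write_wfdb_ann(samples, p)
  expect_identical(read_wfdb_ann(p), samples)
})

test_that("fiducial CSVs round-trip, including empty and sparse sets", {
  d <- withr::local_tempdir()
  p <- file.path(d, "fid.csv")
  # empty set -> header-only file
  write_fiducials(data.frame(), p)
  expect_identical(nrow(read_fiducials(p)), 0L)
  expect_match(readLines(p)[1], "beat")
  # one beat, only R set
  one <- data.frame(beat = 1L, R = 100L)
  write_fiducials(one, p)
  back <- read_fiducials(p)
  expect_identical(back$R, 100L)
  expect_true(all(is.na(back$Q)))
  # full table round trip
  full <- data.frame(beat = 1:3, P_on = c(1L, NA, 20L), P_peak = c(3L, NA, 22L),
                     P_off = c(5L, NA, 24L), Q = c(8L, 30L, NA),
                     QRS_on = c(7L, 29L, 26L), R = c(10L, 32L, 50L),
                     S = c(12L, 34L, NA), QRS_off = c(14L, 36L, 52L),
                     T_on = c(15L, NA, 53L), T_peak = c(18L, NA, 56L),
                     T_off = c(21L, NA, 59L), ST_start = c(14L, 36L, 52L),
                     ST_end = c(15L, NA, 53L))
  write_fiducials(full, p)
  expect_identical(read_fiducials(p), full)
})

test_that("record invariants are enforced at construction", {
  expect_error(ecg_record(matrix(1, 1, 1), 100), class = "fecg_format_error")
  expect_error(ecg_record(matrix(1, 5, 2), 0), class = "fecg_value_error")
  expect_error(ecg_record(matrix(1, 5, 2), 100, ref_fetal_r = c(3, 3)),
               class = "fecg_value_error")
  expect_error(ecg_record(matrix(1, 5, 2), 100, ref_fetal_r = 9),
               class = "fecg_value_error")
})
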