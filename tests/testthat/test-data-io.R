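test_that("the documented example file loses only its missing-value row", {
  for (writer in list(write_cells_csv, write_cells_xlsx)) {
    path <- writer(table1_cells())
    d <- suppressMessages(read_dataset(path))
    expect_equal(nrow(d), 3)
    expect_equal(n_discarded(d), 1)
    expect_equal(discard_log(d)$row, 2)
    expect_match(discard_log(d)$reason, "missing")
    # surviving rows keep file order and raw (signed) values
    expect_equal(d$eye, c("OD", "OD", "OS"))
    expect_equal(d$preop_mag, c(0.25, -2, -1))
    expect_equal(d$source_row, c(1, 3, 4))
  }
})

test_that("complete rows read back exactly, zero-astigmatism eyes retained", {
  path <- write_cells_csv(rbind(c("OD", "1.00", "90", "0.00", "0")))
  d <- read_dataset(path)
  expect_equal(nrow(d), 1)
  expect_equal(n_discarded(d), 0)
  expect_equal(d$postop_mag, 0)  # 0.00 D eyes are never auto-discarded
})

test_that("write/read round trip is exact in both dialects", {
  withr::with_seed(81, raw <- random_dataset(25))
  for (dialect in c("csv", "xlsx")) {
    path <- tempfile(fileext = paste0(".", dialect))
    write_dataset(raw, path)
    back <- read_dataset(path)
    expect_equal(nrow(back), 25)
    expect_equal(back$eye, raw$eye)
    expect_identical(back$preop_mag, raw$preop_mag)
    expect_identical(back$preop_axis, as.numeric(raw$preop_axis))
    expect_identical(back$postop_mag, raw$postop_mag)
    expect_identical(back$postop_axis, as.numeric(raw$postop_axis))
  }
  expect_error(write_dataset(raw[0, ], tempfile(fileext = ".csv")), "empty")
})

test_that("xlsx output is byte-deterministic", {
  withr::with_seed(82, raw <- random_dataset(10))
  p1 <- tempfile(fileext = ".xlsx"); p2 <- tempfile(fileext = ".xlsx")
  write_dataset(raw, p1); write_dataset(raw, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("malformed files fail loudly instead of silently losing data", {
  # comma-decimal notation is a hard error, not a discard
  bad <- write_cells_xlsx(rbind(c("OD", "1.50", "90", "0", "0"),
                                c("OD", "1,50", "90", "0", "0")))
  expect_error(read_dataset(bad), "point decimal")
  # in CSV, comma decimals split fields apart; the shape error carries the hint
  bad_csv <- write_cells_csv(rbind(c("OD", "1,50", "90", "0", "0")))
  expect_error(read_dataset(bad_csv), "point decimal")
  # a header row is an error with a hint, never skipped silently
  hdr <- write_cells_csv(rbind(c("Eye", "PreMag", "PreAxis", "PostMag", "PostAxis"),
                               c("OD", "1.00", "90", "0", "0")))
  expect_error(read_dataset(hdr), "header")
  # wrong column count names the offending shape
  cols <- tempfile(fileext = ".csv")
  writeLines(c("OD,1.00,90,0", "OS,2.00,10,0"), cols)
  expect_error(read_dataset(cols), "expected 5 columns.*found 4")
  # no parseable rows at all (valid eye labels, broken numerics)
  none <- write_cells_csv(rbind(c("OD", "", "90", "0", "0"),
                                c("OS", "x", "90", "0", "0")))
  expect_error(suppressMessages(read_dataset(none)), "empty dataset")
  expect_error(read_dataset(tempfile(fileext = ".csv")), "not found")
})

test_that("row discards conserve the total row count under random corruption", {
  withr::with_seed(91, {
    for (trial in 1:10) {
      n <- sample(5:30, 1)
      mags <- matrix(as.character(round(runif(2 * (n - 1), 0, 4), 2)), ncol = 2)
      axes <- matrix(as.character(sample(0:180, 2 * (n - 1), TRUE)), ncol = 2)
      cells <- rbind(
        c("OD", "1.00", "90", "0.50", "80"),  # keep row 1 valid (no header trap)
        cbind(sample(c("OD", "OS", "??"), n - 1, TRUE),
              mags[, 1], axes[, 1], mags[, 2], axes[, 2])
      )
      # blank a few random numeric cells
      k <- sample(2:(n * 4), 4)
      cells[, 2:5][k] <- ""
      path <- write_cells_csv(cells)
      d <- suppressMessages(read_dataset(path))
      expect_equal(nrow(d) + n_discarded(d), n)
    }
  })
})

test_that("out-of-range readings are discarded with a logged reason", {
  path <- write_cells_csv(rbind(
    c("OD", "1.00", "90", "0", "0"),
    c("OD", "1.00", "200", "0", "0"),   # axis beyond 180
    c("OS", "45.0", "90", "0", "0")     # implausible magnitude
  ))
  d <- suppressMessages(read_dataset(path))
  expect_equal(nrow(d), 1)
  expect_equal(n_discarded(d), 2)
  expect_match(discard_log(d)$reason[1], "axis")
  expect_match(discard_log(d)$reason[2], "magnitude")
})
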