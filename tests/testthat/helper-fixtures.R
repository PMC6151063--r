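# Shared fixtures, built in code at test time.

# Five-column cell matrix mirroring the documented example file: row 2 has a
# missing postoperative axis and must be discarded; rows 3-4 use negative
# cylinder notation. Row 1 is a complete, unambiguous record.
table1_cells <- function() {
  rbind(
    c("OD", "0.25", "70", "0.00", "70"),
    c("OS", "0.75", "88", "-0.25", ""),
    c("OD", "-2.00", "90", "0", "0"),
    c("OS", "-1.00", "180", "0", "0")
  )
}

write_cells_csv <- function(cells, path = tempfile(fileext = ".csv")) {
  writeLines(apply(cells, 1, paste, collapse = ","), path)
  path
}

write_cells_xlsx <- function(cells, path = tempfile(fileext = ".xlsx")) {
  astigvec:::write_xlsx_minimal(cells, path)
  path
}

# Random valid positive-cylinder vectors for property tests.
random_polar <- function(n, min_mag = 0) {
  tibble::tibble(
    magnitude = stats::runif(n, min_mag, 6),
    axis = stats::runif(n, .Machine$double.eps, 180)
  )
}

# Random raw datasets (signed cylinder readings, mixed eyes).
random_dataset <- function(n) {
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  tibble::tibble(
    eye = sample(c("OD", "OS"), n, replace = TRUE),
    preop_mag = sgn * round(stats::runif(n, 0.25, 4) * 4) / 4,
    preop_axis = sample(1:180, n, replace = TRUE),
    postop_mag = sample(c(-1, 1), n, TRUE) * round(stats::runif(n, 0, 2) * 4) / 4,
    postop_axis = sample(1:180, n, replace = TRUE)
  )
}
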