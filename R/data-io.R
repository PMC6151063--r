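# Strict point-decimal number (optional sign, optional exponent).
POINT_DECIMAL_RE <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
COMMA_DECIMAL_RE <- "^[+-]?[0-9]+,[0-9]+$"

new_astig_dataset <- function(records, n_discarded = 0L, source_path = NA_character_,
                              discard_log = NULL) {
  records <- tibble::as_tibble(records)
  attr(records, "n_discarded") <- as.integer(n_discarded)
  attr(records, "source_path") <- source_path
  attr(records, "discard_log") <- discard_log %||%
    tibble::tibble(row = integer(), reason = character())
  class(records) <- c("astig_dataset", class(records))
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of input rows discarded while reading a dataset
#' @param dataset An `astig_dataset`.
#' @return Integer count of discarded rows.
#' @export
n_discarded <- function(dataset) attr(dataset, "n_discarded") %||% 0L

#' Per-row discard log of a dataset
#' @param dataset An `astig_dataset`.
#' @return A tibble with columns `row` (1-based row in the source file) and
#'   `reason`.
#' @export
discard_log <- function(dataset) attr(dataset, "discard_log")

#' @export
print.astig_dataset <- function(x, ...) {
  cat(sprintf("Astigmatism dataset: %d eye(s), %d row(s) discarded\n",
              nrow(x), n_discarded(x)))
  src <- attr(x, "source_path")
  if (!is.na(src)) cat("Source:", src, "\n")
  NextMethod()
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) "xlsx" else "csv"
}

read_raw_cells <- function(path, dialect) {
  if (dialect == "xlsx") {
    df <- suppressMessages(
      readxl::read_excel(path, col_names = FALSE, col_types = "text")
    )
    as.matrix(as.data.frame(df))
  } else {
    df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                          strip.white = TRUE, blank.lines.skip = TRUE)
    as.matrix(df)
  }
}

parse_point_decimal <- function(s) {
  # returns NA where the cell is not a valid point-decimal number
  ok <- !is.na(s) & grepl(POINT_DECIMAL_RE, s)
  out <- rep(NA_real_, length(s))
  out[ok] <- as.numeric(s[ok])
  out
}

#' Read a five-column pre/post-operative cylinder dataset
#'
#' The expected file has exactly five columns and no header row: eye label
#' (`"OD"`/`"OS"`, case-insensitive), preoperative cylinder magnitude
#' (diopters, positive- or negative-cylinder notation), preoperative axis
#' (degrees, 0--180), postoperative magnitude, postoperative axis. Numbers
#' must use point-decimal notation; comma decimals (`"1,50"`) are rejected
#' with an explicit error. Rows with a missing, blank or non-numeric cell,
#' an invalid eye label, an axis outside `[0, 180]`, or an implausible
#' magnitude (at or beyond `max_magnitude`) are discarded, counted, and
#' logged with their 1-based row number. Eyes with 0.00 D of astigmatism
#' are retained; exclusion is at the user's discretion.
#'
#' @param path Path to the data file.
#' @param dialect `"xlsx"`, `"csv"`, or `"auto"` (default: by file
#'   extension; XLSX is the reference dialect).
#' @param max_magnitude Sanity bound on |cylinder| in diopters.
#' @param quiet Suppress per-row discard messages.
#' @return An `astig_dataset`: a tibble with columns `eye`, `preop_mag`,
#'   `preop_axis`, `postop_mag`, `postop_axis`, `source_row`, carrying the
#'   discard count (see [n_discarded()]) and log (see [discard_log()]).
#' @export
read_dataset <- function(path, dialect = c("auto", "xlsx", "csv"),
                         max_magnitude = 30, quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") dialect <- guess_dialect(path)

  cells <- read_raw_cells(path, dialect)
  if (nrow(cells) == 0L) stop("empty dataset: no data rows in ", path)
  if (ncol(cells) != 5L) {
    hint <- if (ncol(cells) > 5L && dialect == "csv") {
      # comma decimals split CSV fields apart, inflating the column count
      " (if numbers are written with comma decimals, e.g. 1,50, please use point decimal notation instead)"
    } else ""
    stop(sprintf(paste0("format error: expected 5 columns (eye, preop ",
                        "magnitude, preop axis, postop magnitude, postop axis) ",
                        "but found %d in %s%s"), ncol(cells), path, hint))
  }

  # comma-decimal cells are a notation error, not missing data
  num_cells <- cells[, 2:5, drop = FALSE]
  comma_hit <- which(!is.na(num_cells) & grepl(COMMA_DECIMAL_RE, num_cells),
                     arr.ind = TRUE)
  if (nrow(comma_hit) > 0L) {
    stop(sprintf(paste0("comma-decimal value '%s' at row %d: please use ",
                        "point decimal notation (e.g. 1.50), not comma"),
                 num_cells[comma_hit[1, 1], comma_hit[1, 2]], comma_hit[1, 1]))
  }

  eye <- toupper(trimws(cells[, 1]))
  nums <- apply(num_cells, 2, parse_point_decimal)
  if (nrow(cells) == 1L) nums <- matrix(nums, nrow = 1)

  # the format has no header; a fully non-numeric first row is a header by
  # mistake, and silently skipping it would hide data loss
  if (!eye[1] %in% c("OD", "OS") && all(is.na(nums[1, ]))) {
    stop("first row is not data (no numeric cells and no OD/OS label); ",
         "the file format has no header row - remove the header row")
  }

  reasons <- character(nrow(cells))
  bad_eye <- !eye %in% c("OD", "OS")
  reasons[bad_eye] <- sprintf("invalid eye label '%s'", cells[bad_eye, 1])
  miss <- reasons == "" & apply(nums, 1, function(r) any(is.na(r)))
  reasons[miss] <- "missing or non-numeric cell"
  bad_axis <- reasons == "" &
    (nums[, 2] < 0 | nums[, 2] > 180 | nums[, 4] < 0 | nums[, 4] > 180)
  reasons[bad_axis] <- "axis outside [0, 180] degrees"
  bad_mag <- reasons == "" &
    (abs(nums[, 1]) >= max_magnitude | abs(nums[, 3]) >= max_magnitude)
  reasons[bad_mag] <- sprintf("magnitude beyond sanity bound (%g D)", max_magnitude)

  keep <- reasons == ""
  log <- tibble::tibble(row = which(!keep), reason = reasons[!keep])
  if (!quiet) {
    for (i in seq_len(nrow(log))) {
      message(sprintf("discarding row %d: %s", log$row[i], log$reason[i]))
    }
  }
  if (!any(keep)) stop("empty dataset: no parseable rows in ", path)

  records <- tibble::tibble(
    eye = eye[keep],
    preop_mag = nums[keep, 1], preop_axis = nums[keep, 2],
    postop_mag = nums[keep, 3], postop_axis = nums[keep, 4],
    source_row = which(keep)
  )
  new_astig_dataset(records, n_discarded = sum(!keep),
                    source_path = path, discard_log = log)
}

# Canonical number formatting: shortest plain representation that parses
# back to the identical double.
format_number <- function(x) {
  s <- sprintf("%.15g", x)
  fix <- as.numeric(s) != x
  s[fix] <- sprintf("%.17g", x[fix])
  s[s == "-0"] <- "0"
  s
}

#' Write a dataset back to XLSX or CSV
#'
#' Writes the five-column, headerless layout that [read_dataset()] reads;
#' the written file re-reads to a field-for-field equal dataset. XLSX
#' output is byte-deterministic (fixed archive timestamps).
#'
#' @param dataset A non-empty `astig_dataset` (or compatible data frame).
#' @param path Output path.
#' @param dialect `"xlsx"`, `"csv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, dialect = c("auto", "xlsx", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- guess_dialect(path)
  if (nrow(dataset) == 0L) stop("refusing to write an empty dataset")
  cells <- cbind(
    as.character(dataset$eye),
    format_number(dataset$preop_mag), format_number(dataset$preop_axis),
    format_number(dataset$postop_mag), format_number(dataset$postop_axis)
  )
  if (dialect == "xlsx") {
    write_xlsx_minimal(cells, path)
  } else {
    utils::write.table(cells, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
  }
  invisible(path)
}
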