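# Minimal single-sheet XLSX writer.
#
# Emits a SpreadsheetML workbook inside a ZIP container with stored
# (uncompressed) entries and fixed timestamps, so identical input produces
# byte-identical files. All cells are written as inline strings, which
# readxl returns verbatim under `col_types = "text"`, guaranteeing exact
# round trips of the canonical number formatting.

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# column index -> A1-style column letter (supports A..Z, enough here)
xlsx_col_letter <- function(i) LETTERS[i]

xlsx_sheet_xml <- function(cells) {
  # cells: character matrix (rows x cols)
  rows <- vapply(seq_len(nrow(cells)), function(r) {
    cs <- vapply(seq_len(ncol(cells)), function(c) {
      sprintf('<c r="%s%d" t="inlineStr"><is><t>%s</t></is></c>',
              xlsx_col_letter(c), r, xml_escape(cells[r, c]))
    }, character(1))
    sprintf('<row r="%d">%s</row>', r, paste0(cs, collapse = ""))
  }, character(1))
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste0(rows, collapse = ""), '</sheetData></worksheet>')
}

xlsx_static_parts <- function() {
  list(
    "[Content_Types].xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      '</Types>'),
    "_rels/.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
      '</Relationships>'),
    "xl/workbook.xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
      'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
      '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    "xl/_rels/workbook.xml.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
      '</Relationships>')
  )
}

le_bytes <- function(x, n) {
  # little-endian byte encoding of a nonnegative value (double-safe)
  b <- integer(n)
  for (i in seq_len(n)) {
    b[i] <- x %% 256
    x <- x %/% 256
  }
  as.raw(b)
}

crc32_raw <- function(raw_vec) {
  if (length(raw_vec) == 0L) return(0)
  hex <- digest::digest(raw_vec, algo = "crc32", serialize = FALSE)
  strtoi(substr(hex, 1, 4), 16L) * 65536 + strtoi(substr(hex, 5, 8), 16L)
}

# Write named character entries (UTF-8 XML text) as a stored-entry ZIP.
write_zip_stored <- function(entries, path) {
  dos_time <- 0          # 00:00:00
  dos_date <- 20513      # 2020-01-01, fixed for determinism
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  centrals <- list()
  offset <- 0
  for (name in names(entries)) {
    data <- charToRaw(enc2utf8(entries[[name]]))
    nm <- charToRaw(name)
    crc <- crc32_raw(data)
    local_hdr <- c(
      charToRaw("PK\x03\x04"), le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(dos_time, 2), le_bytes(dos_date, 2), le_bytes(crc, 4),
      le_bytes(length(data), 4), le_bytes(length(data), 4),
      le_bytes(length(nm), 2), le_bytes(0, 2), nm)
    writeBin(local_hdr, con)
    writeBin(data, con)
    centrals[[name]] <- c(
      charToRaw("PK\x01\x02"), le_bytes(20, 2), le_bytes(20, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(dos_time, 2), le_bytes(dos_date, 2),
      le_bytes(crc, 4), le_bytes(length(data), 4), le_bytes(length(data), 4),
      le_bytes(length(nm), 2), le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 4), le_bytes(offset, 4), nm)
    offset <- offset + length(local_hdr) + length(data)
  }
  cd_start <- offset
  for (cd in centrals) writeBin(cd, con)
  cd_size <- sum(vapply(centrals, length, integer(1)))
  eocd <- c(charToRaw("PK\x05\x06"), le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(length(centrals), 2), le_bytes(length(centrals), 2),
            le_bytes(cd_size, 4), le_bytes(cd_start, 4), le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

write_xlsx_minimal <- function(cells, path) {
  parts <- xlsx_static_parts()
  parts[["xl/worksheets/sheet1.xml"]] <- xlsx_sheet_xml(cells)
  write_zip_stored(parts, path)
}
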