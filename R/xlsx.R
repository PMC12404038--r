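# Minimal deterministic XLSX writer.
#
# No installed package writes .xlsx in this stack, so the few pieces of the
# OOXML spreadsheet container the package needs are emitted directly: a
# single worksheet of inline text strings inside a STORED (uncompressed) ZIP
# archive with fixed entry timestamps. Fixed metadata means identical content
# always produces identical bytes, which the determinism contracts rely on.
# Reading is delegated to readxl.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# little-endian unsigned integer as n raw bytes
.le_raw <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

.crc32 <- function(bytes) {
  if (length(bytes) == 0) return(0)
  hex <- digest::digest(bytes, algo = "crc32", serialize = FALSE)
  hex <- formatC(hex, width = 8, flag = "0")
  sum(strtoi(substring(hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L) * 256^(3:0))
}

# entries: named list of raw vectors (archive member name -> content)
.write_zip_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nentry <- length(entries)
  central <- vector("list", nentry)
  pos <- 0
  for (i in seq_len(nentry)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crc <- .crc32(data)
    n <- length(data)
    # DOS time 00:00:00, date 1981-01-01: deterministic archive metadata
    local <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), .le_raw(20, 2), .le_raw(0, 2),
               .le_raw(0, 2), .le_raw(0, 2), .le_raw(33, 2),
               .le_raw(crc, 4), .le_raw(n, 4), .le_raw(n, 4),
               .le_raw(length(name), 2), .le_raw(0, 2), name)
    writeBin(local, con)
    writeBin(data, con)
    central[[i]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), .le_raw(20, 2),
                      .le_raw(20, 2), .le_raw(0, 2), .le_raw(0, 2), .le_raw(0, 2),
                      .le_raw(33, 2), .le_raw(crc, 4), .le_raw(n, 4), .le_raw(n, 4),
                      .le_raw(length(name), 2), .le_raw(0, 2), .le_raw(0, 2),
                      .le_raw(0, 2), .le_raw(0, 2), .le_raw(0, 4), .le_raw(pos, 4),
                      name)
    pos <- pos + length(local) + n
  }
  cd <- do.call(c, central)
  writeBin(cd, con)
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), .le_raw(0, 2), .le_raw(0, 2),
             .le_raw(nentry, 2), .le_raw(nentry, 2), .le_raw(length(cd), 4),
             .le_raw(pos, 4), .le_raw(0, 2)), con)
  invisible(path)
}

.col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

# Write a data frame as a one-sheet xlsx, every cell an inline text string.
write_xlsx_table <- function(df, path, sheet = "Sheet1") {
  mk_row <- function(vals, r) {
    cells <- vapply(seq_along(vals), function(j) {
      sprintf('<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              .col_letter(j), r, .xml_escape(as.character(vals[j])))
    }, character(1))
    sprintf('<row r="%d">%s</row>', r, paste(cells, collapse = ""))
  }
  rows <- character(nrow(df) + 1)
  rows[1] <- mk_row(colnames(df), 1)
  for (i in seq_len(nrow(df))) {
    rows[i + 1] <- mk_row(unlist(df[i, ], use.names = FALSE), i + 1)
  }
  decl <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n'
  sheet_xml <- paste0(decl,
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
  ct <- paste0(decl,
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>")
  rels <- paste0(decl,
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>")
  wb <- paste0(decl,
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="', .xml_escape(sheet), '" sheetId="1" r:id="rId1"/></sheets>',
    "</workbook>")
  wbrels <- paste0(decl,
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>")
  .write_zip_stored(list(
    "[Content_Types].xml" = charToRaw(enc2utf8(ct)),
    "_rels/.rels" = charToRaw(enc2utf8(rels)),
    "xl/workbook.xml" = charToRaw(enc2utf8(wb)),
    "xl/_rels/workbook.xml.rels" = charToRaw(enc2utf8(wbrels)),
    "xl/worksheets/sheet1.xml" = charToRaw(enc2utf8(sheet_xml))), path)
}
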