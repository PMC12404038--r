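#' Canonicalize descriptor text
#'
#' Annotation exports are merged on their four functional descriptors, so the
#' descriptor strings must be canonical before any comparison: `NA` becomes the
#' empty string, leading/trailing whitespace is stripped, and internal runs of
#' whitespace collapse to single spaces. Character case is preserved here;
#' case-folding happens only inside key comparison (see
#' [build_presence_matrix()]).
#'
#' @param x Character vector (or `NULL`).
#' @return Character vector of the same length (`character(0)` for `NULL`),
#'   never containing `NA`.
#' @examples
#' normalize_text("  Heat  shock ") # "Heat shock"
#' @export
normalize_text <- function(x) {
  if (is.null(x)) return(character(0))
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- gsub("[ \t\r\n]+", " ", x)
  trimws(x)
}

# Canonical descriptor names, in key order.
DESCRIPTORS <- c("Category", "Subcategory", "Subsystem", "Role")

# Header matching is deliberately forgiving about styling ("Sub Category",
# "subcategory", "SUBSYSTEM") but strict about identity: each canonical
# descriptor must match exactly one source header.
.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Resolve source headers for the four descriptor columns
#'
#' @param headers Character vector of column headers as read from the file.
#' @param column_mapping Optional named list/character vector mapping canonical
#'   descriptor names (`Category`, `Subcategory`, `Subsystem`, `Role`) to
#'   source header names, for exports that use other labels (e.g. `Role`
#'   exported as `Function`).
#' @return Named character vector: canonical name -> source header.
#' @keywords internal
resolve_descriptor_columns <- function(headers, column_mapping = NULL) {
  mapping <- stats::setNames(rep(NA_character_, 4), DESCRIPTORS)
  if (!is.null(column_mapping)) {
    column_mapping <- unlist(column_mapping)
    bad <- setdiff(names(column_mapping), DESCRIPTORS)
    if (length(bad)) {
      stop("column_mapping names must be among ", paste(DESCRIPTORS, collapse = ", "),
           "; got: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(column_mapping)) {
      hit <- which(headers == column_mapping[[nm]])
      if (length(hit) == 0) {
        stop("mapped column '", column_mapping[[nm]], "' (for ", nm,
             ") not found in file header", call. = FALSE)
      }
      if (length(hit) > 1) {
        stop("mapped column '", column_mapping[[nm]], "' matches ", length(hit),
             " headers; headers must be unique", call. = FALSE)
      }
      mapping[nm] <- headers[hit]
    }
  }
  nh <- .norm_header(headers)
  for (nm in DESCRIPTORS[is.na(mapping)]) {
    hit <- which(nh == .norm_header(nm))
    if (length(hit) > 1) {
      stop("descriptor column '", nm, "' matches several headers (",
           paste(headers[hit], collapse = ", "), "); disambiguate via column_mapping",
           call. = FALSE)
    }
    if (length(hit) == 1) mapping[nm] <- headers[hit]
  }
  missing <- DESCRIPTORS[is.na(mapping)]
  if (length(missing)) {
    stop("missing required descriptor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mapping)) {
    stop("descriptor columns collide: one source header mapped to several descriptors",
         call. = FALSE)
  }
  mapping
}

.infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "csv", "xls", "xlsx")) ext
  else if (ext %in% c("txt", "tab")) "tsv"
  else stop("cannot infer format from extension '", ext,
            "'; pass format = one of tsv, csv, xls, xlsx", call. = FALSE)
}

#' Read one strain's functional annotation export
#'
#' Reads a subsystem-style annotation table (one row per annotated function,
#' with the descriptor columns `Category`, `Subcategory`, `Subsystem`, `Role`)
#' into a canonical record list. Supported formats are tab-separated,
#' RFC-4180 CSV, and Excel (`.xls`/`.xlsx`, first sheet unless `sheet` is
#' given). Text files are read as UTF-8 and a leading byte-order mark is
#' tolerated.
#'
#' Descriptor cells are passed through [normalize_text()]; empty cells become
#' empty strings (a record with a blank `Subcategory` is still a valid key).
#' Columns beyond the four descriptors (feature ids, gene symbols, ...) are
#' preserved in the record table but never interpreted by the downstream
#' protocol. Rows whose four descriptors are all empty are dropped; everything
#' else is kept in input order.
#'
#' @param path Path to the annotation export.
#' @param strain_id Non-empty strain identifier; becomes the matrix column
#'   name in [build_presence_matrix()].
#' @param column_mapping Optional mapping from canonical descriptor names to
#'   source headers; see [resolve_descriptor_columns()].
#' @param format One of `"auto"` (infer from extension), `"tsv"`, `"csv"`,
#'   `"xls"`, `"xlsx"`.
#' @param sheet Sheet number or name for Excel inputs (default first sheet).
#' @return An object of class `annotation_table`: a list with `strain_id`,
#'   `records` (data frame whose first four columns are the normalized
#'   descriptors, then any passthrough columns), `source_path`,
#'   `source_format`.
#' @export
read_annotation_table <- function(path, strain_id, column_mapping = NULL,
                                  format = c("auto", "tsv", "csv", "xls", "xlsx"),
                                  sheet = 1) {
  format <- match.arg(format)
  strain_id <- normalize_text(strain_id)
  if (length(strain_id) != 1 || !nzchar(strain_id)) {
    stop("strain_id must be a single non-empty string", call. = FALSE)
  }
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .infer_format(path)

  df <- switch(format,
    tsv = utils::read.delim(path, colClasses = "character", check.names = FALSE,
                            fileEncoding = "UTF-8-BOM", na.strings = character(0),
                            stringsAsFactors = FALSE),
    csv = utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8-BOM", na.strings = character(0),
                          stringsAsFactors = FALSE),
    xls = ,
    xlsx = {
      x <- readxl::read_excel(path, sheet = sheet, col_types = "text")
      as.data.frame(x, stringsAsFactors = FALSE, check.names = FALSE)
    })
  headers <- colnames(df)
  if (anyDuplicated(headers)) {
    dup <- unique(headers[duplicated(headers)])
    stop("duplicate column header(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  mapping <- resolve_descriptor_columns(headers, column_mapping)

  records <- data.frame(matrix(character(0), nrow = nrow(df), ncol = 0),
                        stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in DESCRIPTORS) records[[nm]] <- normalize_text(df[[mapping[[nm]]]])
  for (h in setdiff(headers, unname(mapping))) records[[h]] <- df[[h]]

  keep <- Reduce(`|`, lapply(records[DESCRIPTORS], nzchar))
  if (length(keep) == 0) keep <- logical(0)
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL

  structure(list(strain_id = strain_id, records = records,
                 source_path = path, source_format = format),
            class = "annotation_table")
}

#' Construct an annotation table from an in-memory data frame
#'
#' Convenience constructor used by the synthetic-data generator and by tests;
#' applies the same normalization as [read_annotation_table()].
#'
#' @param records Data frame containing the four descriptor columns.
#' @param strain_id Strain identifier.
#' @param source Optional source label.
#' @return An `annotation_table`.
#' @export
annotation_table <- function(records, strain_id, source = "<memory>") {
  mapping <- resolve_descriptor_columns(colnames(records))
  out <- data.frame(matrix(character(0), nrow = nrow(records), ncol = 0),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in DESCRIPTORS) out[[nm]] <- normalize_text(records[[mapping[[nm]]]])
  for (h in setdiff(colnames(records), unname(mapping))) out[[h]] <- records[[h]]
  keep <- Reduce(`|`, lapply(out[DESCRIPTORS], nzchar))
  if (length(keep) == 0) keep <- logical(0)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(strain_id = normalize_text(strain_id), records = out,
                 source_path = source, source_format = "memory"),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("Annotation table: strain ", x$strain_id, "\n",
      "  ", nrow(x$records), " records (", x$source_format, ", ",
      x$source_path, ")\n", sep = "")
  invisible(x)
}

#' Validate annotation tables before matrix construction
#'
#' Checks one table or a batch of tables for the conditions the merge protocol
#' relies on: all four descriptor columns present, at least one record with a
#' non-empty `Role`, and pairwise-distinct strain identifiers across a batch.
#' Issues are reported, not thrown; callers decide whether they are fatal.
#'
#' @param tables An `annotation_table` or a list of them.
#' @return Data frame with columns `strain_id` and `issue`; zero rows when
#'   everything is usable.
#' @export
validate_descriptors <- function(tables) {
  if (inherits(tables, "annotation_table")) tables <- list(tables)
  issues <- list()
  add <- function(strain, msg) issues[[length(issues) + 1]] <<-
    data.frame(strain_id = strain, issue = msg, stringsAsFactors = FALSE)
  for (tab in tables) {
    if (!inherits(tab, "annotation_table")) stop("expected annotation_table objects")
    missing <- setdiff(DESCRIPTORS, colnames(tab$records))
    if (length(missing)) {
      add(tab$strain_id, paste0("missing descriptor column(s): ",
                                paste(missing, collapse = ", ")))
      next
    }
    if (nrow(tab$records) == 0) {
      add(tab$strain_id, "no usable records")
    } else if (!any(nzchar(tab$records$Role))) {
      add(tab$strain_id, "Role column is entirely empty: no usable role data")
    }
  }
  ids <- vapply(tables, function(t) t$strain_id, character(1))
  for (dup in unique(ids[duplicated(ids)])) {
    add(dup, "duplicate strain_id in batch")
  }
  if (length(issues) == 0) {
    return(data.frame(strain_id = character(0), issue = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Write an annotation table to disk
#'
#' Serializes an `annotation_table` back to one of the tabular annotation
#' formats. TSV and CSV are written as UTF-8 with LF line endings; `.xlsx` is
#' written with a minimal deterministic writer (all cells as text, fixed
#' archive metadata, so identical content yields identical bytes). Writing the
#' legacy binary `.xls` format is not supported; such files are read-only
#' inputs.
#'
#' @param table An `annotation_table`.
#' @param path Output path.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"xlsx"`.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(table, path,
                                   format = c("auto", "tsv", "csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- .infer_format(path)
    if (format == "xls") {
      stop("writing legacy .xls is not supported; use .xlsx", call. = FALSE)
    }
  }
  df <- table$records
  switch(format,
    tsv = .write_delim(df, path, sep = "\t"),
    csv = .write_delim(df, path, sep = ","),
    xlsx = write_xlsx_table(df, path))
  invisible(path)
}

.write_delim <- function(df, path, sep) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  esc <- function(x, quote) {
    x <- as.character(x)
    if (quote) {
      need <- grepl(paste0('[",\n]'), x)
      x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    }
    x
  }
  quote <- sep == ","
  lines <- c(paste(esc(colnames(df), quote), collapse = sep),
             if (nrow(df)) vapply(seq_len(nrow(df)), function(i)
               paste(esc(unlist(df[i, ], use.names = FALSE), quote), collapse = sep),
               character(1)))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}
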