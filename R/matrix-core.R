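# Presence-absence matrix construction and count summaries.
#
# The unit of presence is the full (Category, Subcategory, Subsystem, Role)
# descriptor 4-tuple: the same role string under two different subsystem
# contexts is two keys, so multi-context functions keep one matrix row per
# context. Key identity and ordering are case-folded; the display form keeps
# the first-seen casing.

# Unit separator (U+001F) cannot occur in normalized descriptor text.
.KEY_SEP <- "\x1f"

#' Case-folded key identifier for descriptor 4-tuples
#'
#' @param category,subcategory,subsystem,role Normalized descriptor vectors.
#' @return Character vector of comparison-form key ids.
#' @keywords internal
function_key_id <- function(category, subcategory, subsystem, role) {
  paste(tolower(category), tolower(subcategory), tolower(subsystem),
        tolower(role), sep = .KEY_SEP)
}

.table_key_ids <- function(table) {
  r <- table$records
  function_key_id(r$Category, r$Subcategory, r$Subsystem, r$Role)
}

#' Build a binary gene presence-absence matrix from annotation tables
#'
#' Merges per-strain annotation tables on their shared descriptors into one
#' unified matrix: one row per distinct descriptor 4-tuple seen in any strain,
#' one column per strain. An entry is 1 when the strain's table contains at
#' least one record with that key (duplicate records collapse to a single 1)
#' and 0 otherwise -- a strain missing an annotation is imputed as absent.
#'
#' Rows are ordered lexicographically on the case-folded 4-tuple (byte order,
#' locale-independent), so the same inputs always produce the same matrix;
#' columns follow the input order of `tables`.
#'
#' @param tables List of [annotation_table] objects with pairwise-distinct
#'   strain ids.
#' @return An object of class `presence_matrix`: list with `keys` (data frame
#'   of the four display-form descriptor columns), `key_ids` (case-folded
#'   comparison forms, the row identity), and `values` (integer 0/1 matrix,
#'   rows in key order, columns named by strain).
#' @export
build_presence_matrix <- function(tables) {
  if (inherits(tables, "annotation_table")) tables <- list(tables)
  if (length(tables) == 0) stop("need at least one annotation table", call. = FALSE)
  ok <- vapply(tables, inherits, logical(1), what = "annotation_table")
  if (!all(ok)) stop("all inputs must be annotation_table objects", call. = FALSE)
  strains <- vapply(tables, function(t) t$strain_id, character(1))
  if (anyDuplicated(strains)) {
    stop("duplicate strain_id: ", paste(unique(strains[duplicated(strains)]),
                                        collapse = ", "), call. = FALSE)
  }

  per <- lapply(tables, function(t) {
    ids <- .table_key_ids(t)
    first <- !duplicated(ids)
    list(ids = ids[first],
         keys = t$records[first, DESCRIPTORS, drop = FALSE])
  })
  all_ids <- unlist(lapply(per, `[[`, "ids"), use.names = FALSE)
  if (length(all_ids) == 0) {
    stop("no annotation records: cannot build an empty matrix", call. = FALSE)
  }
  first <- !duplicated(all_ids)
  ids <- all_ids[first]
  keys <- do.call(rbind, lapply(per, `[[`, "keys"))[first, , drop = FALSE]
  ord <- order(ids, method = "radix")
  ids <- ids[ord]
  keys <- keys[ord, , drop = FALSE]
  rownames(keys) <- NULL

  values <- matrix(0L, nrow = length(ids), ncol = length(strains),
                   dimnames = list(NULL, strains))
  for (i in seq_along(per)) {
    values[match(per[[i]]$ids, ids), i] <- 1L
  }
  new_presence_matrix(keys, ids, values)
}

new_presence_matrix <- function(keys, key_ids, values) {
  stopifnot(nrow(keys) == length(key_ids), nrow(values) == length(key_ids))
  structure(list(keys = keys, key_ids = key_ids, values = values),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence-absence matrix: ", length(x$key_ids), " functional keys x ",
      ncol(x$values), " strains\n", sep = "")
  cat("  strains: ", paste(colnames(x$values), collapse = ", "), "\n", sep = "")
  cs <- colSums(x$values)
  cat("  keys per strain: ", paste(sprintf("%s=%d", names(cs), cs), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.presence_matrix <- function(object, ...) {
  cs <- colSums(object$values)
  conserved <- sum(rowSums(object$values) == ncol(object$values))
  out <- list(n_keys = length(object$key_ids), n_strains = ncol(object$values),
              keys_per_strain = cs, n_conserved_all = conserved,
              n_categories = length(unique(tolower(object$keys$Category))))
  class(out) <- "summary.presence_matrix"
  out
}

#' @export
print.summary.presence_matrix <- function(x, ...) {
  cat(x$n_keys, " functional keys across ", x$n_strains, " strains (",
      x$n_categories, " categories)\n", sep = "")
  cat("conserved in all strains: ", x$n_conserved_all, "\n", sep = "")
  print(x$keys_per_strain)
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$values)

#' @export
as.matrix.presence_matrix <- function(x, ...) {
  m <- x$values
  rownames(m) <- x$key_ids
  m
}

.check_strains <- function(matrix, strains) {
  unknown <- setdiff(strains, colnames(matrix$values))
  if (length(unknown)) {
    stop("unknown strain_id: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Subset a presence matrix to a set of rows
#'
#' @param matrix A `presence_matrix`.
#' @param rows Logical or integer row index, or character vector of key ids.
#' @return A `presence_matrix` with the selected rows (original order kept).
#' @export
subset_keys <- function(matrix, rows) {
  if (is.character(rows)) rows <- matrix$key_ids %in% rows
  new_presence_matrix(
    keys = matrix$keys[rows, , drop = FALSE],
    key_ids = matrix$key_ids[rows],
    values = matrix$values[rows, , drop = FALSE])
}

#' Functional keys conserved across a strain subset
#'
#' Returns the keys present (value 1) in every strain of `strain_subset` --
#' the core functional complement of that set of strains.
#'
#' @param matrix A `presence_matrix`.
#' @param strain_subset Non-empty character vector of strain ids; defaults to
#'   all strains in the matrix.
#' @return A `presence_matrix` restricted to the conserved keys.
#' @export
conserved_keys <- function(matrix, strain_subset = colnames(matrix$values)) {
  if (length(strain_subset) == 0) stop("strain_subset must be non-empty", call. = FALSE)
  .check_strains(matrix, strain_subset)
  sub <- matrix$values[, strain_subset, drop = FALSE]
  subset_keys(matrix, rowSums(sub) == length(strain_subset))
}

#' Fraction of the dataset conserved across strains
#'
#' The conserved (core) share of the matrix: `100 * n_conserved / n_total`.
#' For example, 522 roles conserved out of 1,990 total is 26.2%, reported in
#' summaries as ~26%.
#'
#' @inheritParams conserved_keys
#' @return Object of class `conserved_fraction`: list with `n_conserved`,
#'   `n_total`, `percent` (exact), `percent_1dp` (one decimal), and
#'   `percent_rounded` (nearest integer).
#' @export
conserved_fraction <- function(matrix, strain_subset = colnames(matrix$values)) {
  if (length(matrix$key_ids) == 0) stop("matrix has no keys", call. = FALSE)
  n_total <- length(matrix$key_ids)
  n_cons <- length(conserved_keys(matrix, strain_subset)$key_ids)
  pct <- 100 * n_cons / n_total
  structure(list(n_conserved = n_cons, n_total = n_total, percent = pct,
                 percent_1dp = round(pct, 1), percent_rounded = round(pct)),
            class = "conserved_fraction")
}

#' @export
print.conserved_fraction <- function(x, ...) {
  cat(sprintf("%d / %d keys conserved: %.1f%% (~%d%%)\n",
              x$n_conserved, x$n_total, x$percent_1dp, x$percent_rounded))
  invisible(x)
}

#' Per-strain, per-category counts of distinct functional keys
#'
#' Tallies, for every strain, how many distinct keys it carries under each
#' functional category. Counts are counts of distinct keys (the matrix is
#' binary), so each strain's counts sum to its matrix column sum. Categories
#' are grouped case-insensitively and displayed with first-seen casing.
#'
#' @param matrix A `presence_matrix`.
#' @return Object of class `category_summary`: long-format data frame with
#'   columns `strain_id`, `category`, `count`.
#' @export
category_counts <- function(matrix) {
  cat_fold <- tolower(matrix$keys$Category)
  first <- !duplicated(cat_fold)
  levels_fold <- cat_fold[first]
  display <- matrix$keys$Category[first]
  ord <- order(levels_fold, method = "radix")
  levels_fold <- levels_fold[ord]
  display <- display[ord]

  strains <- colnames(matrix$values)
  f <- factor(cat_fold, levels = levels_fold)
  counts <- do.call(rbind, lapply(strains, function(s) {
    n <- vapply(split(matrix$values[, s], f), sum, numeric(1))
    data.frame(strain_id = s, category = display, count = as.integer(n),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  class(counts) <- c("category_summary", "data.frame")
  counts
}

#' Reshape a category summary to a categories x strains count matrix
#'
#' @param summary A `category_summary` from [category_counts()].
#' @return Integer matrix, rows = categories, columns = strains.
#' @export
category_matrix <- function(summary) {
  strains <- unique(summary$strain_id)
  cats <- unique(summary$category)
  m <- matrix(0L, length(cats), length(strains), dimnames = list(cats, strains))
  m[cbind(match(summary$category, cats), match(summary$strain_id, strains))] <-
    summary$count
  m
}

#' Write a presence matrix as TSV
#'
#' Four leading descriptor columns (`Category`, `Subcategory`, `Subsystem`,
#' `Role`) followed by one 0/1 column per strain; UTF-8, LF line endings.
#'
#' @param matrix A `presence_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  clash <- intersect(colnames(matrix$values), DESCRIPTORS)
  if (length(clash)) {
    stop("strain name(s) collide with descriptor headers: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  df <- cbind(matrix$keys, as.data.frame(matrix$values, check.names = FALSE))
  .write_delim(df, path, sep = "\t")
  invisible(path)
}

#' Read a presence matrix written by [write_matrix()]
#'
#' @param path Path to a matrix TSV.
#' @return A `presence_matrix`.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8-BOM", na.strings = character(0),
                          stringsAsFactors = FALSE)
  missing <- setdiff(DESCRIPTORS, colnames(df))
  if (length(missing)) {
    stop("not a matrix file; missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  strain_cols <- setdiff(colnames(df), DESCRIPTORS)
  if (length(strain_cols) == 0) stop("matrix file has no strain columns", call. = FALSE)
  keys <- df[, DESCRIPTORS, drop = FALSE]
  for (nm in DESCRIPTORS) keys[[nm]] <- normalize_text(keys[[nm]])
  values <- vapply(strain_cols, function(s) as.integer(df[[s]]),
                   integer(nrow(df)))
  if (nrow(df) == 1) values <- matrix(values, nrow = 1, dimnames = list(NULL, strain_cols))
  if (anyNA(values) || !all(values %in% c(0L, 1L))) {
    stop("matrix values must all be 0 or 1", call. = FALSE)
  }
  ids <- function_key_id(keys$Category, keys$Subcategory, keys$Subsystem, keys$Role)
  new_presence_matrix(keys, ids, values)
}
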