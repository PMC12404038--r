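# Keyword-guided resistome extraction and the two-class comparative protocol.
#
# "Resistome" here is operational: the subset of functional keys whose
# descriptors match a configurable list of stress/resistance search terms
# (efflux, DNA repair, oxidative-stress defense, osmoprotection, ...). The
# comparative protocol then asks, for a query strain against a panel of
# phenotypically resistant and sensitive strains:
#   total     = keyword-matched keys, any strain
#   shared    = total keys present in the query AND >= 1 resistant strain
#   exclusive = shared keys absent from every sensitive strain

#' Load the default resistome keyword list
#'
#' The default terms cover the stress/resistance function families commonly
#' reported for radiation- and desiccation-tolerant bacteria: general stress
#' and resistance terms, efflux/transport, DNA repair, oxidative-stress
#' defense, osmoprotection, chaperones, and siderophore-mediated iron
#' scavenging. The list ships as a plain-text config file
#' (`system.file("extdata", "default_keywords.txt", package = "panresistome")`)
#' and is fully overridable via [read_keywords()] or any character vector.
#'
#' @return A `keyword_set` (character vector of search terms).
#' @export
default_keywords <- function() {
  path <- system.file("extdata", "default_keywords.txt", package = "panresistome")
  read_keywords(path)
}

#' Read a keyword list from file
#'
#' Accepts plain text (one term per line, `#` comments allowed) or a YAML
#' list (`.yaml`/`.yml`). Terms are normalized, de-duplicated
#' case-insensitively, and empty terms dropped.
#'
#' @param path Path to the keyword file.
#' @return A `keyword_set`.
#' @export
read_keywords <- function(path) {
  if (!file.exists(path)) stop("keyword file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  terms <- if (ext %in% c("yaml", "yml")) {
    unlist(yaml::read_yaml(path), use.names = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines[!grepl("^\\s*#", lines)]
  }
  keyword_set(terms)
}

#' Construct a keyword set
#'
#' @param terms Character vector of search terms; matching is always
#'   case-insensitive plain-substring over the four descriptor fields.
#' @return A `keyword_set`.
#' @export
keyword_set <- function(terms) {
  terms <- normalize_text(terms)
  terms <- terms[nzchar(terms)]
  terms <- terms[!duplicated(tolower(terms))]
  structure(terms, class = "keyword_set")
}

#' @export
print.keyword_set <- function(x, ...) {
  cat("Keyword set (", length(x), " terms, case-insensitive substring):\n  ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.keyword_match <- function(keys, terms) {
  if (length(terms) == 0) return(logical(nrow(keys)))
  fields <- lapply(keys[DESCRIPTORS], tolower)
  terms <- tolower(terms)
  hit <- logical(nrow(keys))
  for (term in terms) {
    for (f in fields) {
      hit <- hit | grepl(term, f, fixed = TRUE)
    }
  }
  hit
}

#' Keyword-guided resistome search
#'
#' Retains exactly the matrix rows for which at least one search term occurs,
#' case-insensitively, as a substring of at least one of the four descriptor
#' fields. The strain columns are unchanged; the result is the "total
#' resistome" matrix that the two-class protocol operates on.
#'
#' @param matrix A `presence_matrix`.
#' @param keywords A `keyword_set` or character vector of terms; defaults to
#'   [default_keywords()].
#' @return A `presence_matrix` restricted to keyword-matched rows.
#' @export
filter_resistome <- function(matrix, keywords = default_keywords()) {
  keywords <- keyword_set(keywords)
  if (length(keywords) == 0) {
    warning("empty keyword set: resistome filter retains no rows")
  }
  subset_keys(matrix, .keyword_match(matrix$keys, keywords))
}

# ---- D10 dose handling --------------------------------------------------

.KGY_PER_UNIT <- c(gy = 0.001, kgy = 1, mrad = 10)

#' Convert a D10 dose to kilogray
#'
#' Handles the dose units that strain surveys mix freely: Gy, kGy, and Mrad
#' (1 Mrad = 10 kGy). Ranges convert endpoint-wise.
#'
#' @param value Positive dose: a single value or a length-2 `c(low, high)`
#'   range with `low <= high`.
#' @param unit One of `"Gy"`, `"kGy"`, `"Mrad"` (case-insensitive).
#' @return Dose in kGy, same shape as `value`.
#' @examples
#' d10_to_kgy(370, "Gy")          # 0.37
#' d10_to_kgy(c(0.13, 0.25), "Mrad") # 1.3 2.5
#' @export
d10_to_kgy <- function(value, unit) {
  u <- tolower(normalize_text(unit))
  if (length(u) != 1 || !u %in% names(.KGY_PER_UNIT)) {
    stop("unknown dose unit '", unit, "'; expected Gy, kGy or Mrad", call. = FALSE)
  }
  if (!is.numeric(value) || length(value) < 1 || length(value) > 2 || anyNA(value)) {
    stop("dose must be a single value or a c(low, high) range", call. = FALSE)
  }
  if (any(value <= 0)) stop("dose must be positive", call. = FALSE)
  if (length(value) == 2 && value[1] > value[2]) {
    stop("dose range must satisfy low <= high", call. = FALSE)
  }
  unname(value * .KGY_PER_UNIT[[u]])
}

#' Parse a D10 dose string
#'
#' Accepts a plain number or a `"low-high"` range (hyphen or en dash).
#'
#' @param x Dose string (e.g. `"370"`, `"6-12"`, `"0.13-0.25"`).
#' @return Numeric vector of length 1 or 2, or `NULL` for empty input.
#' @export
parse_d10 <- function(x) {
  x <- normalize_text(x)
  if (length(x) != 1 || !nzchar(x) || x == "-") return(NULL)
  parts <- strsplit(x, "–|—|(?<=[0-9]) *- *(?=[0-9.])", perl = TRUE)[[1]]
  parts <- suppressWarnings(as.numeric(normalize_text(parts)))
  if (length(parts) < 1 || length(parts) > 2 || anyNA(parts)) {
    stop("cannot parse D10 value '", x, "'", call. = FALSE)
  }
  parts
}

#' Classify a strain as radiation-resistant or -sensitive from its D10 dose
#'
#' Applies the two-class rule: a strain whose experimentally validated D10 is
#' at or above `threshold_kgy` (default 2 kGy) is resistant, below it
#' sensitive. A user-asserted class always passes through untouched (survey
#' tables routinely assert "sensitive representative" strains without any
#' D10). For a `(low, high)` range the upper endpoint decides -- the reading
#' under which a reported 0.13-0.25 Mrad (1.3-2.5 kGy) strain is resistant --
#' and a range that straddles the threshold triggers a warning so the call is
#' auditable.
#'
#' @param d10 Dose value or range (numeric), or `NULL`/`NA` when unknown.
#' @param unit Dose unit for `d10` (see [d10_to_kgy()]).
#' @param threshold_kgy Classification threshold in kGy (default 2).
#' @param asserted_class Optional user-asserted class; returned as-is.
#' @param strain Optional strain id used in messages.
#' @return One of `"resistant"`, `"sensitive"`, `"unclassified"`, or the
#'   asserted class.
#' @export
classify_strain <- function(d10 = NULL, unit = "kGy", threshold_kgy = 2,
                            asserted_class = NULL, strain = NULL) {
  lbl <- if (is.null(strain)) "strain" else paste0("strain ", strain)
  if (!is.null(asserted_class)) {
    asserted_class <- tolower(normalize_text(asserted_class))
    if (length(asserted_class) == 1 && nzchar(asserted_class)) return(asserted_class)
  }
  if (is.null(d10) || length(d10) == 0 || anyNA(d10)) {
    warning(lbl, " has no D10 dose and no asserted class: unclassified")
    return("unclassified")
  }
  kgy <- d10_to_kgy(d10, unit)
  if (length(kgy) == 2 && kgy[1] < threshold_kgy && kgy[2] >= threshold_kgy) {
    warning(lbl, " D10 range ", kgy[1], "-", kgy[2], " kGy straddles the ",
            threshold_kgy, " kGy threshold; classified by upper endpoint")
  }
  if (max(kgy) >= threshold_kgy) "resistant" else "sensitive"
}

# ---- Strain panels ------------------------------------------------------

#' Assemble a strain panel for the two-class protocol
#'
#' Builds the query / resistant / sensitive structure from a strain metadata
#' table. Each row needs a strain id and either an asserted class or a D10
#' dose + unit; classes are derived with [classify_strain()] where not
#' asserted. Exactly one strain is designated the query; it belongs to
#' neither phenotype class.
#'
#' @param strains Data frame with columns `strain` (required) and optionally
#'   `class`, `d10` (value or `"low-high"` string), `unit`, `accession`.
#' @param query Strain id of the query strain.
#' @param threshold_kgy Classification threshold in kGy (default 2).
#' @return Object of class `strain_panel`: list with `records` (the annotated
#'   metadata, including `phenotype_class` and `d10_kgy`), `query`,
#'   `resistant`, `sensitive`, `threshold_kgy`.
#' @export
strain_panel <- function(strains, query, threshold_kgy = 2) {
  if (!"strain" %in% colnames(strains)) {
    stop("panel table needs a 'strain' column", call. = FALSE)
  }
  strains$strain <- normalize_text(strains$strain)
  if (anyDuplicated(strains$strain)) {
    stop("duplicate strain ids in panel: ",
         paste(unique(strains$strain[duplicated(strains$strain)]), collapse = ", "),
         call. = FALSE)
  }
  query <- normalize_text(query)
  if (!query %in% strains$strain) {
    stop("query strain '", query, "' not in panel table", call. = FALSE)
  }
  get <- function(nm) if (nm %in% colnames(strains)) strains[[nm]] else
    rep(NA_character_, nrow(strains))
  cls <- normalize_text(get("class"))
  d10_raw <- as.character(get("d10"))
  unit <- normalize_text(get("unit"))
  phen <- character(nrow(strains))
  d10_kgy <- rep(NA_real_, nrow(strains))
  for (i in seq_len(nrow(strains))) {
    if (strains$strain[i] == query) {
      phen[i] <- "query"
      next
    }
    d10 <- parse_d10(d10_raw[i])
    if (!is.null(d10) && nzchar(unit[i])) d10_kgy[i] <- max(d10_to_kgy(d10, unit[i]))
    phen[i] <- classify_strain(
      d10 = d10,
      unit = if (nzchar(unit[i])) unit[i] else "kGy",
      threshold_kgy = threshold_kgy,
      asserted_class = if (nzchar(cls[i])) cls[i] else NULL,
      strain = strains$strain[i])
  }
  records <- data.frame(strain = strains$strain, phenotype_class = phen,
                        d10 = d10_raw, unit = unit, d10_kgy = d10_kgy,
                        accession = normalize_text(get("accession")),
                        stringsAsFactors = FALSE)
  bad <- setdiff(unique(phen), c("query", "resistant", "sensitive", "unclassified"))
  if (length(bad)) {
    stop("unrecognized phenotype class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(records = records, query = query,
                 resistant = records$strain[phen == "resistant"],
                 sensitive = records$strain[phen == "sensitive"],
                 threshold_kgy = threshold_kgy),
            class = "strain_panel")
}

#' Read a strain panel metadata table
#'
#' TSV or CSV (by extension) with columns `strain`, and optionally `class`,
#' `d10`, `unit`, `accession`.
#'
#' @param path Path to the panel file.
#' @param query Query strain id.
#' @param threshold_kgy Classification threshold in kGy.
#' @return A `strain_panel`.
#' @export
read_panel <- function(path, query, threshold_kgy = 2) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8-BOM",
                          na.strings = character(0), stringsAsFactors = FALSE,
                          quote = "\"")
  strain_panel(df, query = query, threshold_kgy = threshold_kgy)
}

#' @export
print.strain_panel <- function(x, ...) {
  cat("Strain panel: query ", x$query, "\n",
      "  resistant (", length(x$resistant), "): ",
      paste(x$resistant, collapse = ", "), "\n",
      "  sensitive (", length(x$sensitive), "): ",
      paste(x$sensitive, collapse = ", "), "\n",
      "  D10 threshold: ", x$threshold_kgy, " kGy\n", sep = "")
  invisible(x)
}

# ---- Shared / exclusive extraction --------------------------------------

#' Shared resistome of a query strain and a resistant panel
#'
#' Keys of the (keyword-filtered) matrix present in the query strain and
#' simultaneously in at least one resistant strain.
#'
#' @param resistome A `presence_matrix`, normally the output of
#'   [filter_resistome()].
#' @param query Query strain id (a matrix column).
#' @param resistant Non-empty character vector of resistant strain ids.
#' @return A `presence_matrix` restricted to the shared keys.
#' @export
shared_resistome <- function(resistome, query, resistant) {
  if (length(resistant) == 0) stop("resistant strain list is empty", call. = FALSE)
  .check_strains(resistome, c(query, resistant))
  in_query <- resistome$values[, query] == 1L
  in_resistant <- rowSums(resistome$values[, resistant, drop = FALSE]) >= 1L
  subset_keys(resistome, in_query & in_resistant)
}

#' Exclusive resistome after subtracting sensitive strains
#'
#' Removes from the shared set every key that is also present in any
#' sensitive strain, leaving the keys retained by the query + resistant
#' strains only.
#'
#' @param shared A `presence_matrix` of shared keys (from
#'   [shared_resistome()]).
#' @param resistome The `presence_matrix` the shared set was derived from
#'   (used to look up presence in the sensitive strains).
#' @param sensitive Character vector of sensitive strain ids (may be empty,
#'   in which case the shared set passes through unchanged).
#' @return A `presence_matrix` restricted to the exclusive keys.
#' @export
exclusive_resistome <- function(shared, resistome, sensitive) {
  if (length(sensitive) == 0) return(shared)
  .check_strains(resistome, sensitive)
  in_sensitive <- resistome$key_ids[
    rowSums(resistome$values[, sensitive, drop = FALSE]) >= 1L]
  subset_keys(shared, !(shared$key_ids %in% in_sensitive))
}

#' Run the full two-class comparative resistome protocol
#'
#' Executes the three extraction stages on a presence matrix: keyword filter
#' (total resistome), intersection of the query with the resistant panel
#' (shared resistome), and subtraction of the sensitive strains (exclusive
#' resistome). The nesting `exclusive` \eqn{\subseteq} `shared`
#' \eqn{\subseteq} `total` holds by construction and is asserted.
#'
#' @param matrix A `presence_matrix` covering all panel strains.
#' @param panel A `strain_panel` with at least one resistant strain.
#' @param keywords Keyword set for the resistome filter.
#' @return Object of class `resistome_sets`: list with `total`, `shared`,
#'   `exclusive` (each a `presence_matrix`) and `provenance` (panel, keyword
#'   list, matrix dimensions, package version).
#' @export
run_two_class_protocol <- function(matrix, panel, keywords = default_keywords()) {
  if (!inherits(panel, "strain_panel")) stop("panel must be a strain_panel", call. = FALSE)
  if (length(panel$resistant) == 0) {
    stop("panel has no resistant strain; the shared-resistome stage is undefined",
         call. = FALSE)
  }
  .check_strains(matrix, c(panel$query, panel$resistant, panel$sensitive))
  keywords <- keyword_set(keywords)
  total <- filter_resistome(matrix, keywords)
  shared <- shared_resistome(total, panel$query, panel$resistant)
  exclusive <- exclusive_resistome(shared, total, panel$sensitive)
  stopifnot(all(shared$key_ids %in% total$key_ids),
            all(exclusive$key_ids %in% shared$key_ids))
  structure(list(
    total = total, shared = shared, exclusive = exclusive,
    provenance = list(
      query = panel$query, resistant = panel$resistant,
      sensitive = panel$sensitive, threshold_kgy = panel$threshold_kgy,
      keywords = as.character(keywords),
      n_matrix_keys = length(matrix$key_ids),
      strains = colnames(matrix$values),
      package = "panresistome",
      version = as.character(utils::packageVersion("panresistome")))),
    class = "resistome_sets")
}

#' @export
print.resistome_sets <- function(x, ...) {
  cat("Two-class resistome protocol: query ", x$provenance$query, "\n",
      "  total resistome:     ", length(x$total$key_ids), " keys\n",
      "  shared resistome:    ", length(x$shared$key_ids),
      " keys (query + >=1 of ", length(x$provenance$resistant), " resistant)\n",
      "  exclusive resistome: ", length(x$exclusive$key_ids),
      " keys (absent from ", length(x$provenance$sensitive), " sensitive)\n",
      sep = "")
  invisible(x)
}

#' Tally directly annotated and keyword-identified stress entries
#'
#' Splits the stress-related complement of a matrix into keys directly
#' annotated under a stress category (default `"Stress Response"`) and
#' additional keyword-identified keys outside that category; `total` is the
#' size of their union. For instance a dataset with 90 directly annotated and
#' 463 additional keyword-identified keys has 553 stress-related entries.
#'
#' @param matrix A `presence_matrix`.
#' @param keywords Keyword set for the resistome search.
#' @param stress_category Category name counted as directly annotated
#'   (case-insensitive).
#' @return List with `n_direct`, `n_keyword_additional`, `n_total`.
#' @export
stress_entry_summary <- function(matrix, keywords = default_keywords(),
                                 stress_category = "Stress Response") {
  direct <- tolower(matrix$keys$Category) == tolower(stress_category)
  matched <- .keyword_match(matrix$keys, keyword_set(keywords))
  list(n_direct = sum(direct),
       n_keyword_additional = sum(matched & !direct),
       n_total = sum(direct | matched))
}
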