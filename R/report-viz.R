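# Deterministic clustered-heatmap reporting and protocol persistence.
#
# Rendering is a pure function of the inputs: labels are pre-sorted so
# clustering ties cannot depend on input order, the color gradient is a fixed
# dark-blue -> green -> yellow ramp, and no timestamps or environment
# metadata are embedded in the image files.

#' Agglomerative leaf order for heatmap axes
#'
#' Hierarchically clusters the rows or columns of a numeric table and returns
#' the dendrogram leaf order. Labels are sorted lexicographically (byte
#' order) before clustering, so equal-distance ties always resolve the same
#' way and the output is a deterministic function of the values.
#'
#' @param values Numeric matrix with dimnames on the clustered axis.
#' @param axis `"rows"` or `"columns"`.
#' @param linkage Agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @param distance Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return Character vector: the axis labels in leaf order (a permutation of
#'   the input labels). A single-label axis returns identity order.
#' @export
cluster_order <- function(values, axis = c("rows", "columns"),
                          linkage = "average", distance = "euclidean") {
  axis <- match.arg(axis)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  m <- if (axis == "columns") t(values) else values
  labels <- rownames(m)
  if (is.null(labels)) stop("clustered axis must have labels", call. = FALSE)
  if (nrow(m) == 0) stop("table is empty", call. = FALSE)
  if (nrow(m) == 1) return(labels)
  ord <- order(labels, method = "radix")
  m <- m[ord, , drop = FALSE]
  h <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  rownames(m)[h$order]
}

# Fixed dark blue -> green -> yellow gradient (viridis), per the heatmap
# convention: minimum darkest blue, maximum yellow.
.heat_palette <- function(n = 256) viridisLite::viridis(n)

#' Render a deterministic clustered heatmap
#'
#' Draws a counts (or binary) table as a heatmap with optional agglomerative
#' row/column ordering via [cluster_order()]. The color gradient runs from
#' dark blue (minimum) through green to yellow (maximum); cells are annotated
#' with their values for small tables. Output format follows the file
#' extension (`.png`, `.svg`, or `.pdf`); any timestamp fields a device
#' embeds (PDF creation dates) are scrubbed after writing, so identical
#' inputs give identical bytes.
#'
#' @param values Numeric matrix with row and column names (e.g. the output of
#'   [category_matrix()]).
#' @param out_path Output image path ending in `.png`, `.svg`, or `.pdf`.
#' @param cluster_rows,cluster_cols Reorder the axis by clustering?
#' @param linkage,distance Clustering parameters, see [cluster_order()].
#' @param annotate Draw the value in each cell; default for tables with at
#'   most 40 rows.
#' @param main Plot title.
#' @param width,height Device size in pixels (png) or inches (svg/pdf).
#' @return `out_path`, invisibly.
#' @export
render_heatmap <- function(values, out_path, cluster_rows = TRUE,
                           cluster_cols = TRUE, linkage = "average",
                           distance = "euclidean", annotate = NULL,
                           main = "", width = NULL, height = NULL) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0) {
    stop("values must be a non-empty numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have row and column names", call. = FALSE)
  }
  if (cluster_rows && nrow(values) > 1) {
    values <- values[cluster_order(values, "rows", linkage, distance), , drop = FALSE]
  }
  if (cluster_cols && ncol(values) > 1) {
    values <- values[, cluster_order(values, "columns", linkage, distance),
                     drop = FALSE]
  }
  if (is.null(annotate)) annotate <- nrow(values) <= 40

  ext <- tolower(tools::file_ext(out_path))
  lab_len <- max(nchar(rownames(values)), 8)
  png_args <- list(filename = out_path,
                   width = if (is.null(width)) 180 + 36 * ncol(values) + 6 * lab_len else width,
                   height = if (is.null(height)) 160 + 18 * nrow(values) else height)
  if (capabilities("cairo")) png_args$type <- "cairo"
  switch(ext,
    png = do.call(grDevices::png, png_args),
    svg = grDevices::svg(out_path, width = if (is.null(width)) 8 else width,
                         height = if (is.null(height)) 6 else height),
    pdf = grDevices::pdf(out_path, width = if (is.null(width)) 8 else width,
                         height = if (is.null(height)) 6 else height),
    stop("unsupported image extension '.", ext, "'; use .png, .svg or .pdf",
         call. = FALSE))
  ok <- FALSE
  tryCatch({
    .draw_heatmap(values, annotate = annotate, main = main)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) stop("heatmap rendering failed for ", out_path, call. = FALSE)
  if (ext == "pdf") .scrub_pdf_dates(out_path)
  invisible(out_path)
}

.draw_heatmap <- function(values, annotate, main) {
  nr <- nrow(values)
  nc <- ncol(values)
  old <- graphics::par(mar = c(1, 10, 6, 3))
  on.exit(graphics::par(old))
  rng <- range(values)
  pal <- .heat_palette()
  # image() draws row 1 at the bottom; flip so the first table row is on top
  z <- t(values[rev(seq_len(nr)), , drop = FALSE])
  graphics::image(x = seq_len(nc), y = seq_len(nr), z = z,
                  col = pal, zlim = if (rng[1] == rng[2]) rng + c(-0.5, 0.5) else rng,
                  axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(3, at = seq_len(nc), labels = colnames(values), las = 2,
                 tick = FALSE, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(values)), las = 2,
                 tick = FALSE, cex.axis = 0.8)
  if (annotate) {
    span <- if (rng[1] == rng[2]) 1 else rng[2] - rng[1]
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        v <- values[i, j]
        frac <- (v - rng[1]) / span
        graphics::text(j, nr - i + 1, format(v), cex = 0.65,
                       col = if (frac > 0.6) "black" else "white")
      }
    }
  }
}

# Overwrite the digits of /CreationDate and /ModDate entries in a PDF with
# zeros, length-preserving so xref offsets stay valid.
.scrub_pdf_dates <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  for (tag in c("/CreationDate (D:", "/ModDate (D:")) {
    pat <- charToRaw(tag)
    hits <- which(bytes == pat[1])
    for (h in hits) {
      end <- h + length(pat) - 1
      if (end > length(bytes) || !identical(bytes[h:end], pat)) next
      i <- end + 1
      while (i <= length(bytes) && bytes[i] != charToRaw(")")) {
        b <- bytes[i]
        if (b >= charToRaw("0") && b <= charToRaw("9")) bytes[i] <- charToRaw("0")
        i <- i + 1
      }
    }
  }
  writeBin(bytes, path)
  invisible(path)
}

#' Persist the protocol output sets
#'
#' Writes `total.tsv`, `shared.tsv`, and `exclusive.tsv` (each in the
#' [write_matrix()] layout: four descriptor columns plus per-strain 0/1
#' columns, restricted to that set's keys) and a `provenance.json` sidecar
#' recording the query, panel classes, keyword list, and package version. An
#' empty set yields a header-only file; every file round-trips through
#' [read_matrix()].
#'
#' @param sets A `resistome_sets` from [run_two_class_protocol()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_sets <- function(sets, out_dir) {
  if (!inherits(sets, "resistome_sets")) {
    stop("sets must be a resistome_sets object", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(total = file.path(out_dir, "total.tsv"),
             shared = file.path(out_dir, "shared.tsv"),
             exclusive = file.path(out_dir, "exclusive.tsv"))
  write_matrix(sets$total, paths["total"])
  write_matrix(sets$shared, paths["shared"])
  write_matrix(sets$exclusive, paths["exclusive"])
  prov_path <- file.path(out_dir, "provenance.json")
  prov <- c(sets$provenance,
            list(n_total = length(sets$total$key_ids),
                 n_shared = length(sets$shared$key_ids),
                 n_exclusive = length(sets$exclusive$key_ids)))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["provenance"] <- prov_path
  invisible(paths)
}
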