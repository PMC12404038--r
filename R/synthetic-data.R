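# Synthetic annotation-panel generator.
#
# Emulates the statistical structure the two-class protocol assumes in real
# subsystem-annotation exports: a core vocabulary of descriptor 4-tuples
# present in every strain, class-specific planted resistome keys (present in
# the query + a non-empty subset of the resistant strains, absent from the
# sensitive strains unless deliberately leaked), and per-strain private noise
# keys. Signatures are planted at the key level: the protocol under test
# operates purely on annotation descriptors, so no sequences are simulated.
# Output is a pure function of (spec, seed).

# Functional category pool for non-keyword keys. None of these strings (nor
# any other descriptor of a non-keyword key) contains a default search term,
# so the keyword filter separates planted from background exactly.
.BG_CATEGORIES <- c(
  "Carbohydrates", "Amino Acids and Derivatives", "Protein Metabolism",
  "DNA Metabolism", "RNA Metabolism", "Respiration", "Cell Wall and Capsule",
  "Cofactors, Vitamins, Prosthetic Groups, Pigments",
  "Nucleosides and Nucleotides", "Fatty Acids, Lipids, and Isoprenoids",
  "Membrane Transport", "Sulfur Metabolism", "Nitrogen Metabolism",
  "Motility and Chemotaxis", "Iron Acquisition and Metabolism",
  "Cell Division and Cell Cycle")

# Categories and role phrases for keyword-matching keys; every phrase embeds
# at least one default search term.
.KW_CATEGORIES <- c("Stress Response", "Virulence, Disease and Defense",
                    "Membrane Transport", "DNA Metabolism")
.KW_PHRASES <- c(
  "multidrug efflux", "DNA repair", "oxidative stress response", "heat shock",
  "osmoprotectant ABC transporter", "glutathione detoxification", "peroxidase",
  "radiation resistance", "chaperone", "glycine betaine uptake",
  "siderophore biosynthesis", "antimicrobial resistance", "amino acid permease")

.VOCAB_CAPACITY <- 99999L

# Draws n vocabulary rows from the current RNG stream; indices start..start+n-1
# make roles globally unique within one generated panel.
.vocab_rows <- function(n, with_keyword, start = 1L) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  empty <- data.frame(Category = character(0), Subcategory = character(0),
                      Subsystem = character(0), Role = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  idx <- seq.int(start, length.out = n)
  if (max(idx) > .VOCAB_CAPACITY) {
    stop("requested vocabulary exceeds capacity (", .VOCAB_CAPACITY, " keys)",
         call. = FALSE)
  }
  if (with_keyword) {
    phrase <- sample(.KW_PHRASES, n, replace = TRUE)
    data.frame(
      Category = sample(.KW_CATEGORIES, n, replace = TRUE),
      Subcategory = ifelse(stats::runif(n) < 0.3, "",
                           paste0("Defense cluster ", sample(26, n, TRUE))),
      Subsystem = paste0(toupper(substring(phrase, 1, 1)), substring(phrase, 2),
                         " system"),
      Role = sprintf("Predicted %s protein PRF%05d", phrase, idx),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      Category = sample(.BG_CATEGORIES, n, replace = TRUE),
      Subcategory = ifelse(stats::runif(n) < 0.3, "",
                           paste0("Division ", LETTERS[sample(26, n, TRUE)])),
      Subsystem = sprintf("Annotated pathway module %03d", sample(97, n, TRUE)),
      Role = sprintf("Conserved hypothetical protein PRF%05d (EC %d.%d.%d.%d)",
                     idx, sample(6, n, TRUE), sample(20, n, TRUE),
                     sample(30, n, TRUE), sample(99, n, TRUE)),
      stringsAsFactors = FALSE)
  }
}

# Evaluate code under a fixed, named RNG without disturbing the caller's
# random stream. The generator kind is recorded in the ground-truth manifest.
.RNG_KIND <- c("Mersenne-Twister", "Inversion", "Rejection")
.with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed, kind = .RNG_KIND[1], normal.kind = .RNG_KIND[2],
           sample.kind = .RNG_KIND[3])
  code
}

#' Generate a synthetic descriptor vocabulary
#'
#' Draws `n` distinct descriptor 4-tuples. With `with_keyword = TRUE` every
#' role embeds one default resistome search term (so [filter_resistome()]
#' with [default_keywords()] retains all of them); with `with_keyword =
#' FALSE` no descriptor contains any default term (the filter retains none).
#' Category names echo the standard subsystem families (Carbohydrates, Amino
#' Acids and Derivatives, Stress Response, DNA Metabolism, ...).
#'
#' @param n Number of keys (>= 0).
#' @param with_keyword Plant a resistome keyword in every role?
#' @param seed Integer seed; same `(n, with_keyword, seed)` gives identical
#'   output.
#' @return Data frame with columns `Category`, `Subcategory`, `Subsystem`,
#'   `Role`; rows are pairwise-distinct keys.
#' @export
generate_vocabulary <- function(n, with_keyword = FALSE, seed = 1) {
  .with_seed(seed, .vocab_rows(n, with_keyword))
}

#' Specify a synthetic strain panel
#'
#' @param n_query Number of query-class strains (>= 1; the first is the
#'   protocol's query strain and the only one carrying planted signatures).
#' @param n_resistant Number of resistant strains (>= 1).
#' @param n_sensitive Number of sensitive strains (>= 0).
#' @param n_core Core keys present in every strain.
#' @param n_shared_planted Keyword-matching keys planted in the query plus a
#'   random non-empty subset of the resistant strains.
#' @param leakage Fraction in `[0, 1]` of planted shared keys additionally
#'   copied into at least one sensitive strain; the non-leaked remainder is
#'   the planted exclusive set (leakage 0 = all exclusive, 1 = none).
#' @param n_noise_per_strain Private keys per strain.
#' @param keyword_fraction_noise Probability that a noise key embeds a
#'   resistome keyword.
#' @param duplicate_rate Probability that an emitted record row is duplicated,
#'   stressing the binary-collapse rule (real exports repeat roles).
#' @param seed Integer seed; output is a pure function of the spec.
#' @return A validated `panel_spec` list.
#' @export
panel_spec <- function(n_query = 1, n_resistant = 3, n_sensitive = 3,
                       n_core = 100, n_shared_planted = 50, leakage = 0,
                       n_noise_per_strain = 20, keyword_fraction_noise = 0.25,
                       duplicate_rate = 0, seed = 1) {
  spec <- list(n_query = as.integer(n_query), n_resistant = as.integer(n_resistant),
               n_sensitive = as.integer(n_sensitive), n_core = as.integer(n_core),
               n_shared_planted = as.integer(n_shared_planted),
               leakage = as.numeric(leakage),
               n_noise_per_strain = as.integer(n_noise_per_strain),
               keyword_fraction_noise = as.numeric(keyword_fraction_noise),
               duplicate_rate = as.numeric(duplicate_rate),
               seed = as.integer(seed))
  if (spec$n_query < 1) stop("n_query must be >= 1", call. = FALSE)
  if (spec$n_resistant < 1) stop("n_resistant must be >= 1", call. = FALSE)
  counts <- unlist(spec[c("n_sensitive", "n_core", "n_shared_planted",
                          "n_noise_per_strain")])
  if (any(counts < 0)) stop("panel counts must be non-negative", call. = FALSE)
  for (nm in c("leakage", "keyword_fraction_noise", "duplicate_rate")) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1) {
      stop(nm, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (spec$leakage > 0 && spec$n_sensitive == 0) {
    stop("leakage > 0 requires at least one sensitive strain", call. = FALSE)
  }
  class(spec) <- "panel_spec"
  spec
}

#' Generate a synthetic annotation panel with planted resistome signatures
#'
#' Emits one annotation table per strain honoring the membership rules of
#' [panel_spec()], plus a ground-truth manifest: core keys in every strain;
#' planted keyword-matching keys in the query strain and a random non-empty
#' subset of the resistant strains; a leakage-chosen complement of those keys
#' copied into sensitive strains; and private noise keys per strain. Strain
#' metadata (synthetic D10 doses consistent with each class) is generated
#' alongside, so the full pipeline -- classification, matrix construction,
#' keyword filter, shared/exclusive extraction -- can run end to end against
#' a known answer.
#'
#' @param spec A `panel_spec` (or arguments forwarded to [panel_spec()]).
#' @return Object of class `synthetic_panel`: list with `tables` (list of
#'   [annotation_table]s), `truth` (core / planted-shared / planted-exclusive
#'   key ids, per-strain key-id sets, the spec, RNG description), and `panel`
#'   (strain metadata data frame with synthetic D10 doses).
#' @export
generate_panel <- function(spec = panel_spec()) {
  if (!inherits(spec, "panel_spec")) stop("spec must be a panel_spec", call. = FALSE)
  .with_seed(spec$seed, {
    strains <- c(sprintf("QRY%02d", seq_len(spec$n_query)),
                 sprintf("RES%02d", seq_len(spec$n_resistant)),
                 if (spec$n_sensitive > 0) sprintf("SEN%02d", seq_len(spec$n_sensitive)))
    query <- strains[1]
    resistant <- grep("^RES", strains, value = TRUE)
    sensitive <- grep("^SEN", strains, value = TRUE)

    nxt <- 1L
    take <- function(n, with_keyword) {
      rows <- .vocab_rows(n, with_keyword, start = nxt)
      nxt <<- nxt + as.integer(n)
      rows
    }
    core <- take(spec$n_core, with_keyword = FALSE)
    planted <- take(spec$n_shared_planted, with_keyword = TRUE)

    # resistant membership: each planted key lands in a non-empty subset
    res_member <- matrix(stats::runif(spec$n_shared_planted * spec$n_resistant) < 0.5,
                         nrow = max(spec$n_shared_planted, 0),
                         ncol = spec$n_resistant)
    if (spec$n_shared_planted > 0) {
      none <- rowSums(res_member) == 0
      res_member[cbind(which(none), sample(spec$n_resistant, sum(none), TRUE))] <- TRUE
    }

    # leakage: a fixed-size subset of planted keys is copied into one random
    # sensitive strain each; the rest is the planted exclusive set
    n_leak <- round(spec$leakage * spec$n_shared_planted)
    leak_idx <- if (n_leak > 0) sort(sample(spec$n_shared_planted, n_leak)) else integer(0)
    leak_target <- if (n_leak > 0) sample(spec$n_sensitive, n_leak, TRUE) else integer(0)

    per_strain_rows <- stats::setNames(vector("list", length(strains)), strains)
    for (s in strains) per_strain_rows[[s]] <- core
    if (spec$n_shared_planted > 0) {
      per_strain_rows[[query]] <- rbind(per_strain_rows[[query]], planted)
      for (j in seq_along(resistant)) {
        sel <- planted[res_member[, j], , drop = FALSE]
        per_strain_rows[[resistant[j]]] <- rbind(per_strain_rows[[resistant[j]]], sel)
      }
      for (k in seq_along(leak_idx)) {
        s <- sensitive[leak_target[k]]
        per_strain_rows[[s]] <- rbind(per_strain_rows[[s]],
                                      planted[leak_idx[k], , drop = FALSE])
      }
    }
    for (s in strains) {
      if (spec$n_noise_per_strain > 0) {
        kw <- stats::runif(spec$n_noise_per_strain) < spec$keyword_fraction_noise
        noise <- rbind(take(sum(!kw), with_keyword = FALSE),
                       take(sum(kw), with_keyword = TRUE))
        per_strain_rows[[s]] <- rbind(per_strain_rows[[s]], noise)
      }
      if (spec$duplicate_rate > 0) {
        rows <- per_strain_rows[[s]]
        dup <- which(stats::runif(nrow(rows)) < spec$duplicate_rate)
        if (length(dup)) per_strain_rows[[s]] <- rbind(rows, rows[dup, , drop = FALSE])
      }
    }
    tables <- lapply(strains, function(s)
      annotation_table(per_strain_rows[[s]], strain_id = s,
                       source = paste0("synthetic:", s)))

    key_ids_of <- function(rows) {
      if (nrow(rows) == 0) return(character(0))
      unique(function_key_id(normalize_text(rows$Category),
                             normalize_text(rows$Subcategory),
                             normalize_text(rows$Subsystem),
                             normalize_text(rows$Role)))
    }
    planted_ids <- key_ids_of(planted)
    exclusive_ids <- setdiff(planted_ids, planted_ids[leak_idx])
    truth <- list(
      core_keys = sort(key_ids_of(core)),
      planted_shared_keys = sort(planted_ids),
      planted_exclusive_keys = sort(exclusive_ids),
      per_strain = lapply(per_strain_rows, function(r) sort(key_ids_of(r))),
      query = query, resistant = resistant, sensitive = sensitive,
      spec = unclass(spec),
      rng = paste(.RNG_KIND, collapse = "/"))

    panel_df <- data.frame(
      strain = strains,
      class = c("query", rep("", length(strains) - 1)),
      d10 = c("", sprintf("%.2f", stats::runif(length(resistant), 2.2, 9.5)),
              if (length(sensitive)) sprintf("%.2f", stats::runif(length(sensitive), 0.1, 1.5))),
      unit = c("", rep("kGy", length(strains) - 1)),
      accession = "",
      stringsAsFactors = FALSE)
    # extra query replicates are typed but carry no dose
    if (spec$n_query > 1) {
      extra <- seq(2, spec$n_query)
      panel_df$class[extra] <- "query-replicate"
      panel_df$d10[extra] <- ""
      panel_df$unit[extra] <- ""
    }

    structure(list(tables = tables, truth = truth, panel = panel_df, spec = spec),
              class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("Synthetic panel (seed ", x$spec$seed, "): ",
      length(x$tables), " strains, query ", x$truth$query, "\n",
      "  core ", length(x$truth$core_keys), " keys; planted shared ",
      length(x$truth$planted_shared_keys), "; planted exclusive ",
      length(x$truth$planted_exclusive_keys), "; noise ",
      x$spec$n_noise_per_strain, "/strain\n", sep = "")
  invisible(x)
}

#' Write a synthetic panel to disk
#'
#' Emits one annotation file per strain (`<strain>.<format>`), the strain
#' metadata as `panel.tsv`, the default keyword list as `keywords.txt`, and
#' the ground-truth manifest as `truth.json`. All files are deterministic
#' functions of the panel object, so two runs with the same spec and seed are
#' byte-identical.
#'
#' @param sim A `synthetic_panel` from [generate_panel()].
#' @param out_dir Output directory (created if needed).
#' @param format Annotation file format: `"tsv"`, `"csv"`, or `"xlsx"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_panel <- function(sim, out_dir, format = c("tsv", "csv", "xlsx")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tab in sim$tables) {
    p <- file.path(out_dir, paste0(tab$strain_id, ".", format))
    write_annotation_table(tab, p, format = format)
    paths[tab$strain_id] <- p
  }
  panel_path <- file.path(out_dir, "panel.tsv")
  .write_delim(sim$panel, panel_path, sep = "\t")
  paths["panel"] <- panel_path

  kw_path <- file.path(out_dir, "keywords.txt")
  file.copy(system.file("extdata", "default_keywords.txt", package = "panresistome"),
            kw_path, overwrite = TRUE)
  paths["keywords"] <- kw_path

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["truth"] <- truth_path
  invisible(paths)
}
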