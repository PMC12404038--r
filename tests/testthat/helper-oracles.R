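# Independent brute-force oracles and fixture builders. The oracles work on
# plain sets of descriptor tuples and never touch the matrix code paths they
# check.

# Tuple set for one annotation table: unique case-folded 4-tuples.
oracle_key_set <- function(table) {
  r <- table$records
  unique(paste(tolower(r$Category), tolower(r$Subcategory), tolower(r$Subsystem),
               tolower(r$Role), sep = "\x1f"))
}

# Brute-force presence tabulation: named list strain -> key set.
oracle_membership <- function(tables) {
  sets <- lapply(tables, oracle_key_set)
  names(sets) <- vapply(tables, function(t) t$strain_id, character(1))
  sets
}

# Presence matrix as a plain logical lookup from the oracle sets.
oracle_presence <- function(tables) {
  sets <- oracle_membership(tables)
  keys <- sort(unique(unlist(sets)), method = "radix")
  m <- vapply(sets, function(s) keys %in% s, logical(length(keys)))
  if (length(keys) == 1) m <- matrix(m, nrow = 1)
  dimnames(m) <- list(keys, names(sets))
  m
}

oracle_conserved <- function(tables, subset) {
  sets <- oracle_membership(tables)[subset]
  Reduce(intersect, sets)
}

oracle_shared <- function(sets_by_strain, query, resistant) {
  intersect(sets_by_strain[[query]],
            unique(unlist(sets_by_strain[resistant])))
}

oracle_exclusive <- function(shared, sets_by_strain, sensitive) {
  setdiff(shared, unique(unlist(sets_by_strain[sensitive])))
}

# Random small panel: a pool of keys, each strain carrying a random subset
# (so strains overlap), returned as annotation_table objects.
random_panel <- function(n_strains = NULL, max_keys = 200, seed = 1) {
  set.seed(seed)
  if (is.null(n_strains)) n_strains <- sample(2:8, 1)
  n_pool <- sample(10:max_keys, 1)
  pool <- rbind(generate_vocabulary(ceiling(n_pool * 0.7), FALSE, seed = seed),
                generate_vocabulary(floor(n_pool * 0.3), TRUE, seed = seed + 1))
  set.seed(seed + 2)
  lapply(seq_len(n_strains), function(i) {
    n_take <- sample(seq_len(nrow(pool)), 1)
    rows <- pool[sample(nrow(pool), n_take), , drop = FALSE]
    annotation_table(rows, strain_id = sprintf("S%02d", i))
  })
}

# Tiny literal table used across the matrix examples:
# strain A = {k1, k2}, strain B = {k1, k3}
tiny_tables <- function() {
  k1 <- c("Carbohydrates", "", "Glycolysis", "Enolase (EC 4.2.1.11)")
  k2 <- c("Carbohydrates", "", "Glycolysis", "Pyruvate kinase (EC 2.7.1.40)")
  k3 <- c("Stress Response", "", "Oxidative stress", "Catalase (EC 1.11.1.6)")
  mk <- function(rows, id) {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    colnames(df) <- c("Category", "Subcategory", "Subsystem", "Role")
    annotation_table(df, strain_id = id)
  }
  list(A = mk(list(k1, k2), "A"), B = mk(list(k1, k3), "B"))
}

# Brute-force agglomerative clustering reproducing stats::hclust leaf-order
# conventions: merge the closest pair (linkage over all inter-cluster leaf
# pairs for "average"/"single"/"complete"), code singletons negatively,
# store each merge with singletons before clusters (ascending |code| within
# a kind), and read leaves off the merge tree depth-first.
oracle_leaf_order <- function(m, linkage = "average") {
  stopifnot(nrow(m) >= 2)
  d <- as.matrix(stats::dist(m))
  link <- switch(linkage, average = mean, single = min, complete = max,
                 stop("oracle supports average/single/complete"))
  members <- as.list(seq_len(nrow(m)))
  code <- -seq_len(nrow(m))
  merges <- list()
  while (length(members) > 1) {
    k <- length(members)
    bestd <- Inf
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        dd <- link(d[members[[i]], members[[j]]])
        if (dd < bestd) {
          bestd <- dd
          best <- c(i, j)
        }
      }
    }
    a <- code[best[1]]
    b <- code[best[2]]
    pair <- if (a < 0 && b < 0) {
      c(a, b)[order(abs(c(a, b)))]
    } else if (a < 0) c(a, b) else if (b < 0) c(b, a) else sort(c(a, b))
    merges[[length(merges) + 1]] <- pair
    joined <- c(members[[best[1]]], members[[best[2]]])
    members <- members[-best]
    code <- code[-best]
    members <- c(members, list(joined))
    code <- c(code, length(merges))
  }
  expand <- function(x) {
    if (x < 0) return(-x)
    c(expand(merges[[x]][1]), expand(merges[[x]][2]))
  }
  rownames(m)[expand(length(merges))]
}
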