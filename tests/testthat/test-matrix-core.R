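test_that("two overlapping strains give the expected 3x2 matrix", {
  tabs <- tiny_tables()
  pm <- build_presence_matrix(tabs)
  expect_equal(dim(pm), c(3L, 2L))
  expect_true(all(pm$values %in% c(0L, 1L)))
  expect_equal(unname(colSums(pm$values)), c(2, 2))
  # k1 (shared) is a row of ones; k2 only in A; k3 only in B
  shared <- pm$values[, "A"] == 1 & pm$values[, "B"] == 1
  expect_equal(sum(shared), 1)
  expect_equal(pm$keys$Role[shared], "Enolase (EC 4.2.1.11)")
  expect_equal(sum(pm$values[, "A"] == 1 & pm$values[, "B"] == 0), 1)
  expect_equal(sum(pm$values[, "A"] == 0 & pm$values[, "B"] == 1), 1)
})

test_that("a single strain yields an all-ones column", {
  tab <- tiny_tables()$A
  pm <- build_presence_matrix(list(tab))
  expect_equal(dim(pm), c(2L, 1L))
  expect_true(all(pm$values == 1L))
})

test_that("duplicate records collapse: adding duplicates never changes the matrix", {
  tabs <- tiny_tables()
  dup <- annotation_table(rbind(tabs$A$records, tabs$A$records,
                                tabs$A$records[1, , drop = FALSE]), "A")
  pm1 <- build_presence_matrix(list(tabs$A, tabs$B))
  pm2 <- build_presence_matrix(list(dup, tabs$B))
  expect_identical(pm1$values, pm2$values)
  expect_identical(pm1$key_ids, pm2$key_ids)
})

test_that("key identity is the full case-folded 4-tuple", {
  df <- data.frame(
    Category = c("Carbohydrates", "Stress Response", "CARBOHYDRATES"),
    Subcategory = "", Subsystem = c("S1", "S2", "s1"),
    Role = c("Enolase", "Enolase", "enolase"), stringsAsFactors = FALSE)
  pm <- build_presence_matrix(list(annotation_table(df, "A")))
  # same role under two contexts = two keys; case variants of one tuple = one
  expect_equal(nrow(pm$values), 2)
  # display form keeps first-seen casing
  expect_true("Carbohydrates" %in% pm$keys$Category)
  expect_false("CARBOHYDRATES" %in% pm$keys$Category)
})

test_that("input table order changes neither row order nor values", {
  tabs <- random_panel(n_strains = 5, max_keys = 80, seed = 31)
  pm1 <- build_presence_matrix(tabs)
  pm2 <- build_presence_matrix(rev(tabs))
  expect_identical(pm1$key_ids, pm2$key_ids)
  expect_identical(pm1$values, pm2$values[, colnames(pm1$values)])
  # column order follows input order
  expect_identical(colnames(pm2$values),
                   rev(vapply(tabs, function(t) t$strain_id, character(1))))
})

test_that("matrix construction matches the set-of-tuples oracle on random panels", {
  for (seed in 1:25) {
    tabs <- random_panel(max_keys = 120, seed = seed)
    pm <- build_presence_matrix(tabs)
    om <- oracle_presence(tabs)
    expect_identical(pm$key_ids, rownames(om), info = paste("seed", seed))
    expect_identical(colnames(pm$values), colnames(om), info = paste("seed", seed))
    expect_identical(unname(pm$values == 1L), unname(om), info = paste("seed", seed))
    # column sums equal distinct key counts of each input table
    expect_equal(unname(colSums(pm$values)),
                 unname(lengths(oracle_membership(tabs))),
                 info = paste("seed", seed))
  }
})

test_that("conserved_keys equals brute-force set intersection", {
  tabs <- tiny_tables()
  pm <- build_presence_matrix(tabs)
  expect_equal(conserved_keys(pm, c("A", "B"))$keys$Role, "Enolase (EC 4.2.1.11)")
  expect_equal(length(conserved_keys(pm, "A")$key_ids), 2) # identity on one strain
  expect_error(conserved_keys(pm, "nope"), "unknown strain")

  for (seed in 26:40) {
    tabs <- random_panel(max_keys = 100, seed = seed)
    pm <- build_presence_matrix(tabs)
    strains <- colnames(pm$values)
    sub <- sample(strains, sample(length(strains), 1))
    got <- conserved_keys(pm, sub)$key_ids
    expect_setequal(got, oracle_conserved(tabs, sub))
  }
})

test_that("conserved_fraction reports exact, one-decimal, and rounded forms", {
  tabs <- tiny_tables()
  pm <- build_presence_matrix(tabs)
  cf <- conserved_fraction(pm)
  expect_equal(cf$n_conserved, 1)
  expect_equal(cf$n_total, 3)
  expect_equal(cf$percent, 100 / 3)
  expect_equal(cf$percent_1dp, 33.3)
  expect_equal(cf$percent_rounded, 33)
  # identical strains -> 100%; disjoint strains -> 0%
  same <- build_presence_matrix(list(tiny_tables()$A, annotation_table(tiny_tables()$A$records, "B")))
  expect_equal(conserved_fraction(same)$percent, 100)
  k_only <- function(role, id) annotation_table(
    data.frame(Category = "C", Subcategory = "", Subsystem = "S", Role = role,
               stringsAsFactors = FALSE), id)
  disj <- build_presence_matrix(list(k_only("r1", "A"), k_only("r2", "B")))
  expect_equal(conserved_fraction(disj)$percent, 0)
})

test_that("category counts match a group-and-count oracle and conserve column sums", {
  tabs <- tiny_tables()
  cc <- category_counts(build_presence_matrix(tabs))
  get <- function(s, cat) cc$count[cc$strain_id == s & cc$category == cat]
  expect_equal(get("A", "Carbohydrates"), 2L)
  expect_equal(get("B", "Carbohydrates"), 1L)
  expect_equal(get("B", "Stress Response"), 1L)

  for (seed in 41:50) {
    tabs <- random_panel(max_keys = 100, seed = seed)
    pm <- build_presence_matrix(tabs)
    cc <- category_counts(pm)
    # per-strain totals equal matrix column sums
    totals <- tapply(cc$count, cc$strain_id, sum)
    expect_equal(as.vector(totals[colnames(pm$values)]),
                 unname(colSums(pm$values)))
    # spot-check against an independent tally from the oracle sets
    sets <- oracle_membership(tabs)
    s <- names(sets)[1]
    cats <- vapply(strsplit(sets[[s]], "\x1f", fixed = TRUE), `[`, character(1), 1)
    tal <- table(cats)
    for (cat in names(tal)) {
      expect_equal(cc$count[cc$strain_id == s & tolower(cc$category) == cat],
                   as.integer(tal[[cat]]))
    }
  }
})

test_that("matrix TSV writing round-trips through the reader", {
  dir <- withr::local_tempdir()
  pm <- build_presence_matrix(random_panel(n_strains = 4, max_keys = 60, seed = 77))
  p <- file.path(dir, "matrix.tsv")
  write_matrix(pm, p)
  back <- read_matrix(p)
  expect_identical(back$key_ids, pm$key_ids)
  expect_identical(back$values, pm$values)
  expect_identical(back$keys, pm$keys)
})

test_that("degenerate inputs are refused with clear errors", {
  expect_error(build_presence_matrix(list()), "at least one")
  tabs <- tiny_tables()
  expect_error(build_presence_matrix(list(tabs$A, annotation_table(tabs$A$records, "A"))),
               "duplicate strain_id")
})
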