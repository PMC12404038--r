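test_that("keyword filter retains descriptor substring matches, case-insensitively", {
  df <- data.frame(
    Category = c("Stress Response", "Membrane Transport", "Carbohydrates"),
    Subcategory = "",
    Subsystem = c("Oxidative stress", "Multidrug efflux pumps", "Glycolysis"),
    Role = c("Thiol peroxidase-Tpx-type (EC 1.11.1.15)",
             "RND transporter subunit", "Enolase"),
    stringsAsFactors = FALSE)
  pm <- build_presence_matrix(list(annotation_table(df, "A")))
  expect_true("Thiol peroxidase-Tpx-type (EC 1.11.1.15)" %in%
                filter_resistome(pm, "peroxid")$keys$Role)
  expect_equal(nrow(filter_resistome(pm, "EFFLUX")$keys), 1)
  expect_equal(nrow(filter_resistome(pm, "enolase")$keys), 1)
  expect_warning(out <- filter_resistome(pm, character(0)), "empty keyword")
  expect_equal(length(out$key_ids), 0)
})

test_that("keyword filtering is idempotent and searches all four descriptors", {
  sim <- generate_panel(panel_spec(seed = 5))
  pm <- build_presence_matrix(sim$tables)
  kw <- default_keywords()
  f1 <- filter_resistome(pm, kw)
  f2 <- filter_resistome(f1, kw)
  expect_identical(f1$key_ids, f2$key_ids)
  expect_identical(f1$values, f2$values)
  # a term only in the Category field still matches
  df <- data.frame(Category = "Stress Response", Subcategory = "",
                   Subsystem = "Misc", Role = "Uncharacterized protein",
                   stringsAsFactors = FALSE)
  pm1 <- build_presence_matrix(list(annotation_table(df, "A")))
  expect_equal(length(filter_resistome(pm1, "stress")$key_ids), 1)
})

test_that("dose conversion handles Gy, kGy, Mrad, and ranges", {
  expect_equal(d10_to_kgy(370, "Gy"), 0.37)
  expect_equal(d10_to_kgy(2, "kGy"), 2)
  expect_equal(d10_to_kgy(c(0.13, 0.25), "Mrad"), c(1.3, 2.5))
  expect_equal(d10_to_kgy(c(6, 12), "kGy"), c(6, 12))
  expect_error(d10_to_kgy(1, "rem"), "unknown dose unit")
  expect_error(d10_to_kgy(-1, "Gy"), "positive")
  expect_error(d10_to_kgy(c(5, 2), "Gy"), "low <= high")
})

test_that("D10 strings parse as single values or ranges with either dash", {
  expect_equal(parse_d10("370"), 370)
  expect_equal(parse_d10("6-12"), c(6, 12))
  expect_equal(parse_d10("0.13–0.25"), c(0.13, 0.25))
  expect_null(parse_d10(""))
  expect_null(parse_d10("-"))
})

test_that("the 2 kGy threshold classifies the panel doses as reported", {
  expect_equal(classify_strain(c(6, 12), "kGy"), "resistant")   # 6-12 kGy range
  expect_equal(classify_strain(370, "Gy"), "sensitive")          # 0.37 kGy
  expect_equal(classify_strain(2.0, "kGy"), "resistant")         # boundary inclusive
  expect_equal(classify_strain(1.999, "kGy"), "sensitive")
  # 0.13-0.25 Mrad = 1.3-2.5 kGy: resistant by upper endpoint, with a warning
  expect_warning(cls <- classify_strain(c(0.13, 0.25), "Mrad"), "straddles")
  expect_equal(cls, "resistant")
  # asserted class wins over any dose
  expect_equal(classify_strain(10, "kGy", asserted_class = "Sensitive"), "sensitive")
  expect_warning(u <- classify_strain(NULL), "unclassified")
  expect_equal(u, "unclassified")
})

test_that("classification is monotone non-decreasing in dose", {
  doses <- sort(stats::runif(50, 0.05, 10))
  classes <- vapply(doses, classify_strain, character(1), unit = "kGy")
  expect_true(all(diff(classes == "resistant") >= 0))
  expect_identical(classes[doses >= 2], rep("resistant", sum(doses >= 2)))
})

test_that("strain_panel derives classes from doses and keeps sets disjoint", {
  df <- data.frame(
    strain = c("PPS68", "Dr_R1", "PAMC25486", "Ec_K12"),
    class = c("query", "", "", "sensitive"),
    d10 = c("", "6-12", "370", ""),
    unit = c("", "kGy", "Gy", ""),
    stringsAsFactors = FALSE)
  panel <- strain_panel(df, query = "PPS68")
  expect_equal(panel$resistant, "Dr_R1")
  expect_setequal(panel$sensitive, c("PAMC25486", "Ec_K12"))
  expect_length(intersect(panel$resistant, panel$sensitive), 0)
  expect_false(panel$query %in% c(panel$resistant, panel$sensitive))
  expect_equal(panel$records$d10_kgy[panel$records$strain == "Dr_R1"], 12)
})

test_that("shared and exclusive sets follow the worked set-algebra examples", {
  mk <- function(roles, id) annotation_table(
    data.frame(Category = "Stress Response", Subcategory = "", Subsystem = "S",
               Role = roles, stringsAsFactors = FALSE), id)
  pm <- build_presence_matrix(list(mk(c("a", "b", "c"), "Q"),
                                   mk(c("b", "c", "d"), "R"),
                                   mk(c("c"), "S")))
  shared <- shared_resistome(pm, "Q", "R")
  expect_setequal(shared$keys$Role, c("b", "c"))
  excl <- exclusive_resistome(shared, pm, "S")
  expect_equal(excl$keys$Role, "b")
  # empty sensitive list: exclusive == shared
  expect_identical(exclusive_resistome(shared, pm, character(0))$key_ids,
                   shared$key_ids)
  # query disjoint from resistant: empty shared
  pm2 <- build_presence_matrix(list(mk(c("a"), "Q"), mk(c("b"), "R")))
  expect_length(shared_resistome(pm2, "Q", "R")$key_ids, 0)
  expect_error(shared_resistome(pm, "Q", character(0)), "empty")
  expect_error(shared_resistome(pm, "Q", "nope"), "unknown strain")
})

test_that("shared/exclusive extraction matches set-algebra oracles on random panels", {
  for (seed in 101:125) {
    tabs <- random_panel(max_keys = 100, seed = seed)
    if (length(tabs) < 3) next
    pm <- build_presence_matrix(tabs)
    strains <- colnames(pm$values)
    query <- strains[1]
    rest <- strains[-1]
    n_res <- sample(length(rest) - 1, 1)
    resistant <- rest[seq_len(n_res)]
    sensitive <- setdiff(rest, resistant)
    sets <- oracle_membership(tabs)
    shared <- shared_resistome(pm, query, resistant)
    expect_setequal(shared$key_ids, oracle_shared(sets, query, resistant))
    excl <- exclusive_resistome(shared, pm, sensitive)
    expect_setequal(excl$key_ids,
                    oracle_exclusive(oracle_shared(sets, query, resistant),
                                     sets, sensitive))
  }
})

test_that("monotonicity: sensitive strains only shrink exclusive, resistant only grow shared", {
  tabs <- random_panel(n_strains = 6, max_keys = 120, seed = 321)
  pm <- build_presence_matrix(tabs)
  strains <- colnames(pm$values)
  query <- strains[1]
  shared12 <- shared_resistome(pm, query, strains[2])
  shared123 <- shared_resistome(pm, query, strains[2:3])
  expect_true(all(shared12$key_ids %in% shared123$key_ids))
  excl1 <- exclusive_resistome(shared123, pm, strains[4])
  excl2 <- exclusive_resistome(shared123, pm, strains[4:5])
  expect_true(all(excl2$key_ids %in% excl1$key_ids))
})

test_that("the full protocol recovers a planted signature and keeps provenance", {
  sim <- generate_panel(panel_spec(n_core = 60, n_shared_planted = 25,
                                   n_noise_per_strain = 10, seed = 7))
  pm <- build_presence_matrix(sim$tables)
  panel <- strain_panel(sim$panel, query = sim$truth$query)
  sets <- run_two_class_protocol(pm, panel)
  expect_setequal(sets$exclusive$key_ids, sim$truth$planted_exclusive_keys)
  expect_true(all(sets$exclusive$key_ids %in% sets$shared$key_ids))
  expect_true(all(sets$shared$key_ids %in% sets$total$key_ids))
  expect_equal(sets$provenance$query, "QRY01")
  expect_length(sets$provenance$keywords, length(default_keywords()))
})

test_that("sensitive strains carrying every query key empty the exclusive set", {
  mk <- function(roles, id) annotation_table(
    data.frame(Category = "Stress Response", Subcategory = "", Subsystem = "S",
               Role = roles, stringsAsFactors = FALSE), id)
  pm <- build_presence_matrix(list(mk(c("a", "b"), "Q"), mk(c("a", "b"), "R"),
                                   mk(c("a", "b", "c"), "S")))
  panel <- strain_panel(data.frame(strain = c("Q", "R", "S"),
                                   class = c("query", "resistant", "sensitive"),
                                   stringsAsFactors = FALSE), query = "Q")
  sets <- run_two_class_protocol(pm, panel, keywords = "stress")
  expect_length(sets$exclusive$key_ids, 0)
  expect_length(sets$shared$key_ids, 2)
})

test_that("stress entries split into direct and keyword-identified counts", {
  df <- rbind(
    data.frame(Category = "Stress Response", Subcategory = "", Subsystem = "S",
               Role = sprintf("direct %d", 1:4), stringsAsFactors = FALSE),
    data.frame(Category = "Membrane Transport", Subcategory = "", Subsystem = "S",
               Role = sprintf("drug efflux pump %d", 1:3), stringsAsFactors = FALSE),
    data.frame(Category = "Carbohydrates", Subcategory = "", Subsystem = "S",
               Role = sprintf("enolase %d", 1:2), stringsAsFactors = FALSE))
  pm <- build_presence_matrix(list(annotation_table(df, "A")))
  s <- stress_entry_summary(pm)
  expect_equal(s$n_direct, 4)
  expect_equal(s$n_keyword_additional, 3)
  expect_equal(s$n_total, 7)
})
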