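test_that("reference generation is deterministic and hierarchy-consistent", {
  a <- gen_reference(50, seed = 3)
  b <- gen_reference(50, seed = 3)
  expect_identical(a, b)
  expect_length(a, 50)
  expect_false(any(duplicated(a)))
  # two species under one genus share every rank above species
  fields <- strsplit(unname(a), ";", fixed = TRUE)
  genus <- vapply(fields, `[`, character(1), 6)
  for (g in unique(genus[duplicated(genus)])) {
    members <- fields[genus == g]
    upper <- vapply(members, function(x) paste(x[1:6], collapse = ";"),
                    character(1))
    expect_length(unique(upper), 1L)
  }
  # forced phylum count covers every phylum
  r <- gen_reference(60, seed = 1, n_phyla = 15)
  expect_length(unique(vapply(strsplit(unname(r), ";"), `[`, character(1), 2)),
                15L)
})

test_that("planted hit tables reproduce their own expected assignments", {
  ref <- gen_reference(120, seed = 5)
  gh <- gen_hits(ref, n_queries = 500, seed = 6)
  a <- assign_taxonomy(gh$hits)
  a <- a[match(gh$truth$query_id, a$otu_id), ]
  got <- apply(a[, tax_ranks()], 1, function(x) {
    x <- x[x != ""]
    if (length(x) == 0) "" else format_lineage(x)
  })
  expect_equal(unname(got), gh$truth$expected_lineage)
  expect_equal(a$assigned_rank, gh$truth$expected_rank)
})

test_that("community generation is seed-deterministic", {
  a <- gen_community(seed = 8)
  b <- gen_community(seed = 8)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$env, b$env)
  expect_identical(a$truth$richness_target, b$truth$richness_target)
  expect_false(identical(a$table$counts, gen_community(seed = 9)$table$counts))
})

test_that("the default community carries the planted structures", {
  comm <- gen_community(seed = 12)
  tab <- comm$table
  # contaminants appear in every control and in true samples
  ctrl <- tab$counts[comm$truth$contaminant_ids, tab$roles != "true_sample"]
  expect_true(all(colSums(ctrl) > 0))
  # richness before decontamination ~ target + contaminants
  true_cols <- tab$roles == "true_sample"
  clean <- tab$counts[setdiff(rownames(tab$counts),
                              comm$truth$contaminant_ids), true_cols]
  expect_equal(unname(otu_richness(clean)),
               unname(comm$truth$richness_target))
  # oxygen missing for the configured fraction
  expect_equal(sum(is.na(comm$env$oxygen_saturation)),
               round(0.15 * sum(true_cols)))
  # depth strata populated as designed
  expect_equal(as.vector(table(classify_depth(comm$env$depth_m))[
    c("epibenthic", "mesobenthic", "bathybenthic")]), rep(30L, 3))
})

test_that("null designs show no spurious environmental correlation", {
  r_vals <- c()
  for (s in 1:8) {
    comm <- gen_community(community_design(effect_size = 0), seed = 400 + s)
    clr <- clr_transform(aggregate_taxa(comm$table, comm$assignments,
                                        "phylum"))
    clr <- clr[comm$env$sample_id, , drop = FALSE]
    grid <- correlation_grid(clr, comm$env,
                             continuous = c("latitude"),
                             categories = character(0))
    r_vals <- c(r_vals, grid$r[, "latitude"])
  }
  expect_lt(abs(mean(r_vals, na.rm = TRUE)), 0.05)
})

test_that("a planted negative oxygen loading is recovered as negative r", {
  neg <- 0
  for (s in 1:10) {
    comm <- gen_community(seed = 500 + s)
    clr <- clr_transform(aggregate_taxa(
      prevalence_filter(remove_contaminants(comm$table)$table),
      comm$assignments, "phylum"))
    clr <- clr[comm$env$sample_id, , drop = FALSE]
    grid <- correlation_grid(clr, comm$env)
    if (grid$r["phylum_05", "oxygen_saturation"] < 0) neg <- neg + 1
  }
  expect_gte(neg, 10 * 0.95 - 1)  # >= 95% of replicates, small-sample slack
})

test_that("planted contaminants surface in the decontamination report", {
  comm <- gen_community(seed = 44)
  res <- remove_contaminants(comm$table)
  profile_top <- names(sort(res$report$contamination_profile,
                            decreasing = TRUE))[1:5]
  expect_setequal(profile_top, comm$truth$contaminant_ids)
  expect_true(res$report$anchor_otu %in% comm$truth$contaminant_ids)
})
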