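hit_row <- function(bitscore, alen, pident = 99, query = "q1",
                    lineage = fixture_lineage_pool()[1]) {
  data.frame(query_id = query, subject_id = "s", pct_identity = pident,
             alignment_length = alen, evalue = 1e-20, bitscore = bitscore,
             lineage = lineage, lineage_missing = is.na(lineage),
             stringsAsFactors = FALSE)
}

test_that("low-score filtering distinguishes the or/and rules", {
  h <- rbind(hit_row(140, 90),    # fails both -> gone under both rules
             hit_row(200, 250),   # passes both
             hit_row(160, 90))    # fails length only
  or_cfg <- filter_config(low_score_rule = "or")
  and_cfg <- filter_config(low_score_rule = "and")
  expect_equal(threshold_filter(h, or_cfg)$bitscore, 200)
  expect_equal(sort(threshold_filter(h, and_cfg)$bitscore), c(160, 200))
  expect_equal(nrow(threshold_filter(h[0, ], or_cfg)), 0L)
})

test_that("margin filter keeps the top band, boundary inclusive", {
  h <- rbind(hit_row(500, 300), hit_row(491, 300), hit_row(489, 300))
  kept <- margin_filter(h, filter_config(margin_fraction = 0.02))
  expect_equal(sort(kept$bitscore), c(491, 500))      # cutoff at 490 exactly
  expect_equal(nrow(margin_filter(h[1, ], filter_config())), 1L)
  same <- rbind(hit_row(300, 300), hit_row(300, 300))
  expect_equal(nrow(margin_filter(same, filter_config())), 2L)
  expect_error(margin_filter(h[0, ], filter_config()), "non-empty")
})

test_that("single perfect hit is assigned to species with full audit", {
  h <- hit_row(800, 400, pident = 100)
  a <- assign_taxonomy(h)
  expect_equal(a$assigned_rank, "species")
  expect_equal(a$species, "Vibrio cholerae")
  expect_equal(a$n_hits_input, 1L)
  expect_equal(a$n_hits_after_margin, 1L)
  expect_equal(a$max_identity, 100)
})

test_that("assignment depth is the shallower of consensus and identity depth", {
  pool <- fixture_lineage_pool()
  # two hits agreeing to family (different genera), identity permits family
  h <- rbind(hit_row(500, 300, pident = 91, lineage = pool[1]),
             hit_row(498, 300, pident = 90.5, lineage = pool[3]))
  a <- assign_taxonomy(h)
  expect_equal(a$lca_rank, "family")
  expect_equal(a$assigned_rank, "family")
  expect_equal(a$family, "Vibrionaceae")
  expect_equal(a$genus, "")
  # same hits at species-grade identity: consensus caps the depth
  h2 <- transform(h, pct_identity = c(99.5, 99.2))
  expect_equal(assign_taxonomy(h2)$assigned_rank, "family")
  # congeneric pair at genus-grade identity: identity caps the depth
  h3 <- rbind(hit_row(500, 300, pident = 96, lineage = pool[1]),
              hit_row(499, 300, pident = 95.8, lineage = pool[2]))
  expect_equal(assign_taxonomy(h3)$assigned_rank, "genus")
})

test_that("queries with no retained hits come back unassigned, never dropped", {
  h <- rbind(hit_row(140, 90, query = "dead"),
             hit_row(800, 400, query = "alive"))
  a <- assign_taxonomy(h)
  expect_setequal(a$otu_id, c("dead", "alive"))
  dead <- a[a$otu_id == "dead", ]
  expect_equal(dead$assigned_rank, "unassigned")
  expect_equal(dead$n_hits_after_threshold, 0L)
  expect_true(all(a$n_hits_input >= a$n_hits_after_threshold))
  expect_true(all(a$n_hits_after_threshold >= a$n_hits_after_margin))
})

test_that("hits lacking a lineage are counted but excluded from consensus", {
  h <- rbind(hit_row(500, 300, pident = 99, lineage = NA),
             hit_row(495, 300, pident = 88,
                     lineage = fixture_lineage_pool()[4]))
  a <- assign_taxonomy(h)
  expect_equal(a$n_hits_after_margin, 2L)
  expect_equal(a$assigned_rank, "order")   # identity 88 permits order
  expect_equal(a$max_identity, 88)         # identity of lineage-bearing hits
  only_na <- hit_row(500, 300, lineage = NA)
  expect_equal(assign_taxonomy(only_na)$assigned_rank, "unassigned")
})

test_that("assignments are invariant under permutation of the hit rows", {
  set.seed(7)
  for (i in 1:25) {
    h <- do.call(rbind, lapply(1:4, function(q)
      random_hitset(paste0("q", q))))
    a1 <- assign_taxonomy(h)
    h_perm <- h[sample.int(nrow(h)), ]
    a2 <- assign_taxonomy(h_perm)
    a2 <- a2[match(a1$otu_id, a2$otu_id), ]
    rownames(a2) <- NULL
    expect_equal(a1, a2)
  }
})

test_that("consensus assignment matches the rank-by-rank oracle", {
  set.seed(11)
  for (i in 1:200) {
    h <- random_hitset("q")
    a <- assign_taxonomy(h)
    o <- oracle_assign(h)
    expect_equal(a$assigned_rank, o$rank, info = paste("case", i))
    got <- unlist(a[1, tax_ranks()], use.names = FALSE)
    expect_equal(got[got != ""], o$names, info = paste("case", i))
  }
})
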