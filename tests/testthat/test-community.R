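test_that("depth classification partitions the positive line", {
  expect_equal(classify_depth(150), "epibenthic")
  expect_equal(classify_depth(200), "mesobenthic")   # boundary closed below
  expect_equal(classify_depth(1000), "mesobenthic")  # boundary closed above
  expect_equal(classify_depth(2415), "bathybenthic")
  expect_error(classify_depth(0), "positive")
  # no gaps or overlaps over random depths
  set.seed(1)
  d <- exp(runif(500, log(1), log(6000)))
  z <- classify_depth(d)
  expect_true(all(z %in% c("epibenthic", "mesobenthic", "bathybenthic")))
  expect_identical(z == "epibenthic", d < 200)
  expect_identical(z == "bathybenthic", d > 1000)
})

test_that("region bands are lower-inclusive and ordered south to north", {
  b <- default_region_boundaries()
  expect_equal(classify_region(b[1] - 1), "Southern Red Sea")
  expect_equal(classify_region(b[1]), "South-Central Red Sea")  # on the cut
  expect_equal(classify_region(b[4] + 0.5), "Gulf of Aqaba")
  expect_equal(classify_region(5), "outside-domain")
  lat <- sort(runif(50, 12.5, 29.5))
  idx <- match(classify_region(lat), region_labels())
  expect_true(all(diff(idx) >= 0))                   # monotone in latitude
})

test_that("prevalence filtering drops OTUs seen in fewer than 3 samples", {
  counts <- rbind(two = c(5L, 8L, 0L, 0L),
                  three = c(1L, 1L, 1L, 0L),
                  zero = c(0L, 0L, 0L, 0L))
  colnames(counts) <- paste0("s", 1:4)
  tab <- otu_table(counts, stats::setNames(rep("true_sample", 4),
                                           colnames(counts)))
  kept <- prevalence_filter(tab)
  expect_identical(rownames(kept$counts), "three")
})

test_that("aggregation conserves totals and pools beyond top-k into other", {
  comm <- gen_community(seed = 5)
  tab <- prevalence_filter(remove_contaminants(comm$table)$table)
  agg <- aggregate_taxa(tab, comm$assignments, "phylum")
  expect_equal(colSums(agg), colSums(tab$counts))    # conservation, exact
  agg12 <- aggregate_taxa(tab, comm$assignments, "phylum", top_k = 12)
  expect_equal(colSums(agg12), colSums(tab$counts))
  expect_true("other" %in% rownames(agg12))
  expect_lte(nrow(agg12), 12 + 2)                    # + other + Unassigned
  # k beyond the number of phyla: nothing to pool
  agg_all <- aggregate_taxa(tab, comm$assignments, "phylum", top_k = 99)
  expect_false("other" %in% rownames(agg_all))
  expect_error(aggregate_taxa(tab, comm$assignments, "kingdom"), "rank")
})

test_that("phylum-class nested aggregation keeps two classes per phylum", {
  comm <- gen_community(seed = 5)
  tab <- prevalence_filter(remove_contaminants(comm$table)$table)
  nested <- aggregate_phylum_class(tab, comm$assignments,
                                   top_phyla = 4, top_classes = 2)
  expect_equal(colSums(nested), colSums(tab$counts))
  kept_phyla <- setdiff(unique(sub(";.*", "", rownames(nested))),
                        c("other", "Unassigned"))
  expect_lte(length(kept_phyla), 4)
  for (p in kept_phyla) {
    expect_lte(sum(startsWith(rownames(nested), paste0(p, ";")) &
                     !endsWith(rownames(nested), ";other")), 2)
  }
})

test_that("clr transform closes rows and matches the closed form", {
  m <- matrix(c(2, 4, 8), nrow = 3, dimnames = list(paste0("t", 1:3), "s1"))
  clr <- clr_transform(m, "none")
  expect_equal(as.numeric(clr), c(log(0.5), 0, log(2)))
  flat <- matrix(1, 4, 1, dimnames = list(paste0("t", 1:4), "s1"))
  expect_equal(as.numeric(clr_transform(flat, "none")), rep(0, 4))
  # row closure on a large table under every pseudocount mode
  comm <- gen_community(seed = 2)
  agg <- aggregate_taxa(comm$table, comm$assignments, "phylum")
  for (mode in c("add_one", "add_half_min", "multiplicative")) {
    x <- clr_transform(agg, mode)
    expect_true(all(abs(rowSums(x)) < 1e-9), info = mode)
    expect_true(all(is.finite(x)))
  }
  # scale invariance, exact, for positive data without pseudocount
  pos <- matrix(rlnorm(30), 5, 6,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
  expect_equal(unclass(clr_transform(pos * 7, "none")),
               unclass(clr_transform(pos, "none")))
  expect_error(clr_transform(matrix(0:1, 2, 1,
                                    dimnames = list(c("a", "b"), "s")),
                             "none"), "zero")
})

test_that("correlation grid matches a naive pairwise-complete oracle", {
  set.seed(21)
  clr <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(sprintf("s%02d", 1:20), paste0("t", 1:8)))
  class(clr) <- c("clr_matrix", "matrix", "array")
  env <- data.frame(sample_id = rownames(clr),
                    latitude = runif(20, 13, 29),
                    depth_m = runif(20, 20, 2400),
                    temperature = rnorm(20, 22),
                    salinity = rnorm(20, 40.5, 0.2),
                    oxygen_saturation = replace(runif(20, 10, 90),
                                                sample(20, 6), NA))
  env <- add_env_categories(env)
  grid <- correlation_grid(clr, env)
  for (v in c("latitude", "depth_m", "oxygen_saturation")) {
    for (j in 1:8) {
      expect_equal(grid$r[j, v], oracle_pearson(clr[, j], env[[v]]),
                   tolerance = 1e-12)
    }
  }
  # oxygen cells use only the observed subset
  expect_true(all(grid$n[, "oxygen_saturation"] == 14))
  # affine image of a covariate correlates perfectly
  clr2 <- clr; clr2[, 1] <- 3 * env$latitude + 2
  expect_equal(unname(correlation_grid(clr2, env)$r[1, "latitude"]), 1)
})

test_that("indicator correlations equal the point-biserial closed form", {
  set.seed(5)
  g <- rep(c(0, 1), c(8, 7))
  y <- rnorm(15) + g
  clr <- matrix(y, 15, 1, dimnames = list(sprintf("s%02d", 1:15), "t1"))
  env <- data.frame(sample_id = rownames(clr), grp = ifelse(g == 1, "hi", "lo"))
  grid <- correlation_grid(clr, env, continuous = character(0),
                           categories = "grp")
  n1 <- sum(g); n0 <- sum(!g); n <- length(g)
  rpb <- (mean(y[g == 1]) - mean(y[g == 0])) / sd(y) *
    sqrt(n1 * n0 / (n * (n - 1)))
  expect_equal(unname(grid$r["t1", "grp:hi"]), rpb, tolerance = 1e-12)
  expect_equal(unname(grid$r["t1", "grp:lo"]), -rpb, tolerance = 1e-12)
})

test_that("constant columns and tiny cells are missing, not zero", {
  clr <- matrix(rnorm(12), 4, 3,
                dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  clr[, 3] <- 5
  env <- data.frame(sample_id = paste0("s", 1:4), latitude = 1:4,
                    flat = rep(2, 4))
  grid <- correlation_grid(clr, env, continuous = c("latitude", "flat"),
                           categories = character(0))
  expect_true(is.na(grid$r["t3", "latitude"]))   # constant taxon
  expect_true(all(is.na(grid$r[, "flat"])))      # constant covariate
})
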