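random_rda_problem <- function(n = 15, q = 6, p = 2) {
  Y <- matrix(rnorm(n * q), n, q,
              dimnames = list(sprintf("s%02d", 1:n), paste0("t", 1:q)))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  # plant some association so constrained axes are non-trivial
  Y <- Y + X %*% matrix(rnorm(p * q), p, q)
  list(Y = Y, X = X)
}

test_that("eigenvalues match the hat-matrix oracle and decompose variance", {
  set.seed(31)
  for (i in 1:25) {
    pr <- random_rda_problem()
    fit <- rda_fit(pr$Y, pr$X)
    o <- oracle_rda_eig(pr$Y, pr$X)
    expect_equal(unname(fit$eig_constrained), o$constrained, tolerance = 1e-9)
    expect_equal(fit$eig_unconstrained, o$unconstrained, tolerance = 1e-9)
    expect_true(all(fit$eig_constrained >= -1e-10))
    expect_lte(length(fit$eig_constrained), ncol(pr$X))
    expect_equal(sum(fit$eig_constrained) + sum(fit$eig_unconstrained),
                 fit$total_variance, tolerance = 1e-9)
  }
})

test_that("rda agrees with the vegan reference on eigenvalues", {
  skip_if_not_installed("vegan")
  set.seed(99)
  pr <- random_rda_problem(n = 20, q = 7, p = 3)
  fit <- rda_fit(pr$Y, pr$X)
  ref <- vegan::rda(pr$Y ~ pr$X)
  expect_equal(unname(fit$eig_constrained), unname(ref$CCA$eig),
               tolerance = 1e-9)
  expect_equal(fit$eig_unconstrained, unname(ref$CA$eig), tolerance = 1e-9)
  expect_equal(fit$r2, unname(vegan::RsquareAdj(ref)$r.squared),
               tolerance = 1e-9)
})

test_that("saturated constraints reduce rda to principal components", {
  set.seed(17)
  n <- 12
  Y <- matrix(rnorm(n * 5), n, 5)
  X <- matrix(rnorm(n * (n - 1)), n, n - 1)   # full-rank basis of sample space
  fit <- rda_fit(Y, X)
  pc <- prcomp(Y)
  keep <- pc$sdev^2 > 1e-12
  expect_equal(unname(fit$eig_constrained), pc$sdev[keep]^2, tolerance = 1e-9)
  expect_equal(sum(fit$eig_unconstrained), 0, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("constraints orthogonal to the response constrain nothing", {
  n <- 20
  Y <- matrix(rep(c(-1, 1), n / 2), n, 3)       # alternating pattern
  X <- matrix(rep(c(1, 1, -1, -1), n / 4), n, 1) # orthogonal by construction
  fit <- rda_fit(Y, X)
  expect_equal(fit$r2, 0, tolerance = 1e-9)
})

test_that("rank-deficient constraints are dropped with a warning", {
  set.seed(4)
  pr <- random_rda_problem()
  X <- cbind(pr$X, dup = pr$X[, 1])
  expect_warning(fit <- rda_fit(pr$Y, X), "dependent")
  expect_equal(fit$m, 2L)
})

test_that("adjusted R2 follows the Ezekiel formula and its edge cases", {
  expect_equal(adjusted_r2(0.5, n = 10, m = 2), 1 - 0.5 * 9 / 7)
  expect_equal(adjusted_r2(0.3, n = 50, m = 0), 0.3)   # no penalty
  expect_lte(adjusted_r2(0, n = 20, m = 3), 0)
  expect_error(adjusted_r2(0.5, n = 4, m = 3), "undefined")
})

test_that("permutation test finds planted drivers and ignores duplicates", {
  set.seed(61)
  n <- 40
  x <- rnorm(n)
  Y <- matrix(rnorm(n * 5), n, 5) + outer(x, rep(1.5, 5))
  pt <- permutation_test(Y, NULL, x, n_perm = 199, seed = 8)
  expect_lte(pt$p_value, 0.01)
  # candidate already spanned by the conditioning set adds nothing
  pt2 <- permutation_test(Y, data.frame(x = x), x, n_perm = 199, seed = 8)
  expect_equal(pt2$statistic, 0)
  expect_equal(pt2$p_value, 1)
})

test_that("forward selection picks a lone planted driver and dedupes", {
  set.seed(13)
  n <- 30
  x <- rnorm(n)
  Y <- matrix(rnorm(n * 4), n, 4) + outer(x, rep(2, 4))
  one <- forward_select(Y, data.frame(x = x), n_perm = 199, seed = 2)
  expect_identical(one$selected, "x")
  dup <- forward_select(Y, data.frame(a = x, b = x), n_perm = 199, seed = 2)
  expect_identical(dup$selected, "a")   # input-order tie-break, one of the pair
  # pure noise: empty selection is a valid result
  null <- forward_select(matrix(rnorm(n * 4), n, 4),
                         data.frame(z = rnorm(n)), n_perm = 199, seed = 2)
  expect_length(null$selected, 0)
  expect_equal(null$r2, 0)
})

test_that("selection is stable under candidate column reordering", {
  comm <- gen_community(seed = 11)
  clr <- clr_transform(aggregate_taxa(
    prevalence_filter(remove_contaminants(comm$table)$table),
    comm$assignments, "phylum"))
  env <- comm$env
  ok <- !is.na(env$oxygen_saturation)
  cand <- env[ok, c("latitude", "depth_m", "oxygen_saturation")]
  a <- forward_select(clr[env$sample_id[ok], ], cand, n_perm = 199, seed = 5)
  b <- forward_select(clr[env$sample_id[ok], ], rev(cand), n_perm = 199,
                      seed = 5)
  expect_setequal(a$selected, b$selected)
})

test_that("planted environmental drivers are recovered on the default design", {
  recovered <- 0
  for (s in 1:10) {
    comm <- gen_community(seed = 100 + s)
    clr <- clr_transform(aggregate_taxa(
      prevalence_filter(remove_contaminants(comm$table)$table),
      comm$assignments, "phylum"))
    env <- comm$env
    ok <- !is.na(env$oxygen_saturation)
    fit <- forward_select(clr[env$sample_id[ok], ],
                          env[ok, c("latitude", "depth_m",
                                    "oxygen_saturation")],
                          n_perm = 199, seed = s)
    if (setequal(fit$selected,
                 c("latitude", "depth_m", "oxygen_saturation")))
      recovered <- recovered + 1
  }
  expect_gte(recovered, 9)
})
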