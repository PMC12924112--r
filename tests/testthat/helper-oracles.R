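# Independent oracles, written against the documented rules rather than the
# package internals: rank-by-rank consensus assignment, naive Pearson, and a
# hat-matrix eigendecomposition for constrained ordination.

# Brute-force consensus assignment for a single query's hits. Applies the
# rules rank by rank: low-score exclusion, bitscore margin, agreement of all
# retained names at each rank from the top, then the identity-permitted
# depth from a cutoff table walked from species upward.
oracle_assign <- function(h, bitscore_min = 150, alen_min = 100,
                          margin = 0.02,
                          cutoffs = c(98, 95, 90, 85, 80, 75)) {
  keep <- h[h$bitscore >= bitscore_min & h$alignment_length >= alen_min, ,
            drop = FALSE]
  if (nrow(keep) > 0) {
    keep <- keep[keep$bitscore >= (1 - margin) * max(keep$bitscore), ,
                 drop = FALSE]
  }
  keep <- keep[!is.na(keep$lineage), , drop = FALSE]
  if (nrow(keep) == 0) {
    return(list(names = character(0), rank = "unassigned"))
  }
  fields <- lapply(strsplit(keep$lineage, ";", fixed = TRUE), function(x) {
    length(x) <- 7
    x[is.na(x)] <- ""
    x
  })
  agree_depth <- 0
  for (d in 1:7) {
    nm <- vapply(fields, `[`, character(1), d)
    if (all(nm != "") && length(unique(nm)) == 1) agree_depth <- d else break
  }
  max_id <- max(keep$pct_identity)
  id_depth <- match(TRUE, max_id > cutoffs)        # 1 = species ... 6 = phylum
  id_depth <- if (is.na(id_depth)) 0 else 8 - id_depth
  depth <- min(agree_depth, id_depth)
  if (depth == 0) {
    list(names = character(0), rank = "unassigned")
  } else {
    list(names = fields[[1]][seq_len(depth)], rank = tax_ranks()[depth])
  }
}

# Naive per-pair Pearson on pairwise-complete observations.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  sum((x[ok] - mean(x[ok])) * (y[ok] - mean(y[ok]))) /
    ((sum(ok) - 1) * sd(x[ok]) * sd(y[ok]))
}

# Constrained-ordination eigenvalues through the explicit hat matrix,
# H = X (X'X)^-1 X', applied to the centred response; residual eigenvalues
# from (I - H) Y.
oracle_rda_eig <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  n <- nrow(Yc)
  fit <- H %*% Yc
  ev_c <- eigen(crossprod(fit) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  res <- Yc - fit
  ev_u <- eigen(crossprod(res) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  list(constrained = ev_c[ev_c > 1e-9],
       unconstrained = ev_u[ev_u > 1e-9])
}
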