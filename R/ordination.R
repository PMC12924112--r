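#' Redundancy analysis of a multivariate response
#'
#' Constrained ordination by least squares: the response matrix is column
#' centred, regressed on the centred constraint matrix, and the fitted
#' values are eigen-decomposed; the residual matrix gives the unconstrained
#' axes. Eigenvalues are on the variance scale (sums of squares divided by
#' `n - 1`), so constrained plus residual eigenvalues add up to the total
#' response variance. Rank-deficient constraint matrices are handled by
#' dropping linearly dependent columns with a warning.
#'
#' Scores are reported in correlation-style (type 2) scaling: species
#' scores are eigenvectors scaled by the square root of their eigenvalue,
#' and site scores (both the observation-based `sites` and the fitted
#' `sites_lc`) are scaled to unit variance per axis. Axis signs are fixed
#' by making the largest-magnitude species loading of each axis positive.
#'
#' @param response Numeric matrix, samples x taxa (e.g. a `clr_matrix`).
#' @param constraints Numeric matrix or data.frame of covariates, one row
#'   per sample; factor/character columns are expanded to indicator
#'   contrasts.
#' @return A list of class `rda_result`: `eig_constrained`,
#'   `eig_unconstrained`, `species_scores`, `site_scores`,
#'   `site_scores_lc`, `biplot_scores`, `total_variance`, `r2`,
#'   `constraint_names`, `n`, `m` (number of constraint columns used).
#' @export
rda_fit <- function(response, constraints) {
  Y <- as.matrix(response)
  X <- expand_covariates(constraints)
  stopifnot(nrow(Y) == nrow(X))
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  dec <- qr(Xc)
  rank <- dec$rank
  if (rank < ncol(Xc)) {
    dropped <- colnames(Xc)[dec$pivot[-seq_len(rank)]]
    warning("dropping linearly dependent constraint column(s): ",
            paste(dropped, collapse = ", "))
  }
  Q <- qr.Q(dec)[, seq_len(rank), drop = FALSE]
  Yhat <- Q %*% crossprod(Q, Yc)
  total <- sum(Yc^2) / (n - 1)

  eig_c <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  kc <- which(eig_c$values > max(1e-12 * max(eig_c$values, 0), 1e-12))
  kc <- kc[kc <= rank]
  lam <- eig_c$values[kc]
  V <- eig_c$vectors[, kc, drop = FALSE]
  # sign convention: largest-magnitude loading of each axis positive
  if (length(kc) > 0L) {
    flip <- apply(V, 2L, function(v) sign(v[which.max(abs(v))]))
    V <- sweep(V, 2L, flip, "*")
  }
  rownames(V) <- colnames(Y)
  colnames(V) <- axis_names("RDA", length(kc))

  resid <- Yc - Yhat
  eig_u <- eigen(crossprod(resid) / (n - 1), symmetric = TRUE)
  eig_u <- eig_u$values[eig_u$values > 1e-12 * max(eig_u$values, 1e-12)]

  if (length(kc) > 0L) {
    sites <- Yc %*% V
    sites_lc <- Yhat %*% V
    unitize <- function(S) {
      sdv <- apply(S, 2L, stats::sd)
      sweep(S, 2L, ifelse(sdv > 0, sdv, 1), "/")
    }
    sites <- unitize(sites)
    sites_lc <- unitize(sites_lc)
    species <- sweep(V, 2L, sqrt(lam), "*")
    biplot <- suppressWarnings(stats::cor(Xc[, colnames(X), drop = FALSE],
                                          sites_lc))
  } else {
    sites <- sites_lc <- matrix(0, n, 0)
    species <- matrix(0, ncol(Y), 0)
    biplot <- matrix(0, ncol(X), 0)
  }
  structure(list(eig_constrained = stats::setNames(lam, colnames(V)),
                 eig_unconstrained = eig_u,
                 species_scores = species,
                 site_scores = sites, site_scores_lc = sites_lc,
                 biplot_scores = biplot,
                 total_variance = total,
                 r2 = sum(lam) / total,
                 constraint_names = colnames(X)[seq_len(rank)],
                 n = n, m = rank),
            class = "rda_result")
}

axis_names <- function(prefix, k) {
  if (k == 0L) character(0) else paste0(prefix, seq_len(k))
}

# Expand a covariate data.frame to a numeric matrix: numeric columns pass
# through, factor/character columns become one indicator per non-reference
# level. A plain matrix passes through unchanged.
expand_covariates <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    return(x)
  }
  x <- as.data.frame(x)
  cols <- list()
  for (v in names(x)) {
    if (is.numeric(x[[v]])) {
      cols[[v]] <- matrix(x[[v]], ncol = 1L, dimnames = list(NULL, v))
    } else {
      f <- factor(x[[v]])
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(v, levels(f)[-1L])
      cols[[v]] <- mm
    }
  }
  do.call(cbind, cols)
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("rda_result: %d constrained axes, %.1f%% of variance constrained\n",
              length(x$eig_constrained), 100 * x$r2))
  invisible(x)
}

#' Adjusted R-squared of a constrained ordination
#'
#' `R2adj = 1 - (1 - R2) (n - 1) / (n - m - 1)` for `n` samples and `m`
#' constraint columns; undefined (error) when `n - m - 1 <= 0`.
#'
#' @param r2 Either an `rda_result` or a plain R-squared value.
#' @param n,m Sample count and constraint-column count (taken from the
#'   `rda_result` when one is given).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n = NULL, m = NULL) {
  if (inherits(r2, "rda_result")) {
    n <- r2$n; m <- r2$m; r2 <- r2$r2
  }
  if (n - m - 1 <= 0)
    stop("adjusted R2 undefined: n - m - 1 <= 0")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Permutation test of one candidate constraint
#'
#' Tests whether `candidate` explains variance in `response` beyond the
#' already-selected constraints in `conditioning`. Both the response and
#' the candidate are residualised on the conditioning terms (reduced-model
#' residual permutation), the candidate's pseudo-F is computed, and the
#' rows of the residualised candidate are permuted to build the null
#' distribution; `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param response Samples x taxa matrix.
#' @param conditioning Matrix/data.frame of already-selected covariates, or
#'   `NULL`.
#' @param candidate One covariate: numeric vector, single-column matrix, or
#'   factor (expanded to an indicator block tested jointly).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream; `NULL` continues
#'   the caller's RNG stream.
#' @return List with `statistic` (pseudo-F), `p_value`, `n_perm`, `df`.
#' @export
permutation_test <- function(response, conditioning, candidate,
                             n_perm = 999L, seed = NULL) {
  stopifnot(n_perm >= 99L)
  if (!is.null(seed)) set.seed(seed)
  Y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  cand <- expand_covariates(if (is.data.frame(candidate) || is.matrix(candidate))
    candidate else data.frame(candidate = candidate))
  p0 <- 0L
  if (!is.null(conditioning) && NCOL(conditioning) > 0L) {
    X0 <- scale(expand_covariates(conditioning), center = TRUE, scale = FALSE)
    q0 <- qr(X0)
    p0 <- q0$rank
    Q0 <- qr.Q(q0)[, seq_len(p0), drop = FALSE]
    Y <- Y - Q0 %*% crossprod(Q0, Y)
    cand <- cand - Q0 %*% crossprod(Q0, scale(cand, center = TRUE, scale = FALSE))
  }
  cand <- scale(cand, center = TRUE, scale = FALSE)
  # a candidate spanned by the conditioning terms leaves only roundoff:
  # drop columns whose residual norm is negligible
  norms <- sqrt(colSums(cand^2))
  cand <- cand[, norms > 1e-8 * max(norms, 1), drop = FALSE]
  if (ncol(cand) == 0L)
    return(list(statistic = 0, p_value = 1, n_perm = n_perm,
                df = c(0, n - 1 - p0)))
  qc <- qr(cand)
  q <- qc$rank
  if (q == 0L)
    return(list(statistic = 0, p_value = 1, n_perm = n_perm, df = c(0, n - 1 - p0)))
  Qc <- qr.Q(qc)[, seq_len(q), drop = FALSE]
  ss_tot <- sum(Y^2)
  df_res <- n - 1L - p0 - q
  fstat <- function(Qp) {
    ss_fit <- sum(crossprod(Qp, Y)^2)
    (ss_fit / q) / ((ss_tot - ss_fit) / df_res)
  }
  obs <- fstat(Qc)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (fstat(Qc[sample.int(n), , drop = FALSE]) >= obs) exceed <- exceed + 1L
  }
  list(statistic = obs, p_value = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, df = c(q, df_res))
}

#' Forward selection of environmental constraints
#'
#' Greedy stepwise construction of a constrained ordination model: at each
#' step the candidate giving the largest adjusted-R-squared gain is
#' examined; it enters the model only if its reduced-model permutation
#' p-value is at most `alpha`, subject to the adjusted-R-squared ceiling of
#' the full model containing all candidates (the double stopping rule of
#' stepwise ordination). Factor candidates enter and leave as indicator
#' blocks. Ties in gain are broken by candidate input order.
#'
#' Two ceiling conventions are offered. The default, `"selected"`, stops
#' the search once the *already selected* model has reached the full
#' model's adjusted R-squared. The `"candidate"` convention instead
#' refuses any step whose *resulting* model would exceed the full model's
#' adjusted R-squared. The two differ materially in one situation: when
#' the remaining candidates are uninformative, the adjusted R-squared of
#' the model holding all true drivers and that of the full model are equal
#' in expectation (the adjustment exactly offsets the variance a noise
#' covariate absorbs), so the `"candidate"` rule degenerates to a coin
#' flip on whether the last informative variable may enter. The
#' `"selected"` rule keeps the ceiling's protection against overfitting
#' past the full model while letting every informative step be decided by
#' its permutation test.
#'
#' @param response Samples x taxa matrix.
#' @param candidates Data frame of candidate covariates (one column each;
#'   factors allowed).
#' @param alpha Entry significance level (default 0.05).
#' @param n_perm Permutations per entry test (default 999).
#' @param seed Integer seed fixing the whole selection's permutation
#'   stream.
#' @param ceiling Full-model adjusted-R-squared stopping convention,
#'   `"selected"` (default) or `"candidate"`; see Details.
#' @return An `rda_result` fitted on the selected covariates (an empty
#'   selection yields `NULL` ordination fields), augmented with `selected`
#'   (names in selection order) and `trace` (data frame: step, variable,
#'   r2, adj_r2, p_value).
#' @export
forward_select <- function(response, candidates, alpha = 0.05,
                           n_perm = 999L, seed = 1L,
                           ceiling = c("selected", "candidate")) {
  ceiling <- match.arg(ceiling)
  stopifnot(is.data.frame(candidates), ncol(candidates) >= 1L)
  set.seed(seed)
  Y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  ss_tot <- sum(Y^2)
  blocks <- lapply(names(candidates), function(v)
    expand_covariates(candidates[, v, drop = FALSE]))
  names(blocks) <- names(candidates)
  ncols <- vapply(blocks, ncol, integer(1))

  r2_of <- function(vars) {
    X <- scale(do.call(cbind, blocks[vars]), center = TRUE, scale = FALSE)
    d <- qr(X)
    Q <- qr.Q(d)[, seq_len(d$rank), drop = FALSE]
    list(r2 = sum(crossprod(Q, Y)^2) / ss_tot, m = d$rank)
  }
  full <- r2_of(names(blocks))
  adj_full <- adjusted_r2(full$r2, n, full$m)

  selected <- character(0)
  trace <- data.frame(step = integer(0), variable = character(0),
                      r2 = numeric(0), adj_r2 = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  adj_cur <- 0
  repeat {
    if (ceiling == "selected" && adj_cur > adj_full + 1e-8) break
    remaining <- setdiff(names(blocks), selected)
    if (length(remaining) == 0L) break
    cand_adj <- vapply(remaining, function(v) {
      fit <- r2_of(c(selected, v))
      if (n - fit$m - 1 <= 0) return(-Inf)
      adjusted_r2(fit$r2, n, fit$m)
    }, numeric(1))
    best <- remaining[which.max(cand_adj)]
    gain <- max(cand_adj) - adj_cur
    if (!is.finite(gain) || gain <= 0) break
    # the tolerance absorbs QR roundoff when the candidate model is the
    # full model under a different column order
    if (ceiling == "candidate" && max(cand_adj) > adj_full + 1e-8) break
    cond <- if (length(selected) > 0L)
      do.call(cbind, blocks[selected]) else NULL
    pt <- permutation_test(response, cond, blocks[[best]],
                           n_perm = n_perm, seed = NULL)
    if (pt$p_value > alpha) break
    selected <- c(selected, best)
    fit <- r2_of(selected)
    adj_cur <- adjusted_r2(fit$r2, n, fit$m)
    trace <- rbind(trace, data.frame(step = length(selected), variable = best,
                                     r2 = fit$r2, adj_r2 = adj_cur,
                                     p_value = pt$p_value,
                                     stringsAsFactors = FALSE))
  }
  result <- if (length(selected) > 0L) {
    rda_fit(response, do.call(cbind, blocks[selected]))
  } else {
    structure(list(eig_constrained = numeric(0), eig_unconstrained = numeric(0),
                   total_variance = sum(Y^2) / (n - 1), r2 = 0,
                   n = n, m = 0L), class = "rda_result")
  }
  result$selected <- selected
  result$trace <- trace
  result$adj_r2_full <- adj_full
  result
}
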