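#' Classify seafloor depth into benthic zones
#'
#' Depth strata follow the standard benthic zonation: epibenthic shallower
#' than 200 m, mesobenthic 200-1000 m (both boundaries inclusive),
#' bathybenthic deeper than 1000 m.
#'
#' @param depth_m Positive seafloor depth(s) in metres.
#' @return Character vector of `"epibenthic"`, `"mesobenthic"`,
#'   `"bathybenthic"`.
#' @export
classify_depth <- function(depth_m) {
  if (any(is.na(depth_m)) || any(depth_m <= 0))
    stop("depth_m must be positive")
  ifelse(depth_m < 200, "epibenthic",
         ifelse(depth_m <= 1000, "mesobenthic", "bathybenthic"))
}

#' Default Red Sea region latitude boundaries
#'
#' Four latitude cut points (decimal degrees N) splitting the Red Sea's
#' roughly 12.5-29.5 degree latitudinal span into five bands, south to
#' north: Southern Red Sea, South-Central, North-Central, Northern Red Sea,
#' Gulf of Aqaba. The published regionalisations of the basin do not print
#' coordinates, so these defaults are configuration values chosen to span
#' the basin evenly north of the southern entrance; override them to match
#' any specific scheme.
#'
#' @return Numeric vector of 4 increasing latitude cut points.
#' @export
default_region_boundaries <- function() c(17, 20.5, 24, 28)

#' Region labels, south to north
#' @return Character vector of the five region labels.
#' @export
region_labels <- function() {
  c("Southern Red Sea", "South-Central Red Sea", "North-Central Red Sea",
    "Northern Red Sea", "Gulf of Aqaba")
}

#' Classify latitude into geographical regions
#'
#' Band membership over the five latitude bands defined by four sorted cut
#' points; a latitude exactly on a cut belongs to the band whose lower
#' bound it is. Latitudes outside `domain` get the explicit label
#' `"outside-domain"`.
#'
#' @param latitude Latitude(s) in decimal degrees.
#' @param boundaries Sorted numeric vector of 4 cut points.
#' @param domain Length-2 numeric range of valid latitudes.
#' @return Character vector of region labels.
#' @export
classify_region <- function(latitude, boundaries = default_region_boundaries(),
                            domain = c(12.5, 29.5)) {
  stopifnot(length(boundaries) == 4L, !is.unsorted(boundaries, strictly = TRUE))
  idx <- findInterval(latitude, boundaries) + 1L  # lower bound inclusive
  out <- region_labels()[idx]
  out[latitude < domain[1L] | latitude > domain[2L]] <- "outside-domain"
  out
}

#' Attach derived region and depth-category labels to metadata
#'
#' @param env Metadata data frame from [read_sample_metadata()].
#' @param boundaries Region latitude cut points.
#' @return `env` with `region_label` and `depth_category` columns added.
#' @export
add_env_categories <- function(env, boundaries = default_region_boundaries()) {
  env$region_label <- classify_region(env$latitude, boundaries)
  env$depth_category <- classify_depth(env$depth_m)
  env
}

#' Discard low-prevalence OTUs
#'
#' Removes OTUs with non-zero counts in fewer than `min_prevalence`
#' samples (default 3, i.e. prevalence < 3 is discarded).
#'
#' @param table An [otu_table()].
#' @param min_prevalence Minimum number of samples with non-zero count.
#' @return The filtered [otu_table()].
#' @export
prevalence_filter <- function(table, min_prevalence = 3L) {
  stopifnot(inherits(table, "otu_table"))
  prev <- rowSums(table$counts > 0L)
  otu_table(table$counts[prev >= min_prevalence, , drop = FALSE], table$roles)
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Sums counts over all OTUs sharing a name at the requested rank. OTUs
#' unassigned at that rank pool into `"Unassigned"`. With `top_k` set, only
#' the `top_k` named taxa with the largest total abundance keep their own
#' row; the remaining named taxa pool into `"other"` (the `"Unassigned"`
#' pool is kept separate and never competes for the top-k slots). Column
#' sums are preserved exactly.
#'
#' @param table An [otu_table()] or a count matrix with OTU rownames.
#' @param assignments A `taxonomy_assignments` data frame covering the
#'   table's OTUs; OTUs absent from it count as unassigned.
#' @param rank One of [tax_ranks()].
#' @param top_k Optional number of named taxa to keep un-pooled.
#' @param other_label Label of the pooled remainder.
#' @return Integer matrix, rows = taxa, columns = samples.
#' @export
aggregate_taxa <- function(table, assignments, rank = "phylum",
                           top_k = NULL, other_label = "other") {
  if (!rank %in% tax_ranks())
    stop("unknown rank: ", rank)
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  labels <- stats::setNames(assignments[[rank]], assignments$otu_id)
  taxon <- labels[rownames(counts)]
  taxon[is.na(taxon) | taxon == ""] <- "Unassigned"
  agg <- rowsum(counts, group = taxon)
  if (!is.null(top_k)) {
    named <- setdiff(rownames(agg), "Unassigned")
    keep <- named[order(rowSums(agg[named, , drop = FALSE]),
                        decreasing = TRUE)][seq_len(min(top_k, length(named)))]
    pool <- setdiff(named, keep)
    if (length(pool) > 0L) {
      other <- colSums(agg[pool, , drop = FALSE])
      agg <- agg[!rownames(agg) %in% pool, , drop = FALSE]
      agg <- rbind(agg, matrix(other, nrow = 1L,
                               dimnames = list(other_label, colnames(agg))))
    }
  }
  storage.mode(agg) <- "integer"
  agg
}

#' Aggregate to the top phyla with their two most abundant classes
#'
#' The nested composition view: the `top_phyla` most abundant phyla are
#' split into their `top_classes` most abundant classes plus a per-phylum
#' `"other"` remainder; all remaining phyla pool into a global `"other"`
#' row and OTUs without a phylum into `"Unassigned"`.
#'
#' @param table An [otu_table()] or count matrix.
#' @param assignments A `taxonomy_assignments` data frame.
#' @param top_phyla,top_classes Numbers of phyla and of classes per phylum
#'   kept un-pooled (defaults 12 and 2).
#' @return Integer matrix with rows labelled `"Phylum;Class"`,
#'   `"Phylum;other"`, `"other"` and `"Unassigned"`.
#' @export
aggregate_phylum_class <- function(table, assignments, top_phyla = 12L,
                                   top_classes = 2L) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  phy <- stats::setNames(assignments$phylum, assignments$otu_id)[rownames(counts)]
  cls <- stats::setNames(assignments$class, assignments$otu_id)[rownames(counts)]
  phy[is.na(phy) | phy == ""] <- "Unassigned"
  cls[is.na(cls) | cls == ""] <- "other"
  phy_tot <- sort(rowSums(rowsum(counts, phy)), decreasing = TRUE)
  named <- setdiff(names(phy_tot), "Unassigned")
  keep_phy <- named[seq_len(min(top_phyla, length(named)))]
  label <- character(length(phy))
  for (i in seq_along(phy)) {
    if (phy[i] == "Unassigned") label[i] <- "Unassigned"
    else if (!phy[i] %in% keep_phy) label[i] <- "other"
    else label[i] <- paste0(phy[i], ";", cls[i])
  }
  agg <- rowsum(counts, label)
  # within each kept phylum, pool all but the top classes into "<phylum>;other"
  for (p in keep_phy) {
    rows <- grep(paste0("^", p, ";"), rownames(agg), value = TRUE)
    cls_names <- sub("^[^;]*;", "", rows)
    ord <- rows[order(rowSums(agg[rows, , drop = FALSE]), decreasing = TRUE)]
    keep_rows <- ord[sub("^[^;]*;", "", ord) != "other"][
      seq_len(min(top_classes, sum(cls_names != "other")))]
    pool <- setdiff(rows, keep_rows)
    if (length(pool) > 0L) {
      pooled <- colSums(agg[pool, , drop = FALSE])
      agg <- agg[!rownames(agg) %in% pool, , drop = FALSE]
      agg <- rbind(agg, matrix(pooled, nrow = 1L,
                               dimnames = list(paste0(p, ";other"),
                                               colnames(agg))))
    }
  }
  storage.mode(agg) <- "integer"
  agg
}

#' Centred log-ratio transform
#'
#' Maps each sample's composition to unconstrained real space:
#' `clr(x)_i = ln(x_i + d) - mean_j ln(x_j + d)`, so every transformed
#' sample sums to zero. Count zeros are handled by the chosen pseudocount
#' mode: `"add_one"` adds 1 to every count; `"add_half_min"` adds half the
#' smallest non-zero count of the matrix; `"multiplicative"` replaces zeros
#' in each sample's proportion vector with 0.65 times its smallest non-zero
#' proportion and shrinks the non-zero proportions to keep the sample
#' closed; `"none"` applies no replacement and errors on zeros.
#'
#' @param table An [otu_table()], or a count/abundance matrix with taxa as
#'   rows and samples as columns.
#' @param pseudocount_mode One of `"add_one"`, `"add_half_min"`,
#'   `"multiplicative"`, `"none"`.
#' @return A numeric matrix of class `clr_matrix`, samples as rows and
#'   taxa as columns, with attributes `pseudocount_mode` and `pseudocount`.
#' @export
clr_transform <- function(table, pseudocount_mode = c("add_one", "add_half_min",
                                                      "multiplicative", "none")) {
  pseudocount_mode <- match.arg(pseudocount_mode)
  x <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  x <- t(x)  # samples x taxa
  if (any(rowSums(x) <= 0))
    stop("sample with zero total abundance: ",
         rownames(x)[rowSums(x) <= 0][1L])
  delta <- 0
  if (pseudocount_mode == "add_one") {
    delta <- 1
    x <- x + 1
  } else if (pseudocount_mode == "add_half_min") {
    delta <- min(x[x > 0]) / 2
    x <- x + delta
  } else if (pseudocount_mode == "multiplicative") {
    x <- x / rowSums(x)
    for (i in seq_len(nrow(x))) {
      z <- x[i, ] == 0
      if (any(z)) {
        d <- 0.65 * min(x[i, !z])
        x[i, !z] <- x[i, !z] * (1 - sum(z) * d)
        x[i, z] <- d
      }
    }
  } else if (any(x == 0)) {
    stop("zero counts present; choose a pseudocount mode other than 'none'")
  }
  lx <- log(x)
  out <- lx - rowMeans(lx)
  structure(out, class = c("clr_matrix", class(out)),
            pseudocount_mode = pseudocount_mode, pseudocount = delta)
}

#' Pearson correlation grid of clr abundances against covariates
#'
#' Computes pairwise-complete Pearson correlations between each taxon's clr
#' abundance and each covariate. Continuous covariates enter as-is;
#' categorical covariates are expanded to one 0/1 indicator per level. A
#' cell with fewer than 3 complete pairs, or with a constant covariate or
#' taxon over the complete pairs, is reported as missing (`NA`), never as
#' zero. Covariates with missing values (e.g. oxygen saturation measured on
#' a platform subset) are handled per cell by restriction to the samples
#' where both members are observed; the per-cell `n` is reported alongside.
#'
#' @param clr A `clr_matrix` (samples x taxa).
#' @param env Metadata data frame aligned to `clr` rows by `sample_id`.
#' @param continuous Names of continuous covariate columns in `env`.
#' @param categories Names of categorical columns to expand into
#'   indicators.
#' @return A list of class `correlation_grid` with matrices `r` and `n`
#'   (rows = taxa, columns = covariates).
#' @export
correlation_grid <- function(clr, env,
                             continuous = c("latitude", "depth_m",
                                            "temperature", "salinity",
                                            "oxygen_saturation"),
                             categories = c("region_label", "depth_category")) {
  stopifnot(!is.null(rownames(clr)), "sample_id" %in% names(env))
  env <- env[match(rownames(clr), env$sample_id), , drop = FALSE]
  if (anyNA(env$sample_id))
    stop("clr samples missing from metadata")
  covs <- list()
  for (v in intersect(continuous, names(env))) covs[[v]] <- as.numeric(env[[v]])
  for (v in intersect(categories, names(env))) {
    for (lev in sort(unique(stats::na.omit(env[[v]])))) {
      covs[[paste0(v, ":", lev)]] <- as.numeric(env[[v]] == lev)
    }
  }
  cov_mat <- do.call(cbind, covs)
  r <- matrix(NA_real_, ncol(clr), ncol(cov_mat),
              dimnames = list(colnames(clr), colnames(cov_mat)))
  n <- matrix(0L, ncol(clr), ncol(cov_mat), dimnames = dimnames(r))
  for (j in seq_len(ncol(cov_mat))) {
    for (i in seq_len(ncol(clr))) {
      ok <- stats::complete.cases(clr[, i], cov_mat[, j])
      n[i, j] <- sum(ok)
      if (n[i, j] >= 3L) {
        x <- clr[ok, i]; y <- cov_mat[ok, j]
        if (stats::sd(x) > 0 && stats::sd(y) > 0)
          r[i, j] <- stats::cor(x, y)
      }
    }
  }
  structure(list(r = r, n = n), class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat(sprintf("correlation_grid: %d taxa x %d covariates (n %d-%d)\n",
              nrow(x$r), ncol(x$r), min(x$n), max(x$n)))
  invisible(x)
}
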