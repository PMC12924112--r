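#' Hit-filtering configuration
#'
#' Bundles the thresholds of the consensus taxonomy-assignment procedure:
#' the E-value contract of the similarity search, the low-score exclusion
#' thresholds, the bitscore margin retained around the best hit, and the
#' per-rank identity cutoffs used to trim lineages.
#'
#' @param evalue_max Maximum E-value hits are assumed to satisfy (the search
#'   itself is run with this threshold; ingest validates it).
#' @param bitscore_min Bitscore below which a hit is low-scoring.
#' @param alen_min Alignment length (bp) below which a hit is low-scoring.
#' @param margin_fraction Retain hits whose bitscore is within this fraction
#'   of the per-query maximum (0.02 keeps the top 2% band).
#' @param identity_cutoffs Named numeric vector, strictly decreasing from
#'   species to phylum: the percent identity a hit must *exceed* for a
#'   lineage to keep that rank.
#' @param low_score_rule `"or"` (default) excludes a hit when *either*
#'   bitscore or alignment length is below threshold; `"and"` excludes only
#'   hits failing both. The stringent `"or"` reading avoids retaining short
#'   perfect alignments on bitscore alone.
#' @param retain_domain If `TRUE`, identity at or below the phylum cutoff
#'   keeps the domain name instead of yielding an empty lineage.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(evalue_max = 1e-5,
                          bitscore_min = 150,
                          alen_min = 100,
                          margin_fraction = 0.02,
                          identity_cutoffs = c(species = 98, genus = 95,
                                               family = 90, order = 85,
                                               class = 80, phylum = 75),
                          low_score_rule = c("or", "and"),
                          retain_domain = FALSE) {
  low_score_rule <- match.arg(low_score_rule)
  stopifnot(evalue_max >= 0, bitscore_min >= 0, alen_min >= 1,
            margin_fraction >= 0, margin_fraction < 1)
  wanted <- c("species", "genus", "family", "order", "class", "phylum")
  if (!identical(names(identity_cutoffs), wanted))
    stop("identity_cutoffs must be named species, genus, family, order, class, phylum")
  if (any(diff(identity_cutoffs) >= 0))
    stop("identity_cutoffs must be strictly decreasing from species to phylum")
  structure(list(evalue_max = evalue_max, bitscore_min = bitscore_min,
                 alen_min = alen_min, margin_fraction = margin_fraction,
                 identity_cutoffs = identity_cutoffs,
                 low_score_rule = low_score_rule,
                 retain_domain = retain_domain),
            class = "filter_config")
}

#' Exclude low-scoring hits
#'
#' Step one of the hit-filtering procedure. Under `low_score_rule = "or"`
#' (default) a hit is retained only when bitscore >= `bitscore_min` *and*
#' alignment length >= `alen_min`; under `"and"` a hit is excluded only when
#' it fails both thresholds.
#'
#' @param hits A hit data frame (see [read_hits()]); may span several
#'   queries.
#' @param config A [filter_config()].
#' @return The retained rows of `hits`.
#' @export
threshold_filter <- function(hits, config = filter_config()) {
  low_bs <- hits$bitscore < config$bitscore_min
  low_al <- hits$alignment_length < config$alen_min
  drop <- if (config$low_score_rule == "or") low_bs | low_al else low_bs & low_al
  hits[!drop, , drop = FALSE]
}

#' Retain hits within the bitscore margin of the best hit
#'
#' Step two: for a single query, keeps exactly the hits whose bitscore is at
#' least `(1 - margin_fraction)` times the maximum bitscore. The boundary is
#' inclusive, so the maximum-scoring hit is always retained.
#'
#' @param hits Hit data frame for one query; must be non-empty.
#' @param config A [filter_config()].
#' @return The retained rows of `hits`.
#' @export
margin_filter <- function(hits, config = filter_config()) {
  if (nrow(hits) == 0L) stop("margin_filter requires a non-empty hit set")
  cutoff <- (1 - config$margin_fraction) * max(hits$bitscore)
  hits[hits$bitscore >= cutoff, , drop = FALSE]
}

#' Consensus taxonomy assignment from similarity hits
#'
#' Applies the full four-step procedure per query: (1) exclude low-scoring
#' hits ([threshold_filter()]); (2) keep only hits within the bitscore
#' margin of the best hit ([margin_filter()]); (3) collapse the retained
#' reference lineages to their lowest common ancestor
#' ([lowest_common_ancestor()]); (4) trim the consensus lineage to the rank
#' permitted by the maximum percent identity among retained hits
#' ([trim_by_identity()]). Queries with no retained hits are reported as
#' unassigned. Hits whose reference lacks a lineage contribute to the input
#' count but not to the consensus.
#'
#' The result is independent of the ordering of rows in `hits`.
#'
#' @param hits A hit data frame as returned by [read_hits()]: columns
#'   `query_id`, `subject_id`, `pct_identity`, `alignment_length`, `evalue`,
#'   `bitscore`, `lineage` (semicolon string, `NA` when missing).
#' @param config A [filter_config()].
#' @return A data frame of class `taxonomy_assignments` with one row per
#'   query: `otu_id`, the seven rank columns (empty past the assigned
#'   rank), `assigned_rank`, `lca_rank`, `max_identity`, and the audit
#'   counts `n_hits_input`, `n_hits_after_threshold`, `n_hits_after_margin`.
#' @export
assign_taxonomy <- function(hits, config = filter_config()) {
  stopifnot(is.data.frame(hits))
  needed <- c("query_id", "subject_id", "pct_identity", "alignment_length",
              "evalue", "bitscore", "lineage")
  missing_cols <- setdiff(needed, names(hits))
  if (length(missing_cols) > 0L)
    stop("hit table lacks columns: ", paste(missing_cols, collapse = ", "))
  groups <- split(hits, factor(hits$query_id, levels = unique(hits$query_id)))
  rows <- lapply(names(groups), function(q) {
    assign_one_query(q, groups[[q]], config)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- empty_assignments()
  class(out) <- c("taxonomy_assignments", "data.frame")
  out
}

assign_one_query <- function(query_id, h, config) {
  n_input <- nrow(h)
  kept <- threshold_filter(h, config)
  n_thr <- nrow(kept)
  if (n_thr > 0L) kept <- margin_filter(kept, config)
  n_mar <- nrow(kept)
  with_lin <- kept[!is.na(kept$lineage), , drop = FALSE]
  if (nrow(with_lin) == 0L) {
    return(assignment_row(query_id, lineage(), "unassigned", "unassigned",
                          NA_real_, n_input, n_thr, n_mar))
  }
  lins <- lapply(with_lin$lineage, parse_lineage)
  lca <- lowest_common_ancestor(lins)
  max_id <- max(with_lin$pct_identity)
  final <- trim_by_identity(lca, max_id, config)
  assignment_row(query_id, final,
                 rank_of(final), rank_of(lca),
                 max_id, n_input, n_thr, n_mar)
}

rank_of <- function(lin) {
  if (length(lin) == 0L) "unassigned" else tax_ranks()[length(lin)]
}

assignment_row <- function(otu_id, lin, assigned_rank, lca_rank,
                           max_identity, n_in, n_thr, n_mar) {
  x <- as.character(lin)
  length(x) <- 7L
  x[is.na(x)] <- ""
  out <- data.frame(otu_id = otu_id, t(x), assigned_rank = assigned_rank,
                    lca_rank = lca_rank, max_identity = max_identity,
                    n_hits_input = n_in, n_hits_after_threshold = n_thr,
                    n_hits_after_margin = n_mar,
                    stringsAsFactors = FALSE)
  names(out)[2:8] <- tax_ranks()
  out
}

empty_assignments <- function() {
  assignment_row(character(0), lineage(), character(0), character(0),
                 numeric(0), integer(0), integer(0), integer(0))[0, ]
}

#' Extract the consensus lineage of one assignment row
#'
#' @param assignments A `taxonomy_assignments` data frame.
#' @param i Row index.
#' @return A `lineage`.
#' @export
assignment_lineage <- function(assignments, i) {
  x <- unlist(assignments[i, tax_ranks()], use.names = FALSE)
  x <- x[x != ""]
  if (length(x) == 0L) lineage() else lineage(x)
}
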