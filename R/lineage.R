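#' Taxonomic rank hierarchy
#'
#' The fixed seven-rank hierarchy used throughout the package, ordered from
#' the root down: domain, phylum, class, order, family, genus, species.
#'
#' @return Character vector of the seven rank names, root first.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Construct a lineage
#'
#' A lineage is a character vector of taxon names filling the rank hierarchy
#' from the top with no gaps; it may terminate early (partial lineage) and
#' may be empty (unassigned).
#'
#' @param ... Taxon names from domain downwards, or a single character
#'   vector.
#' @return A character vector of class `lineage`, named by rank.
#' @export
lineage <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- character(0)
  x <- as.character(x)
  if (length(x) > 7L)
    stop("a lineage has at most 7 ranks, got ", length(x))
  if (any(is.na(x) | x == ""))
    stop("lineage names must be non-empty from the top with no gaps")
  names(x) <- tax_ranks()[seq_along(x)]
  structure(x, class = "lineage")
}

#' Parse a semicolon-delimited lineage string
#'
#' Accepts SILVA-style strings `domain;phylum;...;species` with empty
#' trailing fields for partial lineages, e.g. `"Bacteria;Nitrospirota;;;;;"`.
#' An empty string parses to the empty (unassigned) lineage. A name after a
#' gap (an empty field followed by a non-empty one) is an error: the
#' hierarchy is gap-free from the top.
#'
#' @param x Character scalar.
#' @return A `lineage`.
#' @export
parse_lineage <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (is.na(x) || x == "") return(lineage())
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  length(parts) <- 7L          # pad with NA if fewer than 7 fields
  parts[is.na(parts)] <- ""
  named <- parts != ""
  depth <- if (any(named)) max(which(named)) else 0L
  if (depth > 0L && any(parts[seq_len(depth)] == ""))
    stop("gapped lineage string (empty rank above a named rank): ", x)
  lineage(parts[seq_len(depth)])
}

#' Serialise a lineage to a 7-field semicolon string
#'
#' Inverse of [parse_lineage()]: always emits exactly 7 fields, padding
#' partial lineages with empty trailing fields.
#'
#' @param lin A `lineage` (or plain character vector of taxon names).
#' @return Character scalar.
#' @export
format_lineage <- function(lin) {
  x <- as.character(lin)
  length(x) <- 7L
  x[is.na(x)] <- ""
  paste(x, collapse = ";")
}

#' Lowest common ancestor of a set of lineages
#'
#' The longest common prefix over the ranked hierarchy: names are compared
#' rank-wise by exact string match, stopping at the first disagreement or at
#' the first rank unnamed in any lineage. Fully disjoint lineages give the
#' empty lineage.
#'
#' @param lineages A list of `lineage` objects (or character vectors).
#' @return A `lineage`.
#' @export
lowest_common_ancestor <- function(lineages) {
  stopifnot(is.list(lineages), length(lineages) >= 1L)
  depth <- min(vapply(lineages, length, integer(1)))
  common <- 0L
  for (d in seq_len(depth)) {
    names_d <- vapply(lineages, function(l) as.character(l)[d], character(1))
    if (all(names_d == names_d[1L])) common <- d else break
  }
  if (common == 0L) lineage() else lineage(as.character(lineages[[1L]])[seq_len(common)])
}

#' Trim a lineage according to percent identity
#'
#' Truncates a lineage to the deepest rank its alignment identity supports
#' under the rank-wise identity cutoffs (strict `>` comparison): with the
#' default cutoffs a hit must exceed 98% identity to keep species, 95% for
#' genus, 90% family, 85% order, 80% class and 75% phylum. Identity at or
#' below the phylum cutoff yields the empty lineage unless
#' `config$retain_domain` is `TRUE`, in which case the domain name survives.
#'
#' @param lin A `lineage`.
#' @param identity Percent identity in \[0, 100\].
#' @param config A [filter_config()].
#' @return The trimmed `lineage`.
#' @export
trim_by_identity <- function(lin, identity, config = filter_config()) {
  stopifnot(is.numeric(identity), length(identity) == 1L,
            identity >= 0, identity <= 100)
  max_depth <- identity_rank_depth(identity, config)
  x <- as.character(lin)
  keep <- min(length(x), max_depth)
  if (keep == 0L) lineage() else lineage(x[seq_len(keep)])
}

# Deepest rank index (1 = domain ... 7 = species) permitted by an identity
# value; 0 means wholly unassigned.
identity_rank_depth <- function(identity, config) {
  cutoffs <- config$identity_cutoffs  # named species..phylum, decreasing
  rank_depth <- match(names(cutoffs), tax_ranks())
  passed <- rank_depth[identity > cutoffs]
  if (length(passed) > 0L) return(max(passed))
  if (isTRUE(config$retain_domain)) 1L else 0L
}

#' @export
print.lineage <- function(x, ...) {
  if (length(x) == 0L) cat("<unassigned lineage>\n")
  else cat(paste(as.character(x), collapse = " > "), "\n")
  invisible(x)
}
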