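#' Construct an OTU count table
#'
#' An integer count matrix with OTUs as rows and samples as columns, plus a
#' per-sample role labelling each column as a true sample or as one of the
#' negative-control classes taken along the wet-lab workflow.
#'
#' @param counts Non-negative integer matrix, rows = OTUs (rownames
#'   required), columns = samples (colnames required).
#' @param roles Named character vector mapping every sample to one of
#'   `"true_sample"`, `"field_control"`, `"extraction_control"`,
#'   `"pcr_control"`.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   and `roles`.
#' @export
otu_table <- function(counts, roles) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count table")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  valid <- c("true_sample", "field_control", "extraction_control", "pcr_control")
  absent <- setdiff(colnames(counts), names(roles))
  if (length(absent) > 0L)
    stop("samples missing from roles: ", paste(absent, collapse = ", "))
  roles <- roles[colnames(counts)]
  if (!all(roles %in% valid))
    stop("roles must be one of: ", paste(valid, collapse = ", "))
  structure(list(counts = counts, roles = roles), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%d true, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$roles == "true_sample"), sum(x$roles != "true_sample")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read a tabular similarity-hit file
#'
#' Reads a 12-column tab-separated hit table in the standard tabular output
#' order of local aligners (query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, E-value, bitscore) and attaches each subject's reference
#' lineage. Rows whose subject has no entry in the lineage map are returned
#' with `lineage = NA` and `lineage_missing = TRUE`, never dropped.
#'
#' @param path Path to the hit table (no header).
#' @param lineage_map Named character vector `subject_id -> lineage string`,
#'   e.g. from [read_lineage_map()].
#' @param evalue_max Hits are validated against this search-time E-value
#'   contract.
#' @return Data frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `alignment_length`, `evalue`, `bitscore`, `lineage`,
#'   `lineage_missing`.
#' @export
read_hits <- function(path, lineage_map, evalue_max = 1e-5) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), alignment_length = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      lineage = character(0), lineage_missing = logical(0)))
  }
  bad <- which(nf != 12L)
  if (length(bad) > 0L)
    stop("hit table line ", bad[1L], " has ", nf[bad[1L]],
         " fields, expected 12")
  raw <- utils::read.table(path, sep = "\t", quote = "",
                           colClasses = c("character", "character",
                                          rep("character", 10)),
                           stringsAsFactors = FALSE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v))
      stop("non-numeric ", what, " at hit table line ", which(is.na(v))[1L])
    v
  }
  hits <- data.frame(query_id = raw[[1L]], subject_id = raw[[2L]],
                     pct_identity = num(3L, "percent identity"),
                     alignment_length = as.integer(num(4L, "alignment length")),
                     evalue = num(11L, "E-value"),
                     bitscore = num(12L, "bitscore"),
                     stringsAsFactors = FALSE)
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stop("percent identity outside [0, 100] at line ",
         which(hits$pct_identity < 0 | hits$pct_identity > 100)[1L])
  if (any(hits$alignment_length < 1L))
    stop("alignment length < 1 at line ", which(hits$alignment_length < 1L)[1L])
  if (any(hits$bitscore < 0))
    stop("negative bitscore at line ", which(hits$bitscore < 0)[1L])
  if (any(hits$evalue < 0))
    stop("negative E-value at line ", which(hits$evalue < 0)[1L])
  if (any(hits$evalue > evalue_max))
    stop("E-value above the search threshold ", evalue_max,
         " at line ", which(hits$evalue > evalue_max)[1L])
  hits$lineage <- unname(lineage_map[hits$subject_id])
  hits$lineage_missing <- is.na(hits$lineage)
  hits
}

#' Read a subject-to-lineage map
#'
#' Two-column tab-separated file: subject id, semicolon-delimited lineage
#' string. Every lineage string is validated by [parse_lineage()].
#'
#' @param path Path to the lineage map TSV (no header).
#' @return Named character vector `subject_id -> lineage string`.
#' @export
read_lineage_map <- function(path) {
  raw <- utils::read.table(path, sep = "\t", quote = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) != 2L)
    stop("lineage map must have 2 columns, found ", ncol(raw))
  if (anyDuplicated(raw[[1L]]))
    stop("duplicate subject id in lineage map: ",
         raw[[1L]][duplicated(raw[[1L]])][1L])
  for (i in seq_len(nrow(raw))) parse_lineage(raw[[2L]][i])
  stats::setNames(raw[[2L]], raw[[1L]])
}

#' Write a subject-to-lineage map
#' @param lineage_map Named character vector as from [read_lineage_map()].
#' @param path Output path.
#' @export
write_lineage_map <- function(lineage_map, path) {
  utils::write.table(data.frame(names(lineage_map), unname(lineage_map)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an OTU count table and its sample roles
#'
#' The count table is a TSV whose first column holds OTU ids and whose
#' remaining columns are samples; the roles file is a two-column TSV
#' (header `sample_id`, `role`) covering every sample column.
#'
#' @param path Path to the count TSV.
#' @param roles_path Path to the sample-role TSV.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, roles_path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(tab)[-1L]))
    stop("duplicate sample column in count table: ",
         names(tab)[-1L][duplicated(names(tab)[-1L])][1L])
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric counts in OTU table")
  rownames(counts) <- tab[[1L]]
  roles_df <- utils::read.table(roles_path, sep = "\t", header = TRUE,
                                quote = "", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(roles_df)))
    stop("roles file must have columns sample_id and role")
  roles <- stats::setNames(roles_df$role, roles_df$sample_id)
  otu_table(counts, roles)
}

#' Write an OTU count table (and optionally its roles)
#' @param table An [otu_table()].
#' @param path Output count TSV path.
#' @param roles_path Optional output path for the sample-role TSV.
#' @export
write_otu_table <- function(table, path, roles_path = NULL) {
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roles_path)) {
    utils::write.table(data.frame(sample_id = names(table$roles),
                                  role = unname(table$roles)),
                       roles_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write taxonomy assignments to TSV
#'
#' Columns: `otu_id`, the seven ranks (blank past the assigned rank),
#' `assigned_rank`, `lca_rank`, `max_identity` and the audit counts.
#' [read_assignments()] inverts this losslessly.
#'
#' @param assignments A `taxonomy_assignments` data frame.
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(as.data.frame(assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read taxonomy assignments written by [write_assignments()]
#' @param path Path to the assignments TSV.
#' @return A `taxonomy_assignments` data frame.
#' @export
read_assignments <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = c(otu_id = "character"),
                           na.strings = "NA")
  for (r in tax_ranks()) out[[r]][is.na(out[[r]])] <- ""
  class(out) <- c("taxonomy_assignments", "data.frame")
  out
}

#' Read per-sample environmental metadata
#'
#' CSV with columns `sample_id`, `latitude`, `longitude`, `depth_m`,
#' `temperature`, `salinity`, `oxygen_saturation`. Oxygen may be missing
#' (sensor availability varies by platform) and is kept as `NA`, never
#' coerced to zero. Seafloor depth must be positive.
#'
#' @param path Path to the metadata CSV.
#' @return Data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "latitude", "longitude", "depth_m",
              "temperature", "salinity", "oxygen_saturation")
  absent <- setdiff(needed, names(env))
  if (length(absent) > 0L)
    stop("metadata lacks columns: ", paste(absent, collapse = ", "))
  if (anyDuplicated(env$sample_id))
    stop("duplicate sample_id in metadata")
  if (any(is.na(env$depth_m)) || any(env$depth_m <= 0))
    stop("depth_m must be positive for every sample")
  env
}

#' Write per-sample environmental metadata
#' @param env Metadata data frame.
#' @param path Output CSV path.
#' @export
write_sample_metadata <- function(env, path) {
  utils::write.csv(env, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
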