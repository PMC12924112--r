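#' Remove contamination signal found in negative controls
#'
#' Subtracts from every true sample the reads attributable to contamination,
#' as witnessed by the negative field, extraction and PCR controls carried
#' through the workflow.
#'
#' The default `"subtract_scaled"` method implements a constant-anchor
#' blank-subtraction contract: the per-OTU mean proportional abundance
#' across the controls defines the contamination profile; the OTU with the
#' largest profile value (the anchor, assumed to be pure contamination) sets
#' a per-sample scale equal to its observed count in that sample divided by
#' its profile proportion; each contaminant OTU then has
#' `profile_i / profile_anchor * count_anchor` reads subtracted, floored at
#' zero and rounded down so decontamination never manufactures fractional
#' or negative reads. OTUs absent from all controls are untouched. OTUs
#' whose counts become all-zero are dropped and reported.
#'
#' The `"prevalence_zero"` method simply zeroes every OTU observed in any
#' control above `count_threshold` reads.
#'
#' Control classes are pooled into one blank set by default; with
#' `per_role = TRUE` the subtraction is applied sequentially per control
#' class (field, then extraction, then PCR).
#'
#' @param table An [otu_table()] containing at least one control column and
#'   one true-sample column.
#' @param method `"subtract_scaled"` (default) or `"prevalence_zero"`.
#' @param count_threshold For `"prevalence_zero"`: a control count above
#'   this value marks the OTU as a contaminant (default 0).
#' @param per_role Apply the subtraction per control class sequentially
#'   instead of pooling the blanks.
#' @return A list with elements `table` (an [otu_table()] of the true
#'   samples only) and `report` (a `decontam_report`: `otus_removed`,
#'   `reads_removed_per_sample`, `contamination_profile`, `anchor_otu`,
#'   `method`).
#' @export
remove_contaminants <- function(table,
                                method = c("subtract_scaled", "prevalence_zero"),
                                count_threshold = 0,
                                per_role = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(table, "otu_table"))
  is_ctrl <- table$roles != "true_sample"
  if (!any(is_ctrl))
    stop("table has no control columns; pass the data through unchanged ",
         "instead of calling remove_contaminants")
  if (!any(!is_ctrl))
    stop("table has no true-sample columns")

  samples <- table$counts[, !is_ctrl, drop = FALSE]
  input <- samples

  if (method == "prevalence_zero") {
    controls <- table$counts[, is_ctrl, drop = FALSE]
    contam <- apply(controls, 1L, max) > count_threshold
    samples[contam, ] <- 0L
    profile <- ifelse(contam, 1, 0)
    anchor <- if (any(contam)) rownames(samples)[which(contam)[1L]] else NA_character_
  } else {
    ctrl_sets <- if (per_role) {
      lapply(c("field_control", "extraction_control", "pcr_control"),
             function(r) table$counts[, table$roles == r, drop = FALSE])
    } else {
      list(table$counts[, is_ctrl, drop = FALSE])
    }
    profile <- rep(0, nrow(samples))
    anchor <- NA_character_
    for (controls in ctrl_sets) {
      if (ncol(controls) == 0L) next
      res <- subtract_scaled(samples, controls)
      samples <- res$samples
      profile <- pmax(profile, res$profile)
      if (is.na(anchor)) anchor <- res$anchor
    }
  }

  # an OTU counts as removed when it had reads anywhere in the input table
  # (true samples or controls) and none survive in the cleaned samples
  removed <- rownames(samples)[rowSums(samples) == 0L &
                                 rowSums(table$counts) > 0L]
  keep <- rowSums(samples) > 0L
  out <- otu_table(samples[keep, , drop = FALSE],
                   table$roles[!is_ctrl])
  report <- structure(
    list(otus_removed = removed,
         reads_removed_per_sample = colSums(input) - colSums(samples),
         contamination_profile = stats::setNames(profile, rownames(input)),
         anchor_otu = anchor,
         method = method),
    class = "decontam_report")
  list(table = out, report = report)
}

# Constant-anchor scaled subtraction of the pooled control profile from a
# true-sample count matrix. Controls with zero total reads are ignored (an
# all-zero blank carries no signal).
subtract_scaled <- function(samples, controls) {
  totals <- colSums(controls)
  live <- controls[, totals > 0, drop = FALSE]
  if (ncol(live) == 0L)
    return(list(samples = samples, profile = rep(0, nrow(samples)),
                anchor = NA_character_))
  props <- sweep(live, 2L, colSums(live), "/")
  profile <- rowMeans(props)
  anchor_i <- which.max(profile)
  anchor_counts <- samples[anchor_i, ]
  # epsilon guards the floor against binary representation error (e.g.
  # (10/60)/(50/60)*500 landing at 99.999...)
  removal <- floor(outer(profile / profile[anchor_i], anchor_counts) + 1e-9)
  cleaned <- pmax(samples - removal, 0L)
  cleaned[profile == 0, ] <- samples[profile == 0, ]  # untouched OTUs
  storage.mode(cleaned) <- "integer"
  list(samples = cleaned, profile = profile,
       anchor = rownames(samples)[anchor_i])
}

#' @export
print.decontam_report <- function(x, ...) {
  cat(sprintf("decontam_report (%s): %d OTUs removed, %d reads subtracted\n",
              x$method, length(x$otus_removed),
              sum(x$reads_removed_per_sample)))
  invisible(x)
}
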