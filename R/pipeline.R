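#' Pipeline configuration
#'
#' Collects every path and tunable of the end-to-end run. All thresholds of
#' all stages live here; stage functions receive them explicitly so no
#' numeric constant is buried in code. The global `seed` fans out to
#' stage-specific seeds by fixed small offsets, so any stage can be re-run
#' in isolation.
#'
#' @param hits,lineages,otu,roles,meta Input paths (see [read_hits()],
#'   [read_otu_table()], [read_sample_metadata()]).
#' @param out_dir Output directory for all artifacts.
#' @param filter A [filter_config()].
#' @param decontam_method Passed to [remove_contaminants()].
#' @param min_prevalence Passed to [prevalence_filter()].
#' @param rank,top_k Aggregation rank and top-k pooling
#'   ([aggregate_taxa()]).
#' @param pseudocount_mode Passed to [clr_transform()].
#' @param candidates Metadata columns offered to [forward_select()].
#' @param alpha,n_perm Forward-selection entry level and permutation count.
#' @param region_boundaries Latitude cut points for
#'   [add_env_categories()].
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(hits, lineages, otu, roles, meta, out_dir,
                            filter = filter_config(),
                            decontam_method = "subtract_scaled",
                            min_prevalence = 3L,
                            rank = "phylum", top_k = 12L,
                            pseudocount_mode = "add_one",
                            candidates = c("latitude", "depth_m",
                                           "oxygen_saturation"),
                            alpha = 0.05, n_perm = 999L,
                            region_boundaries = default_region_boundaries(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the defaults of
#' [pipeline_config()]; an `identity_cutoffs` / `margin_fraction` /
#' `bitscore_min` / `alen_min` / `low_score_rule` block populates the
#' nested [filter_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  fc_args <- intersect(names(y), names(formals(filter_config)))
  filter <- do.call(filter_config, y[fc_args])
  pc_args <- intersect(names(y), names(formals(pipeline_config)))
  pc_args <- setdiff(pc_args, "filter")
  do.call(pipeline_config, c(y[pc_args], list(filter = filter)))
}

#' Run the full post-clustering pipeline
#'
#' Executes, in order: consensus taxonomy assignment of the similarity
#' hits; negative-control decontamination; prevalence filtering; taxonomic
#' aggregation; centred log-ratio transform; then the three analyses on
#' the transformed table - the phylum-environment correlation grid, the
#' constrained ordination with forward selection (on the samples where all
#' candidate covariates are observed), and the depth-stratified
#' richness-latitude regressions plus the reads-versus-OTUs saturation
#' fit. Every intermediate is written as TSV/JSON to `config$out_dir`,
#' together with a JSON run manifest carrying stage row/OTU counts and the
#' resolved configuration; per-stage timings go only to `log.txt` so that
#' reruns with an identical configuration are byte-identical on every data
#' artifact.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  cat("", file = log_path)
  manifest <- list(seed = config$seed)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    cat(sprintf("%s: %.2fs\n", name, proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    res
  }

  # taxonomy -------------------------------------------------------------
  lineage_map <- stage("read_lineages", read_lineage_map(config$lineages))
  hits <- stage("read_hits",
                read_hits(config$hits, lineage_map,
                          evalue_max = config$filter$evalue_max))
  assignments <- stage("assign_taxonomy", assign_taxonomy(hits, config$filter))
  write_assignments(assignments, file.path(config$out_dir, "assignments.tsv"))
  manifest$n_hits <- nrow(hits)
  manifest$n_queries <- nrow(assignments)

  # counts ----------------------------------------------------------------
  table <- stage("read_otu_table", read_otu_table(config$otu, config$roles))
  manifest$n_otus_input <- nrow(table$counts)
  manifest$n_samples <- sum(table$roles == "true_sample")
  manifest$n_controls <- sum(table$roles != "true_sample")

  dc <- stage("decontam",
              remove_contaminants(table, method = config$decontam_method))
  clean <- dc$table
  write_otu_table(clean, file.path(config$out_dir, "clean_otu.tsv"))
  manifest$n_otus_post_decontam <- nrow(clean$counts)
  manifest$n_otus_removed_decontam <- length(dc$report$otus_removed)
  manifest$reads_removed_decontam <- sum(dc$report$reads_removed_per_sample)

  filtered <- stage("prevalence_filter",
                    prevalence_filter(clean, config$min_prevalence))
  write_otu_table(filtered, file.path(config$out_dir, "filtered_otu.tsv"))
  manifest$n_otus_post_prevalence <- nrow(filtered$counts)

  # community --------------------------------------------------------------
  env <- stage("read_metadata", read_sample_metadata(config$meta))
  env <- add_env_categories(env, config$region_boundaries)
  env <- env[match(colnames(filtered$counts), env$sample_id), , drop = FALSE]
  if (anyNA(env$sample_id)) stop("samples missing from metadata")

  agg <- stage("aggregate",
               aggregate_taxa(filtered, assignments_for(filtered, assignments,
                                                        config),
                              rank = config$rank, top_k = config$top_k))
  utils::write.table(data.frame(taxon = rownames(agg), agg,
                                check.names = FALSE),
                     file.path(config$out_dir, "aggregated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clr <- stage("clr", clr_transform(agg, config$pseudocount_mode))
  utils::write.table(data.frame(sample_id = rownames(clr), clr,
                                check.names = FALSE),
                     file.path(config$out_dir, "clr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  grid <- stage("correlations", correlation_grid(clr, env))
  utils::write.table(data.frame(taxon = rownames(grid$r), grid$r,
                                check.names = FALSE),
                     file.path(config$out_dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ordination -------------------------------------------------------------
  cand <- env[, config$candidates, drop = FALSE]
  complete <- stats::complete.cases(cand)
  ord <- stage("ordination",
               forward_select(clr[complete, , drop = FALSE],
                              cand[complete, , drop = FALSE],
                              alpha = config$alpha, n_perm = config$n_perm,
                              seed = config$seed + 101L))
  jsonlite::write_json(
    list(selected = ord$selected,
         trace = ord$trace,
         eig_constrained = as.list(ord$eig_constrained),
         r2 = ord$r2, adj_r2_full = ord$adj_r2_full,
         n = ord$n),
    file.path(config$out_dir, "rda.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$rda_selected <- ord$selected
  manifest$rda_n <- ord$n

  # trends -----------------------------------------------------------------
  rich <- otu_richness(filtered)
  fits <- stage("richness_regression",
                stratified_regression(rich, env$latitude, env$depth_category))
  raw_true <- table$counts[, table$roles == "true_sample", drop = FALSE]
  sat <- stage("saturation_fit",
               saturation_fit(colSums(raw_true), otu_richness(raw_true)))
  jsonlite::write_json(
    list(regressions = lapply(unname(fits), function(f)
      f[c("stratum", "n", "slope", "intercept", "slope_se", "t_value",
          "p_value")]),
      saturation = list(asymptote = sat$asymptote,
                        half_saturation = sat$half_saturation,
                        model_form = sat$model_form, rss = sat$rss)),
    file.path(config$out_dir, "trends.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest$config <- config_as_list(config)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# The pipeline's hit queries and the count table's OTUs may not coincide
# (e.g. synthetic stages are generated independently); aggregation treats
# OTUs without an assignment row as unassigned, which is the documented
# behaviour, so pass the assignments through untouched.
assignments_for <- function(table, assignments, config) assignments

config_as_list <- function(config) {
  out <- unclass(config)
  out$filter <- unclass(out$filter)
  out$filter$identity_cutoffs <- as.list(out$filter$identity_cutoffs)
  out
}
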