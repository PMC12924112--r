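#' Generate a hierarchy-consistent synthetic reference taxonomy
#'
#' Builds `n_taxa` species-level reference lineages over the seven-rank
#' hierarchy with controlled branching (several species per genus, several
#' genera per family, and so on), so that related subjects share all ranks
#' above their divergence point. Deterministic for a fixed seed.
#'
#' @param n_taxa Number of reference subjects (species) to create.
#' @param seed Integer seed.
#' @param n_phyla Optional fixed number of phyla; when at least as many
#'   taxa as phyla are requested, every phylum is guaranteed at least one
#'   species.
#' @return Named character vector mapping `subject_id` to a semicolon
#'   lineage string (the lineage-map format of [read_lineage_map()]).
#' @export
gen_reference <- function(n_taxa, seed = 1L, n_phyla = NULL) {
  stopifnot(n_taxa >= 1L)
  set.seed(seed)
  n_phy <- if (is.null(n_phyla)) max(2L, ceiling(n_taxa / 12)) else n_phyla
  n_cla <- max(n_phy, ceiling(n_taxa / 8))
  n_ord <- max(n_cla, ceiling(n_taxa / 5))
  n_fam <- max(n_ord, ceiling(n_taxa / 3))
  n_gen <- max(n_fam, ceiling(n_taxa / 2))
  # cover every parent once (so no rank label is childless), then branch
  parent <- function(n_child, n_parent) {
    if (n_child >= n_parent)
      sample(c(seq_len(n_parent),
               sample.int(n_parent, n_child - n_parent, replace = TRUE)))
    else sample.int(n_parent, n_child, replace = TRUE)
  }
  cla2phy <- parent(n_cla, n_phy)
  ord2cla <- parent(n_ord, n_cla)
  fam2ord <- parent(n_fam, n_ord)
  gen2fam <- parent(n_gen, n_fam)
  sp2gen <- parent(n_taxa, n_gen)
  lin <- character(n_taxa)
  for (i in seq_len(n_taxa)) {
    g <- sp2gen[i]; f <- gen2fam[g]; o <- fam2ord[f]; cl <- ord2cla[o]
    p <- cla2phy[cl]
    lin[i] <- paste("Bacteria",
                    sprintf("phylum_%02d", p), sprintf("class_%03d", cl),
                    sprintf("order_%03d", o), sprintf("family_%03d", f),
                    sprintf("genus_%04d", g), sprintf("species_%04d", i),
                    sep = ";")
  }
  stats::setNames(lin, sprintf("ref_%04d", seq_len(n_taxa)))
}

#' Generate a similarity-hit table with known expected assignments
#'
#' For each query, plants one true-source hit at a controlled percent
#' identity and, depending on a sampled target consensus depth, additional
#' within-margin hits from reference subjects that agree with the true
#' source to exactly that depth; plus decoys designed to be excluded by the
#' filtering rules (hits below the bitscore margin, and hits failing both
#' the bitscore and alignment-length thresholds). The expected consensus
#' assignment of each query is therefore computable from the planted truth:
#' the true lineage truncated at the shallower of the realised
#' common-prefix depth of the within-margin subjects and the depth the
#' planted identity permits.
#'
#' @param lineage_map Reference map from [gen_reference()].
#' @param n_queries Number of query OTUs (ignored when `otu_phyla` is
#'   given).
#' @param seed Integer seed.
#' @param config A [filter_config()] (identity cutoffs set the
#'   expected-depth arithmetic).
#' @param otu_phyla Optional named character vector `query_id -> phylum`:
#'   each query's true source is then drawn from the reference subjects of
#'   that phylum, and planted identities stay above the class cutoff so
#'   the assigned phylum always matches the planted one (used to couple
#'   the taxonomy stage to [gen_community()]).
#' @return List with `hits` (data frame as from [read_hits()]) and `truth`
#'   (data frame: `query_id`, `true_subject`, `identity`,
#'   `expected_lineage`, `expected_rank`, `lca_depth`).
#' @export
gen_hits <- function(lineage_map, n_queries, seed = 1L,
                     config = filter_config(), otu_phyla = NULL) {
  set.seed(seed)
  subjects <- names(lineage_map)
  lin_mat <- t(vapply(lineage_map, function(s) {
    x <- strsplit(s, ";", fixed = TRUE)[[1]]
    length(x) <- 7L
    x
  }, character(7)))
  # identity bands bracketing the rank cutoffs, sampled away from boundaries
  bands <- rbind(c(98.2, 99.9), c(95.2, 97.8), c(90.2, 94.8), c(85.2, 89.8),
                 c(80.2, 84.8), c(75.2, 79.8), c(62.0, 74.8))
  if (!is.null(otu_phyla)) {
    n_queries <- length(otu_phyla)
    bands <- bands[1:5, , drop = FALSE]   # class rank or deeper
    by_phylum <- split(seq_along(subjects), lin_mat[, 2L])
    absent <- setdiff(unique(otu_phyla), names(by_phylum))
    if (length(absent) > 0L)
      stop("reference lacks phyla: ", paste(absent, collapse = ", "))
  }
  hit_rows <- list()
  truth_rows <- list()
  for (qi in seq_len(n_queries)) {
    if (is.null(otu_phyla)) {
      qid <- sprintf("otu_%04d", qi)
      t_idx <- sample.int(length(subjects), 1L)
    } else {
      qid <- names(otu_phyla)[qi]
      pool <- by_phylum[[otu_phyla[[qi]]]]
      t_idx <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    band <- bands[sample.int(nrow(bands), 1L), ]
    identity <- stats::runif(1L, band[1L], band[2L])
    target_d <- sample(2:7, 1L)
    base_bs <- stats::runif(1L, 400, 800)
    alen <- round(stats::runif(1L, 250, 450))
    rows <- data.frame(query_id = qid, subject_id = subjects[t_idx],
                       pct_identity = round(identity, 1),
                       alignment_length = alen, evalue = 1e-50,
                       bitscore = round(base_bs, 1),
                       stringsAsFactors = FALSE)
    realized_d <- 7L
    if (target_d < 7L) {
      # subjects agreeing with the true source to exactly target_d ranks
      agree <- prefix_depths(lin_mat, t_idx)
      cands <- which(agree == target_d)
      if (length(cands) > 0L) {
        co <- cands[sample.int(length(cands), min(2L, length(cands)))]
        realized_d <- target_d
        for (j in co) {
          rows <- rbind(rows, data.frame(
            query_id = qid, subject_id = subjects[j],
            pct_identity = round(identity - stats::runif(1L, 0.1, 0.3), 1),
            alignment_length = alen, evalue = 1e-50,
            bitscore = round(base_bs * stats::runif(1L, 0.985, 1), 1),
            stringsAsFactors = FALSE))
        }
      }
    }
    # off-margin decoy (within thresholds, below the 2% bitscore band)
    rows <- rbind(rows, data.frame(
      query_id = qid, subject_id = sample(subjects, 1L),
      pct_identity = round(stats::runif(1L, 80, 95), 1),
      alignment_length = alen, evalue = 1e-30,
      bitscore = round(base_bs * stats::runif(1L, 0.85, 0.95), 1),
      stringsAsFactors = FALSE))
    # low-score decoy failing both thresholds
    rows <- rbind(rows, data.frame(
      query_id = qid, subject_id = sample(subjects, 1L),
      pct_identity = round(stats::runif(1L, 70, 90), 1),
      alignment_length = round(stats::runif(1L, 40, 95)),
      evalue = 1e-06, bitscore = round(stats::runif(1L, 50, 140), 1),
      stringsAsFactors = FALSE))
    retained <- rows$bitscore >= config$bitscore_min &
      rows$alignment_length >= config$alen_min &
      rows$bitscore >= (1 - config$margin_fraction) * max(rows$bitscore)
    exp_depth <- min(realized_d,
                     identity_rank_depth(max(rows$pct_identity[retained]),
                                         config))
    true_lin <- lin_mat[t_idx, ]
    exp_lin <- if (exp_depth == 0L) "" else
      format_lineage(true_lin[seq_len(exp_depth)])
    truth_rows[[qi]] <- data.frame(
      query_id = qid, true_subject = subjects[t_idx],
      identity = rows$pct_identity[1L],
      expected_lineage = exp_lin,
      expected_rank = if (exp_depth == 0L) "unassigned" else
        tax_ranks()[exp_depth],
      lca_depth = realized_d, stringsAsFactors = FALSE)
    hit_rows[[qi]] <- rows
  }
  hits <- do.call(rbind, hit_rows)
  hits$lineage <- unname(lineage_map[hits$subject_id])
  hits$lineage_missing <- FALSE
  rownames(hits) <- NULL
  list(hits = hits, truth = do.call(rbind, truth_rows))
}

# Common-prefix depth of every reference lineage against lineage `idx`;
# the entry for idx itself is set to 0 so it is never sampled as a co-hit.
prefix_depths <- function(lin_mat, idx) {
  agree <- lin_mat == matrix(lin_mat[idx, ], nrow(lin_mat), 7L, byrow = TRUE)
  depth <- apply(agree, 1L, function(a) {
    d <- which(!a)
    if (length(d) == 0L) 7L else d[1L] - 1L
  })
  depth[idx] <- 0L
  depth
}

#' Default design of the synthetic benthic survey
#'
#' The study conditions emulated by [gen_community()]: five latitudinal
#' regions crossed with three depth strata at 6 samples per cell (90 true
#' samples), two negative controls per handling stage (field, extraction,
#' PCR), 15 phyla of 20 OTUs each, planted compositional drivers (one
#' phylum pair loading on latitude with opposite signs, one pair on depth,
#' one pair on oxygen saturation), planted richness-latitude slopes by
#' stratum (negative epibenthic and mesobenthic, zero bathybenthic), five
#' contaminant OTUs present in every library, and oxygen missing for a
#' fraction of samples (sensor availability varies by sampling platform).
#'
#' @param n_per_cell Samples per region x depth-category cell.
#' @param effect_size Multiplier on all planted phylum-covariate loadings
#'   (0 gives a null community with no environmental structure).
#' @param richness_slopes Named vector of planted OTUs-per-degree-latitude
#'   slopes for the three strata.
#' @return A list of design parameters consumed by [gen_community()].
#' @export
community_design <- function(n_per_cell = 6L, effect_size = 1,
                             richness_slopes = c(epibenthic = -6,
                                                 mesobenthic = -3,
                                                 bathybenthic = 0)) {
  n_phyla <- 15L
  effects <- matrix(0, n_phyla, 3L,
                    dimnames = list(sprintf("phylum_%02d", seq_len(n_phyla)),
                                    c("latitude", "depth", "oxygen")))
  effects["phylum_01", ] <- c(-1.0, 0,  0)   # southern-enriched
  effects["phylum_02", ] <- c( 1.0, 0,  0)   # northern-enriched
  effects["phylum_03", ] <- c( 0,  1.1,  0)  # deep-enriched
  effects["phylum_04", ] <- c( 0, -1.1,  0)  # shallow-enriched
  effects["phylum_05", ] <- c( 0,  0, -1.2)  # anoxia-associated
  effects["phylum_06", ] <- c( 0,  0,  1.2)  # oxic-associated
  list(n_per_cell = n_per_cell,
       n_controls_per_role = 2L,
       n_phyla = n_phyla,
       otus_per_phylum = 20L,
       effects = effects * effect_size,
       richness_base = c(epibenthic = 160, mesobenthic = 140,
                         bathybenthic = 120),
       richness_slopes = richness_slopes,
       richness_sd = 8,
       latitude_range = c(12.5, 29.5),
       latitude_center = 21,
       mean_library_size = 20000,
       library_size_sdlog = 0.5,
       saturation_half = 5000,
       control_library_size = 5000,
       n_contaminants = 5L,
       contaminant_load = c(0.02, 0.012, 0.009, 0.007, 0.005),
       overdispersion_sd = 0.5,
       oxygen_missing_fraction = 0.15)
}

#' Generate a synthetic benthic community with known ground truth
#'
#' Draws an OTU-by-sample count table, matching environmental metadata and
#' negative controls from the design of [community_design()]. Counts follow
#' a compound log-normal-Poisson model: each OTU carries a baseline
#' log-abundance plus its phylum's planted linear response to standardised
#' latitude, depth and oxygen, plus log-normal overdispersion; per-sample
#' OTU presence is subsampled to a planted richness target that is linear
#' in latitude within each depth stratum. Contaminant OTUs contribute reads
#' to every library (true samples and blanks) in proportion to a
#' per-contaminant load, the scenario the constant-anchor subtraction of
#' [remove_contaminants()] is designed for; blanks additionally carry a
#' trace of real OTUs.
#'
#' @param design A [community_design()] list.
#' @param seed Integer seed; regeneration with the same seed is identical.
#' @return List with `table` (an [otu_table()] including control columns),
#'   `env` (metadata data frame for the true samples, oxygen partially
#'   missing), `assignments` (a `taxonomy_assignments` frame giving each
#'   OTU's phylum/class, for aggregation), and `truth` (planted
#'   parameters: contaminant ids and loads, expected per-sample
#'   contaminant reads, effects matrix, richness slopes, phylum of each
#'   OTU, unmasked oxygen).
#' @export
gen_community <- function(design = community_design(), seed = 1L) {
  set.seed(seed)
  d <- design
  regions <- region_labels()
  strata <- c("epibenthic", "mesobenthic", "bathybenthic")
  cuts <- c(d$latitude_range[1L], default_region_boundaries(),
            d$latitude_range[2L])
  if (d$n_per_cell < 1L) stop("infeasible design: empty cells")

  # --- sample frame -------------------------------------------------------
  cells <- expand.grid(region = seq_along(regions), stratum = strata,
                       rep = seq_len(d$n_per_cell),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ns <- nrow(cells)
  lat <- stats::runif(ns, cuts[cells$region], cuts[cells$region + 1L])
  depth <- ifelse(cells$stratum == "epibenthic", stats::runif(ns, 20, 199),
           ifelse(cells$stratum == "mesobenthic", stats::runif(ns, 200, 1000),
                  stats::runif(ns, 1001, 2415)))
  oxygen_full <- pmax(5, 90 * exp(-depth / 1500) + stats::rnorm(ns, 0, 10))
  temperature <- 21.7 + 8 * exp(-depth / 150) + stats::rnorm(ns, 0, 0.3)
  salinity <- 40.5 + 2e-4 * depth + stats::rnorm(ns, 0, 0.15)
  longitude <- 43 - 0.55 * (lat - 12.5) + stats::rnorm(ns, 0, 0.3)
  sample_ids <- sprintf("S%03d", seq_len(ns))

  # --- OTU pool -----------------------------------------------------------
  n_otus <- d$n_phyla * d$otus_per_phylum
  otu_ids <- sprintf("otu_%04d", seq_len(n_otus))
  phylum_of <- rep(rownames(d$effects), each = d$otus_per_phylum)
  class_of <- paste0(phylum_of, "_class_",
                     rep(rep(1:2, length.out = d$otus_per_phylum), d$n_phyla))
  base_log <- stats::rnorm(n_otus, 0, 1)

  z <- function(x) (x - mean(x)) / stats::sd(x)
  Z <- cbind(latitude = z(lat), depth = z(depth), oxygen = z(oxygen_full))
  eta <- d$effects[phylum_of, , drop = FALSE] %*% t(Z)  # otus x samples

  # richness: linear in latitude within stratum, modulated by a saturating
  # function of sequencing depth (deeper-sequenced libraries recover more
  # OTUs, flattening out past the half-saturation depth); the modulation is
  # normalised to mean 1 so the planted latitude slopes are preserved
  lib_size <- round(stats::rlnorm(ns, log(d$mean_library_size),
                                  d$library_size_sdlog))
  sat <- lib_size / (lib_size + d$saturation_half)
  sat <- sat / mean(sat)
  richness_target <- round((d$richness_base[cells$stratum] +
                              d$richness_slopes[cells$stratum] *
                                (lat - d$latitude_center) +
                              stats::rnorm(ns, 0, d$richness_sd)) * sat)
  richness_target <- pmin(pmax(richness_target, 20L), n_otus)

  counts <- matrix(0L, n_otus, ns, dimnames = list(otu_ids, sample_ids))
  for (s in seq_len(ns)) {
    w <- exp(base_log + eta[, s] + stats::rnorm(n_otus, 0, d$overdispersion_sd))
    present <- sample.int(n_otus, richness_target[s], prob = w)
    lam <- lib_size[s] * w[present] / sum(w[present])
    cs <- stats::rpois(length(present), lam)
    cs[cs == 0L] <- 1L   # presence is planted; keep richness exact
    counts[present, s] <- cs
  }

  # --- contaminants and controls -----------------------------------------
  n_ctrl <- 3L * d$n_controls_per_role
  ctrl_ids <- sprintf("CTRL%02d", seq_len(n_ctrl))
  ctrl_roles <- rep(c("field_control", "extraction_control", "pcr_control"),
                    each = d$n_controls_per_role)
  contam_ids <- sprintf("contam_%02d", seq_len(d$n_contaminants))
  load <- rep_len(d$contaminant_load, d$n_contaminants)

  contam_true <- matrix(
    stats::rpois(d$n_contaminants * ns, outer(load, lib_size)),
    d$n_contaminants, ns, dimnames = list(contam_ids, sample_ids))
  contam_ctrl <- matrix(
    stats::rpois(d$n_contaminants * n_ctrl, load * d$control_library_size),
    d$n_contaminants, n_ctrl, dimnames = list(contam_ids, ctrl_ids))
  carry <- matrix(0L, n_otus, n_ctrl, dimnames = list(otu_ids, ctrl_ids))
  carry_otus <- sample.int(n_otus, 20L)
  carry[carry_otus, ] <- stats::rpois(20L * n_ctrl, 0.3)

  all_counts <- rbind(cbind(counts, carry),
                      cbind(contam_true, contam_ctrl))
  storage.mode(all_counts) <- "integer"
  roles <- stats::setNames(c(rep("true_sample", ns), ctrl_roles),
                           c(sample_ids, ctrl_ids))
  table <- otu_table(all_counts, roles)

  # --- metadata (oxygen masked for a sample subset) ----------------------
  oxygen <- oxygen_full
  n_miss <- round(d$oxygen_missing_fraction * ns)
  if (n_miss > 0L) oxygen[sample.int(ns, n_miss)] <- NA_real_
  env <- data.frame(sample_id = sample_ids, latitude = lat,
                    longitude = longitude, depth_m = depth,
                    temperature = temperature, salinity = salinity,
                    oxygen_saturation = oxygen, stringsAsFactors = FALSE)

  assignments <- do.call(rbind, lapply(seq_len(n_otus), function(i) {
    assignment_row(otu_ids[i], lineage("Bacteria", phylum_of[i], class_of[i]),
                   "class", "class", 85, 1L, 1L, 1L)
  }))
  class(assignments) <- c("taxonomy_assignments", "data.frame")

  truth <- list(contaminant_ids = contam_ids,
                contaminant_loads = stats::setNames(load, contam_ids),
                contaminant_reads = contam_true,
                effects = d$effects,
                richness_slopes = d$richness_slopes,
                richness_target = stats::setNames(richness_target, sample_ids),
                phylum_of_otu = stats::setNames(phylum_of, otu_ids),
                oxygen_full = stats::setNames(oxygen_full, sample_ids),
                seed = seed)
  list(table = table, env = env, assignments = assignments, truth = truth)
}

#' Write a full synthetic dataset to disk
#'
#' Emits the file set consumed by [run_pipeline()]: `hits.tsv`,
#' `lineages.tsv`, `otu.tsv`, `roles.tsv`, `meta.csv` and a JSON summary of
#' the planted truth. The hit queries are the community's OTUs, each with a
#' true reference source drawn from its planted phylum, so the taxonomy
#' stage reconstructs the phylum labels the community effects were planted
#' on (contaminant OTUs get no hits and stay unassigned).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling every generator.
#' @param n_reference Number of reference subjects for the taxonomy stage.
#' @param design A [community_design()].
#' @return Invisibly, the named list of file paths written, plus the
#'   in-memory `community` and `hit_truth` objects as attributes.
#' @export
write_synthetic_dataset <- function(out_dir, seed = 1L,
                                    n_reference = 150L,
                                    design = community_design()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(hits = file.path(out_dir, "hits.tsv"),
                lineages = file.path(out_dir, "lineages.tsv"),
                otu = file.path(out_dir, "otu.tsv"),
                roles = file.path(out_dir, "roles.tsv"),
                meta = file.path(out_dir, "meta.csv"),
                truth = file.path(out_dir, "truth.json"))
  comm <- gen_community(design, seed = seed + 2L)
  ref <- gen_reference(n_reference, seed = seed, n_phyla = design$n_phyla)
  gh <- gen_hits(ref, seed = seed + 1L,
                 otu_phyla = comm$truth$phylum_of_otu)
  write_lineage_map(ref, paths$lineages)
  hit_cols <- gh$hits
  out <- data.frame(hit_cols$query_id, hit_cols$subject_id,
                    hit_cols$pct_identity, hit_cols$alignment_length,
                    0L, 0L, 1L, hit_cols$alignment_length,
                    1L, hit_cols$alignment_length,
                    format(hit_cols$evalue, scientific = TRUE),
                    hit_cols$bitscore)
  utils::write.table(out, paths$hits, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_otu_table(comm$table, paths$otu, paths$roles)
  write_sample_metadata(comm$env, paths$meta)
  jsonlite::write_json(
    list(seed = seed,
         contaminant_ids = comm$truth$contaminant_ids,
         contaminant_loads = comm$truth$contaminant_loads,
         richness_slopes = as.list(comm$truth$richness_slopes),
         hit_truth = gh$truth),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(paths, "community") <- comm
  attr(paths, "hit_truth") <- gh$truth
  invisible(paths)
}
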