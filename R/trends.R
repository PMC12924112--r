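#' Per-sample OTU richness
#'
#' Number of OTUs with a non-zero count in each sample; purely
#' presence-based, so invariant to count scaling.
#'
#' @param table An [otu_table()] or count matrix (OTUs x samples).
#' @return Named integer vector, one entry per sample.
#' @export
otu_richness <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  colSums(counts > 0L)
}

#' Richness-latitude regression per depth stratum
#'
#' Fits an ordinary least-squares regression of OTU richness on latitude
#' separately within each depth category, with a two-sided t-test on the
#' latitude slope and a pointwise 95% confidence band for the conditional
#' mean evaluated on a latitude grid. Strata with fewer than 3 samples are
#' skipped with a warning.
#'
#' @param richness Numeric vector of per-sample richness.
#' @param latitude Numeric vector of latitudes, aligned with `richness`.
#' @param depth_category Character/factor vector of stratum labels.
#' @param conf_level Confidence level of the band (default 0.95).
#' @param grid_length Number of grid points for the band.
#' @return A list of class `stratified_fits`, one element per stratum:
#'   each a list with `stratum`, `n`, `slope`, `intercept`, `slope_se`,
#'   `t_value`, `p_value`, and `band` (data frame `latitude`, `fit`,
#'   `lower`, `upper`).
#' @export
stratified_regression <- function(richness, latitude, depth_category,
                                  conf_level = 0.95, grid_length = 50L) {
  stopifnot(length(richness) == length(latitude),
            length(richness) == length(depth_category))
  out <- list()
  for (s in unique(as.character(depth_category))) {
    idx <- depth_category == s
    if (sum(idx) < 3L) {
      warning("stratum '", s, "' has fewer than 3 samples; skipped")
      next
    }
    d <- data.frame(richness = richness[idx], latitude = latitude[idx])
    fit <- stats::lm(richness ~ latitude, data = d)
    cf <- summary(fit)$coefficients
    grid <- data.frame(latitude = seq(min(d$latitude), max(d$latitude),
                                      length.out = grid_length))
    band <- stats::predict(fit, newdata = grid, interval = "confidence",
                           level = conf_level)
    out[[s]] <- list(stratum = s, n = sum(idx),
                     slope = unname(cf["latitude", "Estimate"]),
                     intercept = unname(cf["(Intercept)", "Estimate"]),
                     slope_se = unname(cf["latitude", "Std. Error"]),
                     t_value = unname(cf["latitude", "t value"]),
                     p_value = unname(cf["latitude", "Pr(>|t|)"]),
                     band = data.frame(latitude = grid$latitude,
                                       fit = band[, "fit"],
                                       lower = band[, "lwr"],
                                       upper = band[, "upr"]))
  }
  structure(out, class = "stratified_fits")
}

#' @export
print.stratified_fits <- function(x, ...) {
  for (f in x) {
    cat(sprintf("%-12s n = %3d  slope = %8.2f OTUs/degree  p = %.4g\n",
                f$stratum, f$n, f$slope, f$p_value))
  }
  invisible(x)
}

#' Asymptotic saturation fit of OTUs against sequencing depth
#'
#' Fits a saturating curve to per-sample (reads, OTUs) pairs by nonlinear
#' least squares, to assess whether additional sequencing would still
#' discover OTUs. Two standard forms are available: Michaelis-Menten
#' `a x / (b + x)` (asymptote `a`, half-saturation `b` reads) and the
#' asymptotic exponential `a (1 - exp(-x / b))`. Starting values are
#' self-chosen (`a0 = max(otus)`, `b0 = median(reads)`) and fitting uses
#' Levenberg-Marquardt least squares.
#'
#' @param reads Positive numeric vector of per-sample read counts.
#' @param otus Positive numeric vector of per-sample OTU counts.
#' @param model_form `"michaelis_menten"` (default) or `"exponential"`.
#' @return A list of class `saturation_fit`: `asymptote`,
#'   `half_saturation`, `rss`, `model_form`, `predict` (function of
#'   reads), `converged`.
#' @export
saturation_fit <- function(reads, otus,
                           model_form = c("michaelis_menten", "exponential")) {
  model_form <- match.arg(model_form)
  stopifnot(length(reads) == length(otus), all(reads > 0), all(otus > 0))
  x <- as.numeric(reads); y <- as.numeric(otus)
  curve <- if (model_form == "michaelis_menten") {
    function(p, x) p[[1L]] * x / (p[[2L]] + x)
  } else {
    function(p, x) p[[1L]] * (1 - exp(-x / p[[2L]]))
  }
  fit <- minpack.lm::nls.lm(
    par = c(a = max(y), b = stats::median(x)),
    fn = function(p) y - curve(p, x),
    lower = c(1e-8, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4)
    stop("saturation fit did not converge: ", fit$message,
         " (info = ", fit$info, ")")
  co <- fit$par
  structure(list(asymptote = co[["a"]], half_saturation = co[["b"]],
                 rss = sum(fit$fvec^2),
                 model_form = model_form,
                 predict = function(x) curve(co, x),
                 converged = TRUE),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("saturation_fit (%s): asymptote %.1f OTUs, half-saturation %.0f reads\n",
              x$model_form, x$asymptote, x$half_saturation))
  invisible(x)
}
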