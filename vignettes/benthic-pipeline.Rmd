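---
title: "Post-clustering analysis of benthic 16S surveys with benthos16S"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-clustering analysis of benthic 16S surveys with benthos16S}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthos16S)
```

# What the package does

`benthos16S` covers the stages of a 16S rRNA amplicon survey of marine
sediments that come *after* reads have been merged, denoised and clustered
into OTUs: assigning a consensus taxonomy to each OTU from tabular
sequence-similarity hits, removing contamination witnessed by negative
controls, and analysing community structure along environmental gradients
with compositional methods. A seeded synthetic-data generator plants known
lineages, contaminants and gradients so that every stage can be validated by
recovery tests, and `run_pipeline()` chains everything deterministically.

The motivating setting is a basin-scale survey of Red Sea sediments: samples
spread over roughly 12.5-29.5 degrees N and 20-2400 m of water depth, with
latitude, seafloor depth and near-bottom oxygen saturation as the candidate
drivers of community composition, and OTU richness examined against latitude
separately within the three benthic depth strata (epibenthic < 200 m,
mesobenthic 200-1000 m, bathybenthic > 1000 m).

# Consensus taxonomy from similarity hits

Each OTU arrives with a set of hits against a ranked reference database
(SILVA-style seven-rank lineages: domain, phylum, class, order, family,
genus, species), already restricted by the search's E-value threshold
(1e-05). Assignment proceeds in four steps:

1. **Low-score exclusion.** Hits with bitscore < 150 *or* alignment length
   < 100 bp are excluded. The disjunctive reading is the package default
   (`filter_config(low_score_rule = "or")`): a conjunctive rule would retain
   very short but perfectly matching alignments on bitscore alone, which
   contradicts the stringent intent of the filter. The conjunctive variant
   is available as `low_score_rule = "and"`.
2. **Bitscore margin.** Only hits whose bitscore lies within 2% of the
   query's best bitscore are kept (boundary inclusive, so the best hit
   always survives).
3. **Lowest common ancestor.** If several taxa remain, the retained
   lineages are collapsed to their deepest shared prefix, comparing names
   rank by rank and stopping at the first disagreement or the first rank
   unnamed in any lineage.
4. **Identity trimming.** The consensus lineage is truncated to the deepest
   rank supported by the percent identity of the retained hits, with strict
   cutoffs 98 / 95 / 90 / 85 / 80 / 75% for species through phylum.
   Identity at or below 75% leaves the OTU wholly unassigned; set
   `retain_domain = TRUE` to keep a domain label instead. The identity used
   is the *maximum* among margin-retained, lineage-bearing hits - the least
   destructive choice consistent with "the best retained evidence permits
   rank r".

The final depth is therefore `min(consensus depth, identity-permitted
depth)`. The test suite checks this against an independent rank-by-rank
oracle on a thousand randomised hit sets per run and asserts invariance
under permutation of the hit rows.

Two subtleties uncovered during validation are worth recording. The
monotonicity property "a wider bitscore margin never deepens an assignment"
holds only when (i) percent identity is non-increasing in bitscore within a
query and (ii) every retained hit carries a lineage. Both are properties of
real alignment data violated only by adversarial inputs: a widened margin
could otherwise admit a lower-scoring hit of *higher* identity (deepening
the identity-permitted rank), or replace a lineage-less singleton with an
informative hit. The monotonicity fixtures therefore couple identity to
bitscore rank and are lineage-complete, while the oracle-equivalence
fixtures leave both unconstrained as a harsher stress.

# Decontamination against negative controls

Field, extraction and PCR blanks capture contamination introduced at each
handling stage. `remove_contaminants()` implements a transparent
constant-anchor subtraction contract rather than wrapping any particular
published tool: the mean proportional abundance of each OTU across the
blanks defines the contamination profile; the most control-abundant OTU
(the anchor) is assumed to be pure contamination in true samples, so its
observed count in a sample fixes that sample's contamination scale; every
profiled OTU then loses `profile_i / profile_anchor x anchor count` reads,
floored at zero and rounded *down* so decontamination never manufactures
reads. OTUs absent from all blanks are untouched; OTUs left without reads
anywhere are dropped and reported. Blanks are pooled by default;
`per_role = TRUE` subtracts per control class sequentially. A
prevalence-style alternative (`method = "prevalence_zero"`) simply zeroes
any OTU seen in a control.

The model behind the contract is additive carry-over proportional to a
per-contaminant load in every library, which is exactly what the synthetic
generator plants; under that model the subtraction removes > 95% of planted
contaminant reads in the default design, with the shortfall driven by
counting noise in the blank-derived profile.

# Compositional community analysis

Counts are compositions, so all community statistics run on centred
log-ratio (clr) transformed abundances: `clr(x)_i = ln(x_i + d) - mean_j
ln(x_j + d)`. Zero replacement is a first-class parameter because no single
convention is canonical: `add_one` (default, on integer counts),
`add_half_min`, a multiplicative replacement on proportions, or `none`
(errors on zeros; useful because clr without pseudocount is exactly
scale-invariant, which the tests exploit). Every transformed sample sums to
zero within 1e-9.

Upstream of the transform, OTUs seen in fewer than 3 samples are discarded
(`prevalence_filter()`), counts are aggregated to a rank
(`aggregate_taxa()`, conserving per-sample totals exactly, with top-k
pooling into "other" and a nested top-phyla x top-2-classes view), samples
are classified into depth strata and into five latitudinal regions. The
region cut points default to `c(17, 20.5, 24, 28)` degrees N - configuration
values spanning the basin, since published regionalisations do not print
coordinates - and are overridable everywhere; no test asserts them.

`correlation_grid()` computes Pearson correlations of clr abundances
against continuous covariates and one-hot indicators of the derived
categories, on pairwise-complete observations with the per-cell n reported.
Oxygen saturation is typically available only for a platform subset, so its
column automatically uses the observed subset; cells with n < 3 or a
constant member are missing, never zero. Depth enters in raw metres by
default (a log-depth column can be supplied like any other covariate).

# Constrained ordination and forward selection

`rda_fit()` performs redundancy analysis from first principles: the centred
response is regressed on the centred constraints by QR least squares, the
fitted values are eigen-decomposed (constrained axes), and the residuals
give the unconstrained axes; eigenvalues are on the variance scale so
constrained plus residual eigenvalues reproduce the total variance to
1e-9. Scores are reported in correlation-style (type 2) scaling, with axis
signs fixed by making the largest-magnitude species loading positive.
Linearly dependent constraint columns are dropped with a warning. The test
suite cross-checks the eigenvalues against both an explicit hat-matrix
oracle and the vegan implementation, and asserts the reduction to principal
components under a saturated constraint basis.

Entry testing uses reduced-model residual permutation: response and
candidate are residualised on the already-selected terms, the candidate's
pseudo-F is computed, and its null distribution is built by permuting the
residualised candidate rows; `p = (1 + #[F* >= F]) / (1 + n_perm)`. Under
the null the p-values are uniform (checked by simulation each run).
Categorical candidates enter and leave as indicator blocks tested jointly.

`forward_select()` adds, at each step, the candidate with the largest
adjusted-R-squared gain, provided its permutation p-value is at most
`alpha` (default 0.05, `n_perm` default 999), under the classical double
stopping rule that also bounds the search by the adjusted R-squared of the
full model. The ceiling convention deserves a note. When the remaining
candidates are pure noise, the expected adjusted R-squared of the full
model *equals* that of the model holding all informative variables - the
adjustment exactly offsets the variance a noise covariate absorbs - so a
ceiling applied to each *candidate* model (the convention of the well-known
stepwise implementations) degenerates into a coin flip on whether the last
informative variable may enter, and in simulations it drops a planted
driver in roughly half the replicates. The package therefore applies the
ceiling to the *selected* model by default (`ceiling = "selected"`): the
search stops once the selected model has reached the full model's adjusted
R-squared, which preserves the ceiling's protection against overfitting
while letting every informative step be decided by its own permutation
test. The candidate-model convention remains available as
`ceiling = "candidate"` for compatibility.

Even so, exact-set recovery is bounded by the entry test itself: with five
noise candidates and `alpha = 0.05`, the *best* of five null candidates is
significant in about `1 - 0.95^5 ~ 23%` of datasets, so a noise covariate
occasionally appends to the recovered driver set. This is a property of
marginal stepwise testing (no familywise correction), independent of effect
size; the acceptance suite reports exact-set recovery around 70-80% on the
default design, with all three planted drivers recovered before any noise
covariate in essentially every replicate.

# Richness trends and saturation

`otu_richness()` counts present OTUs per sample on the decontaminated,
prevalence-filtered table (richness is computed after filtering, matching
the pipeline order; the pre-filter alternative is a one-liner on the raw
table). `stratified_regression()` fits ordinary least squares of richness
on latitude within each depth stratum, reporting the slope in OTUs per
degree latitude, its two-sided t-test, and a pointwise 95% confidence band
for the *conditional mean* (a regression band, not a prediction band).
Strata with fewer than 3 samples are skipped with a warning. Slope
confidence intervals achieve 95 +/- 2% coverage in simulation.

`saturation_fit()` fits an asymptotic model of OTUs against reads per
sample by Levenberg-Marquardt least squares, with the functional form as a
flag - Michaelis-Menten `a x / (b + x)` (default) or asymptotic exponential
`a (1 - exp(-x/b))` - since no single form is canonical for
reads-saturation curves. Starting values are self-chosen (`a0 = max(otus)`,
`b0 = median(reads)`); the fit recovers exact parameters to 1e-6 relative
error on noiseless curves and degrades gracefully to a flat line on
constant data.

# The synthetic study design

`community_design()` fixes the emulated study conditions: 5 latitudinal
regions x 3 depth strata x 6 samples (90 true samples), two blanks per
control class (6 controls), 300 OTUs in 15 phyla. Counts follow a compound
log-normal-Poisson: each OTU has a baseline log-abundance (sd 1), its
phylum's planted linear response to standardised latitude, depth and oxygen
(three phylum pairs loading with opposite signs at coefficients 1.0-1.2),
and log-normal overdispersion (sd 0.5); per-sample presence is subsampled
to a planted richness target, linear in latitude within stratum (slopes -6,
-3 and 0 OTUs per degree for epi-, meso- and bathybenthic; bases 160, 140,
120; Gaussian jitter sd 8) and modulated by a saturating function of
library size (half-saturation 5000 reads, mean library 20,000, log-normal
sd 0.5) normalised to preserve the planted slopes. Oxygen decays with depth
(90 exp(-depth/1500) + noise sd 10, floored at 5% saturation) and is masked
for 15% of samples, mirroring platform-restricted sensor coverage. Five
contaminant OTUs contribute Poisson reads proportional to loads of 0.5-2%
of each library, blanks carry the contaminants plus a trace of 20 real
OTUs. These sizes keep a full pipeline run under a second while every
planted structure is comfortably detectable; they were chosen once as
realistic desk-scale analogues of a basin survey, and the recovery tests
run against them unchanged.

What the generator does *not* emulate: sequence-level error (chimeras, PCR
noise), phylogenetic correlation between OTUs beyond shared phylum effects,
spatial autocorrelation within regions, and contaminants whose abundance
anti-correlates with input biomass. Passing recovery tests therefore show
the algorithms implement their contracts, not that real sediment data meet
these assumptions.

# Numerical choices and edge cases

- Counts are strictly integer at ingest; fractional abundances exist only
  downstream of the clr transform, and subtraction floors at zero on
  integers (with a 1e-9 epsilon guarding the floor against binary
  representation error).
- Margin and identity cutoffs compare with the documented strictness
  (margin boundary inclusive, identity strictly greater-than) at every
  rank.
- Eigenvalues below 1e-12 of the leading one are treated as null axes; axis
  signs are fixed by the largest-magnitude loading.
- A candidate covariate spanned by the already-selected terms residualises
  to numerical dust; columns whose residual norm falls below 1e-8 of the
  original are dropped and the test returns p = 1.
- Depth classification errors on non-positive depths; region classification
  returns an explicit `"outside-domain"` label rather than guessing.
- All generators and the pipeline are bit-reproducible under a fixed seed;
  the pipeline writes per-stage timings only to its log so that data
  artifacts are byte-identical across reruns.

# Known limitations

- The decontamination contract assumes contamination proportional to a
  per-library scale anchored on the most control-abundant OTU; it will
  under-remove contaminants that vary independently of the anchor.
- Forward selection inherits the selection-inference limits of stepwise
  procedures discussed above; treat the selected set as descriptive, not
  inferential.
- Pearson correlation grids are linear summaries; monotone non-linear
  responses (e.g. threshold responses to oxygen) are attenuated.
- The saturation fit treats samples as independent design points and knows
  nothing of taxonomic overlap between samples.
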