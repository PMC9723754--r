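#' Assemble the per-sample microbial facet table
#'
#' Runs every facet-index computation over a measurement battery and joins
#' the results into one per-sample table: biomass facets (total, active,
#' B:F), taxonomic facets (Shannon diversity, richness, evenness and
#' dominance for bacteria and fungi, computed on rarefied ASV tables),
#' functional facets (catabolic-gene score, gene evenness), physiological
#' facets (SIR efficiency and range), microbial respiration, and soil
#' stoichiometric ratios.
#'
#' ASV tables are rarefied before diversity is computed; samples below the
#' rarefaction depth get `NA` diversity values (and a warning). `bac_div`
#' and `fun_div` are the Shannon diversities, the facet names used
#' throughout the downstream models.
#'
#' @param data a measurement battery as produced by [simulate_dataset()]:
#'   a list with elements `design`, `soil`, `asv_bacteria`, `asv_fungi`,
#'   `plfa`, `genes`, `catabolic`, `microresp`, `active_biomass`,
#'   `respiration`.
#' @param rarefy_depth_bac,rarefy_depth_fun rarefaction depths for the
#'   bacterial and fungal ASV tables (defaults 28897 and 16542 reads).
#' @param rarefy set `FALSE` to compute diversity on the raw counts.
#' @param scaling gene scaling passed to [gene_scores()].
#' @param marker_map PLFA marker map passed to [biomass_summary()].
#' @param seed seed for the rarefaction subsampling.
#' @return data.frame with one row per sample; attribute `scaling` records
#'   the gene-scaling scheme.
#' @export
compute_facets <- function(data,
                           rarefy_depth_bac = 28897,
                           rarefy_depth_fun = 16542,
                           rarefy = TRUE,
                           scaling = c("minmax", "zscore"),
                           marker_map = plfa_marker_map(),
                           seed = 1L) {
  scaling <- match.arg(scaling)
  samples <- data$design$sample

  bio <- biomass_summary(data$plfa, marker_map)
  gen <- gene_scores(data$genes, data$catabolic, scaling)
  eff <- sir_efficiency(data$microresp)
  rng <- sir_range(data$microresp)
  sto <- soil_stoichiometry(data$soil$toc, data$soil$tn, data$soil$tp)

  div_of <- function(counts, depth, prefix, seed) {
    if (rarefy) counts <- rarefy_counts(counts, depth, seed = seed)
    d <- diversity_indices(counts)
    names(d)[-1] <- paste0(prefix, c("_richness", "_div", "_evenness",
                                     "_dominance"))
    d
  }
  bdiv <- div_of(data$asv_bacteria, rarefy_depth_bac, "bac",
                 derive_seed(seed, 11L))
  fdiv <- div_of(data$asv_fungi, rarefy_depth_fun, "fun",
                 derive_seed(seed, 12L))

  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  merge_in <- function(out, tab) merge(out, tab, by = "sample",
                                       all.x = TRUE, sort = FALSE)
  out <- merge_in(out, bio)
  out$active_biomass <- data$active_biomass[match(samples, names(data$active_biomass))]
  out <- merge_in(out, bdiv)
  out <- merge_in(out, fdiv)
  out <- merge_in(out, gen)
  out$sir_efficiency <- eff[match(samples, names(eff))]
  out$sir_range <- rng[match(samples, names(rng))]
  out$respiration <- data$respiration[match(samples, names(data$respiration))]
  out$cn <- sto$cn[match(samples, data$soil$sample)]
  out$cp <- sto$cp[match(samples, data$soil$sample)]
  out <- out[match(samples, out$sample), ]
  rownames(out) <- NULL
  attr(out, "scaling") <- scaling
  out
}
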