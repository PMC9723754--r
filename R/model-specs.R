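#' Built-in path-model specifications
#'
#' `facet_model_spec()` is the facet-level causal model: microbial biomass
#' (total, active), taxonomic profile (B:F, bacterial and fungal Shannon
#' diversity) and functional profile (catabolic-gene score, gene evenness)
#' are free to correlate (saturated exogenous block), drive the
#' physiological-potential indices (SIR efficiency and range), and,
#' together with the physiological indices, drive microbial respiration.
#'
#' `driver_model_spec()` extends it with the exogenous drivers: tree
#' species richness, soil humidity and the carbon-to-phosphorus ratio act
#' on the facets, the physiological indices and respiration.
#'
#' @param minimal keep only the edges that carry non-zero default
#'   generating coefficients (the specification used in parameter-recovery
#'   experiments); with `minimal = FALSE` all facet-to-function edges are
#'   free, mirroring the full hypothesis structure.
#' @return a [path_spec()].
#' @export
facet_model_spec <- function(minimal = TRUE) {
  facets <- c("total_biomass", "active_biomass", "bf_ratio",
              "bac_div", "fun_div", "cata_score", "fg_evenness")
  groups <- list(
    biomass = c("total_biomass", "active_biomass"),
    taxonomic = c("bf_ratio", "bac_div", "fun_div"),
    functional = c("cata_score", "fg_evenness"),
    physiological = c("sir_efficiency", "sir_range"),
    respiration = "respiration")
  if (minimal) {
    sc <- default_structural_coefficients()
    edges <- sc[sc$source %in% c(facets, "sir_efficiency", "sir_range") &
                  sc$target %in% c("sir_efficiency", "sir_range",
                                   "respiration"),
                c("source", "target")]
  } else {
    edges <- rbind(
      expand.grid(source = facets,
                  target = c("sir_efficiency", "sir_range", "respiration"),
                  stringsAsFactors = FALSE),
      data.frame(source = c("sir_efficiency", "sir_range"),
                 target = "respiration"))
  }
  path_spec(edges, groups = groups, variables = facets)
}

#' @rdname facet_model_spec
#' @export
driver_model_spec <- function(minimal = TRUE) {
  sc <- default_structural_coefficients()
  groups <- list(
    tree_diversity = "tree_richness",
    soil_chemistry = c("humidity", "cp"),
    biomass = c("total_biomass", "active_biomass"),
    taxonomic = c("bf_ratio", "bac_div", "fun_div"),
    functional = c("cata_score", "fg_evenness"),
    physiological = c("sir_efficiency", "sir_range"),
    respiration = "respiration")
  edges <- sc[, c("source", "target")]
  # bf_ratio and cata_score carry no directed edges in the default
  # structure; keep them out of the fitted model
  used <- unique(c(edges$source, edges$target))
  groups <- lapply(groups, intersect, used)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  path_spec(edges, groups = groups,
            variables = c("tree_richness", "humidity", "cp"))
}
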