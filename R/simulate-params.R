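#' Default structural coefficients of the generating causal model
#'
#' The standardized path coefficients used as generator defaults: tree
#' richness and soil drivers act on microbial facets, facets act on the
#' physiological-potential indices, and biomass, diversity and physiology
#' act on microbial respiration. Coefficients are on the standardized
#' scale, so a fitted standardized path estimate is directly comparable to
#' its generating value.
#'
#' @return data.frame with columns `source`, `target`, `coefficient`.
#' @export
default_structural_coefficients <- function() {
  data.frame(
    source = c("active_biomass", "fun_div", "sir_efficiency", "sir_range",
               "total_biomass", "active_biomass", "fg_evenness",
               "tree_richness", "tree_richness", "tree_richness",
               "humidity", "humidity", "cp"),
    target = c("respiration", "respiration", "respiration", "respiration",
               "sir_efficiency", "sir_efficiency", "sir_efficiency",
               "total_biomass", "bac_div", "sir_efficiency",
               "respiration", "total_biomass", "sir_range"),
    coefficient = c(0.590, 0.128, 0.176, 0.213,
                    0.209, 0.258, -0.179,
                    0.173, 0.164, 0.152,
                    0.312, -0.234, 0.269),
    stringsAsFactors = FALSE
  )
}

#' Default correlations between facet disturbances
#'
#' Residual correlations injected between facets that co-vary for reasons
#' outside the directed structure (shared microhabitat, shared substrate
#' pools): total vs active biomass, catabolic-gene score vs gene evenness,
#' and fungal diversity vs active biomass.
#'
#' @return data.frame with columns `a`, `b`, `cor`.
#' @export
default_disturbance_correlations <- function() {
  data.frame(a = c("total_biomass", "cata_score", "fun_div"),
             b = c("active_biomass", "fg_evenness", "active_biomass"),
             cor = c(0.45, 0.57, 0.20),
             stringsAsFactors = FALSE)
}

#' Default covariance of the latent soil-chemistry variables
#'
#' Correlation matrix over (toc, tn, tp, ph, humidity): organic carbon and
#' total nitrogen track each other closely in forest topsoils, phosphorus
#' less so, pH is mildly negatively related to organic matter, and
#' moisture mildly positively.
#'
#' @return 5x5 positive-definite correlation matrix.
#' @export
default_soil_covariance <- function() {
  v <- c("toc", "tn", "tp", "ph", "humidity")
  m <- diag(5)
  dimnames(m) <- list(v, v)
  set_cor <- function(a, b, r) { m[a, b] <<- r; m[b, a] <<- r }
  set_cor("toc", "tn", 0.70)
  set_cor("toc", "tp", 0.30)
  set_cor("tn", "tp", 0.35)
  set_cor("toc", "ph", -0.20)
  set_cor("toc", "humidity", 0.30)
  set_cor("tn", "humidity", 0.20)
  m
}

#' Parameters of the synthetic-data generator
#'
#' Bundles everything the generator needs: the structural coefficients of
#' the causal model, disturbance correlations, the soil-chemistry
#' covariance, per-variable disturbance SDs (default `"auto"`: chosen so
#' every latent facet has unit variance, making generating coefficients
#' directly comparable to standardized estimates), and the observation
#' layer's parameters (ASV pool sizes and read depths, PLFA marker noise,
#' gene-panel and substrate-panel response settings).
#'
#' @param structural_coefficients data.frame `source`/`target`/`coefficient`;
#'   the directed graph must be acyclic.
#' @param disturbance_correlations data.frame `a`/`b`/`cor`.
#' @param exogenous_covariance positive-definite covariance of the latent
#'   soil variables.
#' @param noise_sd `NULL` for automatic unit-variance calibration, or a
#'   named numeric vector of disturbance SDs (values >= 0; 0 gives the
#'   noiseless limit).
#' @param soil_noise_scale multiplier on the soil latent SDs (0 collapses
#'   every soil sample onto the mean vector).
#' @param log_richness use `log(species richness)` instead of the raw
#'   count in the structural equations.
#' @param n_taxa_bacteria,n_taxa_fungi ASV pool sizes.
#' @param depth_bacteria,depth_fungi rarefaction depths the read-depth
#'   draws are centred above, so the rarefaction stage is exercised.
#' @param asv_kappa Dirichlet concentration of the per-sample
#'   compositional jitter (larger = less noise).
#' @param shannon_base,shannon_slope intercept/slope mapping the latent
#'   diversity facet to the target Shannon diversity, per kingdom.
#' @param plfa_noise,gene_noise,microresp_noise lognormal measurement
#'   noise SDs (log scale) of the three assays.
#' @param seed integer seed stored with the parameters.
#' @return object of class `generator_params` (a validated list).
#' @export
generator_params <- function(structural_coefficients = default_structural_coefficients(),
                             disturbance_correlations = default_disturbance_correlations(),
                             exogenous_covariance = default_soil_covariance(),
                             noise_sd = NULL,
                             soil_noise_scale = 1,
                             log_richness = FALSE,
                             n_taxa_bacteria = 2000,
                             n_taxa_fungi = 800,
                             depth_bacteria = 28897,
                             depth_fungi = 16542,
                             asv_kappa = 5000,
                             shannon_base = c(bacteria = 6.4, fungi = 4.6),
                             shannon_slope = c(bacteria = 0.25, fungi = 0.35),
                             plfa_noise = 0.03,
                             gene_noise = 0.05,
                             microresp_noise = 0.03,
                             seed = 1L) {
  sc <- as.data.frame(structural_coefficients)
  stopifnot(all(c("source", "target", "coefficient") %in% names(sc)))
  facet_targets <- unique(sc$target)
  topo_order(unique(c(sc$source, sc$target)),
             sc[, c("source", "target")])  # errors on a cyclic graph
  ev <- eigen(exogenous_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("exogenous_covariance must be positive definite", call. = FALSE)
  if (!is.null(noise_sd)) {
    if (is.null(names(noise_sd)) || any(noise_sd < 0))
      stop("noise_sd must be a named vector of non-negative SDs", call. = FALSE)
  }
  stopifnot(soil_noise_scale >= 0, asv_kappa > 0,
            plfa_noise >= 0, gene_noise >= 0, microresp_noise >= 0)
  structure(list(
    structural_coefficients = sc,
    disturbance_correlations = as.data.frame(disturbance_correlations),
    exogenous_covariance = exogenous_covariance,
    noise_sd = noise_sd,
    soil_noise_scale = soil_noise_scale,
    log_richness = log_richness,
    n_taxa_bacteria = check_count(n_taxa_bacteria, "n_taxa_bacteria"),
    n_taxa_fungi = check_count(n_taxa_fungi, "n_taxa_fungi"),
    depth_bacteria = check_count(depth_bacteria, "depth_bacteria"),
    depth_fungi = check_count(depth_fungi, "depth_fungi"),
    asv_kappa = asv_kappa,
    shannon_base = shannon_base, shannon_slope = shannon_slope,
    plfa_noise = plfa_noise, gene_noise = gene_noise,
    microresp_noise = microresp_noise,
    seed = as.integer(seed)
  ), class = "generator_params")
}

#' @details `facet_structural_coefficients()` returns the facet-level
#'   subset (microbial facets acting on the physiological indices and on
#'   respiration, without the tree/soil drivers): the generating structure
#'   used by parameter-recovery experiments against [facet_model_spec()].
#' @rdname default_structural_coefficients
#' @export
facet_structural_coefficients <- function() {
  sc <- default_structural_coefficients()
  facets <- c("total_biomass", "active_biomass", "bf_ratio", "bac_div",
              "fun_div", "cata_score", "fg_evenness")
  sc[sc$source %in% c(facets, "sir_efficiency", "sir_range"), ]
}

# canonical facet variable names, in generation (topological) order
facet_variables <- function() {
  c("total_biomass", "active_biomass", "bf_ratio", "bac_div", "fun_div",
    "cata_score", "fg_evenness", "sir_efficiency", "sir_range",
    "respiration")
}
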