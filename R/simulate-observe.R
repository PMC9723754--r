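# Observation layer: turns latent facet scores into the measurement
# battery (ASV tables, PLFA markers, gene panel, MicroResp CO2 matrix,
# respiration and active-biomass vectors). Marginal maps are linear (with
# positivity floors) so facet indices recomputed from the observations
# stay linearly related to their latent counterparts.

# internal: composition family p_i(gamma) ~ exp(-gamma * rank_i) over S
# taxa, plus a lookup inverting target Shannon diversity (or Pielou
# evenness) to gamma. Monotone: gamma = 0 is uniform (max H), larger gamma
# more dominated.
geometric_profile <- function(S, gamma) {
  w <- exp(-gamma * seq(0, 1, length.out = S))
  w / sum(w)
}

shannon_of_gamma <- function(S, gamma) {
  vapply(gamma, function(g) shannon_entropy(geometric_profile(S, g)),
         numeric(1))
}

# invert H -> gamma on a fixed grid (H monotone decreasing in gamma)
gamma_for_shannon <- function(S, h_target, gamma_max = 200) {
  grid <- exp(seq(log(1e-3), log(gamma_max), length.out = 200))
  grid <- c(0, grid)
  h <- shannon_of_gamma(S, grid)   # strictly decreasing in gamma
  h_target <- pmin(pmax(h_target, min(h) + 1e-9), max(h) - 1e-9)
  stats::approx(rev(h), rev(grid), xout = h_target, ties = "ordered")$y
}

# single community draw: Dirichlet jitter around the profile, then
# multinomial reads
draw_community <- function(profile, kappa, depth) {
  w <- stats::rgamma(length(profile), shape = kappa * profile)
  if (sum(w) == 0) w[which.max(profile)] <- 1
  stats::rmultinom(1, size = depth, prob = w / sum(w))[, 1]
}

generate_asv_matrix <- function(z_div, S, depth_target, kappa,
                                h_base, h_slope, prefix) {
  n <- length(z_div)
  h_target <- h_base + h_slope * z_div
  gamma <- gamma_for_shannon(S, h_target)
  depths <- round(depth_target * stats::runif(n, 1.05, 1.40))
  counts <- matrix(0L, S, n,
                   dimnames = list(paste0(prefix, seq_len(S)),
                                   names(z_div)))
  for (j in seq_len(n)) {
    counts[, j] <- draw_community(geometric_profile(S, gamma[j]),
                                  kappa, depths[j])
  }
  counts
}

#' Generate the measurement battery from latent facets
#'
#' Observation models, per measurement:
#' \itemize{
#'   \item ASV tables: per-sample communities from a geometric-series
#'     composition whose Shannon diversity is linear in the latent
#'     diversity facet, with Dirichlet compositional jitter and
#'     multinomial read sampling at depths drawn above the rarefaction
#'     depth (so the rarefaction stage is exercised).
#'   \item PLFA markers: bacterial, fungal and unspecific marker pools
#'     split according to latent total biomass and B:F ratio, spread over
#'     markers with fixed weights and lognormal measurement noise.
#'   \item Gene panel: per-sample abundance = overall level (linear in the
#'     latent catabolic score) times a composition whose Pielou evenness
#'     tracks the latent gene-evenness facet, with lognormal noise.
#'   \item MicroResp CO2 matrix: a 14-substrate profile whose Pielou
#'     evenness tracks latent SIR efficiency, with the oxalic-acid and
#'     alanine responses adjusted so their difference is linear in latent
#'     SIR range; lognormal noise, floored at zero.
#'   \item Respiration and active biomass: linear in their latents plus
#'     Gaussian measurement noise, floored at small positive values.
#' }
#'
#' @param latents latent facet table from [generate_facets()].
#' @param params a [generator_params()].
#' @param seed integer seed (defaults to `params$seed`).
#' @return list with elements `asv_bacteria`, `asv_fungi` (taxa x samples
#'   integer matrices), `plfa` (markers x samples), `genes` (genes x
#'   samples), `catabolic` (logical per gene), `microresp` (substrates x
#'   samples), `active_biomass`, `respiration` (named vectors).
#' @export
generate_observations <- function(latents, params = generator_params(),
                                  seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(seed)) seed <- params$seed
  samples <- latents$sample
  n <- length(samples)
  z <- function(v) stats::setNames(latents[[v]], samples)

  # --- communities ---------------------------------------------------------
  set.seed(derive_seed(seed, 31L))
  asv_bac <- generate_asv_matrix(z("bac_div"), params$n_taxa_bacteria,
                                 params$depth_bacteria, params$asv_kappa,
                                 params$shannon_base[["bacteria"]],
                                 params$shannon_slope[["bacteria"]], "bASV")
  set.seed(derive_seed(seed, 32L))
  asv_fun <- generate_asv_matrix(z("fun_div"), params$n_taxa_fungi,
                                 params$depth_fungi, params$asv_kappa,
                                 params$shannon_base[["fungi"]],
                                 params$shannon_slope[["fungi"]], "fASV")

  # --- PLFA ----------------------------------------------------------------
  set.seed(derive_seed(seed, 33L))
  map <- plfa_marker_map()
  total <- pmax(120 + 25 * z("total_biomass"), 5)       # nmol / g dry soil
  bf <- exp(log(6) + 0.35 * z("bf_ratio"))              # B:F ratio
  other_frac <- pmin(pmax(0.08 * exp(stats::rnorm(n, 0, 0.10)), 0.01), 0.5)
  bac_sum <- (1 - other_frac) * total * bf / (1 + bf)
  fun_sum <- (1 - other_frac) * total / (1 + bf)
  oth_sum <- other_frac * total
  kingdoms <- split(map$marker, map$kingdom)
  weights <- lapply(kingdoms, function(mk) {
    w <- seq(2, 1, length.out = length(mk)); w / sum(w)
  })
  plfa <- matrix(0, nrow(map), n, dimnames = list(map$marker, samples))
  fill <- function(markers, w, totals) {
    for (j in seq_len(n)) {
      e <- exp(stats::rnorm(length(markers), 0, params$plfa_noise))
      plfa[markers, j] <<- totals[j] * (w * e) / sum(w * e)
    }
  }
  fill(kingdoms$bacteria, weights$bacteria, bac_sum)
  fill(kingdoms$fungi, weights$fungi, fun_sum)
  fill(kingdoms$other, weights$other, oth_sum)
  # instrument-level noise on each marker (not renormalized)
  plfa <- plfa * exp(matrix(stats::rnorm(length(plfa), 0, params$plfa_noise),
                            nrow(plfa)))

  # --- functional-gene panel ----------------------------------------------
  set.seed(derive_seed(seed, 34L))
  n_genes <- 24
  gene_names <- sprintf("gene%02d", seq_len(n_genes))
  catabolic <- stats::setNames(seq_len(n_genes) <= 16, gene_names)
  level <- pmax(1 + 0.30 * z("cata_score"), 0.2)
  j_target <- pmin(pmax(0.82 + 0.05 * z("fg_evenness"), 0.30), 0.995)
  h_target <- j_target * log(n_genes)
  gamma <- gamma_for_shannon(n_genes, h_target)
  genes <- matrix(0, n_genes, n, dimnames = list(gene_names, samples))
  for (j in seq_len(n)) {
    comp <- geometric_profile(n_genes, gamma[j])
    genes[, j] <- 1e7 * level[j] * comp * n_genes *
      exp(stats::rnorm(n_genes, 0, params$gene_noise))
  }

  # --- MicroResp -----------------------------------------------------------
  set.seed(derive_seed(seed, 35L))
  subs <- microresp_substrates()
  ns <- nrow(subs)
  j_sir <- pmin(pmax(0.80 + 0.06 * z("sir_efficiency"), 0.05), 0.999)
  gamma_sir <- gamma_for_shannon(ns, j_sir * log(ns))
  rng_target <- 1.2 + 0.35 * z("sir_range")
  microresp <- matrix(0, ns, n, dimnames = list(subs$substrate, samples))
  iox <- match("oxalic acid", subs$substrate)
  ial <- match("alanine", subs$substrate)
  for (j in seq_len(n)) {
    v <- 3 * ns * geometric_profile(ns, gamma_sir[j])   # mean level 3
    m <- (v[iox] + v[ial]) / 2
    v[iox] <- m + rng_target[j] / 2
    v[ial] <- m - rng_target[j] / 2
    v <- v * exp(stats::rnorm(ns, 0, params$microresp_noise))
    microresp[, j] <- pmax(v, 0.01)
  }

  # --- respiration & active biomass ---------------------------------------
  set.seed(derive_seed(seed, 36L))
  active <- pmax(60 + 12 * z("active_biomass") + stats::rnorm(n, 0, 1.2), 1)
  resp <- pmax(2 + 0.4 * z("respiration") + stats::rnorm(n, 0, 0.04), 0.01)

  list(asv_bacteria = asv_bac, asv_fungi = asv_fun,
       plfa = plfa, genes = genes, catabolic = catabolic,
       microresp = microresp,
       active_biomass = stats::setNames(active, samples),
       respiration = stats::setNames(resp, samples))
}
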