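#' Generate per-sample soil-chemistry measurements
#'
#' Draws a latent multivariate-normal vector per sample with the
#' covariance in `params$exogenous_covariance` (scaled by
#' `params$soil_noise_scale`), then maps each latent linearly onto a
#' realistic measurement scale, flooring or clipping only where physics
#' demands it (concentrations > 0, pH in [3, 9], relative humidity in
#' (0, 1)). The maps are linear so sample correlations reproduce the
#' specified covariance structure as n grows.
#'
#' @param design a design table from [generate_design()].
#' @param params a [generator_params()].
#' @param seed integer seed (defaults to the seed in `params`).
#' @return data.frame with columns `sample`, `toc`, `tn`, `tp` (g/kg),
#'   `ph`, `humidity`; attribute `latents` holds the underlying
#'   standard-normal draws.
#' @export
generate_soil_chemistry <- function(design, params = generator_params(),
                                    seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(seed)) seed <- params$seed
  n <- nrow(design)
  Cov <- params$exogenous_covariance * params$soil_noise_scale^2
  ev <- eigen(params$exogenous_covariance, symmetric = TRUE)
  if (min(ev$values) <= 0)
    stop("exogenous_covariance must be positive definite", call. = FALSE)
  set.seed(seed)
  Z0 <- matrix(stats::rnorm(n * 5), n, 5)
  L <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors) *
    params$soil_noise_scale
  Z <- Z0 %*% L
  colnames(Z) <- c("toc", "tn", "tp", "ph", "humidity")
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  out <- data.frame(
    sample = design$sample,
    toc = pmax(20 + 4.0 * Z[, "toc"], 0.5),
    tn = pmax(1.8 + 0.35 * Z[, "tn"], 0.05),
    tp = pmax(0.45 + 0.08 * Z[, "tp"], 0.02),
    ph = clip(5.0 + 0.45 * Z[, "ph"], 3, 9),
    humidity = clip(0.30 + 0.06 * Z[, "humidity"], 0.01, 0.99),
    stringsAsFactors = FALSE)
  attr(out, "latents") <- Z
  out
}
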