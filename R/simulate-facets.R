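#' Generate the latent microbial facet table
#'
#' Evaluates the structural equations of the generating causal model on
#' standardized scales: each latent facet is the linear combination of its
#' parents (tree richness, soil-chemistry variables, upstream facets)
#' weighted by the standardized structural coefficients, plus Gaussian
#' disturbance. Disturbances across facets follow
#' `params$disturbance_correlations`. With `noise_sd = NULL` (default)
#' each disturbance SD is calibrated so the facet has unit variance, which
#' keeps generating coefficients on the same scale as downstream
#' standardized estimates; an explicit named `noise_sd` vector overrides
#' this (0 gives the noiseless limit where facets equal their linear
#' predictors exactly).
#'
#' @param design design table (`sample`, `plot`, `richness`).
#' @param soil_chem soil-chemistry table from [generate_soil_chemistry()].
#' @param params a [generator_params()].
#' @param seed integer seed (defaults to `params$seed`).
#' @return data.frame `sample` plus one standardized column per facet
#'   (see `soilfacets:::facet_variables()`); this is the ground truth
#'   retained for recovery testing.
#' @export
generate_facets <- function(design, soil_chem, params = generator_params(),
                            seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(seed)) seed <- params$seed
  n <- nrow(design)
  sc <- params$structural_coefficients

  # standardized driver scores as the analysis will see them
  rich <- if (params$log_richness) log(design$richness) else design$richness
  std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  drivers <- data.frame(
    tree_richness = std(rich),
    toc = std(soil_chem$toc), tn = std(soil_chem$tn), tp = std(soil_chem$tp),
    ph = std(soil_chem$ph), humidity = std(soil_chem$humidity),
    cn = std(soil_chem$toc / soil_chem$tn),
    cp = std(soil_chem$toc / soil_chem$tp))

  facets <- facet_variables()
  bad <- setdiff(unique(sc$target), facets)
  if (length(bad))
    stop("structural target(s) are not facets: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad_src <- setdiff(unique(sc$source), c(facets, names(drivers)))
  if (length(bad_src))
    stop("structural source(s) unknown: ",
         paste(bad_src, collapse = ", "), call. = FALSE)

  # correlated disturbances, one column per facet
  R <- diag(length(facets))
  dimnames(R) <- list(facets, facets)
  dc <- params$disturbance_correlations
  if (nrow(dc)) for (k in seq_len(nrow(dc))) {
    R[dc$a[k], dc$b[k]] <- R[dc$b[k], dc$a[k]] <- dc$cor[k]
  }
  evR <- eigen(R, symmetric = TRUE)
  if (min(evR$values) <= 0)
    stop("disturbance correlation matrix not positive definite", call. = FALSE)
  set.seed(derive_seed(seed, 2L))
  E <- matrix(stats::rnorm(n * length(facets)), n) %*%
    (evR$vectors %*% diag(sqrt(evR$values)) %*% t(evR$vectors))
  colnames(E) <- facets

  # facets in topological order; upstream facets feed downstream equations
  order <- intersect(
    topo_order(unique(c(sc$source, sc$target, facets)),
               sc[, c("source", "target")]),
    facets)
  vals <- matrix(0, n, length(facets), dimnames = list(NULL, facets))
  for (v in order) {
    rows <- sc[sc$target == v, , drop = FALSE]
    pred <- rep(0, n)
    for (k in seq_len(nrow(rows))) {
      s <- rows$source[k]
      x <- if (s %in% facets) vals[, s] else drivers[[s]]
      pred <- pred + rows$coefficient[k] * x
    }
    s_eps <- if (!is.null(params$noise_sd) && v %in% names(params$noise_sd)) {
      params$noise_sd[[v]]
    } else if (nrow(rows) == 0) {
      1
    } else {
      # unit-variance calibration: disturbance absorbs unexplained variance
      vp <- stats::var(pred)
      sqrt(max(1 - if (is.finite(vp)) vp else 0, 0.05))
    }
    vals[, v] <- pred + s_eps * E[, v]
  }
  out <- data.frame(sample = design$sample, vals, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
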