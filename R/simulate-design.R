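#' Configure the experimental design to simulate
#'
#' The default emulates the sampled layout of a large forest
#' biodiversity-ecosystem-functioning experiment: 150 soil samples spread
#' over 52 plots spanning a tree species-richness gradient of 1, 2, 4, 8,
#' 16 and 24 species per plot.
#'
#' @param n_plots number of plots.
#' @param richness_levels set of tree species-richness levels; each plot
#'   gets exactly one level.
#' @param n_samples total number of samples (`>= n_plots`; every plot
#'   receives at least one sample).
#' @param seed integer seed.
#' @return object of class `design_config` (a validated list).
#' @export
design_config <- function(n_plots = 52,
                          richness_levels = c(1, 2, 4, 16, 8, 24),
                          n_samples = 150,
                          seed = 1L) {
  n_plots <- check_count(n_plots, "n_plots")
  n_samples <- check_count(n_samples, "n_samples")
  if (!length(richness_levels) || any(richness_levels < 1))
    stop("richness_levels must be positive integers", call. = FALSE)
  if (n_samples < n_plots)
    stop("need n_samples >= n_plots", call. = FALSE)
  structure(list(n_plots = n_plots,
                 richness_levels = sort(unique(as.integer(richness_levels))),
                 n_samples = n_samples, seed = as.integer(seed)),
            class = "design_config")
}

#' Generate the sample-to-plot-to-richness design table
#'
#' Assigns richness levels to plots by cycling through the levels (so the
#' gradient is covered as evenly as the plot count allows) in randomized
#' plot order, then allocates samples to plots approximately evenly, with
#' the remainder going to randomly chosen plots. Deterministic given the
#' seed in `config`.
#'
#' @param config a [design_config()].
#' @return data.frame with columns `sample`, `plot`, `richness`; one row
#'   per sample, every sample in exactly one plot.
#' @export
generate_design <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  set.seed(config$seed)
  np <- config$n_plots; ns <- config$n_samples
  levels <- config$richness_levels
  plot_richness <- rep_len(levels, np)[sample.int(np)]
  base <- ns %/% np
  extra <- ns %% np
  per_plot <- rep(base, np)
  if (extra > 0) {
    lucky <- sample.int(np, extra)
    per_plot[lucky] <- per_plot[lucky] + 1L
  }
  plot_ids <- sprintf("plot%02d", seq_len(np))
  out <- data.frame(
    sample = sprintf("s%03d", seq_len(ns)),
    plot = rep(plot_ids, per_plot),
    richness = rep(plot_richness, per_plot),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
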