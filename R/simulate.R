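#' Simulate a complete synthetic dataset
#'
#' Runs the whole generator: design table, soil chemistry, latent facet
#' table (the ground truth), and the observation battery. Identical
#' `(config, params, seed)` give byte-identical datasets.
#'
#' @param config a [design_config()].
#' @param params a [generator_params()].
#' @param seed master seed; overrides the seeds stored in `config` and
#'   `params` when given.
#' @return object of class `sf_dataset`: list with `design`, `soil`,
#'   `latents`, the battery elements of [generate_observations()], and
#'   the `config`/`params` used.
#' @export
simulate_dataset <- function(config = design_config(),
                             params = generator_params(),
                             seed = NULL) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    params$seed <- as.integer(seed)
  }
  design <- generate_design(config)
  soil <- generate_soil_chemistry(design, params,
                                  seed = derive_seed(params$seed, 1L))
  latents <- generate_facets(design, soil, params,
                             seed = derive_seed(params$seed, 2L))
  obs <- generate_observations(latents, params,
                               seed = derive_seed(params$seed, 3L))
  structure(c(list(design = design, soil = soil, latents = latents),
              obs, list(config = config, params = params)),
            class = "sf_dataset")
}

#' @export
print.sf_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d samples, %d plots, richness levels %s\n",
              nrow(x$design), length(unique(x$design$plot)),
              paste(sort(unique(x$design$richness)), collapse = "/")))
  cat(sprintf("  ASVs: %d bacterial, %d fungal; %d PLFA markers; %d genes; %d substrates\n",
              nrow(x$asv_bacteria), nrow(x$asv_fungi), nrow(x$plfa),
              nrow(x$genes), nrow(x$microresp)))
  invisible(x)
}

#' Write a synthetic dataset as delimited text tables
#'
#' One TSV per measurement (design, soil, PLFA, genes, MicroResp, ASV
#' tables, respiration/active biomass) plus a JSON sidecar with the
#' ground-truth latents and the generator parameters.
#'
#' @param data an `sf_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "sf_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wm <- function(m, f, id) {
    df <- data.frame(rownames(m), m, check.names = FALSE)
    names(df)[1] <- id
    w(df, f)
  }
  w(data$design, "design.tsv")
  w(data$soil, "soil.tsv")
  w(data$latents, "latents.tsv")
  wm(data$asv_bacteria, "asv_bacteria.tsv", "asv")
  wm(data$asv_fungi, "asv_fungi.tsv", "asv")
  wm(data$plfa, "plfa.tsv", "marker")
  wm(data$genes, "genes.tsv", "gene")
  wm(data$microresp, "microresp.tsv", "substrate")
  w(data.frame(sample = names(data$respiration),
               respiration = data$respiration,
               active_biomass = data$active_biomass[names(data$respiration)]),
    "respiration.tsv")
  w(data.frame(gene = names(data$catabolic), catabolic = data$catabolic),
    "gene_catabolic_map.tsv")
  sidecar <- list(
    seed = data$params$seed,
    structural_coefficients = data$params$structural_coefficients,
    disturbance_correlations = data$params$disturbance_correlations,
    design = list(n_plots = data$config$n_plots,
                  n_samples = data$config$n_samples,
                  richness_levels = data$config$richness_levels))
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir directory containing the TSV tables.
#' @return an `sf_dataset`-shaped list (without `config`/`params`).
#' @export
read_dataset <- function(dir) {
  r <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input table: ", f, call. = FALSE)
    utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
  }
  rm_ <- function(f, id) {
    df <- r(f)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  resp <- r("respiration.tsv")
  cat_map <- r("gene_catabolic_map.tsv")
  out <- list(
    design = r("design.tsv"),
    soil = r("soil.tsv"),
    asv_bacteria = rm_("asv_bacteria.tsv", "asv"),
    asv_fungi = rm_("asv_fungi.tsv", "asv"),
    plfa = rm_("plfa.tsv", "marker"),
    genes = rm_("genes.tsv", "gene"),
    catabolic = stats::setNames(as.logical(cat_map$catabolic), cat_map$gene),
    microresp = rm_("microresp.tsv", "substrate"),
    active_biomass = stats::setNames(resp$active_biomass, resp$sample),
    respiration = stats::setNames(resp$respiration, resp$sample))
  lat <- file.path(dir, "latents.tsv")
  if (file.exists(lat)) out$latents <- r("latents.tsv")
  class(out) <- "sf_dataset"
  out
}
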