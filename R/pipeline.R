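#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between the numeric columns of
#' `x`, with two-sided p-values. Constant columns give `NA` cells (with a
#' warning). The diagonal is exactly 1.
#'
#' @param x data.frame of numeric columns (non-numeric columns dropped).
#' @param min_pairs minimum number of complete pairs per cell.
#' @return list with matrices `r` and `p`.
#' @export
correlation_matrix <- function(x, min_pairs = 3) {
  x <- x[vapply(x, is.numeric, logical(1))]
  vars <- names(x)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  const <- vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(const))
    warning("constant column(s), correlations NA: ",
            paste(vars[const], collapse = ", "), call. = FALSE)
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    ok <- stats::complete.cases(x[[i]], x[[j]])
    if (sum(ok) < min_pairs || const[i] || const[j]) next
    ct <- stats::cor.test(x[[i]][ok], x[[j]][ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}

#' Run the full analysis end to end
#'
#' Orchestrates the whole pipeline on synthetic or file-based inputs:
#' (1) obtain the measurement battery, (2) compute the facet table,
#' (3) standardized linear models of every facet and function on tree
#' species richness, with functional-form comparison, (4) the
#' facet-correlation matrix, (5) stepwise-selected multivariate models of
#' each microbial function on the facets, with adjusted-R2 variance
#' partitioning among biomass/taxonomic/functional groups, and (6) the
#' facet-level path model with fit indices, effect decomposition and
#' group-level absolute-effect summaries. All outputs are written as
#' TSV/JSON under `out_dir`, together with a frozen copy of the resolved
#' configuration; identical seeds produce byte-identical bundles.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param mode `"synthetic"` (default) or `"files"`.
#' @param input_dir directory of input tables (mode `"files"`; the layout
#'   of [write_dataset()]).
#' @param config a [design_config()] (synthetic mode).
#' @param params a [generator_params()] (synthetic mode).
#' @param include_active_biomass set `FALSE` to re-run the whole analysis
#'   without the active-biomass facet (robustness replication).
#' @param rarefy_depth_bac,rarefy_depth_fun,scaling passed to
#'   [compute_facets()].
#' @param alpha significance level for effect summaries.
#' @return invisible list with every stage's results (`data`, `facets`,
#'   `richness_effects`, `correlations`, `function_models`, `varpart`,
#'   `sem`, `decomposition`, `group_effects`).
#' @export
run_full_analysis <- function(out_dir,
                              seed = 1L,
                              mode = c("synthetic", "files"),
                              input_dir = NULL,
                              config = design_config(),
                              params = generator_params(),
                              include_active_biomass = TRUE,
                              rarefy_depth_bac = 28897,
                              rarefy_depth_fun = 16542,
                              scaling = "minmax",
                              alpha = 0.05) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  data <- stage("data", {
    if (mode == "synthetic") simulate_dataset(config, params, seed = seed)
    else read_dataset(input_dir)
  })

  facets <- stage("facets", suppressWarnings(
    compute_facets(data, rarefy_depth_bac = rarefy_depth_bac,
                   rarefy_depth_fun = rarefy_depth_fun,
                   scaling = scaling, seed = derive_seed(seed, 4L))))
  w(facets, "facets.tsv")

  facet_cols <- c("total_biomass", "active_biomass", "bf_ratio",
                  "bac_div", "fun_div", "cata_score", "fg_evenness")
  if (!include_active_biomass)
    facet_cols <- setdiff(facet_cols, "active_biomass")
  fun_cols <- c("sir_efficiency", "sir_range", "respiration")

  richness <- stage("richness_effects", {
    rows <- lapply(c(facet_cols, fun_cols), function(v) {
      fit <- suppressMessages(
        fit_effect_model(facets[[v]], data.frame(richness = data$design$richness)))
      fc <- compare_functional_forms(facets[[v]], data$design$richness)
      co <- fit$coefficients[fit$coefficients$term == "richness", ]
      data.frame(response = v, estimate = co$estimate, se = co$se, p = co$p,
                 r_squared = fit$r_squared, aic = fit$aic,
                 chosen_form = attr(fc, "chosen"))
    })
    do.call(rbind, rows)
  })
  w(richness, "richness_effects.tsv")

  corr <- stage("correlations", correlation_matrix(facets[facet_cols]))
  w(data.frame(facet = rownames(corr$r), corr$r, check.names = FALSE),
    "facet_correlations.tsv")

  groups <- list(biomass = intersect(c("total_biomass", "active_biomass"),
                                     facet_cols),
                 taxonomic = c("bf_ratio", "bac_div", "fun_div"),
                 functional = c("cata_score", "fg_evenness"))
  fm <- stage("function_models", {
    lapply(stats::setNames(fun_cols, fun_cols), function(resp) {
      sel <- suppressMessages(
        stepwise_select(facets[[resp]], facets[facet_cols]))
      gsel <- lapply(groups, intersect, sel$selected)
      y <- as.numeric(rescale_two_sd(facets[[resp]], resp))
      vp <- suppressWarnings(partition_three_groups(
        y, facets[gsel$biomass], facets[gsel$taxonomic],
        facets[gsel$functional], labels = names(groups)))
      list(selection = sel, varpart = vp)
    })
  })
  fm_tab <- do.call(rbind, lapply(names(fm), function(resp) {
    co <- fm[[resp]]$selection$fit$coefficients
    co <- co[co$term != "(Intercept)", , drop = FALSE]
    if (!nrow(co)) return(NULL)
    data.frame(response = resp, co,
               adj_r_squared = fm[[resp]]$selection$fit$adj_r_squared)
  }))
  w(fm_tab, "function_models.tsv")
  vp_tab <- do.call(rbind, lapply(names(fm), function(resp) {
    vp <- fm[[resp]]$varpart
    data.frame(response = resp, fraction = names(vp$fractions),
               value = unname(vp$fractions), full = vp$full)
  }))
  w(vp_tab, "varpart.tsv")

  sem <- stage("sem", {
    spec <- facet_model_spec(minimal = TRUE)
    if (!include_active_biomass) {
      edges <- spec$edges[spec$edges$source != "active_biomass" &
                            spec$edges$target != "active_biomass", ]
      groups2 <- lapply(spec$groups, setdiff, "active_biomass")
      spec <- path_spec(edges, groups = groups2[vapply(groups2, length,
                                                       integer(1)) > 0])
    }
    dat <- facets[, intersect(spec$variables, names(facets)), drop = FALSE]
    fit_path_model(spec, dat)
  })
  w(sem$paths, "sem_paths.tsv")
  idx <- sem_fit_indices(sem)

  decomp <- stage("effects", decompose_effects(sem, alpha = alpha))
  w(as.data.frame(decomp), "sem_effects.tsv")
  ge <- group_effect_summary(decomp, sem$spec$groups, "respiration")
  w(ge, "sem_group_effects.tsv")

  provenance <- list(
    seed = seed, mode = mode,
    include_active_biomass = include_active_biomass,
    rarefy_depth_bac = rarefy_depth_bac, rarefy_depth_fun = rarefy_depth_fun,
    scaling = scaling, alpha = alpha,
    n_samples = nrow(facets),
    design = if (mode == "synthetic")
      list(n_plots = config$n_plots, n_samples = config$n_samples,
           richness_levels = config$richness_levels) else input_dir,
    fit_indices = idx[c("chisq", "df", "rmsea", "cfi", "srmr")])
  jsonlite::write_json(provenance, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = data, facets = facets, richness_effects = richness,
                 correlations = corr, function_models = fm_tab,
                 varpart = vp_tab, sem = sem, fit_indices = idx,
                 decomposition = decomp, group_effects = ge))
}
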