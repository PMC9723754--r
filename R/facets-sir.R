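#' Default MicroResp substrate panel
#'
#' A representative panel of 14 carbon substrates from three chemical
#' classes (saccharides, amino acids, carboxylic acids), spanning molecular
#' weights 89-221 g/mol and mean carbon oxidation states -2..3, with oxalic
#' acid and alanine at the upper and lower oxidation extremes. The panel is
#' synthetic (assembled for the simulator and for documentation of the
#' index definitions), not a transcription of any particular assay plate.
#'
#' @return data.frame with columns `substrate`, `class`, `mw` (g/mol) and
#'   `c_oxidation_state`.
#' @export
microresp_substrates <- function() {
  data.frame(
    substrate = c("glucose", "fructose", "galactose", "xylose", "arabinose",
                  "alanine", "glutamine", "arginine", "cysteine",
                  "oxalic acid", "malic acid", "citric acid",
                  "ascorbic acid", "protocatechuic acid"),
    class = c(rep("saccharide", 5), rep("amino-acid", 4),
              rep("carboxylic-acid", 5)),
    mw = c(180, 180, 180, 150, 150, 89, 146, 174, 121,
           90, 134, 192, 176, 154),
    c_oxidation_state = c(0, 0, 0, 0, 0, -2, -0.4, -1, -0.7,
                          3, 1, 1, 0.7, 0.6),
    stringsAsFactors = FALSE
  )
}

#' Substrate-induced respiration efficiency
#'
#' The Pielou evenness of a sample's CO2 production across the substrate
#' panel: 1 when all substrates elicit equal respiration, 0 when a single
#' substrate accounts for all of it. A sample with zero total CO2 yields
#' `NA`.
#'
#' @param resp numeric matrix of CO2 production (ug CO2-C per g per h),
#'   substrates in rows, samples in columns.
#' @return named numeric vector of efficiencies in `[0, 1]`, one per sample.
#' @export
sir_efficiency <- function(resp) {
  resp <- as.matrix(resp)
  if (any(resp < 0)) stop("CO2 production must be non-negative", call. = FALSE)
  out <- apply(resp, 2, pielou_evenness)
  # one-hot columns: S = 1 means maximal unevenness, efficiency 0
  names(out) <- colnames(resp)
  out
}

#' Substrate-induced respiration response range
#'
#' The signed difference in CO2 production between two substrates at the
#' extremes of carbon oxidation state, by default oxalic acid (upper
#' extreme) minus alanine (lower extreme).
#'
#' @param resp CO2 matrix, substrates in rows, samples in columns.
#' @param upper,lower row names of the two reference substrates.
#' @return named numeric vector, `resp[upper, ] - resp[lower, ]`.
#' @export
sir_range <- function(resp, upper = "oxalic acid", lower = "alanine") {
  resp <- as.matrix(resp)
  for (s in c(upper, lower))
    if (!s %in% rownames(resp))
      stop(sprintf("substrate '%s' not present in the response matrix", s),
           call. = FALSE)
  resp[upper, ] - resp[lower, ]
}

#' Sensitivity of SIR indices to substrate selection
#'
#' Recomputes SIR efficiency (and, where both reference substrates are
#' retained, SIR range) on subsets of the substrate panel and reports the
#' Pearson correlation of each subset index with the full-panel index
#' across samples.
#'
#' Schemes: `"loo"` leaves each substrate out in turn; `"class"` drops one
#' chemical class at a time (requires `classes`); `"random"` draws `reps`
#' random subsets of size `k` (deterministic given `seed`).
#'
#' @param resp CO2 matrix, substrates in rows, samples in columns.
#' @param scheme subset scheme, see Details.
#' @param k,reps,seed size, number and seed of random subsets
#'   (`scheme = "random"` only).
#' @param classes optional character vector of chemical classes per
#'   substrate row (`scheme = "class"`).
#' @param upper,lower reference substrates for [sir_range()].
#' @return data.frame with one row per subset: `subset` (label),
#'   `n_substrates`, `cor_efficiency`, and `cor_range` (`NA` when a
#'   reference substrate is excluded).
#' @export
substrate_sensitivity <- function(resp,
                                  scheme = c("loo", "class", "random"),
                                  k = NULL, reps = 100, seed = 1L,
                                  classes = NULL,
                                  upper = "oxalic acid", lower = "alanine") {
  scheme <- match.arg(scheme)
  resp <- as.matrix(resp)
  n <- nrow(resp)
  full_eff <- sir_efficiency(resp)
  has_range <- all(c(upper, lower) %in% rownames(resp))
  full_rng <- if (has_range) sir_range(resp, upper, lower) else NULL

  subsets <- switch(scheme,
    loo = {
      s <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
      names(s) <- paste0("drop:", rownames(resp))
      s
    },
    class = {
      if (is.null(classes) || length(classes) != n)
        stop("scheme 'class' needs one class label per substrate", call. = FALSE)
      cl <- unique(classes)
      s <- lapply(cl, function(ci) which(classes != ci))
      names(s) <- paste0("drop-class:", cl)
      s
    },
    random = {
      if (is.null(k)) stop("scheme 'random' needs subset size k", call. = FALSE)
      k <- check_count(k, "k")
      set.seed(seed)
      s <- lapply(seq_len(reps), function(i) sort(sample(n, k)))
      names(s) <- paste0("random", seq_len(reps))
      s
    })

  rows <- lapply(names(subsets), function(nm) {
    idx <- subsets[[nm]]
    if (length(idx) < 2)
      stop("subset '", nm, "' leaves fewer than 2 substrates", call. = FALSE)
    sub <- resp[idx, , drop = FALSE]
    ce <- stats::cor(sir_efficiency(sub), full_eff)
    cr <- if (has_range && all(c(upper, lower) %in% rownames(sub)))
      stats::cor(sir_range(sub, upper, lower), full_rng) else NA_real_
    data.frame(subset = nm, n_substrates = length(idx),
               cor_efficiency = ce, cor_range = cr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Soil stoichiometric ratios
#'
#' Elementwise carbon-to-nitrogen and carbon-to-phosphorus ratios from
#' total organic carbon, total nitrogen and total phosphorus. A zero
#' denominator yields `NA` with a warning.
#'
#' @param toc,tn,tp numeric vectors of equal length.
#' @return data.frame with columns `cn` and `cp`.
#' @export
soil_stoichiometry <- function(toc, tn, tp) {
  stopifnot(length(toc) == length(tn), length(toc) == length(tp))
  if (any(tn == 0, na.rm = TRUE) || any(tp == 0, na.rm = TRUE))
    warning("zero TN or TP: corresponding ratio set to NA", call. = FALSE)
  data.frame(cn = ifelse(tn != 0, toc / tn, NA_real_),
             cp = ifelse(tp != 0, toc / tp, NA_real_))
}
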