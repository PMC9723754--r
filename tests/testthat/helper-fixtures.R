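# Small fixtures built in code; all randomness is seeded by the caller.

toy_counts <- function() {
  m <- matrix(c(5L, 3L, 2L,
                4L, 4L, 4L,
                10L, 0L, 0L), nrow = 3,
              dimnames = list(paste0("t", 1:3), c("mixed", "even", "mono")))
  m
}

toy_microresp <- function(n_samples = 6, seed = 42) {
  set.seed(seed)
  subs <- microresp_substrates()
  m <- matrix(stats::rexp(nrow(subs) * n_samples, rate = 0.5),
              nrow(subs), n_samples,
              dimnames = list(subs$substrate, paste0("s", seq_len(n_samples))))
  m
}

toy_plfa <- function(seed = 7) {
  set.seed(seed)
  map <- plfa_marker_map()
  m <- matrix(stats::runif(nrow(map) * 4, 1, 10), nrow(map), 4,
              dimnames = list(map$marker, paste0("s", 1:4)))
  m
}

# a small-but-complete synthetic dataset: tiny ASV pools and depths keep
# the tests fast while still exercising rarefaction
small_params <- function(...) {
  generator_params(n_taxa_bacteria = 150, n_taxa_fungi = 80,
                   depth_bacteria = 2000, depth_fungi = 1500,
                   shannon_base = c(bacteria = 4.2, fungi = 3.4),
                   shannon_slope = c(bacteria = 0.2, fungi = 0.25), ...)
}

small_dataset <- function(n = 80, seed = 1, params = small_params()) {
  simulate_dataset(design_config(n_plots = 20, n_samples = n, seed = seed),
                   params, seed = seed)
}

# printed-coefficient path table of the facet-level causal model
facet_path_table <- function() {
  sc <- facet_structural_coefficients()
  data.frame(source = sc$source, target = sc$target,
             estimate = sc$coefficient, p = 0)
}

facet_groups <- function() {
  list(biomass = c("total_biomass", "active_biomass"),
       taxonomic = c("bf_ratio", "bac_div", "fun_div"),
       functional = c("cata_score", "fg_evenness"),
       physiological = c("sir_efficiency", "sir_range"),
       respiration = "respiration")
}

# independent brute-force adjusted R2 via summary.lm, for varpart oracles
oracle_adj_r2 <- function(y, X) {
  X <- as.data.frame(X)
  if (ncol(X) == 0) return(0)
  summary(stats::lm(y ~ ., data = cbind(data.frame(y = y), X)))$adj.r.squared
}

# random DAG over k nodes with edge probability pr and U(-1,1) weights
random_dag_paths <- function(k, pr = 0.5) {
  nodes <- paste0("v", seq_len(k))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (stats::runif(1) < pr)
      rows[[length(rows) + 1L]] <- data.frame(
        source = nodes[i], target = nodes[j],
        estimate = stats::runif(1, -1, 1), p = 0)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
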